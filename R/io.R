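#' @importFrom stats chisq.test dnbinom median p.adjust quantile rlnorm
#'   rnbinom rnorm runif setNames wilcox.test
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

HIT_COLS <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read coding sequences and keep only their lengths
#'
#' Reads a FASTA file of coding sequences and returns one gene record per
#' sequence. Only the identifier (header token before the first whitespace)
#' and the sequence length are retained; the sequences themselves are
#' discarded, since all downstream computation needs lengths only.
#'
#' @param path Path to a FASTA file.
#' @param library Library label attached to every record, e.g. `"GC"` for the
#'   free-living alga or `"MR"` for the mixed ciliate library.
#' @return A data.frame with columns `gene_id`, `library`, `length_bp`.
#'   Duplicate identifiers and empty sequences are hard errors; an empty file
#'   yields an empty data.frame with a warning.
#' @export
read_fasta <- function(path, library = "GC") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(data.frame(gene_id = character(), library = character(),
                      length_bp = integer(), stringsAsFactors = FALSE))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate FASTA identifier(s): ", paste(unique(dup), collapse = ", "))
  len <- Biostrings::width(seqs)
  if (any(len == 0L))
    stop("empty sequence(s): ", paste(ids[len == 0L], collapse = ", "))
  data.frame(gene_id = ids, library = library, length_bp = as.integer(len),
             stringsAsFactors = FALSE)
}

#' Read a 12-column tabular homology hit file
#'
#' Parses the standard 12-column tab-separated hit table (query, subject,
#' percent identity, alignment length, mismatches, gap opens, query/subject
#' start/end, e-value, bit score). The column count is enforced exactly:
#' extra or missing columns are rejected with the offending line number, as
#' are unparseable numeric fields. Coordinates are 1-based inclusive and are
#' carried through but never used in computation.
#'
#' @param path Path to a headerless tab-separated hit table.
#' @return A data.frame with columns
#'   `qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols != 12L)
  if (length(bad) > 0L)
    stop("line ", bad[1L], ": expected 12 tab-separated columns, found ",
         ncols[bad[1L]])
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num_idx <- 3:12
  out <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                    stringsAsFactors = FALSE)
  for (j in num_idx) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L], ": cannot parse '",
           m[which(is.na(v))[1L], j], "' in column ", HIT_COLS[j],
           " as a number")
    out[[HIT_COLS[j]]] <- v
  }
  int_cols <- c("length", "mismatch", "gapopen", "qstart", "qend",
                "sstart", "send")
  for (cc in int_cols) out[[cc]] <- as.integer(out[[cc]])
  validate_hit_table(out)
  out
}

empty_hit_table <- function() {
  out <- data.frame(qseqid = character(), sseqid = character(),
                    stringsAsFactors = FALSE)
  for (cc in HIT_COLS[3:12]) out[[cc]] <- numeric()
  for (cc in c("length", "mismatch", "gapopen", "qstart", "qend",
               "sstart", "send")) out[[cc]] <- integer()
  out
}

validate_hit_table <- function(hits) {
  stopifnot(is.data.frame(hits), identical(names(hits), HIT_COLS))
  if (nrow(hits) == 0L) return(invisible(hits))
  if (any(hits$evalue < 0)) stop("negative e-value in hit table")
  if (any(!is.finite(hits$bitscore))) stop("non-finite bit score in hit table")
  if (any(hits$pident < 0 | hits$pident > 100))
    stop("percent identity outside [0, 100]")
  if (any(hits$qstart < 1L | hits$sstart < 1L))
    stop("alignment coordinates must be 1-based (>= 1)")
  if (any(hits$length < 1L)) stop("alignment length must be >= 1")
  if (any(hits$mismatch < 0L | hits$gapopen < 0L))
    stop("mismatch/gapopen counts must be non-negative")
  invisible(hits)
}

#' Construct a subject-to-taxon map
#'
#' Maps reference-database subject identifiers to taxon labels and declares
#' which labels are cryptophytes (the prey lineage whose best hits mark a
#' gene as kleptokaryon-derived) and which are ciliates (the host lineage,
#' used by the strict host-confirmation mode).
#'
#' @param subject_taxon Named character vector: `names()` are subject ids,
#'   values are taxon labels.
#' @param cryptophyte_labels Character vector of taxon labels counted as
#'   cryptophyte.
#' @param ciliate_labels Character vector of taxon labels counted as ciliate.
#'   Must be disjoint from `cryptophyte_labels`.
#' @return An object of class `taxon_map`.
#' @export
taxon_map <- function(subject_taxon, cryptophyte_labels,
                      ciliate_labels = character()) {
  if (is.null(names(subject_taxon)) || any(!nzchar(names(subject_taxon))))
    stop("subject_taxon must be a named character vector")
  overlap <- intersect(cryptophyte_labels, ciliate_labels)
  if (length(overlap) > 0L)
    stop("taxon label(s) listed as both cryptophyte and ciliate: ",
         paste(overlap, collapse = ", "))
  structure(list(subject_taxon = subject_taxon,
                 cryptophyte_labels = unique(as.character(cryptophyte_labels)),
                 ciliate_labels = unique(as.character(ciliate_labels))),
            class = "taxon_map")
}

#' Read a subject-to-taxon map from a TSV file
#'
#' Expects three tab-separated columns with a header: `subject_id`,
#' `taxon_label`, `group`, where `group` is one of `cryptophyte`, `ciliate`
#' or `other`.
#'
#' @param path Path to the TSV file.
#' @return A `taxon_map` object.
#' @export
read_taxon_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "taxon_label", "group")
  if (!all(need %in% names(df)))
    stop("taxon map must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(df$group), c("cryptophyte", "ciliate", "other"))
  if (length(bad) > 0L)
    stop("unknown taxon group(s): ", paste(bad, collapse = ", "))
  taxon_map(setNames(df$taxon_label, df$subject_id),
            cryptophyte_labels = unique(df$taxon_label[df$group == "cryptophyte"]),
            ciliate_labels = unique(df$taxon_label[df$group == "ciliate"]))
}

#' Construct a KO functional hierarchy
#'
#' Builds the gene-to-KO and KO-to-pathway-to-subcategory-to-category rollup
#' structure. Every pathway must sit under exactly one subcategory and every
#' subcategory under exactly one category; a pathway listed under two
#' subcategories is a hard error.
#'
#' @param gene_ko Data.frame with columns `gene_id`, `ko` (one row per
#'   assignment; a gene may carry several KOs).
#' @param hierarchy Data.frame with columns `ko`, `pathway`, `subcategory`,
#'   `category`.
#' @param analyzed_categories Optional character vector; when supplied, the
#'   hierarchy is restricted to pathways whose top-level category is in this
#'   set (the "analyzed-only" filter).
#' @return An object of class `ko_hierarchy` with elements `gene_to_kos`,
#'   `ko_to_pathways`, `pathway_to_subcategory`, `subcategory_to_category`.
#' @export
ko_hierarchy <- function(gene_ko, hierarchy, analyzed_categories = NULL) {
  stopifnot(all(c("gene_id", "ko") %in% names(gene_ko)),
            all(c("ko", "pathway", "subcategory", "category") %in%
                  names(hierarchy)))
  if (!is.null(analyzed_categories))
    hierarchy <- hierarchy[hierarchy$category %in% analyzed_categories, ,
                           drop = FALSE]
  ps <- unique(hierarchy[, c("pathway", "subcategory")])
  dup <- ps$pathway[duplicated(ps$pathway)]
  if (length(dup) > 0L)
    stop("pathway(s) listed under multiple subcategories: ",
         paste(unique(dup), collapse = ", "))
  sc <- unique(hierarchy[, c("subcategory", "category")])
  dup <- sc$subcategory[duplicated(sc$subcategory)]
  if (length(dup) > 0L)
    stop("subcategory(s) listed under multiple categories: ",
         paste(unique(dup), collapse = ", "))
  structure(list(
    gene_to_kos = split(gene_ko$ko, gene_ko$gene_id),
    ko_to_pathways = lapply(split(hierarchy$pathway, hierarchy$ko), unique),
    pathway_to_subcategory = setNames(ps$subcategory, ps$pathway),
    subcategory_to_category = setNames(sc$category, sc$subcategory)),
    class = "ko_hierarchy")
}

#' Read a KO hierarchy from gene-to-KO and hierarchy TSV files
#'
#' @param gene_ko_path TSV with header columns `gene_id`, `ko`. Genes never
#'   listed are retained downstream as unannotated.
#' @param hierarchy_path TSV with header columns `ko`, `pathway`,
#'   `subcategory`, `category`.
#' @param analyzed_categories Optional restriction to top-level categories,
#'   see [ko_hierarchy()].
#' @return A `ko_hierarchy` object.
#' @export
read_ko_hierarchy <- function(gene_ko_path, hierarchy_path,
                              analyzed_categories = NULL) {
  gene_ko <- read.delim(gene_ko_path, stringsAsFactors = FALSE)
  hierarchy <- read.delim(hierarchy_path, stringsAsFactors = FALSE)
  ko_hierarchy(gene_ko, hierarchy, analyzed_categories)
}

#' Assemble a per-gene count table joined with gene lengths
#'
#' @param counts Data.frame with columns `library`, `gene_id`, `count`.
#' @param genes Gene records as returned by [read_fasta()] (columns
#'   `gene_id`, `library`, `length_bp`). Genes present here but absent from
#'   `counts` receive count 0; a counted gene without a length is an error.
#' @return A data.frame with columns `library`, `gene_id`, `count`,
#'   `length_bp`, one row per gene record.
#' @export
count_table <- function(counts, genes) {
  stopifnot(all(c("library", "gene_id", "count") %in% names(counts)),
            all(c("gene_id", "library", "length_bp") %in% names(genes)))
  if (nrow(counts) > 0L) {
    if (any(counts$count < 0)) stop("negative read count")
    if (any(counts$count != round(counts$count)))
      stop("non-integer read count")
  }
  gkey <- paste(genes$library, genes$gene_id, sep = "\r")
  if (anyDuplicated(gkey))
    stop("duplicate (library, gene_id) in gene records")
  ckey <- paste(counts$library, counts$gene_id, sep = "\r")
  if (anyDuplicated(ckey))
    stop("duplicate (library, gene_id) in count rows")
  orphan <- !(ckey %in% gkey)
  if (any(orphan))
    stop("counted gene(s) without a length: ",
         paste(counts$gene_id[orphan][seq_len(min(5, sum(orphan)))],
               collapse = ", "))
  cnt <- counts$count[match(gkey, ckey)]
  cnt[is.na(cnt)] <- 0
  data.frame(library = genes$library, gene_id = genes$gene_id,
             count = as.integer(round(cnt)), length_bp = genes$length_bp,
             stringsAsFactors = FALSE)
}

#' Read a per-gene read-count TSV and join gene lengths
#'
#' @param path TSV with header columns `library`, `gene_id`, `count`. Counts
#'   are assumed derived upstream from properly paired reads at mapping
#'   quality >= 30; this function only validates that they are non-negative
#'   integers.
#' @param genes Gene records providing lengths, see [count_table()].
#' @return A count table data.frame.
#' @export
read_count_table <- function(path, genes) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("library", "gene_id", "count")
  if (!all(need %in% names(df)))
    stop("count table must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$count)) stop("non-numeric read count in ", path)
  count_table(df, genes)
}

#' Write a homogeneous result table to TSV with fixed precision
#'
#' Columns are written in their existing (deterministic) order with a header
#' line; numeric columns are rendered to 6 significant digits, so re-reading
#' with [read_results_tsv()] reproduces values to that precision.
#'
#' @param rows A data.frame of result rows, or a list of single-row
#'   data.frames sharing identical column names (mixed row types are an
#'   error).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_results_tsv <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows)) {
    if (length(rows) == 0L) stop("cannot infer columns from an empty list")
    nm <- lapply(rows, names)
    if (length(unique(vapply(nm, paste, "", collapse = "\r"))) != 1L)
      stop("mixed row types: rows do not share identical columns")
    rows <- do.call(rbind, rows)
  }
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- signif(out[[j]], 6)
      out[[j]] <- vapply(v, function(x) {
        if (is.na(x)) NA_character_ else format(x, digits = 6, trim = TRUE)
      }, "")
    }
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read back a result TSV written by [write_results_tsv()]
#'
#' @param path Path to the TSV file.
#' @return A data.frame with column types inferred.
#' @export
read_results_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
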