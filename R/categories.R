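units_for_kos <- function(kos, hier, level) {
  paths <- unique(unlist(hier$ko_to_pathways[kos], use.names = FALSE))
  paths <- paths[!is.na(paths)]
  if (level == "pathway") return(paths)
  unique(unname(hier$pathway_to_subcategory[paths]))
}

#' Roll annotated genes up to pathway or subcategory protein counts
#'
#' Each annotated gene contributes one protein to every unit (pathway or
#' subcategory) reachable through any of its KOs: a gene whose KOs span two
#' pathways counts once in each, but a gene with two KOs in the *same* unit
#' still counts once there. Genes without a KO are excluded.
#'
#' @param genes Gene records (columns `gene_id`, `library`); counts are per
#'   library.
#' @param hier A [ko_hierarchy()].
#' @param level `"subcategory"` or `"pathway"`.
#' @return A data.frame with columns `unit_id`, `level`, `library`,
#'   `n_proteins`, covering every unit of the hierarchy in every library
#'   (zero-count units included).
#' @export
rollup_protein_counts <- function(genes, hier,
                                  level = c("subcategory", "pathway")) {
  level <- match.arg(level)
  stopifnot(inherits(hier, "ko_hierarchy"))
  all_units <- if (level == "pathway") names(hier$pathway_to_subcategory)
               else unique(unname(hier$pathway_to_subcategory))
  libs <- sort(unique(genes$library))
  out <- list()
  for (lib in libs) {
    g <- genes$gene_id[genes$library == lib]
    tally <- setNames(integer(length(all_units)), all_units)
    kos_list <- hier$gene_to_kos[g]
    for (kos in kos_list) {
      if (is.null(kos)) next
      u <- units_for_kos(kos, hier, level)
      u <- u[u %in% all_units]
      tally[u] <- tally[u] + 1L
    }
    out[[lib]] <- data.frame(unit_id = all_units, level = level,
                             library = lib, n_proteins = unname(tally),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Collapse each library to one representative gene per KO
#'
#' Removes within-library redundancy (isoforms, paralogs, alleles or
#' assembly artefacts) by keeping, per library and KO, the gene with the
#' highest read count; ties go to the lexicographically smallest gene id.
#' Genes with several KOs are kept if they are the representative of *any*
#' of their KOs. The operation is idempotent.
#'
#' @param genes Gene records (columns `gene_id`, `library`).
#' @param hier A [ko_hierarchy()].
#' @param counts Count table supplying per-library read counts.
#' @return The subset of `genes` retained after deduplication (unannotated
#'   genes are retained untouched).
#' @export
dedupe_by_ko <- function(genes, hier, counts) {
  stopifnot(inherits(hier, "ko_hierarchy"))
  ckey <- paste(counts$library, counts$gene_id, sep = "\r")
  keep <- logical(nrow(genes))
  for (lib in unique(genes$library)) {
    in_lib <- which(genes$library == lib)
    g <- genes$gene_id[in_lib]
    kos_list <- hier$gene_to_kos[g]
    ann <- !vapply(kos_list, is.null, TRUE)
    keep[in_lib[!ann]] <- TRUE  # unannotated genes pass through
    if (!any(ann)) next
    long <- data.frame(
      gene_id = rep(g[ann], lengths(kos_list[ann])),
      ko = unlist(kos_list[ann], use.names = FALSE),
      stringsAsFactors = FALSE)
    long <- unique(long)
    cnt <- counts$count[match(paste(lib, long$gene_id, sep = "\r"), ckey)]
    cnt[is.na(cnt)] <- 0
    ord <- order(long$ko, -cnt, long$gene_id, method = "radix")
    long <- long[ord, , drop = FALSE]
    reps <- unique(long$gene_id[!duplicated(long$ko)])
    keep[in_lib[ann]] <- g[ann] %in% reps
  }
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Combine transcript reads per KO and normalise by summed length
#'
#' For one library, the reads of all transcripts assigned to the same KO are
#' summed and divided by the summed transcript length, giving a per-KO
#' reads-per-base-pair value. KOs with no transcript in the library are
#' flagged `present = FALSE` (rendered `"NP"` in exports) — distinct from a
#' present transcript with zero reads. A log10 display value is emitted for
#' present KOs with positive reads.
#'
#' @param counts Count table (columns `library`, `gene_id`, `count`,
#'   `length_bp`).
#' @param hier A [ko_hierarchy()].
#' @param library Which library of `counts` to summarise.
#' @return A data.frame with columns `ko_id`, `library`, `total_reads`,
#'   `total_length_bp`, `reads_per_bp`, `present`, `log10_rpbp` covering
#'   every KO in the hierarchy.
#' @export
ko_level_expression <- function(counts, hier, library) {
  stopifnot(inherits(hier, "ko_hierarchy"))
  cc <- counts[counts$library == library, , drop = FALSE]
  kos_list <- hier$gene_to_kos[cc$gene_id]
  ann <- !vapply(kos_list, is.null, TRUE)
  all_kos <- sort(unique(names(hier$ko_to_pathways)))
  reads <- setNames(numeric(length(all_kos)), all_kos)
  lens <- setNames(numeric(length(all_kos)), all_kos)
  if (any(ann)) {
    long <- data.frame(
      i = rep(which(ann), lengths(kos_list[ann])),
      ko = unlist(kos_list[ann], use.names = FALSE),
      stringsAsFactors = FALSE)
    long <- long[long$ko %in% all_kos, , drop = FALSE]
    long <- unique(long)
    r <- tapply(cc$count[long$i], long$ko, sum)
    l <- tapply(cc$length_bp[long$i], long$ko, sum)
    reads[names(r)] <- r
    lens[names(l)] <- l
  }
  present <- lens > 0
  rpbp <- ifelse(present, reads / pmax(lens, 1), NA_real_)
  data.frame(ko_id = all_kos, library = library,
             total_reads = unname(reads),
             total_length_bp = as.integer(unname(lens)),
             reads_per_bp = unname(rpbp),
             present = unname(present),
             log10_rpbp = unname(ifelse(present & reads > 0, log10(rpbp),
                                        NA_real_)),
             stringsAsFactors = FALSE)
}

#' Export a KO-by-library expression matrix with "NP" for absent KOs
#'
#' @param counts Count table.
#' @param hier A [ko_hierarchy()].
#' @param libraries Libraries to include as columns.
#' @return A data.frame with one row per KO and one character column per
#'   library holding the reads-per-bp value (6 significant digits) or
#'   `"NP"` when the KO has no transcript in that library.
#' @export
ko_expression_matrix <- function(counts, hier,
                                 libraries = unique(counts$library)) {
  cols <- lapply(libraries, function(lib) {
    ke <- ko_level_expression(counts, hier, lib)
    ifelse(ke$present, format(signif(ke$reads_per_bp, 6), trim = TRUE), "NP")
  })
  ke <- ko_level_expression(counts, hier, libraries[1L])
  out <- data.frame(ko_id = ke$ko_id, stringsAsFactors = FALSE)
  for (i in seq_along(libraries)) out[[libraries[i]]] <- cols[[i]]
  out
}
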