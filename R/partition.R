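#' Select the best homology hit per query
#'
#' For every query the hit with the smallest e-value is retained; ties are
#' broken by the largest bit score, then by the lexicographically smallest
#' subject id, so the result is invariant to row order. Self-hits (query id
#' equal to subject id) are dropped first: the reference database may contain
#' proteins derived from the query library itself.
#'
#' @param hits A hit-table data.frame as returned by [read_hit_table()].
#' @param exclude_self Drop rows with `qseqid == sseqid` before selection.
#' @return A data.frame with one row per query, same columns as `hits`.
#' @export
best_hit_per_query <- function(hits, exclude_self = TRUE) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) == 0L) return(hits)
  if (exclude_self) hits <- hits[hits$qseqid != hits$sseqid, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$qseqid), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign kleptokaryon versus host origin from best hits
#'
#' A gene is called kleptokaryon-derived (`KN`) when its best hit is to a
#' cryptophyte-labelled subject at an e-value at or below the threshold;
#' every other gene (non-cryptophyte best hit, hit above the threshold, or
#' no hit at all) is conservatively called host (`HOST`). In
#' `strict_ciliate` mode the summary additionally reports how many host
#' calls are *confirmed* host, i.e. have a ciliate best hit at or below the
#' threshold.
#'
#' @param best_hits One best hit per query, from [best_hit_per_query()].
#' @param taxa A [taxon_map()]. Every best-hit subject must resolve.
#' @param gene_ids Character vector of all genes in the library, including
#'   genes with no hit.
#' @param e_threshold E-value cutoff (default 1e-4).
#' @param mode `"default"` or `"strict_ciliate"`.
#' @return A list with `calls` (data.frame: `gene_id`, `origin`,
#'   `best_subject`, `best_taxon`, `best_evalue`, `best_bitscore`,
#'   `threshold`) and `summary` (data.frame: `threshold`, `mode`, `n_total`,
#'   `n_kn`, `n_host`, `fraction_kn`, and `n_confirmed_host` in strict mode).
#' @export
assign_origin <- function(best_hits, taxa, gene_ids, e_threshold = 1e-4,
                          mode = c("default", "strict_ciliate")) {
  mode <- match.arg(mode)
  stopifnot(inherits(taxa, "taxon_map"), is.character(gene_ids))
  if (!is.numeric(e_threshold) || e_threshold <= 0)
    stop("e_threshold must be a positive number")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (nrow(best_hits) > 0L) {
    unknown <- setdiff(best_hits$sseqid, names(taxa$subject_taxon))
    if (length(unknown) > 0L)
      stop("subject(s) missing from taxon map: ",
           paste(unknown[seq_len(min(5, length(unknown)))], collapse = ", "))
    extra <- setdiff(best_hits$qseqid, gene_ids)
    if (length(extra) > 0L)
      stop("hit query(s) not in the gene universe: ",
           paste(extra[seq_len(min(5, length(extra)))], collapse = ", "))
  }
  idx <- match(gene_ids, best_hits$qseqid)
  best_subject <- best_hits$sseqid[idx]
  best_evalue <- best_hits$evalue[idx]
  best_bitscore <- best_hits$bitscore[idx]
  best_taxon <- unname(taxa$subject_taxon[best_subject])
  is_crypto <- !is.na(best_taxon) & best_taxon %in% taxa$cryptophyte_labels
  kn <- is_crypto & !is.na(best_evalue) & best_evalue <= e_threshold
  calls <- data.frame(gene_id = gene_ids,
                      origin = ifelse(kn, "KN", "HOST"),
                      best_subject = best_subject,
                      best_taxon = best_taxon,
                      best_evalue = best_evalue,
                      best_bitscore = best_bitscore,
                      threshold = e_threshold,
                      stringsAsFactors = FALSE)
  n_total <- length(gene_ids)
  n_kn <- sum(kn)
  summary <- data.frame(threshold = e_threshold, mode = mode,
                        n_total = n_total, n_kn = n_kn,
                        n_host = n_total - n_kn,
                        fraction_kn = if (n_total > 0) n_kn / n_total else NA_real_,
                        stringsAsFactors = FALSE)
  if (mode == "strict_ciliate") {
    is_cil <- !is.na(best_taxon) & best_taxon %in% taxa$ciliate_labels
    summary$n_confirmed_host <-
      sum(!kn & is_cil & !is.na(best_evalue) & best_evalue <= e_threshold)
  }
  list(calls = calls, summary = summary)
}

#' Partition-fraction sensitivity sweep over e-value thresholds
#'
#' Applies [assign_origin()] at each threshold and collects the summaries.
#' Tightening the threshold can only shrink the kleptokaryon set, so
#' `fraction_kn` is non-increasing as thresholds decrease.
#'
#' @param hits Full hit table (best hits are recomputed once).
#' @param taxa A [taxon_map()].
#' @param gene_ids All genes in the library.
#' @param thresholds Numeric vector of positive e-value cutoffs.
#' @param mode Passed to [assign_origin()].
#' @return A data.frame of partition summaries, one row per threshold.
#' @export
threshold_sweep <- function(hits, taxa, gene_ids,
                            thresholds = c(1e-4, 1e-30),
                            mode = "default") {
  if (any(!is.finite(thresholds)) || any(thresholds <= 0))
    stop("thresholds must be positive numbers")
  best <- best_hit_per_query(hits)
  out <- lapply(thresholds, function(t)
    assign_origin(best, taxa, gene_ids, e_threshold = t, mode = mode)$summary)
  do.call(rbind, out)
}

#' Extract the kleptokaryon count table after partitioning
#'
#' Subsets the mixed-library rows of a count table to genes called `KN` and
#' relabels them, yielding the two-library (`GC` vs `KN`) table every
#' category-level comparison consumes.
#'
#' @param counts Count table (see [count_table()]) containing the mixed
#'   library and, typically, the `GC` library.
#' @param calls Origin calls from [assign_origin()].
#' @param mixed_library Label of the mixed library in `counts` (default
#'   `"MR"`).
#' @param kn_label Relabel for kleptokaryon rows (default `"KN"`).
#' @return The count table with mixed-library host rows dropped and
#'   kleptokaryon rows relabelled.
#' @export
partition_count_table <- function(counts, calls, mixed_library = "MR",
                                  kn_label = "KN") {
  kn_genes <- calls$gene_id[calls$origin == "KN"]
  keep <- counts$library != mixed_library |
    counts$gene_id %in% kn_genes
  out <- counts[keep, , drop = FALSE]
  out$library[out$library == mixed_library] <- kn_label
  rownames(out) <- NULL
  out
}
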