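#' Reciprocal best hits between two gene sets
#'
#' A pair (g, k) is formed when k is the best hit of g in the forward search
#' and g is the best hit of k in the reverse search, both at or below the
#' e-value threshold. Best hits and their ties are resolved exactly as in
#' [best_hit_per_query()], so the pairing is a deterministic partial
#' matching (each gene in at most one pair).
#'
#' @param fwd Hit table, queries from the first (GC) set against the second
#'   (KN) set.
#' @param rev Hit table in the converse direction.
#' @param e_threshold E-value cutoff applied to both directions.
#' @return A data.frame with columns `gc_gene`, `kn_gene`, `fwd_evalue`,
#'   `rev_evalue`.
#' @export
reciprocal_best_hits <- function(fwd, rev, e_threshold = 1e-4) {
  bf <- best_hit_per_query(fwd, exclude_self = FALSE)
  br <- best_hit_per_query(rev, exclude_self = FALSE)
  bf <- bf[bf$evalue <= e_threshold, , drop = FALSE]
  br <- br[br$evalue <= e_threshold, , drop = FALSE]
  if (nrow(bf) == 0L || nrow(br) == 0L)
    return(data.frame(gc_gene = character(), kn_gene = character(),
                      fwd_evalue = numeric(), rev_evalue = numeric(),
                      stringsAsFactors = FALSE))
  rev_best <- setNames(br$sseqid, br$qseqid)
  mutual <- !is.na(rev_best[bf$sseqid]) & rev_best[bf$sseqid] == bf$qseqid
  out <- data.frame(gc_gene = bf$qseqid[mutual],
                    kn_gene = bf$sseqid[mutual],
                    fwd_evalue = bf$evalue[mutual],
                    rev_evalue = br$evalue[match(bf$sseqid[mutual],
                                                 br$qseqid)],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gc_gene, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

norm_factors <- function(method, factor_gc, factor_kn,
                         effective_size_gc, effective_size_kn) {
  stopifnot(factor_gc > 0, factor_kn > 0,
            effective_size_gc > 0, effective_size_kn > 0)
  structure(list(method = method, factor_gc = factor_gc,
                 factor_kn = factor_kn,
                 effective_size_gc = effective_size_gc,
                 effective_size_kn = effective_size_kn),
            class = "norm_factors")
}

# Two-library TMM scale factor of `obs` against `ref` (log2 scale inside):
# genes zero in either library are excluded; 30 % of the M (log-ratio) tails
# and 5 % of the A (abundance) tails are trimmed; remaining M-values are
# averaged with inverse asymptotic binomial-variance weights.
tmm_pair_factor <- function(obs, ref, logratio_trim = 0.3, sum_trim = 0.05) {
  obs <- as.numeric(obs); ref <- as.numeric(ref)
  nO <- sum(obs); nR <- sum(ref)
  pos <- obs > 0 & ref > 0
  if (!any(pos)) stop("no gene positive in both libraries")
  o <- obs[pos]; r <- ref[pos]
  M <- log2((o / nO) / (r / nR))
  A <- (log2(o / nO) + log2(r / nR)) / 2
  v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * sum_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM &
          rank(A) >= loA & rank(A) <= hiA
  f <- sum(M[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values (TMM) normalisation factors for two libraries
#'
#' Estimates composition-corrected scale factors from the trimmed, weighted
#' mean of gene-wise log-ratios between the libraries. The reference library
#' is the one whose upper-quartile count fraction is nearer the mean upper
#' quartile; factors are rescaled to geometric mean 1 and effective library
#' sizes are `library size * factor`.
#'
#' @param counts_gc,counts_kn Aligned count vectors (typically over RBBH
#'   pairs); at least one gene must be positive in both.
#' @param logratio_trim,sum_trim Trim fractions for the M and A tails.
#' @return A `norm_factors` object (`method = "tmm"`).
#' @export
tmm_factors <- function(counts_gc, counts_kn, logratio_trim = 0.3,
                        sum_trim = 0.05) {
  stopifnot(length(counts_gc) == length(counts_kn))
  if (any(counts_gc < 0) || any(counts_kn < 0)) stop("negative counts")
  if (!any(counts_gc > 0 & counts_kn > 0))
    stop("no gene positive in both libraries")
  lib <- c(sum(counts_gc), sum(counts_kn))
  f75 <- c(upper_quartile_fraction(counts_gc),
           upper_quartile_fraction(counts_kn))
  ref <- if (median(f75) < 1e-20)
    which.max(c(sum(sqrt(counts_gc)), sum(sqrt(counts_kn))))
  else which.min(abs(f75 - mean(f75)))
  mats <- list(counts_gc, counts_kn)
  f <- vapply(1:2, function(i) {
    if (i == ref) 1 else tmm_pair_factor(mats[[i]], mats[[ref]],
                                         logratio_trim, sum_trim)
  }, 0)
  f <- f / exp(mean(log(f)))
  norm_factors("tmm", f[1L], f[2L], lib[1L] * f[1L], lib[2L] * f[2L])
}

# Upper-quartile count fraction over all genes (zeros included), used only
# to pick the TMM reference library.
upper_quartile_fraction <- function(x) {
  quantile(x, 0.75, type = 7, names = FALSE) / sum(x)
}

#' Median-of-ratios (size-factor) normalisation for two libraries
#'
#' Per library, the size factor is the median over genes of the count
#' divided by the gene's geometric mean across the two libraries; genes with
#' a zero geometric mean (zero in either library) are excluded. Factors are
#' rescaled to geometric mean 1 and effective sizes are placed on the
#' geometric-mean library-size scale so both normalisation methods are
#' interchangeable downstream.
#'
#' @param counts_gc,counts_kn Aligned count vectors; at least one gene must
#'   be positive in both.
#' @return A `norm_factors` object (`method = "median_ratio"`).
#' @export
median_ratio_factors <- function(counts_gc, counts_kn) {
  stopifnot(length(counts_gc) == length(counts_kn))
  if (any(counts_gc < 0) || any(counts_kn < 0)) stop("negative counts")
  counts_gc <- as.numeric(counts_gc); counts_kn <- as.numeric(counts_kn)
  pos <- counts_gc > 0 & counts_kn > 0
  if (!any(pos)) stop("no gene positive in both libraries")
  gm <- sqrt(counts_gc[pos] * counts_kn[pos])
  sf <- c(median(counts_gc[pos] / gm), median(counts_kn[pos] / gm))
  f <- sf / exp(mean(log(sf)))
  scale <- exp(mean(log(c(sum(counts_gc), sum(counts_kn)))))
  norm_factors("median_ratio", f[1L], f[2L], scale * f[1L], scale * f[2L])
}

#' Exact conditional negative-binomial test for two libraries, no replicates
#'
#' The two counts are rescaled to the geometric mean of the effective
#' library sizes and rounded; conditional on their sum `s`, the null
#' distribution over splits is `P(k | s) proportional to f(k) f(s - k)` with
#' `f` the negative-binomial mass with mean `s / 2` and the given
#' dispersion. The two-sided p-value sums `P(k | s)` over all `k` whose
#' probability does not exceed that of the observed split, capped at 1.
#'
#' @param y_gc,y_kn Observed counts.
#' @param eff_size_gc,eff_size_kn Positive effective library sizes.
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be > 0. The fixed default 0.3 stands in
#'   for unobservable biological variability in a no-replicate design.
#' @return The two-sided p-value.
#' @export
nb_exact_test <- function(y_gc, y_kn, eff_size_gc = 1, eff_size_kn = 1,
                          dispersion = 0.3) {
  if (y_gc < 0 || y_kn < 0) stop("negative counts")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (eff_size_gc <= 0 || eff_size_kn <= 0)
    stop("effective sizes must be > 0")
  common <- sqrt(eff_size_gc * eff_size_kn)
  y1 <- round(y_gc * common / eff_size_gc)
  y2 <- round(y_kn * common / eff_size_kn)
  s <- y1 + y2
  if (s == 0) return(1)
  size <- 1 / dispersion
  k <- 0:s
  logp <- dnbinom(k, size = size, mu = s / 2, log = TRUE) +
          dnbinom(s - k, size = size, mu = s / 2, log = TRUE)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  pobs <- pr[y1 + 1L]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

#' Normalised log2 fold change (KN over GC) with a pseudo-count prior
#'
#' `log2(((y_kn + prior) / eff_size_kn) / ((y_gc + prior) / eff_size_gc))`.
#' The prior keeps the ratio finite when either count is zero.
#'
#' @param y_gc,y_kn Observed counts.
#' @param factors A `norm_factors` object supplying effective sizes.
#' @param prior Positive pseudo-count (default 0.5).
#' @return The log2 fold change, KN relative to GC.
#' @export
log2_fold_change <- function(y_gc, y_kn, factors, prior = 0.5) {
  stopifnot(inherits(factors, "norm_factors"))
  if (prior <= 0) stop("prior must be > 0")
  log2(((y_kn + prior) / factors$effective_size_kn) /
       ((y_gc + prior) / factors$effective_size_gc))
}

#' Per-pair differential expression over reciprocal best hits
#'
#' Normalisation factors are estimated once over all pairs, then every pair
#' receives an exact conditional negative-binomial p-value at the fixed
#' dispersion and a normalised log2 fold change (KN over GC).
#' Benjamini-Hochberg adjustment runs across pairs, and each pair is
#' classified purely by the fold-change threshold: `over` when
#' `log2fc >= lfc_threshold`, `under` when `log2fc <= -lfc_threshold`,
#' otherwise `ns`.
#'
#' @param counts Count table containing both libraries.
#' @param pairs RBBH pairs (columns `gc_gene`, `kn_gene`), e.g. from
#'   [reciprocal_best_hits()]. Every pair must have counts in both
#'   libraries.
#' @param method Normalisation backend: `"tmm"` or `"median_ratio"`.
#' @param dispersion Fixed negative-binomial dispersion (default 0.3).
#' @param alpha FDR level for the `significant` flag.
#' @param lfc_threshold Fold-change class boundary (default 1, i.e. 2-fold).
#' @param prior Pseudo-count for the fold change.
#' @param libraries Length-2 vector naming the GC-side and KN-side library
#'   labels in `counts`.
#' @return A data.frame with one row per pair: counts, `log2fc`, `p_raw`,
#'   `p_adj`, `significant`, `klass`; the `norm_factors` used are attached
#'   as attribute `"norm_factors"` and the dispersion as `"dispersion"`.
#' @export
run_deg <- function(counts, pairs, method = c("tmm", "median_ratio"),
                    dispersion = 0.3, alpha = 0.05, lfc_threshold = 1,
                    prior = 0.5, libraries = c("GC", "KN")) {
  method <- match.arg(method)
  if (nrow(pairs) == 0L) stop("empty pair list")
  stopifnot(all(c("gc_gene", "kn_gene") %in% names(pairs)))
  gc_rows <- counts[counts$library == libraries[1L], , drop = FALSE]
  kn_rows <- counts[counts$library == libraries[2L], , drop = FALSE]
  ig <- match(pairs$gc_gene, gc_rows$gene_id)
  ik <- match(pairs$kn_gene, kn_rows$gene_id)
  if (anyNA(ig) || anyNA(ik))
    stop("pair gene(s) missing from the count table")
  y_gc <- gc_rows$count[ig]
  y_kn <- kn_rows$count[ik]
  factors <- switch(method,
                    tmm = tmm_factors(y_gc, y_kn),
                    median_ratio = median_ratio_factors(y_gc, y_kn))
  p_raw <- vapply(seq_along(y_gc), function(i)
    nb_exact_test(y_gc[i], y_kn[i], factors$effective_size_gc,
                  factors$effective_size_kn, dispersion), 0)
  log2fc <- log2_fold_change(y_gc, y_kn, factors, prior)
  p_adj <- bh_adjust(p_raw)
  klass <- ifelse(log2fc >= lfc_threshold, "over",
                  ifelse(log2fc <= -lfc_threshold, "under", "ns"))
  out <- data.frame(gc_gene = pairs$gc_gene, kn_gene = pairs$kn_gene,
                    y_gc = y_gc, y_kn = y_kn, log2fc = log2fc,
                    p_raw = p_raw, p_adj = p_adj,
                    significant = p_adj < alpha, klass = klass,
                    stringsAsFactors = FALSE)
  attr(out, "norm_factors") <- factors
  attr(out, "dispersion") <- dispersion
  out
}

#' Classify precomputed log2 fold changes by the class boundary
#'
#' Applies the `over` / `under` / `ns` classification used by [run_deg()]
#' to an existing vector of log2 fold changes, e.g. a published listing.
#'
#' @param log2fc Numeric vector.
#' @param lfc_threshold Class boundary (default 1).
#' @return Character vector of classes.
#' @export
classify_log2fc <- function(log2fc, lfc_threshold = 1) {
  ifelse(log2fc >= lfc_threshold, "over",
         ifelse(log2fc <= -lfc_threshold, "under", "ns"))
}
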