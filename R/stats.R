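#' Pearson chi-square test on a 2x2 contingency table
#'
#' Tests independence on the table `rbind(c(a, b), c(c, d))` (row 1 = GC
#' in/out of a unit, row 2 = KN in/out), with an optional Yates continuity
#' correction (default on, the conventional 2x2 default). A zero row or
#' column margin leaves the expected counts undefined and is an error.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param yates Apply the continuity correction.
#' @return A list with `chi2` and `p` (1 degree of freedom).
#' @export
chi_square_2x2 <- function(a, b, c, d, yates = TRUE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: expected counts are undefined")
  ht <- suppressWarnings(chisq.test(m, correct = yates))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Validated wrapper around the step-up false-discovery-rate adjustment:
#' output is order-preserving with the input, elementwise at least the raw
#' p, and capped at 1. `NA` entries are carried through untouched and do not
#' count toward the number of tests.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return The adjusted vector, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Length-normalised expression: reads per base pair
#'
#' @param count Non-negative read count(s).
#' @param length_bp Positive gene length(s) in bp.
#' @return `count / length_bp`.
#' @export
reads_per_bp <- function(count, length_bp) {
  if (any(length_bp < 1)) stop("length_bp must be >= 1")
  if (any(count < 0)) stop("count must be non-negative")
  count / length_bp
}

#' Mann-Whitney U test with explicit method control
#'
#' Computes the rank-sum statistic U for `x` (midranks under ties) and a
#' two-sided p-value: exact by enumeration when both samples are small
#' (min(n) <= 8) and tie-free, otherwise the normal approximation with tie
#' and continuity corrections. `U_x + U_y = n_x * n_y` always holds.
#'
#' @param x,y Non-empty numeric vectors.
#' @param method `"auto"` (the rule above), `"exact"` (error if ties) or
#'   `"normal"`.
#' @return A list with `U` (for `x`) and `p` (two-sided).
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (method == "exact" && ties)
    stop("exact method is undefined with ties")
  exact <- switch(method,
                  exact = TRUE,
                  normal = FALSE,
                  auto = min(nx, ny) <= 8 && !ties)
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))$p.value
  list(U = U, p = p)
}

#' Protein-count enrichment per functional unit
#'
#' For every unit (subcategory or pathway), tests whether the share of
#' annotated proteins falling in the unit differs between the two libraries
#' with a 2x2 chi-square ([chi_square_2x2()]), then adjusts across units by
#' Benjamini-Hochberg. The out-of-unit cell is `denominator - in-unit`;
#' the denominator is either the sum of unit counts over the analysed units
#' (`"category_sum"`, the default) or a supplied per-library total of
#' KO-annotated proteins (`"annotated_total"`).
#'
#' @param counts Rollup from [rollup_protein_counts()] containing exactly
#'   two libraries.
#' @param denominators `"category_sum"` or `"annotated_total"`.
#' @param annotated_totals Named numeric vector of per-library totals,
#'   required for `"annotated_total"`.
#' @param alpha FDR level for the `significant` flag.
#' @param yates Continuity correction, passed to [chi_square_2x2()].
#' @param libraries Length-2 character vector naming the reference library
#'   and the comparison library (direction is reported for the second, e.g.
#'   `over_in_KN`).
#' @return A data.frame with one row per unit: cell counts `a, b, c, d`,
#'   percentages, `chi2`, `p_raw`, `p_adj`, `direction`
#'   (`over_in_KN`/`under_in_KN`/`none`), `significant`.
#' @export
category_protein_enrichment <- function(counts,
                                        denominators = c("category_sum",
                                                         "annotated_total"),
                                        annotated_totals = NULL,
                                        alpha = 0.05, yates = TRUE,
                                        libraries = c("GC", "KN")) {
  denominators <- match.arg(denominators)
  stopifnot(length(libraries) == 2L)
  if (!all(libraries %in% counts$library))
    stop("counts must contain both libraries: ",
         paste(libraries, collapse = ", "))
  units <- unique(counts$unit_id)
  get <- function(lib) {
    cc <- counts[counts$library == lib, , drop = FALSE]
    v <- setNames(numeric(length(units)), units)
    v[cc$unit_id] <- cc$n_proteins
    v
  }
  n1 <- get(libraries[1L]); n2 <- get(libraries[2L])
  denom <- switch(denominators,
    category_sum = c(sum(n1), sum(n2)),
    annotated_total = {
      if (is.null(annotated_totals) ||
          !all(libraries %in% names(annotated_totals)))
        stop("annotated_totals must be named for both libraries")
      as.numeric(annotated_totals[libraries])
    })
  if (any(n1 > denom[1L]) || any(n2 > denom[2L]))
    stop("unit count exceeds its library denominator")
  chi2 <- p_raw <- numeric(length(units))
  for (i in seq_along(units)) {
    res <- chi_square_2x2(n1[i], denom[1L] - n1[i],
                          n2[i], denom[2L] - n2[i], yates = yates)
    chi2[i] <- res$chi2; p_raw[i] <- res$p
  }
  p_adj <- bh_adjust(p_raw)
  pct1 <- 100 * n1 / denom[1L]
  pct2 <- 100 * n2 / denom[2L]
  direction <- ifelse(pct2 > pct1, "over_in_KN",
                      ifelse(pct2 < pct1, "under_in_KN", "none"))
  data.frame(unit_id = units,
             a = unname(n1), b = denom[1L] - unname(n1),
             c = unname(n2), d = denom[2L] - unname(n2),
             pct_gc = unname(pct1), pct_kn = unname(pct2),
             chi2 = chi2, p_raw = p_raw, p_adj = p_adj,
             direction = direction,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

gene_rpbp_by_unit <- function(counts, hier, level, library,
                              drop_zero = FALSE) {
  cc <- counts[counts$library == library, , drop = FALSE]
  if (drop_zero) cc <- cc[cc$count > 0, , drop = FALSE]
  kos_list <- hier$gene_to_kos[cc$gene_id]
  ann <- which(!vapply(kos_list, is.null, TRUE))
  rows <- lapply(ann, function(i) {
    u <- units_for_kos(kos_list[[i]], hier, level)
    if (length(u) == 0L) return(NULL)
    data.frame(unit_id = u, gene_id = cc$gene_id[i],
               reads_per_bp = cc$count[i] / cc$length_bp[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(unit_id = character(), gene_id = character(),
                      reads_per_bp = numeric(), stringsAsFactors = FALSE)
  out$library <- library
  out
}

#' Long-format gene-level reads-per-bp table by functional unit
#'
#' The per-gene, per-unit expression values underlying the category
#' expression tests — the boxplot-ready long table (one row per gene per
#' unit per library).
#'
#' @param counts Count table.
#' @param hier A [ko_hierarchy()].
#' @param level `"subcategory"` or `"pathway"`.
#' @param libraries Libraries to include.
#' @param drop_zero Exclude genes with zero reads.
#' @return A data.frame with columns `unit_id`, `gene_id`, `reads_per_bp`,
#'   `library`.
#' @export
unit_expression_long <- function(counts, hier,
                                 level = c("subcategory", "pathway"),
                                 libraries = c("GC", "KN"),
                                 drop_zero = FALSE) {
  level <- match.arg(level)
  out <- do.call(rbind, lapply(libraries, function(lib)
    gene_rpbp_by_unit(counts, hier, level, lib, drop_zero)))
  rownames(out) <- NULL
  out
}

#' Category-level expression comparison by Mann-Whitney rank test
#'
#' For every unit at the chosen level, compares the gene-level
#' reads-per-base-pair vector of the first library against the second with
#' [mann_whitney_u()], adjusting across units of that level by
#' Benjamini-Hochberg. Units with no genes in either library are emitted
#' with `p = NA` and excluded from the adjustment. The per-library sums of
#' reads-per-bp are reported as the total-expression proxy.
#'
#' @param counts Count table containing both libraries.
#' @param hier A [ko_hierarchy()].
#' @param level `"subcategory"` or `"pathway"`.
#' @param alpha FDR level for the `significant` flag.
#' @param libraries Length-2 vector; direction is reported for the second.
#' @param drop_zero Exclude zero-count genes from the vectors.
#' @return A data.frame with one row per unit: `unit_id`, `level`, `n_gc`,
#'   `n_kn`, `sum_rpbp_gc`, `sum_rpbp_kn`, `U`, `p_raw`, `p_adj`,
#'   `direction`, `significant`.
#' @export
category_expression <- function(counts, hier,
                                level = c("subcategory", "pathway"),
                                alpha = 0.05, libraries = c("GC", "KN"),
                                drop_zero = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(hier, "ko_hierarchy"), length(libraries) == 2L)
  long <- unit_expression_long(counts, hier, level, libraries, drop_zero)
  units <- if (level == "pathway") names(hier$pathway_to_subcategory)
           else unique(unname(hier$pathway_to_subcategory))
  res <- lapply(units, function(u) {
    x <- long$reads_per_bp[long$unit_id == u & long$library == libraries[1L]]
    y <- long$reads_per_bp[long$unit_id == u & long$library == libraries[2L]]
    row <- data.frame(unit_id = u, level = level,
                      n_gc = length(x), n_kn = length(y),
                      sum_rpbp_gc = sum(x), sum_rpbp_kn = sum(y),
                      U = NA_real_, p_raw = NA_real_,
                      stringsAsFactors = FALSE)
    if (length(x) > 0L && length(y) > 0L) {
      mw <- mann_whitney_u(x, y)
      row$U <- mw$U
      row$p_raw <- mw$p
    }
    row
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_raw)
  half <- out$n_gc * out$n_kn / 2
  out$direction <- ifelse(is.na(out$U) | out$U == half, "none",
                          ifelse(out$U > half, "under_in_KN", "over_in_KN"))
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
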