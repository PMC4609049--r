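test_that("reciprocal best hits require mutual best matches", {
  # symmetric 2x2 structure: a<->x and b<->y are mutual bests
  fwd <- rbind(make_hits("a", "x", 1e-30), make_hits("a", "y", 1e-5),
               make_hits("b", "y", 1e-40), make_hits("b", "x", 1e-6))
  rev <- rbind(make_hits("x", "a", 1e-30), make_hits("x", "b", 1e-5),
               make_hits("y", "b", 1e-40), make_hits("y", "a", 1e-6))
  p <- reciprocal_best_hits(fwd, rev)
  expect_equal(p$gc_gene, c("a", "b"))
  expect_equal(p$kn_gene, c("x", "y"))

  # broken mutuality: fwd best a -> x but rev best x -> b
  rev2 <- rbind(make_hits("x", "b", 1e-50), make_hits("x", "a", 1e-30),
                make_hits("y", "b", 1e-40))
  p2 <- reciprocal_best_hits(fwd, rev2)
  expect_false("x" %in% p2$kn_gene)

  # threshold applies to both directions
  fwd3 <- make_hits("a", "x", 1e-30)
  rev3 <- make_hits("x", "a", 1e-3)
  expect_equal(nrow(reciprocal_best_hits(fwd3, rev3)), 0L)
})

test_that("RBBH matches an exhaustive double-loop oracle on random matrices", {
  set.seed(12)
  for (i in 1:20) {
    emat <- matrix(10^runif(36, -60, -2), 6, 6,
                   dimnames = list(sprintf("q%d", 1:6),
                                   sprintf("s%d", 1:6)))
    got <- reciprocal_best_hits(emat_to_hits(emat),
                                emat_to_hits(emat, transpose = TRUE))
    want <- rbbh_oracle(emat, 1e-4)
    expect_equal(got[, c("gc_gene", "kn_gene")],
                 want, ignore_attr = TRUE)
  }
})

test_that("normalisation factors are unit on identical or depth-scaled libraries", {
  set.seed(6)
  x <- rnbinom(300, mu = 200, size = 2) + 1L
  for (f in list(tmm_factors, median_ratio_factors)) {
    nf <- f(x, x)
    expect_equal(nf$factor_gc, 1)
    expect_equal(nf$factor_kn, 1)
  }
  # pure depth change: TMM factors stay 1 (depth lives in library size)
  nf <- tmm_factors(x, 2L * x)
  expect_equal(nf$factor_gc, 1, tolerance = 1e-10)
  expect_equal(nf$factor_kn, 1, tolerance = 1e-10)
  expect_equal(nf$effective_size_kn / nf$effective_size_gc, 2)
  # median-of-ratios absorbs the same scaling into the factors
  nf2 <- median_ratio_factors(x, 3L * x)
  expect_equal(nf2$factor_kn / nf2$factor_gc, 3)
  expect_equal(nf2$effective_size_kn / nf2$effective_size_gc, 3)

  expect_error(tmm_factors(c(0, 0, 5), c(3, 4, 0)), "positive in both")
})

test_that("median-of-ratios equals the hand-computed medians on a small case", {
  g <- c(10, 20, 30, 0, 50)
  k <- c(20, 10, 90, 5, 50)
  gm <- sqrt(g[-4] * k[-4])
  sf <- c(median(g[-4] / gm), median(k[-4] / gm))
  nf <- median_ratio_factors(g, k)
  expect_equal(nf$factor_kn / nf$factor_gc, sf[2] / sf[1], tolerance = 1e-12)
})

test_that("TMM agrees with the reference implementation on random fixtures", {
  skip_if_not_installed("edgeR")
  set.seed(42)
  for (i in 1:100) {
    n <- sample(50:200, 1)
    g <- rnbinom(n, mu = exp(runif(n, 1, 6)), size = 2)
    k <- rnbinom(n, mu = exp(runif(n, 1, 6)), size = 2)
    if (!any(g > 0 & k > 0)) next
    nf <- tmm_factors(g, k)
    ref <- edgeR::calcNormFactors(cbind(g, k), method = "TMM")
    expect_equal(c(nf$factor_gc, nf$factor_kn), unname(ref),
                 tolerance = 1e-6)
  }
})

test_that("median-of-ratios agrees with the reference size-factor estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(19)
  g <- rnbinom(300, mu = 150, size = 2)
  k <- rnbinom(300, mu = 90, size = 2)
  nf <- median_ratio_factors(g, k)
  sf <- DESeq2::estimateSizeFactorsForMatrix(cbind(g, k))
  expect_equal(nf$factor_gc / nf$factor_kn, unname(sf[1] / sf[2]),
               tolerance = 1e-8)
})

test_that("the exact NB test matches brute-force conditional enumeration", {
  # symmetric split: observed value is the modal split, p = 1
  expect_equal(nb_exact_test(20, 20), 1)

  # frozen example against the enumeration oracle
  expect_equal(nb_exact_test(10, 40, dispersion = 0.3),
               nb_oracle(10, 40, 0.3), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:50) {
    y1 <- sample(0:250, 1); y2 <- sample(0:250, 1)
    d <- runif(1, 0.05, 1)
    expect_equal(nb_exact_test(y1, y2, dispersion = d),
                 nb_oracle(y1, y2, d), tolerance = 1e-12)
  }

  # Poisson limit: conditional binomial exact test
  p_nb <- nb_exact_test(10, 40, dispersion = 1e-8)
  p_bin <- binom.test(10, 50, 0.5)$p.value
  expect_lt(abs(p_nb - p_bin), 1e-4)

  # effective sizes rescale the counts before conditioning
  expect_equal(nb_exact_test(10, 20, eff_size_gc = 1, eff_size_kn = 2),
               nb_exact_test(10, 10), tolerance = 1e-12)
  expect_error(nb_exact_test(-1, 5), "negative")
  expect_error(nb_exact_test(1, 5, dispersion = 0), "> 0")
})

test_that("log2 fold change applies the prior and the effective sizes", {
  nf <- tmm_factors(rep(10L, 50), rep(10L, 50))
  expect_equal(log2_fold_change(10, 10, nf), 0)
  expect_equal(log2_fold_change(0, 0, nf), 0)
  expect_equal(log2_fold_change(10, 40, nf), log2(40.5 / 10.5),
               tolerance = 1e-12)
  expect_equal(log2(40.5 / 10.5), 1.9475, tolerance = 1e-4)
})

test_that("run_deg classifies by fold change and controls the null error rate", {
  set.seed(61)
  n <- 300
  ids <- sprintf("g%04d", 1:n)
  base <- exp(rnorm(n, 4, 1))
  y_gc <- rnbinom(n, mu = base, size = 1 / 0.3)
  y_kn <- rnbinom(n, mu = base, size = 1 / 0.3)
  cts <- toy_counts(c(rep("GC", n), rep("KN", n)), c(ids, ids),
                    c(y_gc, y_kn), rep(500L, 2 * n))
  pairs <- data.frame(gc_gene = ids, kn_gene = ids)
  deg <- run_deg(cts, pairs, method = "tmm")
  expect_equal(nrow(deg), n)
  expect_true(all(deg$p_raw >= 0 & deg$p_raw <= 1))
  expect_equal(deg$klass, classify_log2fc(deg$log2fc))
  # no true effects: few pairs reach significance at FDR 0.05
  expect_lte(mean(deg$significant), 0.08)

  # library-swap antisymmetry: log2fc negates, p unchanged
  cts_sw <- cts
  cts_sw$library <- ifelse(cts$library == "GC", "KN", "GC")
  deg_sw <- run_deg(cts_sw, pairs, method = "tmm")
  expect_equal(deg_sw$log2fc, -deg$log2fc, tolerance = 1e-10)
  expect_equal(deg_sw$p_raw, deg$p_raw, tolerance = 1e-10)

  expect_error(run_deg(cts, pairs[0, ], method = "tmm"), "empty")
})

test_that("run_deg recovers an injected fold change in the median", {
  set.seed(62)
  n <- 500; n_eff <- 50
  ids <- sprintf("g%04d", 1:n)
  base <- exp(rnorm(n, 4, 1))
  shift <- c(rep(4, n_eff), rep(1, n - n_eff))   # first 50 genes: +2 log2
  y_gc <- rnbinom(n, mu = base, size = 1 / 0.3)
  y_kn <- rnbinom(n, mu = base * shift, size = 1 / 0.3)
  cts <- toy_counts(c(rep("GC", n), rep("KN", n)), c(ids, ids),
                    c(y_gc, y_kn), rep(500L, 2 * n))
  deg <- run_deg(cts, data.frame(gc_gene = ids, kn_gene = ids),
                 method = "tmm")
  expect_lt(abs(median(deg$log2fc[1:n_eff]) - 2), 0.3)
  expect_lt(abs(median(deg$log2fc[-(1:n_eff)])), 0.2)
})
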