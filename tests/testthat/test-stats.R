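test_that("2x2 chi-square matches the textbook Pearson computation", {
  # equal proportions: statistic exactly zero without correction
  res <- chi_square_2x2(10, 90, 20, 180, yates = FALSE)
  expect_equal(res$chi2, 0)
  expect_equal(res$p, 1)

  # frozen from an independent computation of expected counts and the
  # Pearson sum (row sums 5149/2307, in-unit column 616)
  res <- chi_square_2x2(374, 4775, 242, 2065, yates = FALSE)
  expect_equal(res$chi2, 21.87964, tolerance = 1e-5)
  expect_equal(res$p, 2.90297e-06, tolerance = 1e-4)

  # textbook oracle on a random table
  set.seed(2)
  for (i in 1:10) {
    m <- matrix(sample(5:80, 4), 2)
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    chi_manual <- sum((m - E)^2 / E)
    expect_equal(chi_square_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2],
                                yates = FALSE)$chi2,
                 chi_manual, tolerance = 1e-10)
  }

  # symmetry under row swap
  a <- chi_square_2x2(12, 88, 30, 170)
  b <- chi_square_2x2(30, 170, 12, 88)
  expect_equal(a$chi2, b$chi2)
  expect_equal(a$p, b$p)

  expect_error(chi_square_2x2(0, 0, 5, 5), "margin")
})

test_that("BH adjustment follows the step-up formula and its invariants", {
  expect_equal(bh_adjust(0.03), 0.03)
  # direct evaluation of p(i) * m / i with monotone enforcement
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_true(all(bh_adjust(c(0.9, 0.95)) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # independent step-up oracle on random vectors
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    m <- length(p)
    o <- order(p)
    manual <- numeric(m)
    manual[o] <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
    adj <- bh_adjust(p)
    expect_equal(adj, manual, tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("reads per base pair is plain length normalisation", {
  expect_equal(reads_per_bp(150, 300), 0.5)
  expect_equal(reads_per_bp(0, 300), 0)
  expect_equal(reads_per_bp(150 * 10, 300 * 2), 0.5 * 5)
  expect_error(reads_per_bp(5, 0), ">= 1")
})

test_that("Mann-Whitney U handles exact, normal and tied cases", {
  # identical samples: U at its null centre, p = 1
  mw <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$U, 4.5)
  expect_equal(mw$p, 1)

  # complete separation at n = 3 vs 3: 2 of the C(6,3) = 20 labelings are
  # at least this extreme, two-sided p = 0.1 (frozen from enumeration)
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1)

  # enumeration oracle over all labelings for a random tie-free case
  set.seed(14)
  x <- runif(4); y <- runif(5)
  U_obs <- mann_whitney_u(x, y, method = "exact")
  pooled <- c(x, y)
  combos <- combn(9, 4)
  U_all <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - 4 * 5 / 2)
  d_obs <- abs(U_obs$U - 10)          # distance from the null mean n1*n2/2
  p_enum <- mean(abs(U_all - 10) >= d_obs - 1e-12)
  expect_equal(U_obs$p, p_enum, tolerance = 1e-12)

  # U_x + U_y = n_x * n_y
  set.seed(15)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(11)
    expect_equal(mann_whitney_u(x, y)$U + mann_whitney_u(y, x)$U, 77)
  }

  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
  expect_error(mann_whitney_u(c(1, 1, 2), c(1, 3), method = "exact"),
               "ties")
})

test_that("normal approximation tracks exact enumeration at n = 8", {
  set.seed(3)
  for (i in 1:200) {
    x <- runif(8); y <- runif(8)
    pe <- mann_whitney_u(x, y, method = "exact")$p
    pn <- mann_whitney_u(x, y, method = "normal")$p
    expect_lt(abs(pe - pn), 0.02)
  }
})

test_that("protein-count enrichment flags differences and respects denominators", {
  # two units with identical proportions in both libraries: none significant
  rollup <- data.frame(unit_id = rep(c("s1", "s2"), 2), level = "subcategory",
                       library = rep(c("GC", "KN"), each = 2),
                       n_proteins = c(100L, 300L, 50L, 150L))
  enr <- category_protein_enrichment(rollup)
  expect_false(any(enr$significant))
  expect_true(all(enr$p_adj >= enr$p_raw))

  # unit present in one library only is included with count zero
  rollup2 <- rbind(rollup,
                   data.frame(unit_id = "s3", level = "subcategory",
                              library = "GC", n_proteins = 40L))
  enr2 <- category_protein_enrichment(rollup2)
  expect_equal(enr2$c[enr2$unit_id == "s3"], 0)

  # annotated-total denominators change the percentages
  enr3 <- category_protein_enrichment(
    rollup, denominators = "annotated_total",
    annotated_totals = c(GC = 800, KN = 400))
  expect_equal(enr3$pct_gc[enr3$unit_id == "s1"], 100 * 100 / 800)
})

test_that("enrichment false-positive rate is controlled on null draws", {
  set.seed(77)
  flagged <- 0L; total <- 0L
  p_units <- rep(1 / 17, 17)
  for (s in 1:20) {
    gc <- as.vector(rmultinom(1, 5000, p_units))
    kn <- as.vector(rmultinom(1, 2300, p_units))
    rollup <- data.frame(unit_id = rep(sprintf("u%02d", 1:17), 2),
                         level = "subcategory",
                         library = rep(c("GC", "KN"), each = 17),
                         n_proteins = c(gc, kn))
    enr <- category_protein_enrichment(rollup)
    flagged <- flagged + sum(enr$significant)
    total <- total + nrow(enr)
  }
  expect_lte(flagged / total, 0.08)
})

test_that("category expression ranks are scale invariant and null-safe", {
  sim <- simulate_dataset(sim_config(seed = 51, n_genes = 450, pi_kn = 1,
                                     n_pathways = 9, n_subcategories = 3,
                                     depth_gc = 1e5, depth_mr = 1e5))
  hier <- ko_hierarchy(sim$gene_ko, sim$hierarchy)
  cts <- sim$counts
  cts$library[cts$library == "MR"] <- "KN"
  ex1 <- category_expression(cts, hier, "pathway")
  expect_true(all(ex1$U[!is.na(ex1$U)] <=
                    (ex1$n_gc * ex1$n_kn)[!is.na(ex1$U)]))

  # multiplying every count by 3 changes no rank, hence no U or p
  cts3 <- cts; cts3$count <- cts3$count * 3L
  ex3 <- category_expression(cts3, hier, "pathway")
  expect_equal(ex3$U, ex1$U)
  expect_equal(ex3$p_raw, ex1$p_raw)

  # identical libraries: nothing can be significant
  ctsI <- cts
  ctsI$count <- rep(cts$count[cts$library == "GC"], 2)
  exI <- category_expression(ctsI, hier, "pathway")
  expect_false(any(exI$significant))

  # a unit with no genes in one library gets NA p and is excluded from BH
  hier_toy <- toy_hier(data.frame(gene_id = c("a", "b"),
                                  ko = c("K1", "K4")))
  cts_toy <- toy_counts(c("GC", "GC", "KN"), c("a", "b", "a"),
                        c(10L, 5L, 7L), c(100L, 100L, 100L))
  ex_toy <- category_expression(cts_toy, hier_toy, "subcategory")
  expect_true(is.na(ex_toy$p_raw[ex_toy$unit_id == "s2"]))
  expect_false(ex_toy$significant[ex_toy$unit_id == "s2"])
})

test_that("an injected pathway shift is detected as over-expression in KN", {
  hits <- 0L
  for (s in 1:5) {
    sim <- simulate_dataset(sim_config(seed = 400 + s, n_genes = 1000,
                                       n_pathways = 20, n_subcategories = 8,
                                       pi_kn = 1, effects = c(path11 = 2),
                                       depth_gc = 8e5, depth_mr = 8e5))
    hier <- ko_hierarchy(sim$gene_ko, sim$hierarchy)
    cts <- sim$counts
    cts$library[cts$library == "MR"] <- "KN"
    ex <- category_expression(cts, hier, "pathway")
    row <- ex[ex$unit_id == "path11", ]
    hits <- hits + (row$significant && row$direction == "over_in_KN")
  }
  expect_gte(hits, 4L)
})
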