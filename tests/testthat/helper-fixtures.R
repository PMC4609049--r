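# Small in-code builders shared across the suite.

make_hits <- function(q, s, evalue, bitscore = 100, pident = 90,
                      aln = 100L) {
  n <- length(q)
  data.frame(qseqid = q, sseqid = s,
             pident = rep_len(pident, n), length = rep_len(aln, n),
             mismatch = rep_len(0L, n), gapopen = rep_len(0L, n),
             qstart = rep_len(1L, n), qend = rep_len(aln, n),
             sstart = rep_len(1L, n), send = rep_len(aln, n),
             evalue = rep_len(evalue, n),
             bitscore = rep_len(bitscore, n),
             stringsAsFactors = FALSE)
}

toy_taxa <- function() {
  taxon_map(c(c1 = "cryptoA", c2 = "cryptoB",
              t1 = "ciliateA", o1 = "otherA", o2 = "otherB"),
            cryptophyte_labels = c("cryptoA", "cryptoB"),
            ciliate_labels = "ciliateA")
}

# 2 categories / 2 subcategories / 3 pathways / 4 KOs toy hierarchy.
toy_hier <- function(gene_ko = NULL) {
  hier_tab <- data.frame(
    ko = c("K1", "K2", "K3", "K4"),
    pathway = c("p1", "p1", "p2", "p3"),
    subcategory = c("s1", "s1", "s1", "s2"),
    category = c("catA", "catA", "catA", "catB"),
    stringsAsFactors = FALSE)
  if (is.null(gene_ko))
    gene_ko <- data.frame(gene_id = c("g1", "g2", "g3"),
                          ko = c("K1", "K2", "K3"),
                          stringsAsFactors = FALSE)
  ko_hierarchy(gene_ko, hier_tab)
}

toy_counts <- function(libs, ids, counts, lens) {
  count_table(
    data.frame(library = libs, gene_id = ids, count = counts,
               stringsAsFactors = FALSE),
    data.frame(gene_id = ids, library = libs, length_bp = lens,
               stringsAsFactors = FALSE))
}

# Independent negative-binomial conditional-test oracle: scalar loop,
# pmf from the gamma-function form (no dnbinom).
nb_oracle <- function(y1, y2, dispersion) {
  size <- 1 / dispersion
  s <- y1 + y2
  if (s == 0) return(1)
  mu <- s / 2
  logf <- function(k) {
    lgamma(k + size) - lgamma(size) - lfactorial(k) +
      size * (log(size) - log(size + mu)) +
      k * (log(mu) - log(size + mu))
  }
  lp <- numeric(s + 1)
  for (k in 0:s) lp[k + 1] <- logf(k) + logf(s - k)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  pobs <- pr[y1 + 1]
  min(1, sum(pr[pr <= pobs * (1 + 1e-12)]))
}

# Exhaustive reciprocal-best-hit oracle over a dense score (e-value) matrix.
rbbh_oracle <- function(emat, e_threshold) {
  qn <- rownames(emat); sn <- colnames(emat)
  pairs <- list()
  for (i in seq_along(qn)) {
    jbest <- which.min(emat[i, ])
    if (emat[i, jbest] > e_threshold) next
    ibest <- which.min(emat[, jbest])
    if (emat[ibest, jbest] > e_threshold) next
    if (ibest == i) pairs[[length(pairs) + 1]] <- c(qn[i], sn[jbest])
  }
  if (length(pairs) == 0)
    return(data.frame(gc_gene = character(), kn_gene = character()))
  out <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  names(out) <- c("gc_gene", "kn_gene")
  out[order(out$gc_gene), , drop = FALSE]
}

emat_to_hits <- function(emat, transpose = FALSE) {
  if (transpose) emat <- t(emat)
  qn <- rownames(emat); sn <- colnames(emat)
  make_hits(rep(qn, times = length(sn)),
            rep(sn, each = length(qn)),
            evalue = as.vector(emat))
}
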