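#' Configuration for the synthetic chimeric-transcriptome generator
#'
#' Defaults emulate the study conditions of a kleptokaryon-dominated mixed
#' library: a two-origin mixture with ~61.5 % of genes derived from the
#' stolen nucleus, lognormal coding-sequence lengths targeting a mean of
#' ~850 bp with standard deviation ~648 bp, a 4-category / 21-subcategory /
#' 89-pathway KO hierarchy, negative-binomial counts at dispersion 0.3 with
#' pathway-level log2 fold-change shifts for the kleptokaryon, and homology
#' hit tables consistent with true origin up to a configurable
#' misassignment rate.
#'
#' @param seed Integer seed; the whole dataset is a pure function of it.
#' @param n_genes Number of paired genes (present in the free-living GC
#'   library and, as the kleptokaryon/host mixture, in the MR library).
#' @param pi_kn True kleptokaryon fraction of MR-library genes.
#' @param n_categories,n_subcategories,n_pathways Hierarchy sizes.
#' @param kos_per_pathway KOs per pathway (each KO sits in one pathway).
#' @param length_meanlog,length_sdlog Lognormal length model; the defaults
#'   give mean ~850 bp, sd ~648 bp.
#' @param baseline_sd Standard deviation (natural log) of the gene-level
#'   baseline expression rate shared between libraries.
#' @param effects Named numeric vector: pathway id -> log2 shift applied to
#'   kleptokaryon-origin genes of that pathway in the MR library.
#' @param dispersion_sim Negative-binomial dispersion of simulated counts.
#' @param depth_gc,depth_mr Target total read counts per library.
#' @param epsilon Probability that a gene's best-hit taxon label is flipped
#'   (cryptophyte <-> non-cryptophyte).
#' @param evalue_exp_range Best-hit e-values are drawn log-uniform with
#'   base-10 exponent uniform on this range (kept below the 1e-4 cutoff by
#'   default).
#' @param n_decoy_gc Extra GC-only genes without an MR counterpart
#'   (exercise unpaired matching).
#' @param unannotated_frac Fraction of genes left without a KO.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 10000L, pi_kn = 0.615,
                       n_categories = 4L, n_subcategories = 21L,
                       n_pathways = 89L, kos_per_pathway = 3L,
                       length_meanlog = 6.5157, length_sdlog = 0.6768,
                       baseline_sd = 1.0, effects = numeric(),
                       dispersion_sim = 0.3,
                       depth_gc = 2e6, depth_mr = 2e6,
                       epsilon = 0, evalue_exp_range = c(-100, -5),
                       n_decoy_gc = 0L, unannotated_frac = 0) {
  stopifnot(pi_kn >= 0, pi_kn <= 1, epsilon >= 0, epsilon <= 1,
            n_genes >= 1, n_categories >= 1, n_subcategories >= 1,
            n_pathways >= 1, kos_per_pathway >= 1, dispersion_sim > 0,
            unannotated_frac >= 0, unannotated_frac < 1)
  if (n_genes < n_pathways)
    stop("infeasible hierarchy: fewer genes than pathways")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

sim_hierarchy <- function(cfg) {
  cats <- sprintf("cat%02d", seq_len(cfg$n_categories))
  subs <- sprintf("sub%02d", seq_len(cfg$n_subcategories))
  paths <- sprintf("path%02d", seq_len(cfg$n_pathways))
  kos <- sprintf("K%05d", seq_len(cfg$n_pathways * cfg$kos_per_pathway))
  data.frame(
    ko = kos,
    pathway = rep(paths, each = cfg$kos_per_pathway),
    subcategory = rep(subs, length.out = cfg$n_pathways)[
      rep(seq_len(cfg$n_pathways), each = cfg$kos_per_pathway)],
    category = rep(cats, length.out = cfg$n_subcategories)[
      match(rep(subs, length.out = cfg$n_pathways)[
        rep(seq_len(cfg$n_pathways), each = cfg$kos_per_pathway)], subs)],
    stringsAsFactors = FALSE)
}

#' Simulate a complete chimeric-transcriptome dataset with ground truth
#'
#' Generates, reproducibly from the seed, everything the pipeline consumes:
#' gene records with lengths for the free-living (GC) and mixed (MR)
#' libraries, a best-hit homology table for the MR library with a taxon
#' map, gene-to-KO and hierarchy tables, a two-library count table, and the
#' ortholog pairs linking kleptokaryon genes to their GC counterparts. The
#' returned `truth` element records each gene's true origin and pathway,
#' the per-pathway log2 shifts and the true kleptokaryon fraction.
#'
#' Counts are negative-binomial with gene-level lognormal baselines shared
#' between libraries, so a pathway's kleptokaryon shift is the only
#' systematic GC-vs-KN difference.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional directory; when given, all inputs are also
#'   written as files in the package's external formats (`genes_gc.fasta`,
#'   `genes_mr.fasta`, `hits_mr.tsv`, `taxa.tsv`, `gene_ko.tsv`,
#'   `hierarchy.tsv`, `counts.tsv`, `pairs.tsv`).
#' @return A list with elements `config`, `genes`, `hits`, `taxa`,
#'   `gene_ko`, `hierarchy`, `counts`, `pairs`, `truth`.
#' @export
simulate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  hier_tab <- sim_hierarchy(cfg)
  n <- cfg$n_genes

  gene_id <- sprintf("g%06d", seq_len(n))
  origin <- ifelse(runif(n) < cfg$pi_kn, "KN", "HOST")
  length_bp <- pmax(30L, as.integer(round(
    rlnorm(n, cfg$length_meanlog, cfg$length_sdlog))))

  # KO assignment: paired genes cycle through KOs so every pathway is
  # populated evenly; a configurable tail is left unannotated.
  ko <- rep(hier_tab$ko, length.out = n)
  annotated <- runif(n) >= cfg$unannotated_frac
  pathway <- hier_tab$pathway[match(ko, hier_tab$ko)]
  pathway[!annotated] <- NA_character_

  # Expression model: shared lognormal baseline per gene; kleptokaryon
  # pathway shifts apply to the MR copy of KN-origin genes only.
  base <- exp(rnorm(n, 0, cfg$baseline_sd)) * length_bp
  delta <- rep(0, n)
  if (length(cfg$effects) > 0) {
    hit <- !is.na(pathway) & pathway %in% names(cfg$effects) &
      origin == "KN"
    delta[hit] <- cfg$effects[pathway[hit]]
  }
  w_gc <- base
  w_mr <- base * 2^delta
  mu_gc <- cfg$depth_gc * w_gc / sum(w_gc)
  mu_mr <- cfg$depth_mr * w_mr / sum(w_mr)
  size <- 1 / cfg$dispersion_sim
  cnt_gc <- rnbinom(n, size = size, mu = mu_gc)
  cnt_mr <- rnbinom(n, size = size, mu = mu_mr)

  # Decoy GC-only genes (no MR counterpart, no pairing partner).
  nd <- cfg$n_decoy_gc
  decoy_id <- if (nd > 0) sprintf("d%06d", seq_len(nd)) else character()
  decoy_len <- if (nd > 0) pmax(30L, as.integer(round(
    rlnorm(nd, cfg$length_meanlog, cfg$length_sdlog)))) else integer()
  decoy_cnt <- if (nd > 0) rnbinom(nd, size = size,
    mu = mean(mu_gc)) else integer()

  genes <- rbind(
    data.frame(gene_id = c(gene_id, decoy_id), library = "GC",
               length_bp = c(length_bp, decoy_len),
               stringsAsFactors = FALSE),
    data.frame(gene_id = gene_id, library = "MR", length_bp = length_bp,
               stringsAsFactors = FALSE))

  counts <- count_table(
    data.frame(library = c(rep("GC", n + nd), rep("MR", n)),
               gene_id = c(gene_id, decoy_id, gene_id),
               count = c(cnt_gc, decoy_cnt, cnt_mr),
               stringsAsFactors = FALSE),
    genes)

  # Taxonomy and best hits for the MR library: true-KN genes hit a
  # cryptophyte subject, host genes a non-cryptophyte one, each flipped
  # with probability epsilon; e-values log-uniform below the cutoff.
  taxa <- taxon_map(
    c(crypto_ref_1 = "Guillardia theta",
      crypto_ref_2 = "Geminigera cryophila",
      ciliate_ref_1 = "Tetrahymena thermophila",
      euk_ref_1 = "Emiliania huxleyi",
      euk_ref_2 = "Thalassiosira pseudonana"),
    cryptophyte_labels = c("Guillardia theta", "Geminigera cryophila"),
    ciliate_labels = "Tetrahymena thermophila")
  crypto_subjects <- c("crypto_ref_1", "crypto_ref_2")
  other_subjects <- c("ciliate_ref_1", "euk_ref_1", "euk_ref_2")
  hit_crypto <- xor(origin == "KN", runif(n) < cfg$epsilon)
  subj <- ifelse(hit_crypto,
                 sample(crypto_subjects, n, replace = TRUE),
                 sample(other_subjects, n, replace = TRUE))
  ev <- 10^runif(n, cfg$evalue_exp_range[1L], cfg$evalue_exp_range[2L])
  hits <- data.frame(qseqid = gene_id, sseqid = subj,
                     pident = round(runif(n, 40, 99), 1),
                     length = pmax(20L, as.integer(length_bp / 3)),
                     mismatch = 0L, gapopen = 0L,
                     qstart = 1L, qend = pmax(20L, as.integer(length_bp / 3)),
                     sstart = 1L, send = pmax(20L, as.integer(length_bp / 3)),
                     evalue = ev,
                     bitscore = round(50 - 1.5 * log10(ev), 1),
                     stringsAsFactors = FALSE)

  pairs <- data.frame(gc_gene = gene_id[origin == "KN"],
                      kn_gene = gene_id[origin == "KN"],
                      stringsAsFactors = FALSE)

  truth <- list(
    genes = data.frame(gene_id = gene_id, origin = origin,
                       pathway = pathway, mu_gc = mu_gc, mu_mr = mu_mr,
                       delta_log2 = delta, stringsAsFactors = FALSE),
    pathway_effects = data.frame(
      pathway = unique(hier_tab$pathway),
      delta_log2 = ifelse(unique(hier_tab$pathway) %in% names(cfg$effects),
                          cfg$effects[unique(hier_tab$pathway)], 0),
      stringsAsFactors = FALSE),
    pi_kn = cfg$pi_kn)

  gene_ko <- data.frame(gene_id = gene_id[annotated], ko = ko[annotated],
                        stringsAsFactors = FALSE)
  out <- list(config = cfg, genes = genes, hits = hits, taxa = taxa,
              gene_ko = gene_ko, hierarchy = hier_tab, counts = counts,
              pairs = pairs, truth = truth)
  if (!is.null(out_dir)) write_sim_files(out, out_dir)
  out
}

write_sim_files <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta_lengths <- function(genes, path) {
    con <- file(path, "w")
    on.exit(close(con))
    set.seed(sum(utf8ToInt(basename(path))) + sim$config$seed)
    for (i in seq_len(nrow(genes))) {
      writeLines(paste0(">", genes$gene_id[i]), con)
      writeLines(paste(sample(c("A", "C", "G", "T"), genes$length_bp[i],
                              replace = TRUE), collapse = ""), con)
    }
  }
  gg <- sim$genes[sim$genes$library == "GC", ]
  gm <- sim$genes[sim$genes$library == "MR", ]
  write_fasta_lengths(gg, file.path(out_dir, "genes_gc.fasta"))
  write_fasta_lengths(gm, file.path(out_dir, "genes_mr.fasta"))
  write.table(sim$hits, file.path(out_dir, "hits_mr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  tm <- sim$taxa
  grp <- ifelse(tm$subject_taxon %in% tm$cryptophyte_labels, "cryptophyte",
                ifelse(tm$subject_taxon %in% tm$ciliate_labels, "ciliate",
                       "other"))
  write.table(data.frame(subject_id = names(tm$subject_taxon),
                         taxon_label = unname(tm$subject_taxon),
                         group = grp),
              file.path(out_dir, "taxa.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$gene_ko, file.path(out_dir, "gene_ko.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$hierarchy, file.path(out_dir, "hierarchy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$counts[, c("library", "gene_id", "count")],
              file.path(out_dir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}

#' Score pipeline outputs against simulation ground truth
#'
#' Reports how well each pipeline stage recovered the generator's truth:
#' the absolute error of the kleptokaryon fraction, pathway-level
#' true/false-positive rates of the expression tests at the FDR cutoff, and
#' the root-mean-square error of the per-pair log2 fold changes.
#'
#' @param truth The `truth` element of [simulate_dataset()] output.
#' @param partition Optional partition summary (one row, from
#'   [assign_origin()]).
#' @param calls Optional origin calls data.frame; adds per-gene accuracy.
#' @param expression Optional pathway-level [category_expression()] result.
#' @param deg Optional [run_deg()] result.
#' @return A data.frame with columns `metric`, `value`.
#' @export
recovery_report <- function(truth, partition = NULL, calls = NULL,
                            expression = NULL, deg = NULL) {
  rows <- list()
  if (!is.null(partition)) {
    rows[["pi_kn_abs_error"]] <-
      abs(partition$fraction_kn - truth$pi_kn)
  }
  if (!is.null(calls)) {
    if (!setequal(calls$gene_id, truth$genes$gene_id))
      stop("mismatched gene universe between calls and truth")
    m <- match(calls$gene_id, truth$genes$gene_id)
    has_hit <- !is.na(calls$best_evalue)
    rows[["partition_accuracy_with_hit"]] <-
      mean(calls$origin[has_hit] == truth$genes$origin[m][has_hit])
  }
  if (!is.null(expression)) {
    te <- truth$pathway_effects
    m <- match(expression$unit_id, te$pathway)
    if (anyNA(m)) stop("mismatched pathway universe")
    pos <- te$delta_log2[m] != 0
    flagged <- expression$significant
    rows[["pathway_tpr"]] <-
      if (any(pos)) mean(flagged[pos]) else NA_real_
    rows[["pathway_fpr"]] <-
      if (any(!pos)) mean(flagged[!pos]) else NA_real_
  }
  if (!is.null(deg)) {
    m <- match(deg$kn_gene, truth$genes$gene_id)
    if (anyNA(m)) stop("mismatched gene universe between deg and truth")
    rows[["log2fc_rmse"]] <-
      sqrt(mean((deg$log2fc - truth$genes$delta_log2[m])^2))
  }
  data.frame(metric = names(rows), value = unlist(rows, use.names = FALSE),
             stringsAsFactors = FALSE)
}
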