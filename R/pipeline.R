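#' Validated configuration for a full pipeline run
#'
#' @param fasta_gc,fasta_mr FASTA files with coding sequences (lengths only
#'   are used).
#' @param hits_mr Tabular homology hits for the mixed (MR) library.
#' @param taxa_path Subject-to-taxon TSV (see [read_taxon_map()]).
#' @param gene_ko_path,hierarchy_path KO annotation TSVs (see
#'   [read_ko_hierarchy()]).
#' @param counts_path Per-gene read-count TSV.
#' @param pairs_path Ortholog-pair TSV with columns `gc_gene`, `kn_gene`.
#' @param out_dir Output directory (created if absent).
#' @param evalue Partition e-value cutoff.
#' @param alpha FDR level shared by all tests.
#' @param dispersion Fixed dispersion of the exact negative-binomial test.
#' @param lfc_threshold Fold-change class boundary.
#' @param denominators Denominator mode for protein-count enrichment.
#' @param method Normalisation backend for differential expression.
#' @param sweep Optional additional e-value thresholds for the partition
#'   sensitivity sweep.
#' @return A list of class `run_config`.
#' @export
run_config <- function(fasta_gc, fasta_mr, hits_mr, taxa_path,
                       gene_ko_path, hierarchy_path, counts_path,
                       pairs_path, out_dir,
                       evalue = 1e-4, alpha = 0.05, dispersion = 0.3,
                       lfc_threshold = 1,
                       denominators = "category_sum", method = "tmm",
                       sweep = c(1e-4, 1e-30)) {
  paths <- c(fasta_gc, fasta_mr, hits_mr, taxa_path, gene_ko_path,
             hierarchy_path, counts_path, pairs_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  if (evalue <= 0) stop("evalue must be > 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (!denominators %in% c("category_sum", "annotated_total"))
    stop("unknown denominators mode: ", denominators)
  if (!method %in% c("tmm", "median_ratio"))
    stop("unknown normalisation method: ", method)
  cfg <- as.list(environment())
  cfg$paths <- NULL; cfg$missing <- NULL
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes partition, rollup, protein-count enrichment, category
#' expression (subcategory and pathway level), reciprocal-best-hit pairing
#' (pairs are read from the pairs file) and differential expression, and
#' writes one TSV per stage plus a run-metadata file recording thresholds,
#' package version and input checksums. Stage failures propagate with the
#' stage name prepended.
#'
#' @param cfg A [run_config()].
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  genes_gc <- stage("read_fasta_gc", read_fasta(cfg$fasta_gc, "GC"))
  genes_mr <- stage("read_fasta_mr", read_fasta(cfg$fasta_mr, "MR"))
  genes <- rbind(genes_gc, genes_mr)
  hits <- stage("read_hits", read_hit_table(cfg$hits_mr))
  taxa <- stage("read_taxa", read_taxon_map(cfg$taxa_path))
  hier <- stage("read_hierarchy",
                read_ko_hierarchy(cfg$gene_ko_path, cfg$hierarchy_path))
  counts <- stage("read_counts", read_count_table(cfg$counts_path, genes))
  pairs <- stage("read_pairs",
                 read.delim(cfg$pairs_path, stringsAsFactors = FALSE))

  part <- stage("partition", {
    best <- best_hit_per_query(hits)
    assign_origin(best, taxa, genes_mr$gene_id, e_threshold = cfg$evalue)
  })
  sweep_tab <- stage("threshold_sweep",
    threshold_sweep(hits, taxa, genes_mr$gene_id, thresholds = cfg$sweep))
  counts2 <- stage("partition_counts",
                   partition_count_table(counts, part$calls))
  genes2 <- rbind(genes_gc,
                  data.frame(gene_id = part$calls$gene_id[
                               part$calls$origin == "KN"],
                             library = "KN",
                             length_bp = genes_mr$length_bp[
                               match(part$calls$gene_id[
                                 part$calls$origin == "KN"],
                                 genes_mr$gene_id)],
                             stringsAsFactors = FALSE))

  rollup <- stage("rollup",
                  rollup_protein_counts(genes2, hier, "subcategory"))
  enrich <- stage("enrichment",
    category_protein_enrichment(rollup, denominators = cfg$denominators,
                                annotated_totals = annotated_totals(genes2,
                                                                    hier),
                                alpha = cfg$alpha))
  expr_sub <- stage("expression_subcategory",
    category_expression(counts2, hier, "subcategory", alpha = cfg$alpha))
  expr_path <- stage("expression_pathway",
    category_expression(counts2, hier, "pathway", alpha = cfg$alpha))
  deg <- stage("deg",
    run_deg(counts2, pairs, method = cfg$method,
            dispersion = cfg$dispersion, alpha = cfg$alpha,
            lfc_threshold = cfg$lfc_threshold))

  w <- function(x, f) write_results_tsv(x, file.path(cfg$out_dir, f))
  w(part$calls, "origin_calls.tsv")
  w(sweep_tab, "partition_sweep.tsv")
  w(rollup, "protein_counts.tsv")
  w(enrich, "enrichment_subcategory.tsv")
  w(expr_sub, "expression_subcategory.tsv")
  w(expr_path, "expression_pathway.tsv")
  w(deg, "deg_pairs.tsv")

  meta <- c(
    sprintf("package_version\t%s",
            as.character(utils::packageVersion("kleptome"))),
    sprintf("evalue\t%g", cfg$evalue),
    sprintf("alpha\t%g", cfg$alpha),
    sprintf("dispersion\t%g", cfg$dispersion),
    sprintf("lfc_threshold\t%g", cfg$lfc_threshold),
    sprintf("denominators\t%s", cfg$denominators),
    sprintf("method\t%s", cfg$method),
    sprintf("tie_break\tevalue,bitscore,subject_id"),
    vapply(c(cfg$fasta_gc, cfg$fasta_mr, cfg$hits_mr, cfg$taxa_path,
             cfg$gene_ko_path, cfg$hierarchy_path, cfg$counts_path,
             cfg$pairs_path),
           function(p) sprintf("md5\t%s\t%s", basename(p),
                               unname(tools::md5sum(p))), ""))
  writeLines(meta, file.path(cfg$out_dir, "run_metadata.tsv"))
  invisible(cfg$out_dir)
}

annotated_totals <- function(genes, hier) {
  libs <- unique(genes$library)
  vapply(libs, function(lib) {
    g <- genes$gene_id[genes$library == lib]
    sum(!vapply(hier$gene_to_kos[g], is.null, TRUE))
  }, 0L) |> setNames(libs)
}

#' Assemble report tables from pipeline outputs
#'
#' Reads the TSVs written by [run_pipeline()] and emits three report files:
#' a subcategory summary (protein counts, percentages, adjusted p,
#' significance and direction), a long gene-level reads-per-bp table by
#' pathway and library (boxplot-ready), and a fold-change listing of
#' classified differentially expressed pairs.
#'
#' @param results_dir Directory produced by [run_pipeline()].
#' @param out_dir Where to write report files (default: `results_dir`).
#' @return Invisible character vector of the files written; errors list any
#'   absent inputs.
#' @export
make_report <- function(results_dir, out_dir = results_dir) {
  need <- c("enrichment_subcategory.tsv", "expression_pathway.tsv",
            "deg_pairs.tsv")
  absent <- need[!file.exists(file.path(results_dir, need))]
  if (length(absent) > 0L)
    stop("missing pipeline output file(s): ", paste(absent, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  enrich <- read_results_tsv(file.path(results_dir,
                                       "enrichment_subcategory.tsv"))
  summary <- enrich[, c("unit_id", "a", "c", "pct_gc", "pct_kn", "p_adj",
                        "direction", "significant")]
  names(summary) <- c("subcategory", "n_proteins_gc", "n_proteins_kn",
                      "pct_gc", "pct_kn", "p_adj", "direction",
                      "significant")
  f1 <- file.path(out_dir, "report_subcategory_summary.tsv")
  write_results_tsv(summary, f1)
  expr <- read_results_tsv(file.path(results_dir, "expression_pathway.tsv"))
  f2 <- file.path(out_dir, "report_pathway_expression.tsv")
  write_results_tsv(expr, f2)
  deg <- read_results_tsv(file.path(results_dir, "deg_pairs.tsv"))
  f3 <- file.path(out_dir, "report_deg_classified.tsv")
  write_results_tsv(deg[deg$klass != "ns", , drop = FALSE], f3)
  invisible(c(f1, f2, f3))
}

#' Packaged example: per-subcategory protein counts for two libraries
#'
#' Protein counts for 17 KEGG-style subcategories in the free-living (GC)
#' and kleptokaryon (KN) libraries, with the published adjusted p-values
#' and over/under-representation flags, as shipped in `inst/extdata`.
#' Useful as a worked example for [category_protein_enrichment()].
#'
#' @return A data.frame with columns `subcategory`, `n_gc`, `n_kn`,
#'   `pct_gc`, `pct_kn`, `p_adj_printed`, `flagged`.
#' @export
example_subcategory_counts <- function() {
  read.delim(system.file("extdata", "subcategory_protein_counts.tsv",
                         package = "kleptome"), stringsAsFactors = FALSE)
}

#' Packaged example: log2 fold changes for pigment-related pathways
#'
#' Published per-transcript log2 fold changes (kleptokaryon over
#' free-living) for the porphyrin & chlorophyll metabolism and carotenoid
#' biosynthesis pathways, as shipped in `inst/extdata`. Useful as a worked
#' example for [classify_log2fc()].
#'
#' @return A data.frame with columns `ko`, `kn_id`, `log2fc`,
#'   `description`, `pathway`.
#' @export
example_pigment_log2fc <- function() {
  read.delim(system.file("extdata", "pigment_pathway_log2fc.tsv",
                         package = "kleptome"), stringsAsFactors = FALSE)
}
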