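#' Run the full selection scan on an input bundle
#'
#' Orchestrates the stages end to end: genotype ingestion and call-rate
#' filtering, per-site Weir & Cockerham Fst, the windowed Z-score scan,
#' effect classification against gene models, fixed/high-Fst site
#' selection with window context, pathway over-representation, the
#' Fst-bin category spectrum and the flanking-Fst category contrast, and
#' optionally a coalescent neutral null. Per-stage TSVs and a JSON run
#' manifest (parameters, seed, package version) are written to `out_dir`
#' when given.
#'
#' All thresholds are surfaced as arguments with the scan's canonical
#' values as defaults; nothing is hard-coded.
#'
#' @param vcf,popmap,gff3,fasta,pathways,background Input paths: the VCF,
#'   two-column sample map, GFF3 gene models, reference FASTA, pathway
#'   membership TSV and background gene list (one id per line).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param window_size Scan window in bp (default 500 kb).
#' @param z_threshold Outlier threshold in SD units (default 5).
#' @param fst_threshold Divergent-site threshold (default 0.75).
#' @param flank_span Flanking-window width in bp (default 50 kb).
#' @param call_rate Minimum per-population called fraction (default 0.5).
#' @param min_sites Minimum sites per window (default 10).
#' @param estimator Window estimator: `"unweighted"` or `"weighted"`.
#' @param test_mode Enrichment tail: `"binomial"` or `"hypergeometric"`.
#' @param spectrum_mode `"multi"` or `"exclusive"` category counting.
#' @param bin_edges Fst bin edges.
#' @param run_null Run the coalescent null stage.
#' @param null_model Demographic model for the null (default
#'   [default_dog_wolf_model()]).
#' @param null_reps Null replicates (default 200).
#' @param seed Seed for the null stage.
#' @return List with `sites`, `fst`, `windows`, `effects`, `divergent`,
#'   `divergent_effects`, `genes`, `enrichment`, `spectrum`, `contrast`
#'   (NULL if too few categories), `null`, `exceedance`, `manifest`.
#' @export
run_scan <- function(vcf, popmap, gff3 = NULL, fasta = NULL,
                     pathways = NULL, background = NULL, out_dir = NULL,
                     window_size = 500000L, z_threshold = 5,
                     fst_threshold = 0.75, flank_span = 50000L,
                     call_rate = 0.5, min_sites = 10L,
                     estimator = "unweighted", test_mode = "binomial",
                     spectrum_mode = "multi",
                     bin_edges = c(0.85, 0.9, 0.95, 1), run_null = FALSE,
                     null_model = NULL, null_reps = 200L, seed = 1L) {
  pm <- if (is.character(popmap)) read_population_map(popmap) else popmap
  sites <- read_sites(vcf, pm)
  sites <- filter_by_call_rate(sites, min_fraction = call_rate)
  fst <- fst_sites(sites)
  windows <- window_scan(fst, window_size = window_size,
                         min_sites = min_sites, threshold = z_threshold,
                         estimator = estimator)
  res <- list(sites = sites, fst = fst, windows = windows)

  if (!is.null(gff3) && !is.null(fasta)) {
    models <- load_gene_models(gff3, fasta)
    res$effects <- classify_variants(sites, models)
    divergent <- select_divergent_sites(fst, sites,
                                        threshold = fst_threshold)
    de <- join_effects(divergent, res$effects)
    de <- annotate_window_context(de, windows)
    res$divergent <- divergent
    res$divergent_effects <- de
    res$genes <- genes_with_functional_divergence(de)
    res$spectrum <- bin_spectrum(de, edges = bin_edges,
                                 mode = spectrum_mode)
    res$contrast <- tryCatch(
      category_contrast(fst, de, span = flank_span),
      error = function(e) NULL)
    if (!is.null(pathways) && !is.null(background)) {
      pw <- if (is.character(pathways) && length(pathways) == 1L)
        read_pathway_table(pathways) else pathways
      bgl <- if (is.character(background) && length(background) == 1L &&
                   file.exists(background)) readLines(background)
        else background
      res$enrichment <- pathway_enrichment(pw, names(res$genes), bgl,
                                           mode = test_mode)
    }
  }

  if (run_null) {
    if (is.null(null_model))
      null_model <- default_dog_wolf_model(window_length = window_size)
    ns <- attr(sites, "pop_sizes")
    samples <- stats::setNames(2L * ns, attr(sites, "populations"))
    names(samples) <- null_model$populations$name[
      seq_along(samples)]  # align labels with the model's demes
    res$null <- null_distribution(null_model, samples, n_reps = null_reps,
                                  seed = seed)
    res$exceedance <- empirical_exceedance(windows, res$null)
  }

  res$manifest <- list(
    package = "canidscan",
    version = as.character(utils::packageVersion("canidscan")),
    seed = seed,
    parameters = list(window_size = window_size, z_threshold = z_threshold,
                      fst_threshold = fst_threshold,
                      flank_span = flank_span, call_rate = call_rate,
                      min_sites = min_sites, estimator = estimator,
                      test_mode = test_mode, spectrum_mode = spectrum_mode,
                      run_null = run_null, null_reps = null_reps),
    inputs = list(vcf = vcf, gff3 = gff3, fasta = fasta))

  if (!is.null(out_dir)) write_scan_outputs(res, out_dir)
  res
}

write_scan_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) utils::write.table(
    x, file.path(out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(res$fst, "fst_sites.tsv")
  write_windows_bed(res$windows, file.path(out_dir, "windows.tsv"))
  if (!is.null(res$effects)) tsv(res$effects, "effects.tsv")
  if (!is.null(res$divergent_effects))
    tsv(res$divergent_effects, "divergent_sites.tsv")
  if (!is.null(res$enrichment)) tsv(res$enrichment, "enrichment.tsv")
  if (!is.null(res$spectrum)) {
    sp <- as.data.frame.table(res$spectrum$counts,
                              responseName = "count")
    names(sp)[1:2] <- c("bin", "category")
    sp$percent <- as.data.frame.table(res$spectrum$percent)$Freq
    tsv(sp, "bin_spectrum.tsv")
  }
  if (!is.null(res$contrast)) tsv(res$contrast$tukey, "tukey.tsv")
  if (!is.null(res$null))
    tsv(data.frame(rep = seq_along(res$null), mean_fst = res$null),
        "null_distribution.tsv")
  writeLines(jsonlite::toJSON(res$manifest, auto_unbox = TRUE,
                              pretty = TRUE, null = "null"),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
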