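# End-to-end orchestration: simulate (or load) -> regions -> catalog ->
# extract (or load signatures) -> decompose -> stats. Every stage is a pure
# function of (inputs, config, seed); outputs are TSV/JSON with a manifest
# carrying the config hash so reruns can be verified byte-identical.

#' Default run configuration
#'
#' All tunables with their standard values: 20-kbp domains, 250 rtu/Mb slope
#' threshold, 1-kbp origin bins (1000 per side), K in 2..7 with stability at
#' least 0.8, 0.2 exposure filter, 0.5% prune tolerance, 1000 perturbations
#' at 5% noise with 0.3 instability, minimum exposure 10, Tukey k = 2.
#' `overrides` (a named list, possibly nested) replaces matching entries.
#'
#' @param overrides named list of settings to override.
#' @return nested configuration list.
#' @export
run_config <- function(overrides = list()) {
  base <- list(
    seed = 1,
    rtu_high_is_early = FALSE,
    simulate = list(n_chrom = 2, chrom_length = 1e6, gc_bias = 0.4,
                    n_samples = 40, mutations_per_sample = 10000,
                    n_signatures = 3, asymmetry_ratio = 1,
                    quartile_multipliers = c(1, 1, 1, 1)),
    regions = list(domain_width = 20000, slope_threshold = 250,
                   origin_bin_width = 1000, origin_max_bins = 1000),
    extract = list(K_range = 2:7, stability_min = 0.8, n_resamples = 100,
                   n_restarts = 10, max_iter = 10000, tol = 1e-9,
                   exposure_filter = 0.2, n_clusters = 27,
                   low_mass_frac = 0.005, load_signatures = NULL),
    decompose = list(prune_tolerance = 0.005, robustness = FALSE,
                     n_perturb = 1000, noise_frac = 0.05, instability = 0.3),
    stats = list(min_exposure = 10, tukey_k = 2))
  utils::modifyList(base, overrides)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline on synthetic data
#'
#' Chains simulate -> regions -> catalog -> extract-or-load-signatures ->
#' decompose -> stats, writing each stage's tables under `outdir` together
#' with a manifest (config hash, seed, package version). Given a fixed
#' config the outputs are byte-identical across reruns.
#'
#' @param config configuration list from [run_config()].
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = run_config(), outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  sim <- cfg$simulate

  # simulate
  genome <- make_genome(cfg$seed, n_chrom = sim$n_chrom,
                        chrom_length = sim$chrom_length, gc_bias = sim$gc_bias)
  ann <- make_domains(genome, domain_width = cfg$regions$domain_width)
  sigs <- example_signatures(sim$n_signatures)
  truth <- synthetic_truth(sigs, asymmetry_ratio = sim$asymmetry_ratio,
                           quartile_multipliers = sim$quartile_multipliers,
                           n_samples = sim$n_samples,
                           mutations_per_sample = sim$mutations_per_sample,
                           seed = cfg$seed)
  # regions: re-derive the domains from the emitted timing profile
  domains <- derive_domains_from_timing(
    ann$profile, domain_width = cfg$regions$domain_width,
    slope_threshold = cfg$regions$slope_threshold,
    rtu_high_is_early = cfg$rtu_high_is_early)
  domains <- assign_timing_quartiles(domains,
                                     rtu_high_is_early = cfg$rtu_high_is_early)
  origin_bins <- build_origin_bins(
    ann$origins, bin_width = cfg$regions$origin_bin_width,
    max_bins = cfg$regions$origin_max_bins,
    chrom_lengths = setNames(as.numeric(width(genome)), names(genome)))

  mutations <- make_cohort(genome, domains, truth, seed = cfg$seed + 1)
  write_genome(genome, file.path(outdir, "genome.fa"))
  write_domains(domains, file.path(outdir, "domains.tsv"))
  write_timing_profile(ann$profile, file.path(outdir, "timing.bedgraph"))
  write_bed(ann$origins, file.path(outdir, "origins.bed"))
  write_mutations(mutations, file.path(outdir, "mutations.tsv"))
  write_signatures(sigs, file.path(outdir, "planted_signatures.tsv"))

  # catalog
  freqs <- count_trinucleotides(genome, domains)
  catalog <- build_catalog(mutations, domains, genome = genome)
  by_quartile <- build_catalog(mutations, domains, genome = genome,
                               stratify_by = "quartile")
  write_catalog(catalog$counts, file.path(outdir, "catalog.tsv"))

  # extract or load signatures
  if (!is.null(cfg$extract$load_signatures)) {
    directional <- read_signatures(cfg$extract$load_signatures)
    model <- NULL
  } else {
    ex <- cfg$extract
    sel <- select_K(catalog$counts, K_range = ex$K_range,
                    stability_min = ex$stability_min,
                    n_resamples = ex$n_resamples, n_restarts = ex$n_restarts,
                    max_iter = ex$max_iter, tol = ex$tol, seed = cfg$seed + 2)
    fit <- sel$fits[[paste0("K", sel$best_K)]]
    kept <- filter_low_exposure(fit$signatures, fit$exposures, catalog$counts,
                                threshold = ex$exposure_filter)
    norm_sigs <- normalize_catalog(kept$signatures, freqs)
    n_cl <- min(ex$n_clusters, ncol(norm_sigs))
    clusters <- cluster_with_reference(norm_sigs, NULL, n_clusters = n_cl)
    directional <- lapply(clusters, annotate_direction,
                          low_mass_frac = ex$low_mass_frac)
    model <- list(selection = sel$table, best_K = sel$best_K,
                  below_threshold = sel$below_threshold,
                  removed = kept$removed)
    jsonlite::write_json(model, file.path(outdir, "model_selection.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  write_signatures(directional, file.path(outdir, "signatures.tsv"))

  # decompose
  block <- build_block_matrix(directional)
  spectra <- normalize_catalog(catalog$counts, freqs)
  dec <- cfg$decompose
  exposures <- do.call(rbind, lapply(rownames(spectra), function(s) {
    ep <- prune_signatures(spectra[s, ], block,
                           tolerance = dec$prune_tolerance)
    if (isTRUE(dec$robustness)) {
      ep <- robustness_filter(spectra[s, ], block, n_perturb = dec$n_perturb,
                              noise_frac = dec$noise_frac,
                              instability = dec$instability,
                              seed = cfg$seed + 3)
    }
    cbind(sample = s, asymmetry_values(ep))
  }))
  write_tsv(exposures, file.path(outdir, "exposures.tsv"))

  quartile_exposures <- do.call(rbind, lapply(names(by_quartile$counts),
                                              function(q) {
    sp <- normalize_catalog(by_quartile$counts[[q]], freqs)
    do.call(rbind, lapply(rownames(sp), function(s) {
      ep <- decompose(sp[s, ], block)
      cbind(sample = s, quartile = q, ep)
    }))
  }))
  write_tsv(quartile_exposures, file.path(outdir, "quartile_exposures.tsv"))

  # stats
  st <- cfg$stats
  asym <- cohort_asymmetry(exposures, min_exposure = st$min_exposure,
                           tukey_k = st$tukey_k)
  trend <- timing_trend(quartile_exposures, min_exposure = st$min_exposure)
  qmeans <- quartile_means(quartile_exposures)
  write_tsv(asym, file.path(outdir, "cohort_asymmetry.tsv"))
  write_tsv(trend, file.path(outdir, "timing_trend.tsv"))
  write_tsv(qmeans, file.path(outdir, "quartile_means.tsv"))

  manifest <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                   package = "strandsig",
                   version = as.character(utils::packageVersion("strandsig")),
                   n_samples = nrow(catalog$counts),
                   n_mutations = catalog$n_input,
                   drop_log = as.list(catalog$drop_log))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = genome, domains = domains, origin_bins = origin_bins,
                 truth = truth, mutations = mutations, catalog = catalog,
                 freqs = freqs, directional = directional, block = block,
                 exposures = exposures,
                 quartile_exposures = quartile_exposures, asymmetry = asym,
                 trend = trend, model = model))
}
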