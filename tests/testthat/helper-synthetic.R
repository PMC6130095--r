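# Shared small fixtures, built once per test run. The 600-kbp two-chromosome
# genome is large enough to contain every trinucleotide in both template
# orientations while keeping the site index cheap.

.fixtures <- new.env(parent = emptyenv())

fixture_world <- function() {
  if (is.null(.fixtures$world)) {
    genome <- make_genome(101, n_chrom = 2, chrom_length = 3e5)
    ann <- make_domains(genome, replicon_spacing = 2e5)
    domains <- assign_timing_quartiles(ann$domains)
    .fixtures$world <- list(
      genome = genome, annotation = ann, domains = domains,
      sites = site_index(genome, domains),
      freqs = count_trinucleotides(genome, domains))
  }
  .fixtures$world
}

fixture_cohort <- function(asymmetry_ratio = 1, n_samples = 8,
                           mutations_per_sample = 3000, seed = 11,
                           quartile_multipliers = c(1, 1, 1, 1),
                           n_signatures = 3) {
  w <- fixture_world()
  truth <- synthetic_truth(example_signatures(n_signatures),
                           asymmetry_ratio = asymmetry_ratio,
                           quartile_multipliers = quartile_multipliers,
                           n_samples = n_samples,
                           mutations_per_sample = mutations_per_sample,
                           seed = seed)
  make_cohort(w$genome, w$domains, truth, sites = w$sites)
}

# random directional signatures for solver-level tests (not well separated)
random_signatures <- function(n, seed) {
  set.seed(seed)
  t96 <- mutation_types_96()
  lapply(seq_len(n), function(i) {
    w <- rexp(96)
    w <- w / sum(w)
    list(weights = setNames(w, t96$label),
         direction = setNames(sample(c("leading", "lagging"), 96, TRUE),
                              t96$label),
         provenance = paste0("rand_", i))
  })
}
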