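#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data — a two-chromosome genome,
# alternating left/right replication domains with a timing gradient, a
# three-signature directional library, and a 40-sample cohort with a planted
# 3:1 matching:inverse strand asymmetry and a mutation rate rising across
# timing quartiles. All downstream stages read from results/data.

suppressPackageStartupMessages(library(strandsig))

outdir <- "results/data"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260927

genome <- make_genome(seed, n_chrom = 2, chrom_length = 1e6, gc_bias = 0.4)
ann <- make_domains(genome)
sigs <- example_signatures(3)
# per-sample signature activity varies across the cohort (as in real
# tumors); without that variation NMF could not separate the mixture
set.seed(seed)
expo_w <- matrix(rexp(40 * 3), 40)
expo_w <- expo_w / rowSums(expo_w)
truth <- synthetic_truth(sigs,
                         exposure_weights = expo_w,
                         asymmetry_ratio = 3,
                         quartile_multipliers = c(1, 1.3, 1.6, 2),
                         n_samples = 40, mutations_per_sample = 10000,
                         seed = seed)
domains <- assign_timing_quartiles(ann$domains)
mutations <- make_cohort(genome, domains, truth)

write_genome(genome, file.path(outdir, "genome.fa"))
write_domains(domains, file.path(outdir, "true_domains.tsv"))
write_timing_profile(ann$profile, file.path(outdir, "timing.bedgraph"))
write_bed(ann$origins, file.path(outdir, "origins.bed"))
write_mutations(mutations, file.path(outdir, "mutations.tsv"))
write_signatures(sigs, file.path(outdir, "planted_signatures.tsv"))
jsonlite::write_json(
  list(seed = seed, n_samples = truth$n_samples,
       mutations_per_sample = truth$mutations_per_sample,
       asymmetry_ratio = truth$asymmetry_ratio,
       quartile_multipliers = truth$quartile_multipliers,
       mean_exposure_weights = colMeans(truth$exposure_weights)),
  file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)

cat("simulated", nrow(mutations), "mutations in", truth$n_samples,
    "samples over", nrow(domains), "replication domains\n")
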