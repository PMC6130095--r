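#!/usr/bin/env Rscript
# Stage 6: cohort statistics. Per signature: the exact sign test on
# matching - inverse exposure differences across exposed samples
# (BH-corrected), the replication-timing trend (per-sample OLS slope of
# exposure vs quartile, sign test on slopes), per-quartile cohort means,
# and a negative control in which domain placement and annotation are
# randomized.

suppressPackageStartupMessages(library(strandsig))

datadir <- "results/data"
outdir <- "results"
exposures <- read.delim(file.path(datadir, "exposures.tsv"))
quartile_exposures <- read.delim(file.path(datadir, "quartile_exposures.tsv"))

asym <- cohort_asymmetry(exposures, min_exposure = 10, tukey_k = 2)
trend <- timing_trend(quartile_exposures, min_exposure = 10)
qmeans <- quartile_means(quartile_exposures)
write.table(asym, file.path(outdir, "cohort_asymmetry.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(trend, file.path(outdir, "timing_trend.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(qmeans, file.path(outdir, "quartile_means.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("strand asymmetry (planted matching:inverse ratio 3:1):\n")
print(asym, row.names = FALSE)
cat("\nreplication-timing trend (planted Q1..Q4 rate 1, 1.3, 1.6, 2):\n")
print(trend[, c("signature", "n", "median_slope_matching",
                "pct_positive_matching", "q_matching")], row.names = FALSE)

# negative control: randomized replication annotation
genome <- read_genome(file.path(datadir, "genome.fa"))
domains <- assign_timing_quartiles(read_domains(file.path(datadir, "domains.tsv")))
mutations <- read_mutations(file.path(datadir, "mutations.tsv"))
directional <- read_signatures(file.path(datadir, "signatures.tsv"))
block <- build_block_matrix(directional)
lens <- setNames(as.numeric(Biostrings::width(genome)), names(genome))
rand_dom <- randomize_domains(domains, lens, seed = 20260928)
counts <- build_catalog(mutations, rand_dom, genome = genome)$counts
rand_expo <- do.call(rbind, lapply(rownames(counts), function(s) {
  cbind(sample = s, decompose(as.numeric(counts[s, ]), block))
}))
rand_asym <- cohort_asymmetry(rand_expo, min_exposure = 10)
write.table(rand_asym, file.path(outdir, "cohort_asymmetry_randomized.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nrandomized-annotation control:\n")
print(rand_asym[, c("signature", "median_difference", "p", "q")],
      row.names = FALSE)
shrink <- median(abs(asym$median_difference) /
                   pmax(abs(rand_asym$median_difference), 1))
cat(sprintf(paste0("asymmetry magnitude collapses %.0f-fold under the",
                   " randomized annotation\n"), shrink))
cat("(with 80 shared 20-kbp domains a common-mode residual can stay\n",
    "nominally significant; see the methods vignette for the geometry)\n")
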