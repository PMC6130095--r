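#!/usr/bin/env Rscript
# Stage 2: derive the replication-domain annotation from the binned timing
# profile alone (slope of timing vs position per 20-kbp window, windows below
# 250 rtu/Mb dropped), assign timing quartiles, and build 1-kbp
# direction-annotated bins around the origins. Writing the derived domains —
# rather than reusing the generator's — means the whole downstream analysis
# rests on the same operational definition as real timing data would.

suppressPackageStartupMessages(library(strandsig))

datadir <- "results/data"
profile <- read_timing_profile(file.path(datadir, "timing.bedgraph"))
domains <- derive_domains_from_timing(profile, domain_width = 20000,
                                      slope_threshold = 250)
domains <- assign_timing_quartiles(domains)
write_domains(domains, file.path(datadir, "domains.tsv"))

genome <- read_genome(file.path(datadir, "genome.fa"))
origins <- read_bed(file.path(datadir, "origins.bed"))
bins <- build_origin_bins(origins, bin_width = 1000, max_bins = 1000,
                          chrom_lengths = setNames(as.numeric(Biostrings::width(genome)),
                                                   names(genome)))
write.table(bins, file.path(datadir, "origin_bins.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

true_dom <- read_domains(file.path(datadir, "true_domains.tsv"))
key <- function(x) paste(x$chrom, x$start, x$end)
shared <- intersect(key(true_dom), key(domains))
agree <- mean(domains$direction[match(shared, key(domains))] ==
                true_dom$direction[match(shared, key(true_dom))])
cat("derived", nrow(domains), "domains;", length(shared),
    "coincide with generator domains, direction agreement",
    sprintf("%.1f%%", 100 * agree), "\n")
print(table(domains$quartile))
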