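#!/usr/bin/env Rscript
# Stage 3: classify the cohort's SNVs into the 96 contextual types, orient
# them to the leading/lagging template via the derived domains, and build the
# strand-resolved catalogs: one global 40 x 192 matrix and one per timing
# quartile. Also computes the per-strand trinucleotide frequencies used for
# genome-scale normalization.

suppressPackageStartupMessages(library(strandsig))

datadir <- "results/data"
genome <- read_genome(file.path(datadir, "genome.fa"))
domains <- assign_timing_quartiles(read_domains(file.path(datadir, "domains.tsv")))
mutations <- read_mutations(file.path(datadir, "mutations.tsv"))

catalog <- build_catalog(mutations, domains, genome = genome)
by_quartile <- build_catalog(mutations, domains, genome = genome,
                             stratify_by = "quartile")
write_catalog(catalog$counts, file.path(datadir, "catalog.tsv"))
for (q in names(by_quartile$counts)) {
  write_catalog(by_quartile$counts[[q]],
                file.path(datadir, paste0("catalog_", q, ".tsv")))
}

freqs <- count_trinucleotides(genome, domains)
write.table(data.frame(trinuc = names(freqs$leading),
                       leading = freqs$leading, lagging = freqs$lagging,
                       genome = freqs$genome),
            file.path(datadir, "trinuc_freqs.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("cataloged", sum(catalog$counts), "of", catalog$n_input, "mutations (",
    sum(catalog$drop_log), "dropped: outside derived domains or invalid)\n")
cat("leading-template counts:", sum(catalog$counts[, 1:96]),
    " lagging:", sum(catalog$counts[, 97:192]), "\n")
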