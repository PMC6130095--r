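# Readers and writers for the plain-text formats the workflow consumes and
# emits. Internal coordinates are 0-based half-open (BED); the mutation TSV
# and VCF use 1-based positions and are converted here, at the boundary.

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write replication domains as BED6-like TSV
#'
#' Columns: chrom, start, end, name, score (mean timing in rtu), strand
#' (`+` = right-replicating, `-` = left-replicating).
#'
#' @param domains data frame (chrom, start, end, direction, timing).
#' @param path file path.
#' @return `read_domains`: data frame (chrom, start, end, direction, timing).
#' @export
write_domains <- function(domains, path) {
  bed <- data.frame(chrom = domains$chrom, start = domains$start,
                    end = domains$end,
                    name = sprintf("domain_%d", seq_len(nrow(domains))),
                    score = domains$timing,
                    strand = ifelse(domains$direction == "right", "+", "-"))
  write_tsv(bed, path)
}

#' @rdname write_domains
#' @export
read_domains <- function(path) {
  bed <- read.delim(path, stringsAsFactors = FALSE)
  bad <- !bed$strand %in% c("+", "-")
  if (any(bad)) {
    stop("invalid strand value in domains BED at line ",
         which(bad)[1L] + 1L, " of ", path)
  }
  data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
             direction = ifelse(bed$strand == "+", "right", "left"),
             timing = bed$score)
}

#' Read and write a binned replication-timing profile (bedGraph)
#'
#' @param profile data frame (chrom, start, end, timing).
#' @param path file path.
#' @export
write_timing_profile <- function(profile, path) {
  write.table(profile[, c("chrom", "start", "end", "timing")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_timing_profile
#' @export
read_timing_profile <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(x[, 1:4], c("chrom", "start", "end", "timing"))
}

#' Read/write plain BED intervals (masks, origins)
#'
#' @param intervals data frame (chrom, start, end).
#' @param path file path.
#' @export
write_bed <- function(intervals, path) {
  write.table(intervals[, c("chrom", "start", "end")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(x[, 1:3], c("chrom", "start", "end"))
}

#' Read somatic SNVs from TSV or VCF
#'
#' TSV columns: sample, chrom, pos (1-based), ref, alt, optional context.
#' VCF input (requires the vcfR package) takes the sample name from the
#' `sample` argument, splits multi-allelic records per ALT allele and keeps
#' SNVs only.
#'
#' @param path file path (`.vcf` / `.vcf.gz` dispatches to the VCF reader).
#' @param sample sample identifier for VCF input.
#' @return data frame (sample, chrom, pos, ref, alt[, context]).
#' @export
read_mutations <- function(path, sample = NULL) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stop("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    alt_split <- strsplit(fix$ALT, ",", fixed = TRUE)
    n_alt <- lengths(alt_split)
    out <- data.frame(
      sample = if (is.null(sample)) basename(path) else sample,
      chrom = rep(fix$CHROM, n_alt),
      pos = rep(as.integer(fix$POS), n_alt),
      ref = rep(fix$REF, n_alt),
      alt = unlist(alt_split))
    out[nchar(out$ref) == 1L & nchar(out$alt) == 1L, , drop = FALSE]
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
}

#' Write a mutation table as TSV
#'
#' @param mutations data frame (sample, chrom, pos, ref, alt[, context]).
#' @param path file path.
#' @export
write_mutations <- function(mutations, path) write_tsv(mutations, path)

#' Read and write strand-resolved catalogs
#'
#' Rows are samples, the 192 labelled columns follow the canonical order of
#' [mutation_types_192()].
#'
#' @param catalog samples x 192 matrix.
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  write_tsv(cbind(sample = rownames(catalog), as.data.frame(catalog)), path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x$sample
  stopifnot(identical(colnames(m), catalog_colnames()))
  m
}

#' Read and write directional signatures
#'
#' 96 rows (canonical type order); per signature a weight column and a
#' direction column (`<name>` and `<name>.direction`).
#'
#' @param signatures list of directional signatures.
#' @param path file path.
#' @export
write_signatures <- function(signatures, path) {
  t96 <- mutation_types_96()
  out <- data.frame(type = t96$label)
  for (s in signatures) {
    out[[s$provenance]] <- unname(s$weights)
    out[[paste0(s$provenance, ".direction")]] <- unname(s$direction)
  }
  write_tsv(out, path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(identical(x$type, mutation_types_96()$label))
  nms <- setdiff(names(x), "type")
  weight_cols <- nms[!grepl("\\.direction$", nms)]
  lapply(weight_cols, function(nm) {
    list(weights = setNames(x[[nm]], x$type),
         direction = setNames(x[[paste0(nm, ".direction")]], x$type),
         provenance = nm)
  })
}

#' Read a reference signature matrix (COSMIC-style TSV)
#'
#' Tab-delimited, 96 rows with a type label column (`A[C>A]A` style) and one
#' column per signature; rows are reordered to the canonical order.
#'
#' @param path file path.
#' @param type_column name of the label column (default first column).
#' @return 96 x N numeric matrix.
#' @export
read_reference_signatures <- function(path, type_column = NULL) {
  x <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(type_column)) type_column <- names(x)[1L]
  ord <- match(mutation_types_96()$label, x[[type_column]])
  stopifnot(!anyNA(ord))
  m <- as.matrix(x[ord, setdiff(names(x), type_column), drop = FALSE])
  rownames(m) <- mutation_types_96()$label
  m
}

#' Write a genome as FASTA
#'
#' @param genome named `DNAStringSet`.
#' @param path file path.
#' @export
write_genome <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) Biostrings::readDNAStringSet(path)
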