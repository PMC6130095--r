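# Strand-resolved mutation catalogs: samples x 192 count matrices with the
# canonical column order of mutation_types_192() (leading block 1-96,
# lagging block 97-192).

catalog_colnames <- function() mutation_types_192()$label

#' Annotate classified mutations with their replication domain
#'
#' Maps each classified mutation to the replication domain containing it,
#' drops mutations that fall in an exclusion mask or outside every domain,
#' and assigns the replication template strand
#' (see [assign_template()]).
#'
#' @param classified data frame from [classify_mutations()]`$classified`.
#' @param domains data frame of replication domains (chrom, start, end,
#'   direction, optionally timing/quartile).
#' @param masks optional exclusion intervals (chrom, start, end).
#' @return list with `annotated` (surviving rows plus `direction`,
#'   `template` and any domain metadata) and `drop_log` (named counts:
#'   masked, outside_domain).
#' @keywords internal
annotate_mutations <- function(classified, domains, masks = NULL) {
  validate_intervals(domains, "domains")
  n <- nrow(classified)
  masked <- rep(FALSE, n)
  if (!is.null(masks) && nrow(masks)) {
    for (chr in unique(classified$chrom)) {
      m <- masks[masks$chrom == chr, , drop = FALSE]
      if (!nrow(m)) next
      i <- which(classified$chrom == chr)
      hit <- IRanges::overlapsAny(
        IRanges::IRanges(classified$pos[i], classified$pos[i]),
        IRanges::IRanges(m$start + 1L, m$end))
      masked[i] <- hit
    }
  }
  dom_idx <- rep(NA_integer_, n)
  for (chr in unique(classified$chrom)) {
    d_i <- which(domains$chrom == chr)
    if (!length(d_i)) next
    i <- which(classified$chrom == chr & !masked)
    if (!length(i)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(classified$pos[i], classified$pos[i]),
      IRanges::IRanges(domains$start[d_i] + 1L, domains$end[d_i]),
      select = "first")
    dom_idx[i] <- d_i[ov]
  }
  keep <- !masked & !is.na(dom_idx)
  annotated <- classified[keep, , drop = FALSE]
  extra <- setdiff(names(domains), c("chrom", "start", "end"))
  for (nm in extra) annotated[[nm]] <- domains[[nm]][dom_idx[keep]]
  annotated$template <- assign_template(annotated$pyr_strand, annotated$direction)
  list(annotated = annotated,
       drop_log = c(masked = sum(masked), outside_domain = sum(!masked & !keep)))
}

#' Build a strand-resolved 192-type mutation catalog
#'
#' Classifies mutations into the 96 contextual types, orients them to the
#' leading/lagging replication template using the domain annotation, and
#' counts them per sample into a samples x 192 matrix. With `stratify_by`,
#' one catalog is built per stratum (e.g. per timing quartile), each sample
#' keeping a row in every stratum.
#'
#' @param mutations data frame (sample, chrom, pos, ref, alt[, context]).
#' @param domains replication domains (chrom, start, end, direction, ...).
#' @param masks optional exclusion intervals.
#' @param genome optional `DNAStringSet` for context lookup/validation.
#' @param stratify_by optional name of a domain metadata column (e.g.
#'   `"quartile"`) to split catalogs by.
#' @return list with `counts` (matrix, or named list of matrices when
#'   stratified), `drop_log` (rejected/masked/outside counts) and
#'   `n_input` for conservation checks.
#' @export
build_catalog <- function(mutations, domains, masks = NULL, genome = NULL,
                          stratify_by = NULL) {
  cls <- classify_mutations(mutations, genome)
  ann <- annotate_mutations(cls$classified, domains, masks)
  a <- ann$annotated
  samples <- sort(unique(mutations$sample))
  count_one <- function(rows) {
    idx <- rows$type96 + ifelse(rows$template == "lagging", 96L, 0L)
    tab <- table(factor(rows$sample, levels = samples),
                 factor(idx, levels = seq_len(192L)))
    m <- matrix(as.integer(tab), nrow = length(samples), ncol = 192L,
                dimnames = list(samples, catalog_colnames()))
    m
  }
  counts <- if (is.null(stratify_by)) {
    count_one(a)
  } else {
    stopifnot(stratify_by %in% names(a))
    lvls <- sort(unique(a[[stratify_by]]))
    setNames(lapply(lvls, function(l) {
      count_one(a[a[[stratify_by]] == l, , drop = FALSE])
    }), lvls)
  }
  drop_log <- c(table(factor(cls$rejected$reason,
                             levels = c("ref_equals_alt", "non_acgt",
                                        "context_mismatch", "unknown_chrom",
                                        "out_of_range"))),
                ann$drop_log)
  list(counts = counts, drop_log = drop_log, n_input = nrow(mutations))
}

# Collapse map from the 64 trinucleotides to pyrimidine-centric 32 counts,
# split by the strand carrying the central pyrimidine (cached after first use).
.collapse_cache <- new.env(parent = emptyenv())
collapse64_map <- function() {
  if (is.null(.collapse_cache$map)) {
    all64 <- apply(expand.grid(BASES, BASES, BASES,
                               stringsAsFactors = FALSE)[, 3:1],
                   1L, paste0, collapse = "")
    pt <- pyr_trinuc(all64)
    .collapse_cache$map <- list(names64 = all64, pyr32 = pt$trinuc,
                                on_plus = pt$pyr_strand == "plus")
  }
  .collapse_cache$map
}

#' Count pyrimidine-centric trinucleotides per replication template strand
#'
#' For every unmasked position inside a replication domain whose plus-strand
#' 3-mer has a central pyrimidine, the 3-mer is counted in the template class
#' given by the domain direction (a plus-strand pyrimidine in a
#' left-replicating domain sits on the leading template); positions with a
#' central purine contribute their reverse-complement 3-mer to the opposite
#' class. Whole-genome collapsed counts are returned alongside.
#'
#' @param genome named `DNAStringSet`.
#' @param domains replication domains (chrom, start, end, direction).
#' @param masks optional exclusion intervals.
#' @return list with `leading`, `lagging` and `genome`: named 32-vectors over
#'   [pyrimidine_trinucs()].
#' @export
count_trinucleotides <- function(genome, domains, masks = NULL) {
  t32 <- pyrimidine_trinucs()
  zero <- setNames(numeric(32L), t32)
  lead <- lag_ <- zero
  pieces <- apply_exclusions(domains, masks)
  for (i in seq_len(nrow(pieces))) {
    chr <- pieces$chrom[i]
    L <- width(genome)[match(chr, names(genome))]
    if (is.na(L)) stop("domain on unknown chromosome ", chr)
    if (pieces$end[i] > L) {
      warning("domain beyond end of ", chr, "; truncated")
      pieces$end[i] <- L
    }
    # central positions (0-based) p in [max(start,1), min(end,L-1)-1]
    p0 <- max(pieces$start[i], 1L)
    p1 <- min(pieces$end[i], L - 1L) - 1L
    if (p1 < p0) next
    # 0-based centre p needs 1-based bases p..p+2; centres p0..p1 span [p0, p1+2]
    s <- Biostrings::subseq(genome[[chr]], start = p0, end = p1 + 2L)
    f <- Biostrings::oligonucleotideFrequency(s, width = 3L)
    cm <- collapse64_map()
    pyr_counts <- tapply(f[cm$names64][cm$on_plus], cm$pyr32[cm$on_plus], sum)
    pur_counts <- tapply(f[cm$names64][!cm$on_plus], cm$pyr32[!cm$on_plus], sum)
    pyr_counts <- replace(zero, names(pyr_counts), pyr_counts)
    pur_counts <- replace(zero, names(pur_counts), pur_counts)
    if (pieces$direction[i] == "left") {   # plus-strand pyrimidine -> leading
      lead <- lead + pyr_counts
      lag_ <- lag_ + pur_counts
    } else {
      lead <- lead + pur_counts
      lag_ <- lag_ + pyr_counts
    }
  }
  gf <- colSums(Biostrings::oligonucleotideFrequency(genome, width = 3L))
  cm <- collapse64_map()
  gen <- tapply(gf[cm$names64], cm$pyr32, sum)
  gen <- replace(zero, names(gen), gen)
  list(leading = lead, lagging = lag_, genome = gen)
}

#' Normalize a catalog or signature by strand trinucleotide frequencies
#'
#' Each entry for contextual type `t` on template strand `s` is scaled by
#' `genome_count(trinuc(t)) / strand_count(trinuc(t), s)`, converting
#' strand-restricted counts to genome-scale values comparable with
#' genome-based reference signatures. Calling the function again with the
#' arguments swapped (`strand_counts = list(leading = g, lagging = g)`,
#' `genome_counts = original strand counts`) inverts the transform.
#'
#' @param x numeric matrix with 192 columns (samples x types), or a 192
#'   vector/matrix of signature weights (types x signatures).
#' @param strand_counts list with `leading` and `lagging` 32-vectors over
#'   [pyrimidine_trinucs()] (e.g. from [count_trinucleotides()]).
#' @param genome_counts 32-vector, or list with per-strand 32-vectors.
#' @param zero_policy `"error"` (default) fails when a zero strand count
#'   meets a positive entry; `"pseudocount"` adds 1 to zero divisors.
#' @return object of the same shape as `x`, real-valued.
#' @export
normalize_catalog <- function(x, strand_counts, genome_counts = strand_counts$genome,
                              zero_policy = c("error", "pseudocount")) {
  zero_policy <- match.arg(zero_policy)
  t96 <- mutation_types_96()
  ctx <- t96$context
  strand192 <- rep(c("leading", "lagging"), each = 96L)
  denom <- c(strand_counts$leading[ctx], strand_counts$lagging[ctx])
  numer <- if (is.list(genome_counts)) {
    c(genome_counts$leading[ctx], genome_counts$lagging[ctx])
  } else {
    rep(genome_counts[ctx], 2L)
  }
  vec_input <- is.null(dim(x))
  m <- if (vec_input) matrix(x, nrow = 1L) else x
  by_row <- ncol(m) == 192L     # samples x 192; else 192 x signatures
  if (!by_row && nrow(m) != 192L) stop("x must have a dimension of length 192")
  vals <- if (by_row) m else t(m)
  bad <- denom == 0 & colSums(abs(vals)) > 0
  if (any(bad)) {
    if (zero_policy == "error") {
      stop("zero strand trinucleotide count with positive entries for ",
           paste(head(ctx[((which(bad) - 1L) %% 96L) + 1L]), collapse = ", "))
    }
    denom[denom == 0] <- 1
  }
  factor <- ifelse(denom == 0, 0, numer / denom)
  vals <- sweep(vals, 2L, factor, `*`)
  out <- if (by_row) vals else t(vals)
  if (vec_input) out <- setNames(as.vector(out), names(x))
  out
}
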