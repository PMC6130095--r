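# Synthetic study data with planted ground truth: a random genome, an
# alternating left/right replication-domain annotation with a timing
# gradient, a library of well-separated directional signatures, and mutation
# cohorts drawn from those signatures with configurable strand asymmetry and
# per-quartile rate multipliers. Every generative parameter is carried in a
# `synthetic_truth` list so recovery can be checked end to end.

#' Generate a random genome
#'
#' I.i.d. (or first-order Markov) nucleotide sequence with configurable GC
#' content, deterministic per seed.
#'
#' @param seed integer seed.
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 1e6).
#' @param gc_bias GC fraction (default 0.4, roughly mammalian).
#' @param transition optional 4 x 4 first-order Markov transition matrix
#'   (rows/cols A, C, G, T); overrides `gc_bias` beyond the first base.
#' @return named `DNAStringSet` (`chr1`, `chr2`, ...).
#' @export
make_genome <- function(seed, n_chrom = 2, chrom_length = 1e6, gc_bias = 0.4,
                        transition = NULL) {
  set.seed(seed)
  probs <- c(A = (1 - gc_bias) / 2, C = gc_bias / 2,
             G = gc_bias / 2, T = (1 - gc_bias) / 2)
  seqs <- vapply(seq_len(n_chrom), function(i) {
    if (is.null(transition)) {
      paste(sample(BASES, chrom_length, replace = TRUE, prob = probs),
            collapse = "")
    } else {
      stopifnot(all(dim(transition) == c(4L, 4L)))
      p <- transition / rowSums(transition)
      x <- integer(chrom_length)
      x[1L] <- sample.int(4L, 1L, prob = probs)
      for (j in 2:chrom_length) x[j] <- sample.int(4L, 1L, prob = p[x[j - 1L], ])
      paste(BASES[x], collapse = "")
    }
  }, character(1))
  setNames(Biostrings::DNAStringSet(seqs), paste0("chr", seq_len(n_chrom)))
}

#' Generate alternating replication domains with a timing gradient
#'
#' Synthetic origins are placed every `replicon_spacing` bp (the first at
#' half a spacing). Replication proceeds outwards, so domains right of an
#' origin are right-replicating and domains to its left left-replicating.
#' Timing (lower rtu = earlier under the default dialect) rises linearly
#' from `timing_range[1]` at the origin to `timing_range[2]` at the
#' termination midpoint between adjacent origins, so every replicon
#' populates all four timing quartiles. A binned timing profile over the
#' same gradient is emitted alongside, from which
#' [derive_domains_from_timing()] recovers the emitted directions.
#'
#' @param genome named `DNAStringSet` (only lengths are used).
#' @param domain_width domain width in bp (default 20000).
#' @param replicon_spacing origin spacing in bp (default 4e5; with the
#'   default timing range this yields a 400 rtu/Mb gradient, comfortably
#'   above the 250 rtu/Mb slope threshold).
#' @param timing_range timing at the origin and at the termination site
#'   (default c(10, 90) rtu).
#' @param profile_bin timing-profile bin width in bp (default 2500).
#' @return list with `domains` (chrom, start, end, direction, timing),
#'   `profile` (chrom, start, end, timing) and `origins` (chrom, start,
#'   end; 1-kbp intervals centred on each origin).
#' @export
make_domains <- function(genome, domain_width = 20000,
                         replicon_spacing = 4e5, timing_range = c(10, 90),
                         profile_bin = 2500) {
  half <- replicon_spacing / 2
  grad <- (timing_range[2L] - timing_range[1L]) / half
  per_chrom <- lapply(names(genome), function(chr) {
    L <- width(genome)[match(chr, names(genome))]
    origins <- seq(half, L - 1, by = replicon_spacing)
    timing_at <- function(x) {
      d <- vapply(x, function(xi) min(abs(xi - origins)), numeric(1))
      timing_range[1L] + pmin(d, half) * grad
    }
    n_win <- floor(L / domain_width)
    ws <- (seq_len(n_win) - 1L) * domain_width
    we <- ws + domain_width
    mid <- (ws + we) / 2
    nearest <- vapply(mid, function(xi) origins[which.min(abs(xi - origins))],
                      numeric(1))
    # keep windows lying entirely on one flank within half a spacing
    on_right <- mid > nearest
    flank_lo <- ifelse(on_right, nearest, pmax(nearest - half, 0))
    flank_hi <- ifelse(on_right, pmin(nearest + half, L), nearest)
    keep <- ws >= flank_lo & we <= flank_hi
    dom <- data.frame(chrom = chr, start = as.integer(ws[keep]),
                      end = as.integer(we[keep]),
                      direction = ifelse(on_right[keep], "right", "left"),
                      timing = (timing_at(ws[keep]) + timing_at(we[keep])) / 2)
    n_bin <- floor(L / profile_bin)
    bs <- (seq_len(n_bin) - 1L) * profile_bin
    prof <- data.frame(chrom = chr, start = as.integer(bs),
                       end = as.integer(bs + profile_bin),
                       timing = timing_at(bs + profile_bin / 2))
    orig <- data.frame(chrom = chr, start = as.integer(origins - 500),
                       end = as.integer(origins + 500))
    list(domains = dom, profile = prof, origins = orig)
  })
  list(domains = do.call(rbind, lapply(per_chrom, `[[`, "domains")),
       profile = do.call(rbind, lapply(per_chrom, `[[`, "profile")),
       origins = do.call(rbind, lapply(per_chrom, `[[`, "origins")))
}

#' Deterministic library of well-separated directional signatures
#'
#' Signatures occupy disjoint substitution groups (so pairwise cosine
#' similarity is zero) with smoothly varying weights over the 16 contexts of
#' each group, and alternate their dominant template: signature 1 is
#' lagging-flagged throughout, signature 2 leading, signature 3 lagging on
#' C-contexts and leading on the rest, and so on.
#'
#' @param n number of signatures (1-6; default 3).
#' @return list of directional signatures (`weights`, `direction`,
#'   `provenance`).
#' @export
example_signatures <- function(n = 3) {
  stopifnot(n >= 1, n <= 6)
  t96 <- mutation_types_96()
  groups <- split(seq_len(96L), t96$substitution)[
    c("C>A", "C>T", "T>C", "C>G", "T>A", "T>G")]
  lapply(seq_len(n), function(i) {
    w <- numeric(96L)
    idx <- groups[[i]]
    w[idx] <- 1 + sin(seq(0, pi, length.out = length(idx))) * 3
    w <- w / sum(w)
    dir <- rep(if (i %% 2L == 1L) "lagging" else "leading", 96L)
    if (i == 3L) dir[substr(t96$context, 2L, 2L) == "C"] <- "lagging"
    list(weights = setNames(w, t96$label),
         direction = setNames(dir, t96$label),
         provenance = paste0("planted_", i))
  })
}

#' Bundle the generative ground truth of a synthetic cohort
#'
#' @param signatures list of directional signatures (see
#'   [example_signatures()]).
#' @param exposure_weights n_samples x n_signatures matrix of per-sample
#'   signature mixing proportions (rows sum to 1), or a single vector
#'   recycled for all samples.
#' @param asymmetry_ratio per-signature matching:inverse odds of a mutation
#'   falling on its annotated template (1 = no planted asymmetry).
#' @param quartile_multipliers mutation-rate multiplier per timing quartile
#'   Q1..Q4 (default c(1, 1, 1, 1)).
#' @param n_samples number of samples (default 40).
#' @param mutations_per_sample Poisson mean mutation count per sample
#'   (default 10000).
#' @param seed integer seed.
#' @return list of class `synthetic_truth`.
#' @export
synthetic_truth <- function(signatures, exposure_weights = NULL,
                            asymmetry_ratio = 1,
                            quartile_multipliers = c(1, 1, 1, 1),
                            n_samples = 40, mutations_per_sample = 10000,
                            seed = 1) {
  K <- length(signatures)
  if (is.null(exposure_weights)) exposure_weights <- rep(1 / K, K)
  if (is.null(dim(exposure_weights))) {
    exposure_weights <- matrix(exposure_weights, n_samples, K, byrow = TRUE)
  }
  stopifnot(ncol(exposure_weights) == K, length(quartile_multipliers) == 4L)
  asymmetry_ratio <- rep_len(asymmetry_ratio, K)
  structure(list(signatures = signatures,
                 exposure_weights = exposure_weights,
                 asymmetry_ratio = asymmetry_ratio,
                 quartile_multipliers = quartile_multipliers,
                 n_samples = n_samples,
                 mutations_per_sample = mutations_per_sample,
                 seed = seed),
            class = "synthetic_truth")
}

# 192-element strand-resolved spectrum of one directional signature at a
# given matching:inverse odds ratio: a type flagged leading places mass
# r/(r+1) on the leading template.
strand_spectrum <- function(signature, ratio) {
  p_flag <- ratio / (ratio + 1)
  lead <- ifelse(signature$direction == "leading",
                 signature$weights * p_flag, signature$weights * (1 - p_flag))
  lag_ <- signature$weights - lead
  c(lead, lag_)
}

#' Index all mutable sites of a genome under a domain annotation
#'
#' One row per genomic position inside a replication domain (excluding
#' masked positions and chromosome edges) with its plus-strand trinucleotide
#' context, the strand of the central pyrimidine, the replication template
#' of that pyrimidine, and the timing quartile. Computed once and reused
#' across cohorts.
#'
#' @inheritParams build_catalog
#' @return data frame (chrom, pos, context, pyr32, pyr_strand, template,
#'   quartile).
#' @export
site_index <- function(genome, domains, masks = NULL) {
  if (!"quartile" %in% names(domains)) {
    domains <- assign_timing_quartiles(domains)
  }
  pieces <- apply_exclusions(domains, masks)
  rows <- lapply(seq_len(nrow(pieces)), function(i) {
    chr <- pieces$chrom[i]
    L <- width(genome)[match(chr, names(genome))]
    p0 <- max(pieces$start[i], 1L)
    p1 <- min(pieces$end[i], L - 1L) - 1L
    if (p1 < p0) return(NULL)
    s <- as.character(Biostrings::subseq(genome[[chr]], start = p0, end = p1 + 2L))
    n <- p1 - p0 + 1L
    ctx <- substring(s, seq_len(n), seq_len(n) + 2L)
    pt <- pyr_trinuc(ctx)
    data.frame(chrom = chr, pos = seq.int(p0 + 1L, by = 1L, length.out = n),
               context = ctx, pyr32 = pt$trinuc, pyr_strand = pt$pyr_strand,
               template = assign_template(pt$pyr_strand, pieces$direction[i]),
               quartile = pieces$quartile[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a mutation cohort with planted strand asymmetry
#'
#' Per sample, the mutation count is Poisson around
#' `truth$mutations_per_sample`; each mutation draws a signature by the
#' sample's exposure weights, then a strand-resolved channel (96-type x
#' template) from the signature's spectrum at its planted matching:inverse
#' ratio, and finally a genomic site whose trinucleotide context and
#' template orientation match the channel, weighted by the timing-quartile
#' rate multipliers. Records are emitted as plus-strand SNVs.
#'
#' @param genome named `DNAStringSet`.
#' @param domains replication domains (quartiles assigned if absent).
#' @param truth a [synthetic_truth()] object.
#' @param seed integer seed (defaults to `truth$seed`).
#' @param sites optional precomputed [site_index()].
#' @param masks optional exclusion intervals (used when `sites` is built).
#' @return data frame of mutation records (sample, chrom, pos, ref, alt,
#'   context) with attribute `truth`.
#' @export
make_cohort <- function(genome, domains, truth, seed = truth$seed,
                        sites = NULL, masks = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (is.null(sites)) sites <- site_index(genome, domains, masks)
  set.seed(seed)
  K <- length(truth$signatures)
  t96 <- mutation_types_96()
  spectra <- vapply(seq_len(K), function(k) {
    strand_spectrum(truth$signatures[[k]], truth$asymmetry_ratio[k])
  }, numeric(192))
  qmult <- setNames(truth$quartile_multipliers, paste0("Q", 1:4))
  site_w <- qmult[sites$quartile]
  site_groups <- split(seq_len(nrow(sites)),
                       paste0(sites$pyr32, "_", sites$template))

  n_mut <- rpois(truth$n_samples, truth$mutations_per_sample)
  sample_id <- rep(sprintf("S%03d", seq_len(truth$n_samples)), n_mut)
  total <- sum(n_mut)
  sig_of <- integer(total)
  off <- 0L
  for (s in seq_len(truth$n_samples)) {
    if (n_mut[s] > 0L) {
      sig_of[off + seq_len(n_mut[s])] <-
        sample.int(K, n_mut[s], replace = TRUE, prob = truth$exposure_weights[s, ])
    }
    off <- off + n_mut[s]
  }
  channel <- integer(total)
  for (k in seq_len(K)) {
    i <- which(sig_of == k)
    if (length(i)) {
      channel[i] <- sample.int(192L, length(i), replace = TRUE,
                               prob = spectra[, k])
    }
  }
  channel_group <- paste0(t96$context[((seq_len(192L) - 1L) %% 96L) + 1L], "_",
                          rep(c("leading", "lagging"), each = 96L))
  available <- channel_group %in% names(site_groups)
  group_key <- channel_group[channel]
  missing <- !available[channel]
  if (any(missing)) {
    # no genomic site matches the drawn channel: resample the channel from
    # the signature's spectrum restricted to placeable channels
    warning(sum(missing), " mutations redrawn onto placeable channels")
    for (k in seq_len(K)) {
      i <- which(missing & sig_of == k)
      if (length(i)) {
        channel[i] <- sample(which(available), length(i), replace = TRUE,
                             prob = spectra[available, k])
      }
    }
    group_key <- channel_group[channel]
  }
  type96 <- ((channel - 1L) %% 96L) + 1L
  template <- ifelse(channel > 96L, "lagging", "leading")

  site_row <- integer(total)
  for (g in unique(group_key)) {
    i <- which(group_key == g)
    cand <- site_groups[[g]]
    site_row[i] <- cand[sample.int(length(cand), length(i), replace = TRUE,
                                   prob = site_w[cand])]
  }
  hit <- sites[site_row, , drop = FALSE]
  sub_ref <- t96$ref[type96]
  sub_alt <- t96$alt[type96]
  on_minus <- hit$pyr_strand == "minus"
  ref <- ifelse(on_minus, complement_bases(sub_ref), sub_ref)
  alt <- ifelse(on_minus, complement_bases(sub_alt), sub_alt)
  out <- data.frame(sample = sample_id, chrom = hit$chrom, pos = hit$pos,
                    ref = ref, alt = alt, context = hit$context)
  out <- out[order(out$sample, out$chrom, out$pos), ]
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}
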