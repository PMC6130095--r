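test_that("strand trinucleotide counts match a per-position oracle", {
  # single central C in a left domain lands on the leading template
  genome <- Biostrings::DNAStringSet(c(chr1 = "ACA"))
  dom <- data.frame(chrom = "chr1", start = 0L, end = 3L, direction = "left")
  fr <- count_trinucleotides(genome, dom)
  expect_equal(unname(fr$leading["ACA"]), 1)
  expect_equal(sum(fr$leading), 1)
  expect_equal(sum(fr$lagging), 0)
  # all-N sequence contributes nothing
  fr_n <- count_trinucleotides(Biostrings::DNAStringSet(c(chr1 = "NNNNNN")),
                               transform(dom, end = 6L))
  expect_equal(sum(fr_n$leading) + sum(fr_n$lagging), 0)

  # 100-bp random sequence vs brute-force enumeration per position
  set.seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = s))
  dom <- data.frame(chrom = "chr1", start = c(0L, 60L), end = c(40L, 100L),
                    direction = c("left", "right"))
  masks <- data.frame(chrom = "chr1", start = 10L, end = 20L)
  fr <- count_trinucleotides(genome, dom, masks)
  oracle <- list(leading = setNames(numeric(32), pyrimidine_trinucs()),
                 lagging = setNames(numeric(32), pyrimidine_trinucs()))
  for (p in 1:100) {            # p is 1-based central position
    p0 <- p - 1L
    in_dom <- which(dom$start <= p0 & p0 < dom$end)
    if (!length(in_dom) || (10 <= p0 && p0 < 20) || p == 1 || p == 100) next
    tri <- substr(s, p - 1, p + 1)
    central <- substr(tri, 2, 2)
    if (central %in% c("C", "T")) {
      strand <- "plus"
    } else {
      strand <- "minus"
      tri <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
    }
    cls <- assign_template(strand, dom$direction[in_dom])
    oracle[[cls]][tri] <- oracle[[cls]][tri] + 1
  }
  expect_equal(fr$leading, oracle$leading)
  expect_equal(fr$lagging, oracle$lagging)
})

test_that("catalog counts one mutation in the expected strand-resolved slot", {
  genome <- Biostrings::DNAStringSet(c(chr1 = "AAACGTTT"))
  dom <- data.frame(chrom = "chr1", start = 0L, end = 8L, direction = "left")
  mut <- data.frame(sample = "s1", chrom = "chr1", pos = 4L, ref = "C",
                    alt = "T")
  cat1 <- build_catalog(mut, dom, genome = genome)
  expect_equal(sum(cat1$counts), 1L)
  expect_equal(unname(cat1$counts[1L, "A[C>T]G_leading"]), 1L)
})

test_that("classified + rejected + dropped equals the input record count", {
  w <- fixture_world()
  mut <- fixture_cohort(n_samples = 4, mutations_per_sample = 500)
  # corrupt some records and push some outside all domains
  mut$alt[1:5] <- mut$ref[1:5]
  mut$pos[6:10] <- 1L   # chromosome edge: no full context
  masks <- data.frame(chrom = "chr1", start = 0L, end = 50000L)
  cat1 <- build_catalog(mut, w$domains, masks = masks, genome = w$genome)
  expect_equal(sum(cat1$counts) + sum(cat1$drop_log), cat1$n_input)
  expect_gte(cat1$drop_log[["masked"]], 1L)
  expect_equal(unname(cat1$drop_log["ref_equals_alt"]), 5L)
})

test_that("catalog equals an independent per-record recomputation", {
  w <- fixture_world()
  mut <- fixture_cohort(n_samples = 3, mutations_per_sample = 400, seed = 21)
  cat1 <- build_catalog(mut, w$domains, genome = w$genome)
  t96 <- mutation_types_96()
  oracle <- matrix(0L, nrow(cat1$counts), 192L,
                   dimnames = dimnames(cat1$counts))
  for (i in seq_len(nrow(mut))) {
    tri <- mut$context[i]
    sub <- paste0(mut$ref[i], ">", mut$alt[i])
    if (mut$ref[i] %in% c("A", "G")) {
      tri <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
      sub <- paste0(chartr("ACGT", "TGCA", mut$ref[i]), ">",
                    chartr("ACGT", "TGCA", mut$alt[i]))
      strand <- "minus"
    } else {
      strand <- "plus"
    }
    d <- w$domains[w$domains$chrom == mut$chrom[i] &
                     w$domains$start < mut$pos[i] &
                     mut$pos[i] <= w$domains$end, ]
    if (!nrow(d)) next
    tpl <- assign_template(strand, d$direction[1L])
    idx <- which(t96$substitution == sub & t96$context == tri)
    col <- idx + if (tpl == "lagging") 96L else 0L
    oracle[mut$sample[i], col] <- oracle[mut$sample[i], col] + 1L
  }
  expect_equal(unname(cat1$counts), unname(oracle))
})

test_that("flipping every domain direction swaps the strand blocks exactly", {
  w <- fixture_world()
  mut <- fixture_cohort(n_samples = 3, mutations_per_sample = 500, seed = 31)
  flipped <- transform(w$domains,
                       direction = ifelse(direction == "left", "right", "left"))
  a <- build_catalog(mut, w$domains, genome = w$genome)$counts
  b <- build_catalog(mut, flipped, genome = w$genome)$counts
  expect_equal(unname(a[, 1:96]), unname(b[, 97:192]))
  expect_equal(unname(a[, 97:192]), unname(b[, 1:96]))
})

test_that("trinucleotide normalization scales, inverts and guards zeros", {
  t32 <- pyrimidine_trinucs()
  equal <- setNames(rep(100, 32), t32)
  x <- matrix(rpois(192 * 2, 10), nrow = 2,
              dimnames = list(c("a", "b"), catalog_colnames()))
  # equal strand and genome frequencies: identity
  same <- normalize_catalog(x, list(leading = equal, lagging = equal), equal)
  expect_equal(unname(same), unname(x) * 1.0)
  # strand count half the genome count: entries double
  halved <- normalize_catalog(x, list(leading = equal / 2, lagging = equal / 2),
                              equal)
  expect_equal(unname(halved), unname(x) * 2.0)
  # round trip with swapped arguments recovers the input
  w <- fixture_world()
  y <- normalize_catalog(x, w$freqs)
  back <- normalize_catalog(y, list(leading = w$freqs$genome,
                                    lagging = w$freqs$genome),
                            list(leading = w$freqs$leading,
                                 lagging = w$freqs$lagging))
  expect_equal(back, x * 1.0, tolerance = 1e-12)
  # zero divisor with positive entry errors; with zero entry yields zero
  zeroed <- w$freqs
  zeroed$leading["ACA"] <- 0
  expect_error(normalize_catalog(x, zeroed), "zero strand")
  x0 <- x
  aca_leading <- paste0(c("A[C>A]A", "A[C>G]A", "A[C>T]A"), "_leading")
  x0[, aca_leading] <- 0L   # every type sharing the ACA context
  expect_equal(unname(normalize_catalog(x0, zeroed)[, "A[C>A]A_leading"]),
               c(0, 0))
  expect_silent(normalize_catalog(x, zeroed, zero_policy = "pseudocount"))
})

test_that("signature-shaped input (192 rows) normalizes column-wise", {
  w <- fixture_world()
  sig <- matrix(runif(192 * 2), nrow = 192)
  out <- normalize_catalog(sig, w$freqs)
  t96 <- mutation_types_96()
  f1 <- w$freqs$genome[t96$context[1L]] / w$freqs$leading[t96$context[1L]]
  expect_equal(out[1L, 1L], sig[1L, 1L] * unname(f1))
  expect_equal(dim(out), dim(sig))
})
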