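make_profile <- function(timing, bin = 1000, chrom = "chr1") {
  n <- length(timing)
  data.frame(chrom = chrom, start = (seq_len(n) - 1L) * bin,
             end = seq_len(n) * bin, timing = timing)
}

test_that("domain direction follows the sign of the timing slope", {
  # linearly rising 500 rtu/Mb: every window right-replicating
  prof <- make_profile(seq(0, by = 0.5, length.out = 100))  # 0.5 rtu/kb
  dom <- derive_domains_from_timing(prof, domain_width = 20000,
                                    slope_threshold = 250)
  expect_equal(nrow(dom), 5L)
  expect_true(all(dom$direction == "right"))
  # the dialect flag inverts the convention
  dom_hi <- derive_domains_from_timing(prof, domain_width = 20000,
                                       slope_threshold = 250,
                                       rtu_high_is_early = TRUE)
  expect_true(all(dom_hi$direction == "left"))
  # flat profile: no domain survives the slope threshold
  flat <- make_profile(rep(5, 100))
  expect_equal(nrow(derive_domains_from_timing(flat, 20000, 250)), 0L)
})

test_that("triangular profiles split into flanks and lose the apex window", {
  # rise then fall at |slope| = 400 rtu/Mb, apex at 50 kbp of a 100-kbp chrom
  n <- 100
  x <- (seq_len(n) - 0.5) * 1000   # bin midpoints
  timing <- 400e-6 * (50000 - abs(x - 50000))
  prof <- make_profile(timing)
  dom <- derive_domains_from_timing(prof, domain_width = 20000,
                                    slope_threshold = 250)
  # brute-force oracle: per 20-kbp window, least-squares slope of its bins
  oracle <- sapply(0:4, function(w) {
    idx <- which(floor(x / 20000) == w)
    unname(coef(lm(timing[idx] ~ x[idx]))[2L]) * 1e6
  })
  kept <- which(abs(oracle) >= 250)
  expect_equal(dom$start, (kept - 1L) * 20000L)
  expect_equal(dom$direction, ifelse(oracle[kept] > 0, "right", "left"))
  # ascending flank right-replicating, descending flank left, apex dropped
  expect_true(all(dom$direction[dom$end <= 50000] == "right"))
  expect_true(all(dom$direction[dom$start >= 50000] == "left"))
  expect_false(any(dom$start < 50000 & dom$end > 50000))
})

test_that("degenerate profiles are skipped or rejected", {
  one_bin <- make_profile(5)
  expect_warning(dom <- derive_domains_from_timing(one_bin), "< 2 profile bins")
  expect_equal(nrow(dom), 0L)
  shuffled <- make_profile(1:10)[c(2, 1, 3:10), ]
  expect_silent(derive_domains_from_timing(shuffled))  # sorted internally
  overlapping <- make_profile(1:10)
  overlapping$start[2L] <- 500L
  expect_error(derive_domains_from_timing(overlapping), "non-monotone|overlap")
})

test_that("timing quartiles are balanced, ordered and dialect-aware", {
  dom <- data.frame(chrom = "chr1", start = 0:7 * 1000, end = 1:8 * 1000,
                    direction = "left", timing = 1:8)
  q <- assign_timing_quartiles(dom)
  # low rtu = early by default: timings 1,2 are the earliest quarter
  expect_equal(q$quartile[q$timing %in% c(1, 2)], c("Q1", "Q1"))
  expect_equal(q$quartile[q$timing %in% c(7, 8)], c("Q4", "Q4"))
  q_hi <- assign_timing_quartiles(dom, rtu_high_is_early = TRUE)
  expect_equal(q_hi$quartile[q_hi$timing %in% c(8, 7)], c("Q1", "Q1"))
  # 4 domains: one per quartile; 5 domains: sizes 2,1,1,1
  q4 <- assign_timing_quartiles(dom[1:4, ])
  expect_equal(sort(unique(q4$quartile)), paste0("Q", 1:4))
  q5 <- assign_timing_quartiles(dom[1:5, ])
  expect_equal(as.vector(table(q5$quartile)), c(2L, 1L, 1L, 1L))
  expect_warning(assign_timing_quartiles(transform(dom, timing = 3)),
                 "identical")
})

test_that("quartile sizes never differ by more than one", {
  for (n in c(4L, 7L, 9L, 23L, 40L)) {
    dom <- data.frame(chrom = "chr1", start = seq_len(n) * 10L - 10L,
                      end = seq_len(n) * 10L, direction = "left",
                      timing = rev(seq_len(n)))
    sizes <- table(assign_timing_quartiles(dom)$quartile)
    expect_lt(max(abs(sizes - n / 4)), 1)
  }
})

test_that("origin bins stop at half the distance to the next origin", {
  origins <- data.frame(chrom = "chr1", start = c(9999, 19999),
                        end = c(10001, 20001))
  bins <- build_origin_bins(origins, bin_width = 1000, max_bins = 1000)
  between <- bins[bins$start >= 10000 & bins$end <= 20000, ]
  # 5 bins on each side of the 10-kbp gap, none crossing the midpoint
  expect_equal(sum(between$side == "right_of_origin"), 5L)
  expect_equal(sum(between$side == "left_of_origin"), 5L)
  expect_true(all(between$end[between$side == "right_of_origin"] <= 15000))
  expect_true(all(between$start[between$side == "left_of_origin"] >= 15000))
  expect_equal(bins$direction,
               ifelse(bins$side == "right_of_origin", "right", "left"))
})

test_that("a lone origin on a large chromosome yields max_bins per side", {
  origins <- data.frame(chrom = "chr1", start = 1499999, end = 1500001)
  bins <- build_origin_bins(origins, bin_width = 1000, max_bins = 1000,
                            chrom_lengths = c(chr1 = 3e6))
  expect_equal(sum(bins$side == "left_of_origin"), 1000L)
  expect_equal(sum(bins$side == "right_of_origin"), 1000L)
  expect_true(all(bins$end - bins$start == 1000L))
  expect_true(all(bins$index >= 1L))
  # an origin at position 0 has no left-side bins
  at_zero <- build_origin_bins(data.frame(chrom = "chr1", start = 0, end = 1),
                               chrom_lengths = c(chr1 = 5000))
  expect_equal(sum(at_zero$side == "left_of_origin"), 0L)
})

test_that("origin bins from random placements never overlap", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample.int(2e5, 8))
    origins <- data.frame(chrom = "chr1", start = pos, end = pos + 2L)
    bins <- build_origin_bins(origins, bin_width = 500, max_bins = 50)
    ir <- IRanges::IRanges(bins$start + 1L, bins$end)
    expect_equal(sum(IRanges::width(IRanges::reduce(ir))), sum(IRanges::width(ir)))
  }
  expect_warning(
    build_origin_bins(data.frame(chrom = "chr1", start = c(0, 50),
                                 end = c(100, 150))),
    "merged")
})

test_that("mask subtraction matches a per-base membership oracle", {
  iv <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  out <- apply_exclusions(iv, data.frame(chrom = "chr1", start = 40L, end = 60L))
  expect_equal(out$start, c(0L, 60L))
  expect_equal(out$end, c(40L, 100L))
  expect_equal(nrow(apply_exclusions(iv, iv)), 0L)
  adj <- apply_exclusions(data.frame(chrom = "chr1", start = 0L, end = 40L),
                          data.frame(chrom = "chr1", start = c(10L, 20L),
                                     end = c(20L, 30L)))
  expect_equal(adj[, c("start", "end")],
               data.frame(start = c(0L, 30L), end = c(10L, 40L)))
  # property: per-base oracle and length conservation on random toys
  set.seed(7)
  for (rep in 1:20) {
    iv <- data.frame(chrom = "chr1", start = 0L, end = 10000L)
    ms <- sort(sample.int(9900L, 6L))
    masks <- data.frame(chrom = "chr1", start = ms,
                        end = ms + sample.int(400L, 6L))
    out <- apply_exclusions(iv, masks)
    base_in <- rep(TRUE, 10000L)
    for (j in seq_len(nrow(masks))) {
      base_in[(masks$start[j] + 1L):masks$end[j]] <- FALSE
    }
    covered <- rep(FALSE, 10000L)
    for (j in seq_len(nrow(out))) covered[(out$start[j] + 1L):out$end[j]] <- TRUE
    expect_equal(covered, base_in)
    overlap_len <- sum(!base_in)
    expect_equal(sum(out$end - out$start) + overlap_len, 10000L)
  }
})

test_that("domain randomization is deterministic and width-preserving", {
  w <- fixture_world()
  lens <- setNames(as.numeric(Biostrings::width(w$genome)), names(w$genome))
  r1 <- randomize_domains(w$domains, lens, seed = 5)
  r2 <- randomize_domains(w$domains, lens, seed = 5)
  expect_identical(r1, r2)
  expect_equal(sort(r1$end - r1$start), sort(w$domains$end - w$domains$start))
  expect_equal(sort(r1$timing), sort(w$domains$timing))
  # placements do not overlap
  for (chr in unique(r1$chrom)) {
    d <- r1[r1$chrom == chr, ]
    ir <- IRanges::IRanges(d$start + 1L, d$end)
    expect_equal(sum(IRanges::width(IRanges::reduce(ir))),
                 sum(IRanges::width(ir)))
  }
  too_big <- data.frame(chrom = "chr1", start = 0L, end = 2000L,
                        direction = "left", timing = 1)
  expect_error(randomize_domains(too_big, c(chr1 = 1000), seed = 1),
               "cannot place")
})
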