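# independent oracle: dense grid search over e >= 0, refined once around the
# coarse optimum; evaluates ||m - S e||^2 via the precomputed Gram matrix
grid_search_nnls <- function(S, m, upper, steps = 12L) {
  G <- crossprod(S)
  b <- crossprod(S, m)
  mm <- sum(m^2)
  eval_obj <- function(E) {
    rowSums((E %*% G) * E) - 2 * as.numeric(E %*% b) + mm
  }
  p <- ncol(S)
  axes <- lapply(seq_len(p), function(i) seq(0, upper[i], length.out = steps))
  E <- as.matrix(expand.grid(axes))
  best <- E[which.min(eval_obj(E)), ]
  # one refinement pass at 1/10 the coarse spacing
  spacing <- vapply(axes, function(a) a[2L] - a[1L], numeric(1))
  axes2 <- lapply(seq_len(p), function(i) {
    seq(max(0, best[i] - spacing[i]), best[i] + spacing[i], length.out = 21L)
  })
  E2 <- as.matrix(expand.grid(axes2))
  i2 <- which.min(eval_obj(E2))
  list(e = as.numeric(E2[i2, ]), resolution = spacing / 10)
}

test_that("the block matrix has the documented structure and symmetry", {
  t96 <- mutation_types_96()
  all_leading <- list(weights = setNames(rep(1 / 96, 96), t96$label),
                      direction = setNames(rep("leading", 96), t96$label),
                      provenance = "lead_only")
  blk <- build_block_matrix(list(all_leading))
  expect_equal(dim(blk$S), c(192L, 2L))
  expect_true(all(blk$S_LG == 0))
  sigs <- random_signatures(4, seed = 20)
  blk4 <- build_block_matrix(sigs)
  # disjoint support and additivity back to the 96 weights
  expect_true(all(blk4$S_LD * blk4$S_LG == 0))
  w <- vapply(sigs, function(s) unname(s$weights), numeric(96))
  expect_equal(unname(blk4$S_LD + blk4$S_LG), w)
  # swapping every flag exchanges the diagonal and off-diagonal blocks
  swapped <- lapply(sigs, function(s) {
    s$direction <- setNames(ifelse(s$direction == "leading",
                                   "lagging", "leading"), names(s$direction))
    s
  })
  blk_sw <- build_block_matrix(swapped)
  expect_equal(blk_sw$S_LD, blk4$S_LG)
  expect_equal(blk_sw$S_LG, blk4$S_LD)
  # 29 signatures give a 192 x 58 system
  blk29 <- build_block_matrix(random_signatures(29, seed = 21))
  expect_equal(dim(blk29$S), c(192L, 58L))
})

test_that("exact members of the model space are recovered", {
  sigs <- random_signatures(3, seed = 22)
  blk <- build_block_matrix(sigs)
  e_true <- c(100, 40, 5, 0, 60, 10)
  m <- as.numeric(blk$S %*% e_true)
  fit <- decompose(m, blk)
  e_hat <- c(fit$e_matching, fit$e_inverse)
  expect_equal(e_hat, e_true, tolerance = 1e-8)
  expect_lt(fit$residual[1L], 1e-8)
  # all-zero spectrum: zero exposures and residual
  fit0 <- decompose(numeric(192), blk)
  expect_true(all(fit0$e_matching == 0 & fit0$e_inverse == 0))
  expect_equal(fit0$residual[1L], 0)
})

test_that("a perfectly matching sample has zero inverse exposure", {
  sigs <- example_signatures(2)
  blk <- build_block_matrix(sigs)
  # mutations exactly on the annotated strands of each signature
  m <- as.numeric(blk$S %*% c(300, 200, 0, 0))
  fit <- asymmetry_values(decompose(m, blk))
  expect_equal(fit$e_inverse, c(0, 0))
  expect_equal(fit$e_matching, c(300, 200), tolerance = 1e-8)
  expect_true(all(fit$difference > 0))
})

test_that("swapping the strand halves of the spectrum swaps matching and inverse", {
  sigs <- random_signatures(3, seed = 23)
  blk <- build_block_matrix(sigs)
  set.seed(24)
  for (i in 1:10) {
    m <- rexp(192, rate = 1 / 10)
    a <- decompose(m, blk)
    b <- decompose(c(m[97:192], m[1:96]), blk)
    expect_equal(a$e_matching, b$e_inverse, tolerance = 1e-9)
    expect_equal(a$e_inverse, b$e_matching, tolerance = 1e-9)
  }
})

test_that("NNLS agrees with a dense grid search on small instances", {
  set.seed(25)
  for (trial in 1:20) {
    n_sig <- sample(1:2, 1L)
    sigs <- random_signatures(n_sig, seed = 250 + trial)
    blk <- build_block_matrix(sigs)
    e_true <- runif(2 * n_sig, 0, 100)
    m <- as.numeric(blk$S %*% e_true) + abs(rnorm(192, 0, 0.5))
    fit <- decompose(m, blk)
    e_hat <- c(fit$e_matching, fit$e_inverse)
    g <- grid_search_nnls(blk$S, m, upper = rep(150, 2 * n_sig))
    # NNLS is at least as good as the grid optimum, and close to it
    r_nnls <- sum((m - blk$S %*% e_hat)^2)
    r_grid <- sum((m - blk$S %*% g$e)^2)
    expect_lte(r_nnls, r_grid + 1e-9)
    expect_lt(max(abs(e_hat - g$e)), max(g$resolution) * 2)
  }
})

test_that("pruning removes unused signatures and respects the tolerance", {
  sigs <- example_signatures(2)
  blk <- build_block_matrix(sigs)
  m <- as.numeric(blk$S %*% c(500, 0, 0, 0))   # signature 1 only
  fit <- prune_signatures(m, blk, tolerance = 0.005)
  expect_equal(fit$pruned, c(FALSE, TRUE))
  expect_equal(fit$e_matching[1L], 500, tolerance = 1e-6)
  # tolerance 0 with a strict error increase for any removal: nothing pruned
  sigs3 <- random_signatures(3, seed = 26)
  blk3 <- build_block_matrix(sigs3)
  m3 <- as.numeric(blk3$S %*% c(100, 80, 60, 20, 10, 5))
  fit3 <- prune_signatures(m3, blk3, tolerance = 0)
  expect_false(any(fit3$pruned))
  # zero spectrum prunes everything at zero exposure
  fit0 <- prune_signatures(numeric(192), blk)
  expect_true(all(fit0$pruned))
  expect_true(all(fit0$e_matching == 0))
})

test_that("the robustness filter is inert without noise and keeps strong signatures", {
  sigs <- example_signatures(3)
  blk <- build_block_matrix(sigs)
  m <- as.numeric(blk$S %*% c(400, 300, 200, 50, 40, 30))
  quiet <- robustness_filter(m, blk, n_perturb = 20, noise_frac = 0,
                             seed = 27)
  expect_true(all(quiet$stable))
  for (s in 1:3) {
    noisy <- robustness_filter(m, blk, n_perturb = 100, noise_frac = 0.05,
                               seed = 27 + s)
    expect_true(all(noisy$stable))   # well-separated, well-exposed signatures
  }
})

test_that("near-collinear signatures are flagged unstable under perturbation", {
  t96 <- mutation_types_96()
  set.seed(28)
  w <- rexp(96)
  w <- w / sum(w)
  base_dir <- setNames(sample(c("leading", "lagging"), 96, TRUE), t96$label)
  twin <- function(eps, nm) {
    w2 <- w + runif(96, 0, eps)
    w2 <- w2 / sum(w2)
    list(weights = setNames(w2, t96$label), direction = base_dir,
         provenance = nm)
  }
  sigs <- list(twin(0, "a"), twin(1e-4, "b"))   # cosine > 0.999
  blk <- build_block_matrix(sigs)
  m <- as.numeric(blk$S %*% c(200, 200, 0, 0))
  fit <- robustness_filter(m, blk, n_perturb = 200, noise_frac = 0.05,
                           seed = 29)
  expect_true(any(!fit$stable))
})
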