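# Matching/inverse exposure decomposition. The block design matrix
#   S = [ S_LD  S_LG ]
#       [ S_LG  S_LD ]
# pairs each directional signature's leading-flagged weights (S_LD) and
# lagging-flagged weights (S_LG) so that the first N exposure coefficients
# (e_matching) place the signature on its annotated strands and the last N
# (e_inverse) on the swapped strands.

#' Assemble the block signature matrix from directional signatures
#'
#' @param signatures list of directional signatures (elements with `weights`
#'   (96) and `direction` (96 of `"leading"`/`"lagging"`)), e.g. from
#'   [annotate_direction()].
#' @return list with `S` (192 x 2N), `S_LD`, `S_LG` (96 x N) and
#'   `signature_names`.
#' @export
build_block_matrix <- function(signatures) {
  stopifnot(length(signatures) >= 1L)
  nms <- vapply(seq_along(signatures), function(i) {
    p <- signatures[[i]]$provenance
    if (is.null(p)) paste0("sig_", i) else p
  }, character(1))
  S_LD <- vapply(signatures, function(s) {
    ifelse(s$direction == "leading", s$weights, 0)
  }, numeric(96))
  S_LG <- vapply(signatures, function(s) {
    ifelse(s$direction == "lagging", s$weights, 0)
  }, numeric(96))
  S_LD <- matrix(S_LD, nrow = 96L, dimnames = list(NULL, nms))
  S_LG <- matrix(S_LG, nrow = 96L, dimnames = list(NULL, nms))
  S <- rbind(cbind(S_LD, S_LG), cbind(S_LG, S_LD))
  colnames(S) <- c(paste0(nms, ".matching"), paste0(nms, ".inverse"))
  list(S = S, S_LD = S_LD, S_LG = S_LG, signature_names = nms)
}

as_spectrum <- function(spectrum) {
  if (is.list(spectrum) && !is.null(spectrum$m_LD)) {
    stopifnot(length(spectrum$m_LD) == 96L, length(spectrum$m_LG) == 96L)
    return(c(spectrum$m_LD, spectrum$m_LG))
  }
  stopifnot(length(spectrum) == 192L)
  as.numeric(spectrum)
}

exposure_pair <- function(block, e, residual, pruned = character(),
                          unstable = character()) {
  N <- length(block$signature_names)
  data.frame(signature = block$signature_names,
             e_matching = e[seq_len(N)],
             e_inverse = e[N + seq_len(N)],
             pruned = block$signature_names %in% pruned,
             stable = !(block$signature_names %in% unstable),
             residual = residual,
             row.names = NULL)
}

#' Decompose a strand-resolved spectrum into matching and inverse exposures
#'
#' Solves `min ||m - S e||` over `e >= 0` by non-negative least squares,
#' where `m` is the concatenated (leading, lagging) trinucleotide-normalized
#' spectrum and `S` the block signature matrix. `e_matching` is the exposure
#' of each signature on its annotated strands, `e_inverse` on the swapped
#' strands.
#'
#' @param spectrum 192-vector, or list with `m_LD` and `m_LG` (96 each).
#' @param block result of [build_block_matrix()].
#' @return data frame (signature, e_matching, e_inverse, pruned, stable,
#'   residual); the `difference` and `fold_change` asymmetry statistics can
#'   be added with [asymmetry_values()].
#' @export
decompose <- function(spectrum, block) {
  m <- as_spectrum(spectrum)
  fit <- nnls_fit(block$S, m)
  exposure_pair(block, fit$x, fit$resid)
}

#' Per-signature strand-asymmetry statistics
#'
#' @param exposures data frame from [decompose()] and friends.
#' @param epsilon pseudo-exposure added to both terms of the fold change
#'   (default 1, in exposure units, i.e. roughly mutation counts).
#' @return `exposures` with added `difference` and `fold_change` columns.
#' @export
asymmetry_values <- function(exposures, epsilon = 1) {
  exposures$difference <- exposures$e_matching - exposures$e_inverse
  exposures$fold_change <- log2((exposures$e_matching + epsilon) /
                                  (exposures$e_inverse + epsilon))
  exposures
}

refit_subset <- function(block, m, active) {
  N <- length(block$signature_names)
  cols <- c(active, N + active)
  if (!length(active)) {
    return(list(x = numeric(0), resid = sqrt(sum(m^2))))
  }
  nnls_fit(block$S[, cols, drop = FALSE], m)
}

expand_subset <- function(block, active, x) {
  N <- length(block$signature_names)
  e <- numeric(2L * N)
  e[c(active, N + active)] <- x
  e
}

#' Prune spuriously exposed signatures
#'
#' Starting from the full NNLS fit, the signature with the smallest total
#' exposure (matching + inverse) is removed (both parts at once) and the
#' exposures refit; the removal is kept as long as the residual does not
#' exceed the original (unpruned) residual by more than `tolerance`
#' (relative). The first rejected removal stops the greedy loop.
#'
#' @inheritParams decompose
#' @param tolerance relative residual increase allowed over the original
#'   fit (default 0.005, i.e. 0.5%).
#' @return data frame as [decompose()], with `pruned` flags set.
#' @export
prune_signatures <- function(spectrum, block, tolerance = 0.005) {
  m <- as_spectrum(spectrum)
  N <- length(block$signature_names)
  full <- nnls_fit(block$S, m)
  r0 <- full$resid
  active <- seq_len(N)
  x <- full$x
  repeat {
    if (!length(active)) break
    tot <- x[seq_along(active)] + x[length(active) + seq_along(active)]
    drop_i <- active[which.min(tot)]
    candidate <- setdiff(active, drop_i)
    fit <- refit_subset(block, m, candidate)
    if (fit$resid <= r0 * (1 + tolerance)) {
      active <- candidate
      x <- fit$x
    } else {
      break
    }
  }
  e <- expand_subset(block, active, x)
  resid <- if (length(active)) refit_subset(block, m, active)$resid else sqrt(sum(m^2))
  pruned <- block$signature_names[setdiff(seq_len(N), active)]
  exposure_pair(block, e, resid, pruned = pruned)
}

#' Filter exposures that are not robust to spectrum noise
#'
#' The spectrum is perturbed `n_perturb` times with independent Gaussian
#' noise (sd = `noise_frac` of each entry, negatives clamped to zero) and
#' exposures refit each time. A signature is unstable for this sample when
#' its perturbation quartiles deviate from the unperturbed total exposure
#' `x` by 30% or more: `(q75 - x)/x >= 0.3` or `(x - q25)/x >= 0.3`. A
#' signature with `x = 0` is unstable only when some perturbed exposure
#' exceeds `zero_floor`. Unstable signatures are removed and the exposures
#' recomputed with the remaining ones.
#'
#' @inheritParams decompose
#' @param n_perturb number of perturbations (default 1000).
#' @param noise_frac noise standard deviation as a fraction of each entry
#'   (default 0.05).
#' @param instability relative quartile deviation that flags a signature
#'   (default 0.3).
#' @param zero_floor absolute exposure floor for zero-exposure signatures
#'   (default 10).
#' @param seed integer seed (required).
#' @return data frame as [decompose()], with `stable` flags set and
#'   exposures refit on the stable set.
#' @export
robustness_filter <- function(spectrum, block, n_perturb = 1000,
                              noise_frac = 0.05, instability = 0.3,
                              zero_floor = 10, seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  m <- as_spectrum(spectrum)
  N <- length(block$signature_names)
  base <- nnls_fit(block$S, m)
  x <- base$x[seq_len(N)] + base$x[N + seq_len(N)]
  perturbed <- matrix(0, n_perturb, N)
  for (p in seq_len(n_perturb)) {
    mp <- pmax(m + rnorm(length(m), mean = 0, sd = noise_frac * m), 0)
    ep <- nnls_fit(block$S, mp)$x
    perturbed[p, ] <- ep[seq_len(N)] + ep[N + seq_len(N)]
  }
  q25 <- apply(perturbed, 2L, quantile, probs = 0.25, type = 7)
  q75 <- apply(perturbed, 2L, quantile, probs = 0.75, type = 7)
  unstable <- ifelse(x > 0,
                     (q75 - x) / x >= instability | (x - q25) / x >= instability,
                     apply(perturbed, 2L, max) > zero_floor)
  active <- which(!unstable)
  fit <- refit_subset(block, m, active)
  e <- expand_subset(block, active, fit$x)
  exposure_pair(block, e, fit$resid,
                unstable = block$signature_names[unstable])
}
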