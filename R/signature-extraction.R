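# Strand-specific signature extraction: bootstrapped NMF with model selection
# by reconstruction error and cluster stability, low-exposure filtering,
# clustering against an optional reference catalog, and directional
# annotation of the cluster representatives.

nnls_fit <- function(A, b) {
  if (all(b == 0) || ncol(A) == 0L) {
    return(list(x = numeric(ncol(A)), resid = sqrt(sum(b^2))))
  }
  fit <- pracma::lsqnonneg(A, b)
  list(x = fit$x, resid = sqrt(sum((b - A %*% fit$x)^2)))
}

nnls_exposures <- function(signatures, V) {
  out <- vapply(seq_len(ncol(V)), function(j) nnls_fit(signatures, V[, j])$x,
                numeric(ncol(signatures)))
  out <- matrix(out, nrow = ncol(signatures), ncol = ncol(V),
                dimnames = list(colnames(signatures), colnames(V)))
  out
}

#' Extract strand-specific signatures by bootstrapped NMF
#'
#' Each resample draws a multinomial bootstrap of every sample's 192-type
#' counts and factorizes it at rank `K` ([nmf_mu()]). The pooled signatures
#' from all resamples are partitioned into `K` clusters by cosine distance
#' (`cluster::pam`); the mean silhouette width of that partition is the
#' stability of rank `K`, the mean Frobenius residual across resamples its
#' error. Cluster centroids, column-normalized, are the representative
#' signatures; exposures are refit on the unperturbed catalog by NNLS.
#'
#' @param catalog samples x 192 count matrix.
#' @param K number of signatures.
#' @param n_resamples bootstrap resamples (default 100).
#' @param n_restarts,max_iter,tol passed to [nmf_mu()].
#' @param seed integer seed; fixed seed gives bit-identical reruns.
#' @return list with `signatures` (192 x K, columns sum to 1), `exposures`
#'   (K x samples), `error`, `stability`, `K`.
#' @export
nmf_extract <- function(catalog, K, n_resamples = 100, n_restarts = 10,
                        max_iter = 10000, tol = 1e-9, seed = 1) {
  V <- t(catalog)
  totals <- colSums(V)
  V <- V[, totals > 0, drop = FALSE]
  if (ncol(V) < K) stop("K exceeds the number of samples with nonzero totals")
  set.seed(seed)
  pooled <- vector("list", n_resamples)
  errs <- numeric(n_resamples)
  for (r in seq_len(n_resamples)) {
    Vb <- vapply(seq_len(ncol(V)), function(j) {
      as.numeric(rmultinom(1L, size = sum(V[, j]), prob = V[, j] / sum(V[, j])))
    }, numeric(nrow(V)))
    fit <- nmf_mu(Vb, K, n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    pooled[[r]] <- fit$W
    errs[r] <- fit$error
  }
  Wp <- do.call(cbind, pooled)
  if (K == 1L) {
    reps <- matrix(rowMeans(Wp), ncol = 1L)
    stability <- 1
  } else {
    d <- cosine_dist(Wp)
    part <- cluster::pam(d, k = K, diss = TRUE)
    stability <- part$silinfo$avg.width
    reps <- vapply(seq_len(K), function(k) {
      rowMeans(Wp[, part$clustering == k, drop = FALSE])
    }, numeric(nrow(Wp)))
  }
  reps <- sweep(reps, 2L, colSums(reps), `/`)
  rownames(reps) <- rownames(V)
  colnames(reps) <- paste0("S", seq_len(K))
  expo <- nnls_exposures(reps, V)
  list(signatures = reps, exposures = expo,
       error = mean(errs), stability = stability, K = K)
}

#' Select the number of signatures by error and stability
#'
#' Runs [nmf_extract()] over `K_range` and selects, among ranks with
#' stability at least `stability_min`, the minimizer of
#' `error_K / max(error) + (1 - stability_K)`; ties go to the smaller K.
#' When no rank reaches the stability threshold, the most stable rank is
#' returned with `below_threshold = TRUE`.
#'
#' @inheritParams nmf_extract
#' @param K_range candidate ranks (default 2:7).
#' @param stability_min minimum acceptable stability (default 0.8).
#' @return list with `best_K`, `below_threshold`, `table` (per-K error,
#'   stability, objective) and `fits` (the [nmf_extract()] results).
#' @export
select_K <- function(catalog, K_range = 2:7, stability_min = 0.8,
                     n_resamples = 100, n_restarts = 10, max_iter = 10000,
                     tol = 1e-9, seed = 1) {
  stopifnot(length(K_range) >= 1L)
  fits <- lapply(seq_along(K_range), function(i) {
    nmf_extract(catalog, K_range[i], n_resamples = n_resamples,
                n_restarts = n_restarts, max_iter = max_iter, tol = tol,
                seed = seed + i - 1L)
  })
  err <- vapply(fits, `[[`, numeric(1), "error")
  stab <- vapply(fits, `[[`, numeric(1), "stability")
  sel <- select_rule(K_range, err, stab, stability_min)
  c(sel, list(fits = setNames(fits, paste0("K", K_range))))
}

# the model-selection rule itself, separated from the NMF runs: among ranks
# with stability >= stability_min minimize error/max(error) + (1 - stability),
# ties to the smaller K; if none qualifies, the most stable K is flagged.
select_rule <- function(K_range, error, stability, stability_min = 0.8) {
  objective <- error / max(error) + (1 - stability)
  tab <- data.frame(K = K_range, error = error, stability = stability,
                    objective = objective)
  eligible <- which(stability >= stability_min)
  if (length(eligible)) {
    best <- eligible[order(objective[eligible], K_range[eligible])][1L]
    below <- FALSE
  } else {
    best <- order(-stability, K_range)[1L]
    below <- TRUE
  }
  list(best_K = K_range[best], below_threshold = below, table = tab)
}

#' Remove signatures with uniformly low exposure
#'
#' A signature is discarded when the 95th percentile of its per-sample
#' exposures, divided by the mean total exposure per sample, is below
#' `threshold` (strictly; a ratio exactly at the threshold is retained).
#' Exposures are refit by NNLS on the retained set.
#'
#' @param signatures 192 x K matrix.
#' @param exposures K x samples matrix from [nmf_extract()].
#' @param catalog samples x 192 count matrix for the refit.
#' @param threshold exposure ratio cut-off (default 0.2).
#' @return list with `signatures`, `exposures` (refit), `removed` (names).
#' @export
filter_low_exposure <- function(signatures, exposures, catalog,
                                threshold = 0.2) {
  mean_total <- mean(colSums(exposures))
  ratio <- if (mean_total > 0) {
    apply(exposures, 1L, quantile, probs = 0.95, type = 7) / mean_total
  } else {
    rep(0, nrow(exposures))
  }
  keep <- ratio >= threshold
  if (!any(keep)) stop("all signatures fall below the exposure filter")
  sig <- signatures[, keep, drop = FALSE]
  expo <- nnls_exposures(sig, t(catalog))
  list(signatures = sig, exposures = expo,
       removed = colnames(signatures)[!keep])
}

embed_reference <- function(reference_96) {
  rbind(reference_96 / 2, reference_96 / 2)
}

#' Cluster strand-specific signatures with a reference catalog
#'
#' Reference 96-type signatures (if supplied) are embedded into 192
#' dimensions with equal leading and lagging halves, pooled with the
#' extracted strand-specific signatures, and clustered by unsupervised
#' hierarchical clustering (cosine distance, complete linkage), cutting the
#' tree at `n_clusters`. Each cluster's representative 96-type signature is
#' the reference member in its original form when one is present, otherwise
#' the mean of the members' collapsed (leading + lagging) halves. A
#' declarative `overrides` table can reassign members between clusters.
#'
#' @param strand_signatures 192 x M matrix, genome-normalized (see
#'   [normalize_catalog()]) so extracted and reference signatures are
#'   comparable.
#' @param reference_96 optional 96 x R matrix of reference signatures.
#' @param n_clusters number of clusters to cut the tree at (default 27 when
#'   the pool is large enough, otherwise it must be <= pool size).
#' @param overrides optional data frame (member, cluster) of manual
#'   reassignments applied after the cut.
#' @return list of clusters, each with `members`, `is_reference`,
#'   `strand_members` (192 x m matrix, possibly 0 columns),
#'   `representative_96` (named 96-vector, sums to 1) and `provenance`
#'   (reference name or `novel_<i>`).
#' @export
cluster_with_reference <- function(strand_signatures, reference_96 = NULL,
                                   n_clusters = 27, overrides = NULL) {
  stopifnot(nrow(strand_signatures) == 192L)
  if (is.null(colnames(strand_signatures))) {
    colnames(strand_signatures) <- paste0("extracted_", seq_len(ncol(strand_signatures)))
  }
  pool <- strand_signatures
  is_ref <- rep(FALSE, ncol(pool))
  if (!is.null(reference_96)) {
    stopifnot(nrow(reference_96) == 96L)
    if (is.null(colnames(reference_96))) {
      colnames(reference_96) <- paste0("Reference.", seq_len(ncol(reference_96)))
    }
    pool <- cbind(pool, embed_reference(reference_96))
    is_ref <- c(is_ref, rep(TRUE, ncol(reference_96)))
  }
  if (n_clusters > ncol(pool)) stop("n_clusters exceeds the pooled signature count")
  if (n_clusters == ncol(pool)) {
    assignment <- seq_len(ncol(pool))
  } else {
    hc <- hclust(cosine_dist(pool), method = "complete")
    assignment <- cutree(hc, k = n_clusters)
  }
  names(assignment) <- colnames(pool)
  if (!is.null(overrides)) {
    assignment[overrides$member] <- overrides$cluster
  }
  novel_i <- 0L
  lapply(sort(unique(assignment)), function(cl) {
    idx <- which(assignment == cl)
    refs <- idx[is_ref[idx]]
    strands <- idx[!is_ref[idx]]
    strand_members <- pool[, strands, drop = FALSE]
    if (length(refs)) {
      # use the reference closest (cosine) to the cluster mean, original form
      mean_member <- rowMeans(pool[, idx, drop = FALSE])
      sims <- cosine_similarity(pool[, refs, drop = FALSE],
                                matrix(mean_member, ncol = 1L))
      ref_name <- colnames(pool)[refs[which.max(sims)]]
      rep96 <- reference_96[, ref_name]
      provenance <- ref_name
    } else {
      collapsed <- rowMeans(strand_members[1:96, , drop = FALSE] +
                              strand_members[97:192, , drop = FALSE]) / 2
      rep96 <- collapsed / sum(collapsed)
      novel_i <<- novel_i + 1L
      provenance <- paste0("novel_", novel_i)
    }
    names(rep96) <- mutation_types_96()$label
    list(members = colnames(pool)[idx], is_reference = is_ref[idx],
         strand_members = strand_members, representative_96 = rep96,
         provenance = provenance, id = cl)
  })
}

#' Annotate a signature cluster with per-type strand direction
#'
#' For each of the 96 mutation types, the leading and lagging weights are
#' summed across the cluster's strand-specific members; the larger side is
#' the type's direction. Types whose mass is below `low_mass_frac` of the
#' total signature mass (or exactly tied) inherit the predominant direction
#' of the other types in the same substitution group (e.g. all C>T types);
#' a group with no informative types inherits the overall majority, and a
#' complete tie defaults to leading. Clusters containing only reference
#' members carry no strand evidence and are flagged all-leading with
#' `no_evidence = TRUE`.
#'
#' @param cluster one element of the [cluster_with_reference()] result.
#' @param low_mass_frac mass fraction below which a type's own evidence is
#'   considered unclear (default 0.005).
#' @return a directional signature: list with `weights` (96, sum 1),
#'   `direction` (96-vector of `"leading"`/`"lagging"`), `provenance`,
#'   `no_evidence`.
#' @export
annotate_direction <- function(cluster, low_mass_frac = 0.005) {
  t96 <- mutation_types_96()
  weights <- cluster$representative_96
  if (!ncol(cluster$strand_members)) {
    return(list(weights = weights,
                direction = setNames(rep("leading", 96L), t96$label),
                provenance = cluster$provenance, no_evidence = TRUE))
  }
  lead <- rowSums(cluster$strand_members[1:96, , drop = FALSE])
  lag_ <- rowSums(cluster$strand_members[97:192, , drop = FALSE])
  mass <- lead + lag_
  clear <- mass >= low_mass_frac * sum(mass) & lead != lag_
  dir <- ifelse(lead > lag_, "leading", "lagging")
  group_dir <- vapply(split(seq_len(96L), t96$substitution), function(i) {
    informative <- i[clear[i]]
    if (!length(informative)) return(NA_character_)
    net <- sum(lead[informative]) - sum(lag_[informative])
    if (net == 0) NA_character_ else if (net > 0) "leading" else "lagging"
  }, character(1))
  overall <- if (sum(lead[clear]) >= sum(lag_[clear])) "leading" else "lagging"
  fallback <- group_dir[t96$substitution]
  fallback[is.na(fallback)] <- overall
  dir[!clear] <- fallback[!clear]
  list(weights = weights, direction = setNames(dir, t96$label),
       provenance = cluster$provenance, no_evidence = FALSE)
}
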