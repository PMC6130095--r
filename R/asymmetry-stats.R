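# Cohort-level statistics: exact sign tests of strand asymmetry, BH
# correction, per-sample replication-timing slopes, Tukey-fence outlier
# handling and spatial exposure profiles.

#' Exact two-sided binomial sign test
#'
#' Zeros are discarded; with `n` nonzero values and `k` positives the
#' p-value is twice the smaller exact tail of Binomial(n, 1/2), capped at 1.
#'
#' @param values numeric vector of paired differences.
#' @return p-value in (0, 1].
#' @export
sign_test <- function(values) {
  stopifnot(length(values) >= 1L)
  values <- values[!is.na(values)]
  nz <- values[values != 0]
  n <- length(nz)
  if (n == 0L) {
    warning("all values are zero; sign test p = 1")
    return(1)
  }
  k <- sum(nz > 0)
  lower <- pbinom(k, n, 0.5)
  upper <- pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Benjamini-Hochberg step-up correction
#'
#' Thin wrapper over `p.adjust(method = "BH")`; `NA` entries are excluded
#' from the family and returned as `NA`.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the input order.
#' @export
bh_correct <- function(p_values) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  p.adjust(p_values, method = "BH")
}

#' Tukey-fence outlier detection
#'
#' Fences are placed at `q25 - k * IQR` and `q75 + k * IQR` using type-7
#' (linear interpolation) quantiles; values strictly outside the fences are
#' outliers.
#'
#' @param values numeric vector (at least 4 values for meaningful fences).
#' @param k fence multiplier (default 2).
#' @return list with `kept`, `outliers`, `fences` and logical `is_outlier`.
#' @export
tukey_outliers <- function(values, k = 2) {
  q <- quantile(values, c(0.25, 0.75), type = 7, na.rm = TRUE)
  iqr <- q[2L] - q[1L]
  fences <- c(lower = unname(q[1L] - k * iqr), upper = unname(q[2L] + k * iqr))
  out <- values < fences[1L] | values > fences[2L]
  out[is.na(out)] <- FALSE
  list(kept = values[!out], outliers = values[out], fences = fences,
       is_outlier = out)
}

#' Cohort-level replication strand asymmetry per signature
#'
#' For each signature, samples with total exposure (matching + inverse) of
#' at least `min_exposure` are retained; their matching - inverse
#' differences (after Tukey-fence outlier removal when `tukey_k` is not
#' `NULL`) feed an exact sign test, with BH correction across signatures.
#'
#' @param exposures data frame with columns `sample`, `signature`,
#'   `e_matching`, `e_inverse` (one row per sample x signature).
#' @param min_exposure minimum total exposure for a sample to count
#'   (default 10).
#' @param tukey_k Tukey fence multiplier applied to the differences before
#'   the statistics, or `NULL` to disable (default 2).
#' @return data frame (signature, n_exposed, n_outliers, median_difference,
#'   pct_matching, p, q); signatures with no exposed samples get `NA`
#'   statistics and are excluded from the BH family.
#' @export
cohort_asymmetry <- function(exposures, min_exposure = 10, tukey_k = 2) {
  per_sig <- lapply(split(exposures, exposures$signature), function(d) {
    d <- d[d$e_matching + d$e_inverse >= min_exposure, , drop = FALSE]
    if (!nrow(d)) {
      return(data.frame(n_exposed = 0L, n_outliers = 0L,
                        median_difference = NA_real_,
                        pct_matching = NA_real_, p = NA_real_))
    }
    diffs <- d$e_matching - d$e_inverse
    n_out <- 0L
    if (!is.null(tukey_k) && length(diffs) >= 4L) {
      tk <- tukey_outliers(diffs, k = tukey_k)
      n_out <- length(tk$outliers)
      diffs <- tk$kept
    }
    data.frame(n_exposed = nrow(d), n_outliers = n_out,
               median_difference = median(diffs),
               pct_matching = 100 * mean(diffs > 0),
               p = sign_test(diffs))
  })
  out <- do.call(rbind, per_sig)
  out <- cbind(signature = names(per_sig), out)
  rownames(out) <- NULL
  out$q <- bh_correct(out$p)
  out
}

per_sample_slope <- function(x, y) {
  if (length(unique(x)) < 2L) return(NA_real_)
  cov(x, y) / var(x)
}

#' Replication-timing trend of signature exposures
#'
#' For each sample and signature, an ordinary least squares line of exposure
#' versus quartile index (1-4) is fitted separately for the matching and
#' inverse exposures; the cohort significance per signature is an exact sign
#' test on the per-sample slopes, BH-corrected across signatures within
#' each orientation.
#'
#' @param quartile_exposures data frame with columns `sample`, `signature`,
#'   `quartile` (1-4 or `"Q1"`..`"Q4"`), `e_matching`, `e_inverse`.
#' @param min_exposure minimum summed (over quartiles) total exposure for a
#'   sample to enter the slope test (default 10).
#' @return data frame per signature: `n`, `median_slope_matching`,
#'   `pct_positive_matching`, `p_matching`, `q_matching` and the same for
#'   inverse.
#' @export
timing_trend <- function(quartile_exposures, min_exposure = 10) {
  qe <- quartile_exposures
  qe$quartile_index <- if (is.numeric(qe$quartile)) qe$quartile else
    as.integer(sub("^Q", "", qe$quartile))
  per_sig <- lapply(split(qe, qe$signature), function(d) {
    slopes <- lapply(split(d, d$sample), function(s) {
      if (sum(s$e_matching + s$e_inverse) < min_exposure) return(NULL)
      if (length(unique(s$quartile_index)) < 2L) return(NULL)
      c(matching = per_sample_slope(s$quartile_index, s$e_matching),
        inverse = per_sample_slope(s$quartile_index, s$e_inverse))
    })
    slopes <- do.call(rbind, slopes)
    if (is.null(slopes) || !nrow(slopes)) {
      return(data.frame(n = 0L, median_slope_matching = NA_real_,
                        pct_positive_matching = NA_real_, p_matching = NA_real_,
                        median_slope_inverse = NA_real_,
                        pct_positive_inverse = NA_real_, p_inverse = NA_real_))
    }
    data.frame(n = nrow(slopes),
               median_slope_matching = median(slopes[, "matching"]),
               pct_positive_matching = 100 * mean(slopes[, "matching"] > 0),
               p_matching = sign_test(slopes[, "matching"]),
               median_slope_inverse = median(slopes[, "inverse"]),
               pct_positive_inverse = 100 * mean(slopes[, "inverse"] > 0),
               p_inverse = sign_test(slopes[, "inverse"]))
  })
  out <- do.call(rbind, per_sig)
  out <- cbind(signature = names(per_sig), out)
  rownames(out) <- NULL
  out$q_matching <- bh_correct(out$p_matching)
  out$q_inverse <- bh_correct(out$p_inverse)
  out
}

#' Cohort mean and standard error of exposures per quartile
#'
#' @inheritParams timing_trend
#' @return data frame (signature, quartile, mean_matching, se_matching,
#'   mean_inverse, se_inverse, n).
#' @export
quartile_means <- function(quartile_exposures) {
  qe <- quartile_exposures
  grp <- interaction(qe$signature, qe$quartile, drop = TRUE)
  out <- lapply(split(qe, grp), function(d) {
    n <- nrow(d)
    data.frame(signature = d$signature[1L], quartile = d$quartile[1L], n = n,
               mean_matching = mean(d$e_matching),
               se_matching = if (n > 1L) sd(d$e_matching) / sqrt(n) else NA_real_,
               mean_inverse = mean(d$e_inverse),
               se_inverse = if (n > 1L) sd(d$e_inverse) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$signature, out$quartile), ]
}

#' Mean spatial exposure profile around origins or transitions
#'
#' Averages per-bin, per-strand exposures across samples, after removing
#' samples whose total exposure is a Tukey-fence outlier. Bins with no
#' observation are reported as `NA`; the standard error of a single-sample
#' bin is `NA`.
#'
#' @param bin_exposures data frame with columns `sample`, `signature`,
#'   `bin` (signed index or position relative to the anchor), `strand`
#'   (`"plus"`/`"minus"`), `exposure`.
#' @param tukey_k fence multiplier for per-sample totals, `NULL` to disable
#'   (default 2).
#' @return data frame (signature, bin, strand, n, mean, se).
#' @export
spatial_profile <- function(bin_exposures, tukey_k = 2) {
  be <- bin_exposures
  kept <- lapply(split(be, be$signature), function(d) {
    if (!is.null(tukey_k)) {
      totals <- tapply(d$exposure, d$sample, sum)
      if (length(totals) >= 4L) {
        tk <- tukey_outliers(as.numeric(totals), k = tukey_k)
        d <- d[!(d$sample %in% names(totals)[tk$is_outlier]), , drop = FALSE]
      }
    }
    d
  })
  be <- do.call(rbind, kept)
  grp <- interaction(be$signature, be$bin, be$strand, drop = TRUE)
  out <- lapply(split(be, grp), function(d) {
    n <- nrow(d)
    data.frame(signature = d$signature[1L], bin = d$bin[1L],
               strand = d$strand[1L], n = n, mean = mean(d$exposure),
               se = if (n > 1L) sd(d$exposure) / sqrt(n) else NA_real_)
  })
  out <- do.call(rbind, out)
  # complete the bin x strand grid per signature: bins with no observation
  # are reported as NA, not zero
  full <- expand.grid(signature = unique(out$signature),
                      bin = sort(unique(out$bin)),
                      strand = unique(out$strand),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- merge(full, out, all.x = TRUE)
  out$n[is.na(out$n)] <- 0L
  rownames(out) <- NULL
  out[order(out$signature, out$strand, out$bin), ]
}
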