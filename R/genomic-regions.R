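# Genomic intervals are plain data frames with 0-based half-open coordinates
# (chrom, start, end), the BED convention; 1-based inputs are converted at the
# reader boundary.

validate_intervals <- function(x, what = "interval") {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) && (any(x$start >= x$end) || any(!nzchar(x$chrom)))) {
    stop(what, " table violates start < end / non-empty chrom")
  }
  invisible(x)
}

empty_intervals <- function(extra = character()) {
  out <- data.frame(chrom = character(), start = integer(), end = integer())
  for (nm in extra) out[[nm]] <- vector(mode = "numeric", length = 0L)
  out
}

#' Derive left/right-replicating domains from a replication-timing profile
#'
#' The genome is tiled with fixed-width windows; within each window the slope
#' of timing versus position is estimated by ordinary least squares over the
#' profile bins falling in the window (bin midpoints). Windows whose slope
#' magnitude is below `slope_threshold` (replication-timing peaks, valleys and
#' plateaus) are removed. Under the default timing dialect (lower rtu =
#' earlier replication) a positive slope means the fork travels rightwards, so
#' the window is a right-replicating domain; a negative slope gives a
#' left-replicating domain. Setting `rtu_high_is_early = TRUE` inverts the
#' sign convention.
#'
#' @param profile data frame (chrom, start, end, timing), bins sorted and
#'   non-overlapping per chromosome.
#' @param domain_width window width in bp (default 20000).
#' @param slope_threshold minimum slope magnitude in rtu per Mb (default 250).
#' @param rtu_high_is_early timing dialect flag; `FALSE` (default) means a
#'   lower rtu value replicates earlier.
#' @return data frame of domains (chrom, start, end, direction, timing) where
#'   `timing` is the mean profile value over the window.
#' @export
derive_domains_from_timing <- function(profile, domain_width = 20000,
                                       slope_threshold = 250,
                                       rtu_high_is_early = FALSE) {
  validate_intervals(profile, "timing profile")
  stopifnot("timing" %in% names(profile), domain_width > 0)
  out <- lapply(split(profile, profile$chrom), function(p) {
    p <- p[order(p$start), , drop = FALSE]
    if (any(diff(p$start) <= 0) || any(p$end[-nrow(p)] > p$start[-1L])) {
      stop("non-monotone or overlapping profile bins on ", p$chrom[1L])
    }
    if (nrow(p) < 2L) {
      warning("chromosome ", p$chrom[1L], " has < 2 profile bins; skipped")
      return(empty_intervals(c("direction", "timing")))
    }
    mid <- (p$start + p$end) / 2
    w0 <- min(p$start)
    win <- floor((mid - w0) / domain_width)
    keep_win <- vapply(split(seq_len(nrow(p)), win), function(idx) {
      if (length(idx) < 2L) return(c(NA_real_, NA_real_, NA_real_))
      x <- mid[idx]
      y <- p$timing[idx]
      slope <- cov(x, y) / var(x) * 1e6   # rtu per Mb
      c(win[idx[1L]], slope, mean(y))
    }, numeric(3))
    keep_win <- keep_win[, !is.na(keep_win[1L, ]) &
                           abs(keep_win[2L, ]) >= slope_threshold, drop = FALSE]
    if (!ncol(keep_win)) return(empty_intervals(c("direction", "timing")))
    slope <- keep_win[2L, ]
    dir_right <- if (rtu_high_is_early) slope < 0 else slope > 0
    data.frame(chrom = p$chrom[1L],
               start = as.integer(w0 + keep_win[1L, ] * domain_width),
               end = as.integer(w0 + (keep_win[1L, ] + 1) * domain_width),
               direction = ifelse(dir_right, "right", "left"),
               timing = keep_win[3L, ])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Assign replication-timing quartiles to domains
#'
#' Domains are ranked by mean timing and split into four quartiles, Q1 being
#' the earliest-replicating quarter and Q4 the latest. Quartile sizes differ
#' by at most one, earlier quartiles taking the extra domain; ties in timing
#' are broken by (chrom, start) for determinism.
#'
#' @inheritParams derive_domains_from_timing
#' @param domains data frame of replication domains with a `timing` column.
#' @return `domains` with an added `quartile` column (`"Q1"`..`"Q4"`).
#' @export
assign_timing_quartiles <- function(domains, rtu_high_is_early = FALSE) {
  stopifnot(nrow(domains) >= 4L, "timing" %in% names(domains))
  if (length(unique(domains$timing)) == 1L) {
    warning("all domain timings identical; quartiles assigned by rank order")
  }
  key <- if (rtu_high_is_early) -domains$timing else domains$timing
  ord <- order(key, domains$chrom, domains$start)
  n <- nrow(domains)
  sizes <- diff(ceiling(n * (0:4) / 4))
  q <- rep(paste0("Q", 1:4), times = sizes)
  domains$quartile <- q[order(ord)]  # map back to input order
  domains
}

#' Build 1-kbp direction-annotated bins around replication origins
#'
#' Around each origin midpoint, up to `max_bins` fixed-width bins are emitted
#' on each side, truncated so that no bin reaches half the distance to the
#' adjacent origin midpoint (and, when `chrom_lengths` is given, the
#' chromosome ends). Replication proceeds outwards from the origin, so bins
#' left of an origin are left-replicating and bins to the right are
#' right-replicating.
#'
#' @param origins data frame (chrom, start, end) of origin intervals;
#'   overlapping origins are merged with a warning.
#' @param bin_width bin width in bp (default 1000).
#' @param max_bins maximum bins per side (default 1000).
#' @param chrom_lengths optional named vector of chromosome lengths.
#' @return data frame (chrom, start, end, side, index, direction) with
#'   `index` the 1-based distance rank from the origin.
#' @export
build_origin_bins <- function(origins, bin_width = 1000, max_bins = 1000,
                              chrom_lengths = NULL) {
  validate_intervals(origins, "origins")
  out <- lapply(split(origins, origins$chrom), function(o) {
    o <- o[order(o$start), , drop = FALSE]
    ir <- IRanges::reduce(IRanges::IRanges(o$start + 1L, o$end))
    if (length(ir) < nrow(o)) warning("overlapping origins merged on ", o$chrom[1L])
    mid <- floor((IRanges::start(ir) - 1L + IRanges::end(ir)) / 2)
    L <- if (!is.null(chrom_lengths)) chrom_lengths[[o$chrom[1L]]] else Inf
    k <- length(mid)
    res <- vector("list", 2L * k)
    for (i in seq_len(k)) {
      avail_l <- if (i == 1L) mid[i] else (mid[i] - mid[i - 1L]) / 2
      avail_r <- if (i == k) L - mid[i] else (mid[i + 1L] - mid[i]) / 2
      n_l <- min(max_bins, floor(avail_l / bin_width))
      n_r <- min(max_bins, floor(avail_r / bin_width))
      if (n_l > 0) {
        j <- seq_len(n_l)
        res[[2L * i - 1L]] <- data.frame(
          chrom = o$chrom[1L],
          start = as.integer(mid[i] - j * bin_width),
          end = as.integer(mid[i] - (j - 1L) * bin_width),
          side = "left_of_origin", index = j, direction = "left")
      }
      if (n_r > 0) {
        j <- seq_len(n_r)
        res[[2L * i]] <- data.frame(
          chrom = o$chrom[1L],
          start = as.integer(mid[i] + (j - 1L) * bin_width),
          end = as.integer(mid[i] + j * bin_width),
          side = "right_of_origin", index = j, direction = "right")
      }
    }
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (is.null(out)) out <- empty_intervals(c("side", "index", "direction"))
  out
}

#' Subtract exclusion masks from a set of intervals
#'
#' Set subtraction on 0-based half-open intervals: the returned intervals are
#' the maximal runs of each input interval not covered by any mask. Metadata
#' columns of the input are carried over to the surviving fragments.
#'
#' @param intervals data frame (chrom, start, end, ...).
#' @param masks data frame (chrom, start, end) of regions to exclude.
#' @return data frame with the same columns as `intervals`.
#' @export
apply_exclusions <- function(intervals, masks) {
  validate_intervals(intervals)
  if (is.null(masks) || nrow(masks) == 0L || nrow(intervals) == 0L) {
    return(intervals)
  }
  validate_intervals(masks, "mask")
  pieces <- lapply(seq_len(nrow(intervals)), function(i) {
    row <- intervals[i, , drop = FALSE]
    m <- masks[masks$chrom == row$chrom, , drop = FALSE]
    if (!nrow(m)) return(row)
    keep <- IRanges::setdiff(
      IRanges::IRanges(row$start + 1L, row$end),
      IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end)))
    if (!length(keep)) return(NULL)
    out <- row[rep(1L, length(keep)), , drop = FALSE]
    out$start <- IRanges::start(keep) - 1L
    out$end <- IRanges::end(keep)
    out
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- intervals[0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Randomize replication-domain placement as a negative control
#'
#' Places the same multiset of domain widths uniformly at random (without
#' overlap) on their original chromosomes, and shuffles the
#' direction/timing annotations among domains. Used to verify that
#' strand-asymmetry signals vanish when the replication annotation is
#' destroyed.
#'
#' @param domains data frame of domains (chrom, start, end, direction, timing).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param seed integer seed (required; output is deterministic per seed).
#' @return data frame with the same columns as `domains`.
#' @export
randomize_domains <- function(domains, chrom_lengths, seed) {
  stopifnot(!missing(seed))
  validate_intervals(domains, "domains")
  set.seed(seed)
  out <- lapply(split(domains, domains$chrom), function(d) {
    L <- chrom_lengths[[d$chrom[1L]]]
    widths <- d$end - d$start
    slack <- L - sum(widths)
    if (slack < 0) stop("cannot place domains without overlap on ", d$chrom[1L])
    # uniform non-overlapping placement: random order, random gap allocation
    ord <- sample.int(nrow(d))
    gaps <- diff(c(0, sort(runif(nrow(d), 0, slack))))
    starts <- cumsum(gaps) + cumsum(c(0, widths[ord][-nrow(d)]))
    d2 <- d[ord, , drop = FALSE]
    d2$start <- as.integer(floor(starts))
    d2$end <- d2$start + widths[ord]
    d2
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  # shuffle annotations jointly across all domains
  perm <- sample.int(nrow(out))
  for (nm in intersect(c("direction", "timing", "quartile"), names(out))) {
    out[[nm]] <- out[[nm]][perm]
  }
  out
}
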