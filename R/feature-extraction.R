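#' Build extracted ion electropherograms (EICs)
#'
#' Sums centroid intensities within a +/- `tol_mda` window around each
#' target m/z, per scan, over the trace's full scan grid (scans with no
#' centroid in the window contribute zero). In automatic mode candidate
#' centers are derived by single-linkage 1-D clustering of all centroid m/z
#' values: the sorted m/z axis is split wherever the gap between neighbours
#' exceeds `tol_mda`, clusters with fewer than `min_points` centroids are
#' discarded, and the intensity-weighted mean of each surviving cluster
#' becomes a candidate center. Two species less than `tol_mda` apart are
#' therefore merged into one candidate (below the resolution of the rule).
#'
#' @param trace Raw trace data.frame (`time_min`, `mz`, `intensity`, and
#'   optionally `scan`), rows in non-decreasing time order.
#' @param targets Numeric vector of target m/z values, or `NULL` for
#'   automatic candidate discovery.
#' @param tol_mda Extraction half-window in milli-Dalton (default 5).
#' @param min_points Minimum cluster size in automatic mode (default 5).
#' @param exclude_mz Optional m/z values (e.g. calibrant clusters) whose
#'   neighbourhood is excluded from automatic candidates.
#' @param exclude_tol_da Half-width of the exclusion zones (default 0.02 Da).
#' @return List of `eic` objects, each a list with `target_mz`, `tol_mda`,
#'   `time` (strictly increasing), `intensity`, and `mz` (per-scan
#'   intensity-weighted centroid m/z, `NA` where the window is empty).
#' @export
build_eics <- function(trace, targets = NULL, tol_mda = 5, min_points = 5L,
                       exclude_mz = NULL, exclude_tol_da = 0.02) {
  if (is.null(trace) || !nrow(trace)) stop("empty trace", call. = FALSE)
  if (is.unsorted(trace$time_min)) {
    stop("trace scan times must be non-decreasing", call. = FALSE)
  }
  tol <- tol_mda / 1000
  grid <- sort(unique(trace$time_min))
  scan_of <- match(trace$time_min, grid)

  ord <- order(trace$mz)
  mz_s <- trace$mz[ord]
  int_s <- trace$intensity[ord]
  scan_s <- scan_of[ord]

  if (is.null(targets)) {
    gap <- diff(mz_s)
    cluster <- cumsum(c(1L, as.integer(gap > tol)))
    size <- tabulate(cluster)
    centers <- vapply(split(seq_along(mz_s), cluster), function(ix) {
      stats::weighted.mean(mz_s[ix], int_s[ix])
    }, numeric(1))
    centers <- centers[size >= min_points]
    if (!is.null(exclude_mz) && length(centers)) {
      keep <- vapply(centers, function(m) {
        all(abs(m - exclude_mz) > exclude_tol_da)
      }, logical(1))
      centers <- centers[keep]
    }
    targets <- unname(sort(centers))
  }
  if (!length(targets)) return(list())

  lapply(targets, function(ctr) {
    lo <- findInterval(ctr - tol, mz_s) + 1L
    hi <- findInterval(ctr + tol, mz_s)
    inten <- numeric(length(grid))
    mzw <- rep(NA_real_, length(grid))
    if (hi >= lo) {
      ix <- lo:hi
      sums <- rowsum(int_s[ix], scan_s[ix])
      sc <- as.integer(rownames(sums))
      inten[sc] <- sums[, 1]
      wm <- rowsum(int_s[ix] * mz_s[ix], scan_s[ix])
      mzw[sc] <- wm[, 1] / sums[, 1]
    }
    structure(list(target_mz = ctr, tol_mda = tol_mda, time = grid,
                   intensity = inten, mz = mzw), class = "eic")
  })
}

# robust baseline noise: scaled MAD of the lowest-50% intensity points,
# floored at min_noise (one count) so sparse zero-heavy EICs stay finite
eic_noise <- function(intensity, min_noise = 1) {
  low <- sort(intensity)[seq_len(ceiling(length(intensity) / 2))]
  max(1.4826 * stats::median(abs(low - stats::median(low))), min_noise)
}

#' Detect peaks in an EIC
#'
#' Local maxima whose apex exceeds `sn_min` times the baseline noise are
#' reported as molecular features. Noise is 1.4826 times the median absolute
#' deviation of the lowest-50% intensity points of the EIC, floored at
#' `min_noise` counts. An apex must be supported by at least `min_support`
#' consecutive scans at or above half its height (rejects single-scan noise
#' spikes). Peak boundaries are found by walking outward from the apex to
#' the nearest valley or to the first point at or below `boundary_frac` of
#' the apex, whichever comes first; the under-the-curve area is the
#' trapezoidal integral between the boundaries.
#'
#' @param eic An `eic` object from [build_eics()] (>= 5 points).
#' @param sn_min Signal-to-noise gate (default 15).
#' @param min_noise Noise floor in counts (default 1).
#' @param min_support Minimum consecutive scans at >= half apex (default 3).
#' @param boundary_frac Boundary fallback as a fraction of apex (default
#'   0.01).
#' @return data.frame of features: `mz` (intensity-weighted over the peak),
#'   `mt_min` (apex time), `area`, `sn`, `apex_intensity`, `width_min` (full
#'   width at half maximum), `bound_span_min` (integration span).
#' @export
detect_peaks <- function(eic, sn_min = 15, min_noise = 1, min_support = 3L,
                         boundary_frac = 0.01) {
  x <- eic$intensity
  n <- length(x)
  if (n < 5L) stop("EIC must have at least 5 points", call. = FALSE)
  noise <- eic_noise(x, min_noise)

  cand <- which(x > c(-Inf, x[-n]) & x >= c(x[-1], -Inf))
  cand <- cand[cand > 1L & cand < n]
  cand <- cand[x[cand] > sn_min * noise]
  out <- list()
  for (apex in cand) {
    half <- x[apex] / 2
    l <- apex; while (l > 1L && x[l - 1L] >= half) l <- l - 1L
    r <- apex; while (r < n && x[r + 1L] >= half) r <- r + 1L
    if (r - l + 1L < min_support) next
    fwhm <- eic$time[r] - eic$time[l]  # half-height span = the peak width
    floor_i <- boundary_frac * x[apex]
    lb <- apex
    while (lb > 1L) {
      if (x[lb] <= floor_i) break
      if (x[lb - 1L] > x[lb]) break  # valley: signal rises again to the left
      lb <- lb - 1L
    }
    rb <- apex
    while (rb < n) {
      if (x[rb] <= floor_i) break
      if (x[rb + 1L] > x[rb]) break
      rb <- rb + 1L
    }
    if (rb <= lb) next
    seg <- lb:rb
    area <- sum(diff(eic$time[seg]) * (x[seg][-length(seg)] + x[seg][-1]) / 2)
    if (area <= 0) next
    w <- x[seg]
    mz_feat <- if (all(is.na(eic$mz[seg]) | w == 0)) eic$target_mz else {
      stats::weighted.mean(eic$mz[seg], w, na.rm = TRUE)
    }
    out[[length(out) + 1L]] <- data.frame(
      mz = mz_feat, mt_min = eic$time[apex], area = area,
      sn = x[apex] / noise, apex_intensity = x[apex],
      width_min = fwhm, bound_span_min = eic$time[rb] - eic$time[lb]
    )
  }
  if (!length(out)) {
    return(data.frame(mz = numeric(0), mt_min = numeric(0),
                      area = numeric(0), sn = numeric(0),
                      apex_intensity = numeric(0), width_min = numeric(0),
                      bound_span_min = numeric(0)))
  }
  do.call(rbind, out)
}

#' Extract molecular features from a raw trace
#'
#' Composition of automatic [build_eics()] and [detect_peaks()], followed by
#' deduplication: when two records agree in m/z within the extraction
#' tolerance and in migration time within one peak width (the kept record's
#' full width at half maximum), the higher-S/N record is kept.
#'
#' @inheritParams build_eics
#' @inheritParams detect_peaks
#' @param run_id Run identifier attached to the output (taken from the
#'   trace when present).
#' @return data.frame of features: `run_id`, `mz`, `mt_min`, `area`, `sn`,
#'   `apex_intensity`, `width_min`.
#' @export
extract_features <- function(trace, tol_mda = 5, sn_min = 15,
                             min_points = 5L, min_noise = 1,
                             min_support = 3L, boundary_frac = 0.01,
                             exclude_mz = NULL, exclude_tol_da = 0.02,
                             run_id = NULL) {
  eics <- build_eics(trace, tol_mda = tol_mda, min_points = min_points,
                     exclude_mz = exclude_mz,
                     exclude_tol_da = exclude_tol_da)
  peaks <- lapply(eics, detect_peaks, sn_min = sn_min, min_noise = min_noise,
                  min_support = min_support, boundary_frac = boundary_frac)
  feats <- do.call(rbind, peaks)
  if (is.null(feats) || !nrow(feats)) {
    feats <- data.frame(mz = numeric(0), mt_min = numeric(0),
                        area = numeric(0), sn = numeric(0),
                        apex_intensity = numeric(0), width_min = numeric(0),
                        bound_span_min = numeric(0))
  }
  if (nrow(feats) > 1L) {
    ord <- order(-feats$sn, feats$mz)
    feats <- feats[ord, , drop = FALSE]
    keep <- logical(nrow(feats))
    for (i in seq_len(nrow(feats))) {
      kept <- which(keep)
      dup <- length(kept) && any(
        abs(feats$mz[kept] - feats$mz[i]) <= tol_mda / 1000 &
          abs(feats$mt_min[kept] - feats$mt_min[i]) <=
            pmax(feats$width_min[kept], 1e-9)
      )
      keep[i] <- !dup
    }
    feats <- feats[keep, , drop = FALSE]
    feats <- feats[order(feats$mz, feats$mt_min), , drop = FALSE]
  }
  if (is.null(run_id)) {
    run_id <- if ("run_id" %in% names(trace) && nrow(trace)) {
      trace$run_id[1]
    } else "run1"
  }
  feats <- cbind(run_id = run_id, feats, stringsAsFactors = FALSE)
  rownames(feats) <- NULL
  feats
}
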