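#' Locate calibrant peaks in a raw trace
#'
#' For each theoretical sodium-formate cluster m/z, collects the trace
#' centroids within +/- `tol_mda` and reports their intensity-weighted mean
#' m/z as the observed calibrant position.
#'
#' @param trace Raw trace data.frame.
#' @param series Theoretical calibrant m/z values (see [calibrant_series()]).
#' @param tol_mda Match half-window in mDa (default 20).
#' @return data.frame with `mz_theoretical`, `mz_observed`, `n_centroids`;
#'   unmatched clusters are dropped.
#' @export
match_calibrant_peaks <- function(trace, series, tol_mda = 20) {
  tol <- tol_mda / 1000
  rows <- lapply(series, function(th) {
    ix <- which(abs(trace$mz - th) <= tol)
    if (!length(ix)) return(NULL)
    data.frame(mz_theoretical = th,
               mz_observed = stats::weighted.mean(trace$mz[ix],
                                                  trace$intensity[ix]),
               n_centroids = length(ix))
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(mz_theoretical = numeric(0), mz_observed = numeric(0),
                      n_centroids = integer(0))
  }
  out
}

#' Fit a linear m/z recalibration on calibrant observations
#'
#' Ordinary least squares of theoretical on observed calibrant m/z, giving a
#' per-run linear map `corrected = gain * observed + offset`. TOF mass error
#' is near-linear over one decade of m/z, so three or more calibrant points
#' constrain the map. Fewer than 3 matched calibrants is a calibration
#' error; callers typically catch it, flag the run, and fall back to the
#' identity map.
#'
#' @param observed,theoretical Matched calibrant m/z vectors (equal length,
#'   >= 3).
#' @return list with `gain`, `offset`, `residual_rms_ppm` (post-fit
#'   residuals on the calibrants, in ppm), `n_calibrants`.
#' @export
fit_mz_recalibration <- function(observed, theoretical) {
  stopifnot(length(observed) == length(theoretical))
  if (length(observed) < 3L) {
    stop("m/z calibration requires at least 3 matched calibrant peaks",
         call. = FALSE)
  }
  fit <- stats::lm(theoretical ~ observed)
  gain <- unname(stats::coef(fit)[2])
  offset <- unname(stats::coef(fit)[1])
  resid_ppm <- (gain * observed + offset - theoretical) / theoretical * 1e6
  list(gain = gain, offset = offset,
       residual_rms_ppm = sqrt(mean(resid_ppm^2)),
       n_calibrants = length(observed))
}

# references whose m/z lies within ppm_tol of another reference (isobars);
# these may not serve as alignment anchors
ambiguous_references <- function(refdb, ppm_tol = 3) {
  vapply(seq_len(nrow(refdb)), function(i) {
    d <- abs(refdb$mz_theoretical[-i] - refdb$mz_theoretical[i]) /
      refdb$mz_theoretical[i] * 1e6
    any(d <= ppm_tol)
  }, logical(1))
}

polyval <- function(coefs, x) {
  out <- 0
  for (k in rev(seq_along(coefs))) out <- out * x + coefs[k]
  out
}

poly_monotone <- function(coefs, range, n = 512L) {
  tt <- seq(range[1], range[2], length.out = n)
  dcf <- coefs[-1] * seq_len(length(coefs) - 1L)
  all(polyval(dcf, tt) > 0)
}

#' Fit the migration-time alignment polynomial
#'
#' Aligns a run's observed migration times to the reference database with a
#' third-order polynomial, via a two-pass anchor scheme. Pass 1 matches
#' features to references by m/z alone (within `ppm_tol`) inside a wide
#' migration-time window (+/- `mt_window_frac` of the run duration around
#' the reference time); references that are m/z-ambiguous (another reference
#' within `ppm_tol`, e.g. leucine/isoleucine) are excluded, and only
#' references with exactly one candidate feature become anchors. A cubic is
#' fitted by least squares when at least 8 anchors are available (linear
#' otherwise); pass 2 drops anchors with residuals above 3 times the RMS and
#' refits. The returned polynomial is verified monotone increasing over the
#' observed range; on failure the order is reduced (3 to 2 to 1) until
#' monotone.
#'
#' @param features Feature data.frame with recalibrated `mz` and raw
#'   `mt_min` columns.
#' @param refdb Reference database.
#' @param ppm_tol Anchor m/z tolerance (default 3 ppm).
#' @param mt_window_frac Pass-1 migration-time window as a fraction of the
#'   run duration (default 0.2).
#' @param duration_min Run duration; defaults to the largest observed
#'   migration time.
#' @return list with `coefs` (a0..a3, zero-padded), `order`, `anchors`
#'   (data.frame `mt_observed`, `mt_reference`, `name`, `residual`),
#'   `rms_resid_min`, `rms_resid_pct` (RMS residual as percent of run
#'   duration).
#' @export
fit_mt_alignment <- function(features, refdb, ppm_tol = 3,
                             mt_window_frac = 0.2, duration_min = NULL) {
  if (is.null(duration_min)) duration_min <- max(features$mt_min)
  usable <- refdb[!ambiguous_references(refdb, ppm_tol), , drop = FALSE]
  win <- mt_window_frac * duration_min
  anchors <- do.call(rbind, lapply(seq_len(nrow(usable)), function(i) {
    dppm <- abs(features$mz - usable$mz_theoretical[i]) /
      usable$mz_theoretical[i] * 1e6
    cand <- which(dppm <= ppm_tol &
                    abs(features$mt_min - usable$ref_mt_min[i]) <= win)
    if (length(cand) != 1L) return(NULL)
    data.frame(mt_observed = features$mt_min[cand],
               mt_reference = usable$ref_mt_min[i],
               name = usable$name[i], stringsAsFactors = FALSE)
  }))
  if (is.null(anchors) || nrow(anchors) < 4L) {
    stop("migration-time alignment requires at least 4 anchors (got ",
         if (is.null(anchors)) 0L else nrow(anchors), ")", call. = FALSE)
  }

  fit_order <- function(anc, order) {
    stats::lm(mt_reference ~ poly(mt_observed, degree = order, raw = TRUE),
              data = anc)
  }
  order1 <- if (nrow(anchors) >= 8L) 3L else 1L
  fit <- fit_order(anchors, order1)
  res <- stats::resid(fit)
  keep <- abs(res) <= 3 * sqrt(mean(res^2))
  anchors2 <- anchors[keep, , drop = FALSE]
  order2 <- if (nrow(anchors2) >= 8L) order1 else 1L
  if (nrow(anchors2) < 4L) anchors2 <- anchors
  fit <- fit_order(anchors2, order2)

  rng <- range(anchors2$mt_observed)
  ord <- order2
  repeat {
    coefs <- unname(stats::coef(fit))
    coefs[is.na(coefs)] <- 0
    if (poly_monotone(coefs, rng) || ord == 1L) break
    ord <- ord - 1L
    fit <- fit_order(anchors2, ord)
  }
  coefs <- c(coefs, rep(0, 4L - length(coefs)))
  anchors2$residual <- unname(stats::resid(fit))
  rms <- sqrt(mean(anchors2$residual^2))
  list(coefs = coefs, order = ord, anchors = anchors2,
       rms_resid_min = rms, rms_resid_pct = 100 * rms / duration_min)
}

#' Assemble a per-run calibration model
#'
#' @param mz_fit Result of [fit_mz_recalibration()], or `NULL` for the
#'   identity map (run flagged).
#' @param mt_fit Result of [fit_mt_alignment()], or `NULL` for the identity
#'   map (run flagged).
#' @return A `calibration_model` list with `mz` (gain, offset), `mt`
#'   (polynomial coefficients a0..a3), `flagged`, and residual summaries.
#' @export
calibration_model <- function(mz_fit = NULL, mt_fit = NULL) {
  structure(list(
    mz = if (is.null(mz_fit)) list(gain = 1, offset = 0,
                                   residual_rms_ppm = NA_real_,
                                   n_calibrants = 0L) else mz_fit,
    mt = if (is.null(mt_fit)) list(coefs = c(0, 1, 0, 0), order = 1L,
                                   anchors = NULL,
                                   rms_resid_min = NA_real_,
                                   rms_resid_pct = NA_real_) else mt_fit,
    flagged = is.null(mz_fit) || is.null(mt_fit)
  ), class = "calibration_model")
}

#' Apply a calibration model to features
#'
#' Corrects feature m/z with the linear recalibration map and aligns
#' migration times with the alignment polynomial. Row order is preserved;
#' raw values are kept in `mz_raw` / `mt_raw_min`, and `mz` / `mt_min` are
#' replaced by their corrected values. Applying the identity model returns
#' the input values unchanged.
#'
#' @param features Feature data.frame (`mz`, `mt_min`).
#' @param model A `calibration_model`.
#' @return The feature data.frame with corrected `mz` and aligned `mt_min`.
#' @export
apply_calibration <- function(features, model) {
  stopifnot(inherits(model, "calibration_model"))
  out <- features
  if (is.null(out$mz_raw)) out$mz_raw <- out$mz
  if (is.null(out$mt_raw_min)) out$mt_raw_min <- out$mt_min
  out$mz <- model$mz$gain * out$mz_raw + model$mz$offset
  out$mt_min <- polyval(model$mt$coefs, out$mt_raw_min)
  out
}

#' Calibrate and align one run
#'
#' Convenience wrapper: locates calibrant peaks in the trace, fits the m/z
#' recalibration, applies it to the features, fits the migration-time
#' alignment against the reference database, and returns the calibrated
#' features plus the model. Calibration or alignment failures flag the run
#' and fall back to the identity map instead of aborting the experiment.
#'
#' @param trace Raw trace for the run.
#' @param features Extracted features for the run.
#' @param refdb Reference database.
#' @param n_calibrant Largest calibrant cluster index to look for.
#' @param ppm_tol Anchor tolerance for the alignment fit.
#' @param duration_min Run duration.
#' @return list with `features` (calibrated + aligned) and `model`.
#' @export
calibrate_run <- function(trace, features, refdb, n_calibrant = 7L,
                          ppm_tol = 3, duration_min = NULL) {
  series <- calibrant_series(n_calibrant)$mz_theoretical
  cal <- match_calibrant_peaks(trace, series)
  mz_fit <- if (nrow(cal) >= 3L) {
    fit_mz_recalibration(cal$mz_observed, cal$mz_theoretical)
  } else NULL
  tmp <- apply_calibration(features, calibration_model(mz_fit, NULL))
  mt_fit <- tryCatch(
    fit_mt_alignment(tmp, refdb, ppm_tol = ppm_tol,
                     duration_min = duration_min),
    error = function(e) NULL
  )
  model <- calibration_model(mz_fit, mt_fit)
  list(features = apply_calibration(features, model), model = model)
}
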