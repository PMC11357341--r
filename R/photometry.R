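#' Construct a two-channel photometry recording
#'
#' Paired 415 nm (isosbestic) and 470 nm (GCaMP) frame series for one fiber
#' on a uniform time grid.
#'
#' @param time frame times, s; strictly increasing and uniform.
#' @param F415,F470 fluorescence, a.u.; same length as \code{time}.
#' @param fiber_side "left" or "right".
#' @param frame_rate per-channel frame rate, Hz.
#' @param meta optional list of session metadata.
#' @return object of class \code{photometry_recording}.
#' @export
photometry_recording <- function(time, F415, F470, fiber_side, frame_rate,
                                 meta = list()) {
  if (length(F415) != length(time) || length(F470) != length(time))
    stopf("F415/F470 must match time in length")
  if (length(time) > 1L) {
    dtv <- diff(time)
    if (any(dtv <= 0)) stopf("time must be strictly increasing")
    if (max(dtv) - min(dtv) > 1e-6)
      stopf("time grid not uniform within 1e-6 s")
  }
  structure(list(time = time, F415 = F415, F470 = F470,
                 fiber_side = fiber_side, frame_rate = frame_rate,
                 meta = meta, trim_offset = 0),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("<photometry_recording> %s fiber: %d frames @ %g Hz (%.1f s)\n",
              x$fiber_side, length(x$time), x$frame_rate,
              if (length(x$time)) diff(range(x$time)) else 0))
  invisible(x)
}

#' Drop the initial frames of a recording
#'
#' Removes the first \code{n} frames of both channels (LED/camera settling)
#' and re-zeroes the time axis to the new first frame. The amount of clock
#' shift is kept in the \code{trim_offset} field so event timestamps on the
#' original clock can be mapped onto the trimmed trace.
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param n number of frames to drop (default 300).
#' @export
trim_frames <- function(rec, n = 300) {
  if (n == 0L) return(rec)
  if (length(rec$time) <= n)
    stopf("recording has %d frames, cannot trim %d", length(rec$time), n)
  keep <- (n + 1L):length(rec$time)
  out <- rec
  out$trim_offset <- rec$trim_offset + rec$time[n + 1L] - rec$time[1L]
  out$time <- rec$time[keep] - rec$time[n + 1L]
  out$F415 <- rec$F415[keep]
  out$F470 <- rec$F470[keep]
  out
}

#' Fit a biexponential photobleaching curve to the isosbestic channel
#'
#' Nonlinear least squares of
#' \eqn{F(t) = A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + C}
#' by Levenberg-Marquardt with an analytic Jacobian, parameterising the time
#' constants on the log scale so they stay positive. Initialisation is
#' deterministic: \code{C} from the median of the last decile of the trace,
#' \code{A1 = A2 = (F(0) - C)/2}, and time constants at 5\% and 50\% of the
#' trace duration; there is no randomness in the fit. The returned
#' components are ordered so \code{tau1 <= tau2}.
#'
#' @param time frame times, s.
#' @param F415 isosbestic fluorescence, a.u.
#' @param max_iter maximum Levenberg-Marquardt iterations.
#' @param n_max_fit the optimiser runs on a uniformly decimated copy of the
#'   trace of at most this many frames (the returned fitted values and
#'   r-squared are evaluated on the full grid); set to \code{Inf} to fit
#'   every frame.
#' @return object of class \code{bleach_fit}: coefficients
#'   \code{A1, tau1, A2, tau2, C}, \code{r_squared}, \code{fitted} values,
#'   \code{converged} flag and \code{message}.
#' @export
fit_biexponential <- function(time, F415, max_iter = 100, n_max_fit = 30000) {
  if (length(time) < 100L) stopf("need at least 100 frames to fit bleaching")
  if (!all(is.finite(F415))) stopf("non-finite values in F415")
  t0 <- time - time[1L]
  dur <- t0[length(t0)]
  sub <- seq.int(1L, length(t0), by = max(1L, ceiling(length(t0) / n_max_fit)))
  ts <- t0[sub]
  Fs <- F415[sub]
  C0 <- stats::median(F415[t0 >= 0.9 * dur])
  A0 <- (F415[1L] - C0) / 2
  par0 <- c(A1 = A0, lt1 = log(0.05 * dur), A2 = A0, lt2 = log(0.5 * dur),
            C = C0)
  resid_fn <- function(p) {
    Fs - (p["A1"] * exp(-ts / exp(p["lt1"])) +
            p["A2"] * exp(-ts / exp(p["lt2"])) + p["C"])
  }
  jac_fn <- function(p) {
    e1 <- exp(-ts / exp(p["lt1"]))
    e2 <- exp(-ts / exp(p["lt2"]))
    cbind(-e1, -p["A1"] * e1 * ts / exp(p["lt1"]),
          -e2, -p["A2"] * e2 * ts / exp(p["lt2"]),
          -1)
  }
  fit <- tryCatch(
    suppressWarnings(   # non-convergence is reported via the converged flag
      minpack.lm::nls.lm(par = par0, fn = resid_fn, jac = jac_fn,
                         control = minpack.lm::nls.lm.control(maxiter = max_iter))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    co <- c(A1 = 0, tau1 = 0.05 * dur, A2 = 0, tau2 = 0.5 * dur,
            C = mean(F415))
    return(structure(list(coefficients = co, r_squared = NA_real_,
                          fitted = rep(mean(F415), length(t0)),
                          residuals = F415 - mean(F415), time = time,
                          converged = FALSE, message = conditionMessage(fit)),
                     class = "bleach_fit"))
  }
  p <- fit$par
  co <- c(A1 = unname(p["A1"]), tau1 = exp(unname(p["lt1"])),
          A2 = unname(p["A2"]), tau2 = exp(unname(p["lt2"])),
          C = unname(p["C"]))
  if (co["tau1"] > co["tau2"])
    co <- c(A1 = unname(co["A2"]), tau1 = unname(co["tau2"]),
            A2 = unname(co["A1"]), tau2 = unname(co["tau1"]),
            C = unname(co["C"]))
  fitted <- co["A1"] * exp(-t0 / co["tau1"]) + co["A2"] * exp(-t0 / co["tau2"]) +
    co["C"]
  names(fitted) <- NULL
  ssr <- sum((F415 - fitted)^2)
  sst <- sum((F415 - mean(F415))^2)
  r2 <- if (sst <= .Machine$double.eps * sum(F415^2)) 1 else 1 - ssr / sst
  structure(list(coefficients = co, r_squared = r2, fitted = fitted,
                 residuals = F415 - fitted, time = time,
                 converged = fit$info %in% 1:4, message = fit$message),
            class = "bleach_fit")
}

#' @export
coef.bleach_fit <- function(object, ...) object$coefficients

#' @export
print.bleach_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "<bleach_fit> F(t) = %.4g exp(-t/%.4g) + %.4g exp(-t/%.4g) + %.4g\n",
    co["A1"], co["tau1"], co["A2"], co["tau2"], co["C"]))
  cat(sprintf("  r^2 = %.4f, %s\n", x$r_squared,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  invisible(x)
}

#' @export
predict.bleach_fit <- function(object, time = NULL, ...) {
  if (is.null(time)) return(object$fitted)
  co <- object$coefficients
  t0 <- time - object$time[1L]
  unname(co["A1"] * exp(-t0 / co["tau1"]) + co["A2"] * exp(-t0 / co["tau2"]) +
           co["C"])
}

#' @export
residuals.bleach_fit <- function(object, ...) object$residuals

#' @export
plot.bleach_fit <- function(x, F415 = NULL, ...) {
  if (!is.null(F415))
    graphics::plot(x$time, F415, type = "l", col = "grey60",
                   xlab = "time (s)", ylab = "F415 (a.u.)", ...)
  else
    graphics::plot(x$time, x$fitted, type = "n", xlab = "time (s)",
                   ylab = "F415 (a.u.)", ...)
  graphics::lines(x$time, x$fitted, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Robustly scale the bleach fit to the 470 nm channel with RANSAC
#'
#' Random sample consensus linear regression of the GCaMP channel on the
#' fitted bleach curve: repeatedly fits a line through two random frames,
#' counts frames within a residual threshold (1.4826 times the median
#' absolute deviation of an initial OLS fit's residuals unless given), keeps
#' the largest consensus set, and refits by OLS on those inliers.
#' Calcium transients and motion frames fall outside the consensus, so the
#' recovered slope and intercept track the baseline relation only. Fully
#' deterministic given \code{seed}.
#'
#' @param fitted_curve bleach-fit values on the trimmed grid, a.u.
#' @param F470 GCaMP channel, same length.
#' @param seed integer seed (mandatory).
#' @param n_iter number of random samples (default 100).
#' @param min_samples minimal sample size per iteration (default 2).
#' @param threshold residual threshold, a.u.; default the MAD rule above.
#' @return object of class \code{ransac_fit}: \code{slope},
#'   \code{intercept}, logical \code{inlier_mask}, \code{scaled_fit}
#'   (\code{slope * fitted_curve + intercept}), \code{threshold}.
#' @export
ransac_scale <- function(fitted_curve, F470, seed, n_iter = 100,
                         min_samples = 2, threshold = NULL) {
  x <- fitted_curve
  y <- F470
  n <- length(x)
  if (length(y) != n) stopf("fitted_curve and F470 lengths differ")
  if (max(x) - min(x) <= 0) stopf("need at least 2 distinct x-values")
  if (missing(seed)) stopf("ransac_scale requires a seed")
  ols_line <- function(xi, yi) {   # closed-form simple OLS, no allocations
    mx <- mean(xi); my <- mean(yi)
    b <- sum((xi - mx) * (yi - my)) / sum((xi - mx)^2)
    c(my - b * mx, b)
  }
  ols <- ols_line(x, y)
  if (is.null(threshold)) {
    threshold <- stats::mad(y - ols[1L] - ols[2L] * x)
    threshold <- max(threshold, 1e-9 * max(abs(y), 1))
  }
  best_n <- -1L
  best <- c(NA_real_, NA_real_)
  ## candidate lines are scored on a deterministic stride subsample (the
  ## consensus mask and final refit use every frame)
  score_idx <- seq.int(1L, n, by = max(1L, n %/% 25000L))
  xsub <- x[score_idx]
  ysub <- y[score_idx]
  with_seed(seed, {
    for (i in seq_len(n_iter)) {
      idx <- sample.int(n, min_samples)
      xs <- x[idx]
      ys <- y[idx]
      if (max(xs) - min(xs) < .Machine$double.eps * max(abs(xs), 1)) next
      cf <- if (min_samples == 2L) {
        sl <- (ys[2L] - ys[1L]) / (xs[2L] - xs[1L])
        c(ys[1L] - sl * xs[1L], sl)
      } else stats::lm.fit(cbind(1, xs), ys)$coefficients
      n_in <- sum(abs(ysub - cf[1L] - cf[2L] * xsub) <= threshold)
      if (n_in > best_n) {
        best_n <- n_in
        best <- cf
      }
    }
  })
  if (best_n < 2L) {
    warnf("RANSAC found no consensus; falling back to OLS")
    cf <- ols
    mask <- rep(TRUE, n)
  } else {
    ## local optimisation: refit on the consensus set and re-derive the
    ## inliers from the refit line until the mask stabilises, removing the
    ## tilt the two-point candidate imprints on the refit
    mask <- abs(y - best[1L] - best[2L] * x) <= threshold
    for (it in 1:20) {
      cf <- ols_line(x[mask], y[mask])
      new_mask <- abs(y - cf[1L] - cf[2L] * x) <= threshold
      if (sum(new_mask) < 2L || identical(new_mask, mask)) break
      mask <- new_mask
    }
  }
  structure(list(slope = unname(cf[2L]), intercept = unname(cf[1L]),
                 inlier_mask = mask, scaled_fit = unname(cf[2L] * x + cf[1L]),
                 threshold = threshold, n_iter = n_iter),
            class = "ransac_fit")
}

#' @export
print.ransac_fit <- function(x, ...) {
  cat(sprintf("<ransac_fit> F470 ~ %.4g + %.4g * fit; %d/%d inliers (%.1f%%)\n",
              x$intercept, x$slope, sum(x$inlier_mask), length(x$inlier_mask),
              100 * mean(x$inlier_mask)))
  invisible(x)
}

#' @export
coef.ransac_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Zero-phase low-pass filter
#'
#' Second-order Butterworth low-pass applied forward and backward
#' (\code{signal::filtfilt}), giving zero phase shift and unit DC gain.
#' Skipped with a warning when the sampling rate does not resolve the
#' cutoff (\code{frame_rate <= 2 * cutoff}).
#'
#' @param x signal.
#' @param frame_rate sampling rate, Hz.
#' @param cutoff cutoff frequency, Hz (default 6).
#' @param order filter order (default 2).
#' @export
lowpass <- function(x, frame_rate, cutoff = 6, order = 2) {
  if (!all(is.finite(x))) stopf("non-finite values in input to lowpass")
  if (frame_rate <= 2 * cutoff) {
    warnf("frame rate %g Hz cannot resolve a %g Hz cutoff; filtering skipped",
          frame_rate, cutoff)
    return(x)
  }
  bf <- signal::butter(order, cutoff / (frame_rate / 2), type = "low")
  ## odd-reflection padding so the zero initial filter state settles in the
  ## padding, not in the data (filtfilt alone leaves start-up transients)
  n <- length(x)
  p <- min(n - 1L, 60L)
  xp <- c(2 * x[1L] - x[(p + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(p + 1L):(p + n)]
}

#' Corrected fluorescence (dF/F) from the scaled isosbestic control
#'
#' Divides the (filtered) GCaMP channel by the scaled isosbestic control.
#' \code{mode = "ratio"} is the plain quotient \code{F470 / control};
#' \code{mode = "subtract"} is \code{(F470 - control) / control}. The two
#' differ by exactly 1 pointwise, so they yield identical traces after
#' per-session z-scoring.
#'
#' @param F470_filtered filtered GCaMP channel.
#' @param control scaled isosbestic control trace, strictly positive.
#' @param mode "ratio" or "subtract".
#' @return numeric dF/F trace. Signals a condition of class
#'   \code{photolick_qc_error} when the control is not strictly positive.
#' @export
compute_dff <- function(F470_filtered, control, mode = c("ratio", "subtract")) {
  mode <- match.arg(mode)
  if (length(F470_filtered) != length(control))
    stopf("F470 and control lengths differ")
  if (any(control <= 0))
    stop(structure(class = c("photolick_qc_error", "error", "condition"),
                   list(message = "nonpositive control fit", call = NULL)))
  if (mode == "ratio") F470_filtered / control
  else (F470_filtered - control) / control
}

#' Z-score a dF/F trace over the whole session
#' @param dff dF/F trace for one fiber-session.
#' @return \code{(dff - mean(dff)) / sd(dff)}.
#' @export
zscore_session <- function(dff) {
  s <- stats::sd(dff)
  if (!is.finite(s) || s == 0) stopf("zero-variance dF/F trace cannot be z-scored")
  (dff - mean(dff)) / s
}

#' Quality control for one processed recording
#'
#' Fails a recording for a poor bleach fit (low r-squared or
#' non-convergence), a small RANSAC consensus (excessive motion or cable
#' artifacts), a nonpositive control fit, or sustained extreme excursions of
#' the z-scored trace (cable disconnects). Reasons are fixed strings so
#' downstream tooling can act on them.
#'
#' @param fit a \code{bleach_fit}.
#' @param scale a \code{ransac_fit}.
#' @param zdff z-scored dF/F trace (may be NULL if dF/F failed upstream).
#' @param frame_rate Hz, for the dwell limit.
#' @param r2_min minimum bleach-fit r-squared (default 0.8).
#' @param inlier_min minimum RANSAC inlier fraction (default 0.5).
#' @param excursion_z excursion bound in z-units (default 10).
#' @param dwell_s maximum time the bound may be exceeded contiguously, s
#'   (default 1).
#' @return list with \code{passed} (logical) and \code{reason}
#'   (NA when passed).
#' @export
qc_recording <- function(fit, scale, zdff, frame_rate,
                         r2_min = 0.8, inlier_min = 0.5,
                         excursion_z = 10, dwell_s = 1) {
  fail <- function(reason) list(passed = FALSE, reason = reason)
  if (!fit$converged || !is.finite(fit$r_squared) || fit$r_squared < r2_min)
    return(fail("poor bleach fit"))
  if (mean(scale$inlier_mask) < inlier_min)
    return(fail("low inlier fraction"))
  if (is.null(zdff)) return(fail("nonpositive control fit"))
  over <- abs(zdff) > excursion_z
  if (any(over)) {
    runs <- rle(over)
    if (max(runs$lengths[runs$values]) > dwell_s * frame_rate)
      return(fail("excursion bound exceeded"))
  }
  list(passed = TRUE, reason = NA_character_)
}

#' Run the full preprocessing chain on one recording
#'
#' Fixed stage order: trim the first frames, fit the biexponential bleach
#' curve on the isosbestic channel, RANSAC-scale the fit to the GCaMP
#' channel, zero-phase low-pass both channels at 6 Hz, divide by the scaled
#' control, z-score by session, and apply quality control.
#'
#' The division control is chosen by \code{control}: the default
#' \code{"scaled_isosbestic"} applies the RANSAC slope/intercept to the
#' (filtered) raw isosbestic channel, so additive artifacts shared by the
#' two channels cancel in the quotient; \code{"scaled_fit"} divides by the
#' smooth scaled bleach curve instead, which corrects bleaching only.
#'
#' @param rec a \code{\link{photometry_recording}}.
#' @param seed integer seed for the RANSAC stage.
#' @param trim_n frames to trim (default 300).
#' @param cutoff low-pass cutoff, Hz.
#' @param dff_mode "ratio" or "subtract" (see \code{\link{compute_dff}}).
#' @param control "scaled_isosbestic" or "scaled_fit".
#' @param qc named list overriding \code{\link{qc_recording}} thresholds.
#' @return object of class \code{dff_trace}: \code{time} (re-zeroed),
#'   \code{dff}, \code{zdff}, \code{qc}, \code{bleach_fit}, \code{scale},
#'   \code{trim_offset}, \code{frame_rate}, \code{meta}, \code{fiber_side}.
#' @export
process_recording <- function(rec, seed, trim_n = 300, cutoff = 6,
                              dff_mode = c("ratio", "subtract"),
                              control = c("scaled_isosbestic", "scaled_fit"),
                              qc = list()) {
  dff_mode <- match.arg(dff_mode)
  control <- match.arg(control)
  r <- trim_frames(rec, trim_n)
  fit <- fit_biexponential(r$time, r$F415)
  scale <- ransac_scale(fit$fitted, r$F470, seed = seed)
  f470 <- lowpass(r$F470, r$frame_rate, cutoff)
  ctrl <- if (control == "scaled_isosbestic") {
    scale$slope * lowpass(r$F415, r$frame_rate, cutoff) + scale$intercept
  } else scale$scaled_fit
  dz <- tryCatch({
    dff <- compute_dff(f470, ctrl, dff_mode)
    list(dff = dff, zdff = zscore_session(dff))
  }, photolick_qc_error = function(e) list(dff = NULL, zdff = NULL))
  qc_args <- utils::modifyList(
    list(fit = fit, scale = scale, zdff = dz$zdff, frame_rate = r$frame_rate),
    qc)
  qcres <- do.call(qc_recording, qc_args)
  structure(list(time = r$time, dff = dz$dff, zdff = dz$zdff, qc = qcres,
                 bleach_fit = fit, scale = scale, trim_offset = r$trim_offset,
                 frame_rate = r$frame_rate, meta = r$meta,
                 fiber_side = r$fiber_side, dff_mode = dff_mode,
                 control = control),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %s fiber, %d frames @ %g Hz; QC %s%s\n",
              x$fiber_side, length(x$time), x$frame_rate,
              if (x$qc$passed) "passed" else "FAILED",
              if (x$qc$passed) "" else paste0(" (", x$qc$reason, ")")))
  invisible(x)
}

#' @export
plot.dff_trace <- function(x, what = c("zdff", "dff"), ...) {
  what <- match.arg(what)
  graphics::plot(x$time, x[[what]], type = "l", xlab = "time (s)",
                 ylab = if (what == "zdff") "z(dF/F)" else "dF/F", ...)
  invisible(x)
}
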