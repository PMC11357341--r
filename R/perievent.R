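#' Align a z-scored dF/F trace to drink starts
#'
#' Extracts one row per drink on a common relative-time grid spanning the
#' 10-s peri-drink window (5 s before to 5 s after bottle contact), sampled
#' by linear interpolation of the trace. The grid has \code{n_bins} points
#' at the left edges of equal bins, so at the default 150 bins and a 15 Hz
#' recording the grid coincides with the native frames. Drinks whose window
#' would run off the trace are dropped and logged, never padded.
#'
#' @param trace a \code{\link{process_recording}} result (\code{dff_trace}),
#'   or a list with \code{time} and \code{zdff}.
#' @param events data.frame with one row per drink: \code{start} (s, on the
#'   trace clock) and \code{length} (drink length, s); any further columns
#'   are carried through as row metadata.
#' @param window numeric length-2, s relative to drink start.
#' @param n_bins number of grid points (default 150).
#' @return object of class \code{perievent_matrix}: \code{values}
#'   (rows = retained drinks), \code{t_rel} (grid), \code{events} (metadata
#'   of retained rows), and \code{dropped} (data.frame of excluded events
#'   with reasons).
#' @export
align_to_drinks <- function(trace, events, window = c(-5, 5), n_bins = 150) {
  time <- trace$time
  z <- trace$zdff
  if (is.null(z)) stopf("trace has no zdff (QC-failed recording?)")
  t_rel <- window[1L] + (seq_len(n_bins) - 1L) * diff(window) / n_bins
  lo <- time[1L] - window[1L]          # earliest admissible start
  hi <- time[length(time)] - window[2L]
  ok <- events$start >= lo & events$start <= hi
  dropped <- events[!ok, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "window exceeds recording"
  kept <- events[ok, , drop = FALSE]
  vals <- matrix(NA_real_, nrow(kept), n_bins)
  for (i in seq_len(nrow(kept)))
    vals[i, ] <- stats::approx(time, z, xout = kept$start[i] + t_rel,
                               ties = "ordered")$y
  structure(list(values = vals, t_rel = t_rel, events = kept,
                 dropped = dropped, window = window),
            class = "perievent_matrix")
}

#' @export
print.perievent_matrix <- function(x, ...) {
  cat(sprintf("<perievent_matrix> %d events x %d bins over [%g, %g] s (%d dropped)\n",
              nrow(x$values), length(x$t_rel), x$window[1L], x$window[2L],
              nrow(x$dropped)))
  invisible(x)
}

#' Per-drink transient metrics: peak amplitude, time to peak, AUC
#'
#' For each aligned row, searches the drinking event itself (relative time 0
#' to the drink end, capped at +5 s) for the maximum z-scored signal. Time
#' to peak is the first argmax on the grid; the area under the curve is the
#' trapezoidal integral of the row from the peak time to the drink end
#' (capped at the window edge), an off-kinetics measure of how long the
#' signal stays elevated after the peak.
#'
#' @param pem a \code{\link{align_to_drinks}} result.
#' @return data.frame with the event metadata plus \code{peak_amplitude}
#'   (z-units), \code{time_to_peak} (s from drink start), \code{auc}
#'   (z-units times s) and \code{drink_end} (the capped end used, s).
#' @export
transient_metrics <- function(pem) {
  t_rel <- pem$t_rel
  ev <- pem$events
  n <- nrow(ev)
  peak <- ttp <- auc <- dend <- numeric(n)
  for (i in seq_len(n)) {
    row <- pem$values[i, ]
    m <- transient_metrics_row(row, t_rel, ev$length[i])
    peak[i] <- m$peak; ttp[i] <- m$ttp; auc[i] <- m$auc; dend[i] <- m$end
  }
  cbind(ev, data.frame(peak_amplitude = peak, time_to_peak = ttp,
                       auc = auc, drink_end = dend))
}

## single-row metric kernel; end cap = min(drink length, window edge, grid max)
transient_metrics_row <- function(row, t_rel, drink_length) {
  cap <- min(drink_length, max(t_rel), 5)
  win <- which(t_rel >= 0 & t_rel <= cap)
  peak <- max(row[win])
  ipk <- win[which.max(row[win])]
  ttp <- t_rel[ipk]
  seg <- which(t_rel >= ttp & t_rel <= cap)
  xs <- t_rel[seg]
  ys <- row[seg]
  if (cap > xs[length(xs)]) {       # close the integral at the cap itself
    xs <- c(xs, cap)
    ys <- c(ys, stats::approx(t_rel, row, xout = cap)$y)
  }
  list(peak = peak, ttp = ttp, auc = trapz(xs, ys), end = cap)
}

#' Group mean +/- SEM peri-event traces
#'
#' Per-bin mean and standard error across events within each metadata
#' group (by default sex x fluid x hemisphere).
#'
#' @param pem a \code{\link{align_to_drinks}} result, or a list with
#'   \code{values}, \code{t_rel}, \code{events} pooled across sessions.
#' @param by character vector of grouping columns present in the event
#'   metadata.
#' @return long data.frame: grouping columns, \code{t_rel}, \code{mean},
#'   \code{sem} (NA for singleton groups), \code{n} (events in group).
#' @export
group_mean_trace <- function(pem, by = c("sex", "fluid", "side")) {
  ev <- pem$events
  if (!all(by %in% names(ev)))
    stopf("grouping columns missing from event metadata: %s",
          paste(setdiff(by, names(ev)), collapse = ", "))
  if (!nrow(ev)) stopf("no events to group")
  key <- interaction(ev[by], drop = TRUE, sep = "|")
  out <- lapply(levels(key), function(k) {
    rows <- pem$values[key == k, , drop = FALSE]
    n <- nrow(rows)
    mu <- colMeans(rows)
    sem <- if (n >= 2L) apply(rows, 2L, stats::sd) / sqrt(n) else
      rep(NA_real_, ncol(rows))
    meta <- ev[which(key == k)[1L], by, drop = FALSE]
    cbind(meta[rep(1L, length(pem$t_rel)), , drop = FALSE],
          data.frame(t_rel = pem$t_rel, mean = mu, sem = sem, n = n,
                     row.names = NULL))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pool peri-event matrices from several recordings
#' @param pems list of \code{perievent_matrix} objects on identical grids.
#' @return one \code{perievent_matrix} with rows concatenated.
#' @export
pool_perievents <- function(pems) {
  pems <- pems[vapply(pems, function(p) nrow(p$values) > 0L, logical(1))]
  if (!length(pems)) stopf("no events to pool")
  t_rel <- pems[[1L]]$t_rel
  for (p in pems)
    if (!isTRUE(all.equal(p$t_rel, t_rel))) stopf("peri-event grids differ")
  structure(list(values = do.call(rbind, lapply(pems, `[[`, "values")),
                 t_rel = t_rel,
                 events = do.call(rbind, lapply(pems, `[[`, "events")),
                 dropped = do.call(rbind, lapply(pems, `[[`, "dropped")),
                 window = pems[[1L]]$window),
            class = "perievent_matrix")
}
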