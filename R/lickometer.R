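#' Construct a lickometer session
#'
#' One animal-session of 3-s-binned beam-break records plus bottle and body
#' weights. The device writes one record per occupied 3-s window: the number
#' of beam-break onsets (\code{n_events}) and the total broken duration
#' within the window (\code{event_duration}, capped at 3 s). Windows whose
#' duration is carried over from a break that started earlier (e.g. a slow
#' leak holding the beam) can have \code{n_events = 0}.
#'
#' @param animal_id,sex,fluid,session_index,week session metadata; sex in
#'   \{male, female\}, fluid in \{water, alcohol\}.
#' @param duration session length, s (7200 Mon-Thu, 14400 Fri).
#' @param records data.frame with \code{bin_start}, \code{n_events},
#'   \code{event_duration}.
#' @param bottle_pre,bottle_post session bottle weights, g.
#' @param body_weight animal weight, g.
#' @param homecage_pre,homecage_post home-cage water bottle weights, g
#'   (inter-session intake); may be NA.
#' @return object of class \code{lick_session}.
#' @export
lick_session <- function(animal_id, sex, fluid, session_index, week, duration,
                         records, bottle_pre, bottle_post, body_weight,
                         homecage_pre = NA_real_, homecage_post = NA_real_) {
  records <- as.data.frame(records)
  need <- c("bin_start", "n_events", "event_duration")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  x <- structure(list(
    animal_id = as.character(animal_id), sex = sex, fluid = fluid,
    session_index = as.integer(session_index), week = as.integer(week),
    duration = duration, records = records,
    bottle_pre = bottle_pre, bottle_post = bottle_post,
    body_weight = body_weight,
    homecage_pre = homecage_pre, homecage_post = homecage_post),
    class = "lick_session")
  validate_lick_session(x)
  x
}

validate_lick_session <- function(x) {
  r <- x$records
  if (nrow(r)) {
    bad <- which(r$bin_start %% 3 != 0)
    if (length(bad)) stopf("record %d: bin_start %s is not a multiple of 3 s",
                           bad[1], format(r$bin_start[bad[1]]))
    if (any(diff(r$bin_start) <= 0))
      stopf("record %d: bin_start values must be strictly increasing",
            which(diff(r$bin_start) <= 0)[1] + 1L)
    bad <- which(r$bin_start >= x$duration)
    if (length(bad)) stopf("record %d: bin_start %g beyond session duration %g",
                           bad[1], r$bin_start[bad[1]], x$duration)
    bad <- which(r$event_duration < 0 | r$event_duration > 3)
    if (length(bad)) stopf("record %d: event_duration %g outside [0, 3] s",
                           bad[1], r$event_duration[bad[1]])
    bad <- which(r$n_events < 0 | r$n_events != round(r$n_events))
    if (length(bad)) stopf("record %d: n_events must be a nonnegative count",
                           bad[1])
  }
  if (!is.na(x$bottle_pre) && !is.na(x$bottle_post) &&
      x$bottle_post > x$bottle_pre)
    stopf("bottle_post exceeds bottle_pre")
  invisible(x)
}

#' @export
print.lick_session <- function(x, ...) {
  cat(sprintf("<lick_session> %s session %d (%s, %s, week %d): %d records, %d s\n",
              x$animal_id, x$session_index, x$sex, x$fluid, x$week,
              nrow(x$records), x$duration))
  invisible(x)
}

#' Read a lickometer log CSV
#'
#' Expects the dialect written by \code{\link{write_lick_log}}: leading
#' \code{# key: value} metadata lines followed by a header row
#' \code{bin_start_s,n_events,event_duration_s}. Malformed rows are reported
#' with their file line numbers.
#'
#' @param path file path.
#' @return a \code{\link{lick_session}}.
#' @export
read_lick_log <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  for (ln in lines[hdr]) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3L) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  body_start <- if (length(hdr)) max(hdr) + 1L else 1L
  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  if (!length(body) || !grepl("bin_start_s", body[1]))
    stopf("%s: missing column header 'bin_start_s,n_events,event_duration_s'",
          path)
  cols <- strsplit(body[1], ",")[[1]]
  need <- c("bin_start_s", "n_events", "event_duration_s")
  if (!all(need %in% cols))
    stopf("%s: missing columns %s", path,
          paste(setdiff(need, cols), collapse = ", "))
  records <- data.frame(bin_start = numeric(0), n_events = integer(0),
                        event_duration = numeric(0))
  if (length(body) > 1L) {
    vals <- utils::read.csv(text = paste(body, collapse = "\n"))
    bad <- which(!is.finite(vals$bin_start_s) | !is.finite(vals$n_events) |
                   !is.finite(vals$event_duration_s))
    if (length(bad))
      stopf("%s line %d: non-numeric record", path,
            body_start + bad[1])
    records <- data.frame(bin_start = vals$bin_start_s,
                          n_events = as.integer(vals$n_events),
                          event_duration = vals$event_duration_s)
    bad <- which(records$event_duration < 0 | records$event_duration > 3)
    if (length(bad))
      stopf("%s line %d: event_duration %g outside [0, 3] s", path,
            body_start + bad[1], records$event_duration[bad[1]])
    bad <- which(diff(records$bin_start) <= 0)
    if (length(bad))
      stopf("%s line %d: bin_start not strictly increasing", path,
            body_start + bad[1] + 1L)
  }
  num <- function(key, default = NA_real_) {
    if (is.null(meta[[key]])) default else as.numeric(meta[[key]])
  }
  lick_session(
    animal_id = meta$animal_id %||% "unknown",
    sex = meta$sex %||% "male", fluid = meta$fluid %||% "water",
    session_index = num("session_index", 1), week = num("week", 1),
    duration = num("duration_s", 7200), records = records,
    bottle_pre = num("bottle_pre_g"), bottle_post = num("bottle_post_g"),
    body_weight = num("body_weight_g"),
    homecage_pre = num("homecage_pre_g"), homecage_post = num("homecage_post_g"))
}

#' Write a lickometer log CSV
#' @param session a \code{\link{lick_session}}.
#' @param path output path.
#' @export
write_lick_log <- function(session, path) {
  s <- session
  meta <- c(animal_id = s$animal_id, sex = s$sex, fluid = s$fluid,
            session_index = s$session_index, week = s$week,
            duration_s = s$duration, bottle_pre_g = s$bottle_pre,
            bottle_post_g = s$bottle_post, body_weight_g = s$body_weight,
            homecage_pre_g = s$homecage_pre, homecage_post_g = s$homecage_post)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  writeLines("bin_start_s,n_events,event_duration_s", con)
  r <- s$records
  if (nrow(r))
    writeLines(sprintf("%s,%d,%s",
                       format(r$bin_start, trim = TRUE, digits = 15),
                       r$n_events,
                       format(r$event_duration, trim = TRUE, digits = 15)),
               con)
  invisible(path)
}

#' Merge occupied 3-s windows into drinks
#'
#' Any tube interaction within a 3-s device window defines a drink;
#' consecutive occupied windows (bin starts exactly 3 s apart) are merged
#' into a single drink whose event count and duration sum over the merged
#' windows. Occupied means \code{n_events > 0} or \code{event_duration > 0}.
#'
#' @param session a \code{\link{lick_session}} or a record data.frame.
#' @return data.frame with one row per drink: \code{drink}, \code{start},
#'   \code{end}, \code{n_events}, \code{event_duration}, \code{length}
#'   (\code{end - start}), sorted by start. The attribute
#'   \code{record_drink} maps each occupied input record to its drink index.
#' @export
bin_to_drinks <- function(session) {
  r <- if (inherits(session, "lick_session")) session$records else session
  occ <- which(r$n_events > 0L | r$event_duration > 0)
  empty <- data.frame(drink = integer(0), start = numeric(0), end = numeric(0),
                      n_events = integer(0), event_duration = numeric(0),
                      length = numeric(0))
  if (!length(occ)) return(structure(empty, record_drink = integer(0)))
  bs <- r$bin_start[occ]
  new_run <- c(TRUE, diff(bs) != 3)
  drink_id <- cumsum(new_run)
  out <- data.frame(
    drink = seq_len(max(drink_id)),
    start = as.numeric(tapply(bs, drink_id, min)),
    end = as.numeric(tapply(bs, drink_id, max)) + 3,
    n_events = as.integer(tapply(r$n_events[occ], drink_id, sum)),
    event_duration = as.numeric(tapply(r$event_duration[occ], drink_id, sum)))
  out$length <- out$end - out$start
  structure(out, record_drink = drink_id, record_rows = occ)
}

#' Clean artifact drinks with the events-vs-duration linear model
#'
#' Fits a line of the per-drink event count on the per-drink event duration
#' across a session's drinks, and removes drinks whose raw residual exceeds
#' \code{threshold} in absolute value (event-count units). Slow leaks sit
#' far below the line (long duration, few events) and bottle chews far
#' above it (many events at near-zero duration).
#'
#' The default line is the Theil-Sen median-of-pairwise-slopes estimator:
#' leak drinks are extreme outliers along the duration axis, and a
#' leverage-robust fit is what keeps them from dragging the line toward
#' themselves and masking their own residuals (which a one-pass
#' least-squares fit does). \code{method = "ols"} gives the plain
#' least-squares line instead. With fewer than three drinks, or a
#' degenerate fit (no duration spread), all drinks are passed through with
#' a warning.
#'
#' @param drinks data.frame from \code{\link{bin_to_drinks}}.
#' @param threshold residual cutoff in event-count units (default 3).
#' @param method "theil-sen" (default) or "ols".
#' @return list of class \code{lick_cleaning}: \code{kept}, \code{removed}
#'   (drink data.frames), \code{model} (list with \code{slope},
#'   \code{intercept}, \code{residuals}), \code{threshold}, \code{fitted}
#'   (logical: was a line actually fitted).
#' @export
clean_events <- function(drinks, threshold = 3,
                         method = c("theil-sen", "ols")) {
  method <- match.arg(method)
  passthrough <- function(msg) {
    warnf("clean_events: %s; passing all drinks through", msg)
    structure(list(kept = drinks, removed = drinks[0, , drop = FALSE],
                   model = list(slope = NA_real_, intercept = NA_real_,
                                residuals = rep(NA_real_, nrow(drinks))),
                   threshold = threshold, fitted = FALSE),
              class = "lick_cleaning")
  }
  if (nrow(drinks) < 3L) return(passthrough("fewer than 3 drinks"))
  x <- drinks$event_duration
  y <- drinks$n_events
  if (stats::var(x) <= .Machine$double.eps * mean(x)^2)
    return(passthrough("degenerate fit: all drink durations equal"))
  if (method == "ols") {
    fit <- stats::lm.fit(cbind(1, x), y)
    slope <- unname(fit$coefficients[2L])
    intercept <- unname(fit$coefficients[1L])
  } else {
    ij <- utils::combn(length(x), 2L)
    dx <- x[ij[2L, ]] - x[ij[1L, ]]
    ok <- abs(dx) > .Machine$double.eps * pmax(abs(x[ij[1L, ]]), 1)
    slope <- stats::median((y[ij[2L, ]] - y[ij[1L, ]])[ok] / dx[ok])
    intercept <- stats::median(y - slope * x)
  }
  res <- y - intercept - slope * x
  out <- abs(res) > threshold
  structure(list(kept = drinks[!out, , drop = FALSE],
                 removed = drinks[out, , drop = FALSE],
                 model = list(slope = slope, intercept = intercept,
                              residuals = res),
                 threshold = threshold, fitted = TRUE),
            class = "lick_cleaning")
}

#' @export
print.lick_cleaning <- function(x, ...) {
  cat(sprintf("<lick_cleaning> kept %d / removed %d drinks (|residual| > %g)\n",
              nrow(x$kept), nrow(x$removed), x$threshold))
  if (x$fitted)
    cat(sprintf("  events ~ %.3f + %.3f * duration\n",
                x$model$intercept, x$model$slope))
  invisible(x)
}

#' Drinking microstructure summary for one session
#'
#' Computes the session's microstructure features from its cleaned drinks:
#' total events and event duration, drink count, latency to drink (first raw
#' beam-break window, before cleaning), mean inter-drink interval
#' (start-to-start gaps of successive cleaned drinks), front-loading (events
#' in the first 30 min, over cleaned drinks), and gram-per-kilogram fluid
#' intakes from the bottle weights. Undefined features (latency with no
#' events, IDI with fewer than two drinks) are NA.
#'
#' @param session a \code{\link{lick_session}}.
#' @param clean apply \code{\link{clean_events}} first (default TRUE).
#' @param threshold residual threshold for cleaning.
#' @return one-row data.frame with session keys and feature columns,
#'   including the pre-cleaning totals (\code{raw_total_events},
#'   \code{raw_total_event_duration}) alongside the cleaned ones.
#' @export
microstructure <- function(session, clean = TRUE, threshold = 3) {
  s <- session
  drinks <- bin_to_drinks(s)
  record_drink <- attr(drinks, "record_drink")
  record_rows <- attr(drinks, "record_rows")
  if (clean && nrow(drinks) >= 3L) {
    cl <- clean_events(drinks, threshold)
  } else {
    cl <- structure(list(kept = drinks, removed = drinks[0, , drop = FALSE],
                         model = NULL, threshold = threshold, fitted = FALSE),
                    class = "lick_cleaning")
  }
  kept <- cl$kept
  occ <- s$records[record_rows, , drop = FALSE]
  kept_bins <- record_drink %in% kept$drink
  latency <- if (nrow(occ)) occ$bin_start[1] else NA_real_
  idi <- if (nrow(kept) >= 2L) mean(diff(kept$start)) else NA_real_
  frontload <- sum(occ$n_events[kept_bins & occ$bin_start < 1800])
  intake <- if (is.na(s$bottle_pre) || is.na(s$bottle_post)) NA_real_ else
    compute_intake(s$bottle_pre, s$bottle_post, s$body_weight, s$fluid)
  inter <- if (is.na(s$homecage_pre) || is.na(s$homecage_post)) NA_real_ else
    intersession_intake(s$homecage_pre, s$homecage_post, s$body_weight)
  data.frame(
    animal_id = s$animal_id, sex = s$sex, fluid = s$fluid,
    week = s$week, session = s$session_index, duration_s = s$duration,
    total_events = sum(kept$n_events),
    total_event_duration = sum(kept$event_duration),
    n_drinks = nrow(kept),
    raw_total_events = sum(drinks$n_events),
    raw_total_event_duration = sum(drinks$event_duration),
    n_drinks_removed = nrow(cl$removed),
    latency_s = latency,
    mean_idi_s = idi,
    frontload_events = frontload,
    intake_gkg = intake,
    intersession_gkg = inter,
    stringsAsFactors = FALSE)
}

#' Gram-per-kilogram fluid intake from bottle weights
#'
#' Water: consumed grams divided by body weight in kg. Alcohol (20\% v/v
#' ethanol in water): consumed solution grams are converted to millilitres
#' with the solution density, to grams of ethanol with the 20\% volume
#' fraction and ethanol density, then divided by body weight in kg.
#'
#' @param bottle_pre,bottle_post bottle weights, g (\code{pre >= post}).
#' @param body_weight animal weight, g.
#' @param fluid "water" or "alcohol".
#' @param rho_solution density of the 20\% v/v ethanol solution, g/mL.
#' @param rho_ethanol density of ethanol, g/mL.
#' @param vol_frac ethanol volume fraction of the solution.
#' @return intake in g/kg (grams of water, or grams of ethanol, per kg).
#' @export
compute_intake <- function(bottle_pre, bottle_post, body_weight,
                           fluid = c("water", "alcohol"),
                           rho_solution = 0.9687, rho_ethanol = 0.78945,
                           vol_frac = 0.20) {
  fluid <- match.arg(fluid)
  if (any(bottle_pre < bottle_post))
    stopf("negative consumption: bottle_post exceeds bottle_pre")
  if (any(body_weight <= 0)) stopf("body_weight must be positive")
  d <- bottle_pre - bottle_post
  g <- if (fluid == "water") d else d / rho_solution * vol_frac * rho_ethanol
  g / (body_weight / 1000)
}

#' Inter-session water intake in g/kg
#'
#' Water consumed from the home-cage bottle between sessions, per kg body
#' weight; identical arithmetic to \code{\link{compute_intake}} for water.
#'
#' @param homecage_pre,homecage_post home-cage bottle weights, g.
#' @param body_weight animal weight, g.
#' @export
intersession_intake <- function(homecage_pre, homecage_post, body_weight) {
  compute_intake(homecage_pre, homecage_post, body_weight, "water")
}
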