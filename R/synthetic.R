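#' Default peri-drink transient amplitude map
#'
#' Mean transient amplitude (arbitrary fluorescence units) for each
#' sex x fluid x hemisphere cell. The defaults emulate the lateralised
#' pattern seen in cortico-striatal drinking recordings: the largest
#' responses at left-hemisphere inputs in males drinking alcohol, water
#' responses intermediate, right-hemisphere alcohol responses suppressed
#' below water, and attenuated effects in females.
#'
#' @return a data.frame with columns \code{sex}, \code{fluid}, \code{side},
#'   \code{amplitude}.
#' @export
default_amplitude_map <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 4L),
    fluid = rep(rep(c("water", "alcohol"), each = 2L), 2L),
    side = rep(c("left", "right"), 4L),
    amplitude = c(
      0.35, 0.30,  # male water  left/right
      0.50, 0.20,  # male alcohol left/right
      0.28, 0.25,  # female water left/right
      0.33, 0.22), # female alcohol left/right
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for one animal-session
#'
#' Bundles every parameter of the synthetic lickometer + dual-fiber
#' photometry session generator. The defaults describe a 2-hour
#' limited-access drinking session recorded at 15 Hz per channel with
#' biexponential photobleaching, channel-shared motion artifacts,
#' event-locked calcium transients with double-exponential kinetics, and a
#' bout-structured lick stream into which leak and chew artifacts can be
#' injected.
#'
#' @param session_duration session length in seconds (7200 for weekday
#'   2-h sessions, 14400 for the 4-h Friday session).
#' @param frame_rate effective per-channel frame rate in Hz. 15 Hz gives a
#'   10-s peri-event window exactly 150 samples.
#' @param bleach named vector \code{c(A1, tau1, A2, tau2, C)} of the
#'   isosbestic-channel biexponential bleach curve
#'   \eqn{A_1 e^{-t/\tau_1} + A_2 e^{-t/\tau_2} + C} (a.u., s).
#' @param channel_scale true inter-channel scale \code{s}: the 470 nm
#'   baseline is \code{s} times the 415 nm bleach curve.
#' @param kernel list with \code{rise_tau} and \code{decay_tau} (s) of the
#'   transient kernel; defaults approximate slow GCaMP indicator kinetics.
#' @param amplitude_map data.frame as \code{\link{default_amplitude_map}}.
#' @param amplitude_cv coefficient of variation of per-drink transient
#'   amplitudes around the map mean (default 0.1; draws truncated at 0).
#' @param motion list \code{rate} (events/min), \code{amplitude} (a.u.),
#'   \code{duration} (s) of additive artifacts shared by both channels of a
#'   fiber.
#' @param noise_sigma i.i.d. Gaussian frame noise, a.u. (default 0.5\% of
#'   the asymptotic baseline).
#' @param bout_model list controlling the lick stream: \code{n_bouts},
#'   \code{events_per_bout} (mean licks per bout), \code{bout_dispersion}
#'   (lognormal sd of the per-bout intensity, giving realistic
#'   overdispersion in bout sizes), \code{spacing_min} (minimum quiet gap
#'   between bouts, s; must exceed 6 s so bouts map to distinct 3-s-window
#'   drinks), \code{lick_interval} (mean inter-lick interval, s),
#'   \code{lick_duration} (mean beam-break duration per lick, s), and
#'   \code{duration_cv} (coefficient of variation of lick durations).
#' @param artifacts list \code{n_leak}, \code{leak_multiplier},
#'   \code{n_chew}, \code{chew_multiplier} passed to
#'   \code{\link{inject_artifacts}}.
#' @param sex,fluid,animal_id,session_index session metadata. Sessions 1-15
#'   are water weeks 1-3; 16-30 alcohol weeks 4-6.
#' @param body_weight animal weight, g.
#' @param bottle_pre pre-session bottle weight, g.
#' @param intake_g intended fluid consumption, g (bottle_pre - bottle_post).
#'   Default 1.2 g water / 0.35 g alcohol solution, scaled by session length.
#' @param homecage_pre,intersession_g home-cage water bottle weight and
#'   intended inter-session water consumption, g.
#' @param seed integer; fully determines the generated session.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(session_duration = 7200,
                       frame_rate = 15,
                       bleach = c(A1 = 2, tau1 = 30, A2 = 1, tau2 = 600, C = 10),
                       channel_scale = 1.0,
                       kernel = list(rise_tau = 0.3, decay_tau = 1.5),
                       amplitude_map = default_amplitude_map(),
                       amplitude_cv = 0.1,
                       motion = list(rate = 0.5, amplitude = 1.0, duration = 0.3),
                       noise_sigma = 0.05,
                       bout_model = list(n_bouts = 25, events_per_bout = 12,
                                         bout_dispersion = 0.6, spacing_min = 6.5,
                                         lick_interval = 0.125, lick_duration = 0.05,
                                         duration_cv = 0.1),
                       artifacts = list(n_leak = 1, leak_multiplier = 10,
                                        n_chew = 1, chew_multiplier = 10),
                       sex = "male", fluid = "water",
                       animal_id = "sim01", session_index = 1L,
                       body_weight = 25, bottle_pre = 100,
                       intake_g = NULL, homecage_pre = 150, intersession_g = 3,
                       seed = 1L) {
  kb <- c(A1 = NA, tau1 = NA, A2 = NA, tau2 = NA, C = NA)
  kb[names(bleach)] <- bleach
  if (anyNA(kb)) stopf("bleach must name A1, tau1, A2, tau2, C")
  if (kb["tau1"] <= 0 || kb["tau2"] <= 0) stopf("bleach taus must be positive")
  if (!is.null(kernel$rise_tau)) {
    if (kernel$rise_tau <= 0 || kernel$decay_tau <= 0)
      stopf("kernel taus must be positive")
    if (kernel$rise_tau >= kernel$decay_tau)
      stopf("kernel rise_tau must be smaller than decay_tau")
  }
  if (!sex %in% c("male", "female")) stopf("sex must be 'male' or 'female'")
  if (!fluid %in% c("water", "alcohol")) stopf("fluid must be 'water' or 'alcohol'")
  if (is.null(intake_g))
    intake_g <- (if (fluid == "water") 1.2 else 0.35) * session_duration / 7200
  bm <- utils::modifyList(
    list(n_bouts = 25, events_per_bout = 12, bout_dispersion = 0.6,
         spacing_min = 6.5, lick_interval = 0.125, lick_duration = 0.05,
         duration_cv = 0.1),
    bout_model)
  if (bm$spacing_min <= 6)
    stopf("bout spacing_min must exceed 6 s so bouts map to distinct drinks")
  art <- utils::modifyList(
    list(n_leak = 1, leak_multiplier = 10, n_chew = 1, chew_multiplier = 10),
    artifacts)
  structure(list(
    session_duration = session_duration, frame_rate = frame_rate,
    bleach = kb, channel_scale = channel_scale, kernel = kernel,
    amplitude_map = amplitude_map, amplitude_cv = amplitude_cv,
    motion = motion, noise_sigma = noise_sigma,
    bout_model = bm, artifacts = art, sex = sex, fluid = fluid,
    animal_id = animal_id, session_index = as.integer(session_index),
    body_weight = body_weight, bottle_pre = bottle_pre, intake_g = intake_g,
    homecage_pre = homecage_pre, intersession_g = intersession_g,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %s session %d: %s %s, %d s @ %g Hz, seed %d\n",
              x$animal_id, x$session_index, x$sex, x$fluid,
              x$session_duration, x$frame_rate, x$seed))
  invisible(x)
}

#' Unit-peak double-exponential transient kernel
#'
#' \eqn{k(t) \propto e^{-t/\tau_d} - e^{-t/\tau_r}}, sampled on a grid of
#' step \code{dt} and normalised so its sampled maximum is exactly 1.
#' \code{k(0) = 0}. The continuous argmax sits at
#' \eqn{t^* = \ln(\tau_d/\tau_r)\,\tau_r\tau_d/(\tau_d-\tau_r)}.
#'
#' @param rise_tau,decay_tau time constants, s; \code{0 < rise_tau < decay_tau}.
#' @param dt sampling step, s.
#' @param t_max kernel support, s (default \code{8 * decay_tau}).
#' @return numeric vector of kernel values with attributes \code{time}
#'   (sample times) and \code{t_peak} (continuous argmax).
#' @export
transient_kernel <- function(rise_tau, decay_tau, dt, t_max = 8 * decay_tau) {
  if (!is.finite(rise_tau) || !is.finite(decay_tau) || rise_tau <= 0 || decay_tau <= 0)
    stopf("kernel taus must be positive")
  if (rise_tau >= decay_tau)
    stopf("rise_tau must be strictly smaller than decay_tau")
  t <- seq(0, t_max, by = dt)
  k <- exp(-t / decay_tau) - exp(-t / rise_tau)
  k <- k / max(k)
  structure(k, time = t,
            t_peak = log(decay_tau / rise_tau) * rise_tau * decay_tau /
              (decay_tau - rise_tau))
}

#' Generate a bout-structured lick stream
#'
#' Lays out \code{n_bouts} drinking bouts across the session. Bout sizes are
#' overdispersed (lognormal intensity, Poisson count), inter-lick intervals
#' are gamma-distributed around \code{lick_interval}, and beam-break
#' durations vary with coefficient of variation \code{duration_cv}.
#' Inter-bout quiet gaps always exceed \code{spacing_min} (> 6 s), so after
#' 3-s-window binning every bout becomes a distinct drink.
#'
#' @param bout_model list as in \code{\link{sim_config}}.
#' @param session_duration session length, s.
#' @param seed integer seed.
#' @return data.frame with one row per beam break: \code{bout}, \code{onset}
#'   (s), \code{duration} (s); zero rows when \code{n_bouts = 0}.
#' @export
make_lick_schedule <- function(bout_model, session_duration, seed) {
  bm <- bout_model
  n <- bm$n_bouts
  empty <- data.frame(bout = integer(0), onset = numeric(0), duration = numeric(0))
  if (n == 0L) return(empty)
  with_seed(seed, {
    lam <- bm$events_per_bout *
      exp(stats::rnorm(n, 0, bm$bout_dispersion) - bm$bout_dispersion^2 / 2)
    n_ev <- 1L + stats::rpois(n, pmax(lam - 1, 0))
    streams <- vector("list", n)
    bout_dur <- numeric(n)
    for (b in seq_len(n)) {
      gaps <- stats::rgamma(n_ev[b], shape = 9, rate = 9 / bm$lick_interval)
      onsets <- cumsum(c(0, gaps[-1]))
      durs <- pmax(bm$lick_duration * (1 + bm$duration_cv * stats::rnorm(n_ev[b])),
                   0.005)
      durs <- pmin(durs, c(diff(onsets), bm$lick_duration * 2))
      streams[[b]] <- data.frame(bout = b, onset = onsets, duration = durs)
      bout_dur[b] <- onsets[n_ev[b]] + durs[n_ev[b]]
    }
    fixed <- sum(bout_dur) + n * bm$spacing_min + 1
    if (fixed >= session_duration)
      stopf("infeasible lick schedule: %d bouts need %.1f s but session is %d s",
            n, fixed, session_duration)
    extra <- stats::rexp(n, rate = 1)
    extra <- extra / sum(extra) * (session_duration - 1 - fixed) *
      stats::runif(1, 0.6, 0.95)
    starts <- numeric(n)
    tcur <- 0
    for (b in seq_len(n)) {
      starts[b] <- tcur + bm$spacing_min + extra[b]
      tcur <- starts[b] + bout_dur[b]
    }
    out <- do.call(rbind, streams)
    out$onset <- out$onset + starts[out$bout]
    stopifnot(max(out$onset + out$duration) < session_duration)
    out
  })
}

#' Inject leak and chew artifacts into a lick stream
#'
#' Leak bouts have every beam-break duration multiplied by
#' \code{leak_multiplier} (long broken duration, event count unchanged),
#' emulating a slowly leaking spout that holds the beam broken. Chew bouts
#' have each lick replaced by \code{chew_multiplier} near-instantaneous
#' (2 ms) taps, inflating the event count at near-zero duration.
#'
#' @param stream data.frame from \code{\link{make_lick_schedule}}.
#' @param artifacts list \code{n_leak}, \code{leak_multiplier},
#'   \code{n_chew}, \code{chew_multiplier}.
#' @param seed integer seed.
#' @return list with \code{stream} (modified), \code{leak_bouts},
#'   \code{chew_bouts} (integer bout indices).
#' @export
inject_artifacts <- function(stream, artifacts, seed) {
  art <- artifacts
  n_inj <- art$n_leak + art$n_chew
  bouts <- unique(stream$bout)
  if (n_inj == 0L)
    return(list(stream = stream, leak_bouts = integer(0), chew_bouts = integer(0)))
  if (n_inj > length(bouts))
    stopf("%d artifact injections requested but only %d bouts available",
          n_inj, length(bouts))
  with_seed(seed, {
    pick <- sample(bouts, n_inj)
    leak <- sort(pick[seq_len(art$n_leak)])
    chew <- sort(setdiff(pick, leak))
    st <- stream
    if (length(leak)) {
      i <- st$bout %in% leak
      st$duration[i] <- st$duration[i] * art$leak_multiplier
    }
    if (length(chew)) {
      keep <- st[!st$bout %in% chew, , drop = FALSE]
      reps <- lapply(chew, function(b) {
        ev <- st[st$bout == b, , drop = FALSE]
        m <- art$chew_multiplier
        data.frame(bout = b,
                   onset = rep(ev$onset, each = m) +
                     rep(seq(0, by = 0.01, length.out = m), nrow(ev)),
                   duration = 0.002)
      })
      st <- rbind(keep, do.call(rbind, reps))
      st <- st[order(st$onset), , drop = FALSE]
      rownames(st) <- NULL
    }
    list(stream = st, leak_bouts = leak, chew_bouts = chew)
  })
}

#' Bin a continuous lick stream into 3-s device windows
#'
#' Emulates the lickometer firmware: each 3-s window stores the number of
#' beam-break onsets and the total broken duration within the window. A
#' break that outlasts its window spills its remaining duration into the
#' following windows without incrementing their event count, so windows
#' with \code{n_events = 0} but positive duration can occur (leaks).
#'
#' @param stream data.frame (\code{onset}, \code{duration}).
#' @param session_duration session length, s.
#' @param bin window width, s (device constant, 3).
#' @return data.frame \code{bin_start}, \code{n_events},
#'   \code{event_duration} containing only occupied windows.
#' @export
bin_lick_stream <- function(stream, session_duration, bin = 3) {
  n_bins <- ceiling(session_duration / bin)
  ev <- integer(n_bins)
  du <- numeric(n_bins)
  for (i in seq_len(nrow(stream))) {
    o <- stream$onset[i]
    d <- stream$duration[i]
    b0 <- floor(o / bin)
    ev[b0 + 1L] <- ev[b0 + 1L] + 1L
    while (d > 1e-12 && b0 < n_bins) {
      inwin <- min(d, (b0 + 1) * bin - o)
      du[b0 + 1L] <- min(du[b0 + 1L] + inwin, bin)
      d <- d - inwin
      o <- (b0 + 1) * bin
      b0 <- b0 + 1L
    }
  }
  occ <- which(ev > 0L | du > 0)
  data.frame(bin_start = (occ - 1L) * bin, n_events = ev[occ],
             event_duration = du[occ])
}

#' Simulate one animal-session of lickometer and dual-fiber photometry data
#'
#' Generates a bout-structured lick stream (with optional leak/chew
#' artifacts), bins it into the 3-s device format, and synthesises paired
#' 415/470 nm frame series for left and right fibers:
#' \deqn{F_{415}(t) = B(t) + M(t) + \epsilon,\qquad
#'       F_{470}(t) = s\,B(t) + M(t) + \sum_i A_i k(t - t_i) + \epsilon}
#' with \eqn{B} the biexponential bleach curve, \eqn{M} additive motion
#' artifacts identical on both channels of a fiber, \eqn{k} the unit-peak
#' transient kernel and \eqn{A_i} per-drink amplitudes drawn from the
#' sex/fluid/side mean with 10\% CV, truncated at zero. Transient onsets are
#' the first lick of each bout, snapped to the frame grid (TTL timestamps
#' are captured at frame resolution).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{left}, \code{right}
#'   (\code{\link{photometry_recording}} objects), \code{licks}
#'   (\code{\link{lick_session}}), and \code{truth} (ground-truth list:
#'   bleach parameters, channel scale, per-side drink onsets and amplitudes,
#'   motion onset times, injected leak/chew drink indices, intended intake).
#' @export
simulate_session <- function(config) {
  cf <- config
  stopifnot(inherits(cf, "sim_config"))
  dt <- 1 / cf$frame_rate
  if (8 * cf$kernel$decay_tau > cf$session_duration)
    stopf("transient kernel support (%.1f s) exceeds session length",
          8 * cf$kernel$decay_tau)

  stream <- make_lick_schedule(cf$bout_model, cf$session_duration,
                               derive_seed(cf$seed, "schedule"))
  inj <- inject_artifacts(stream, cf$artifacts, derive_seed(cf$seed, "artifacts"))
  records <- bin_lick_stream(inj$stream, cf$session_duration)

  week <- (cf$session_index - 1L) %/% 5L + 1L
  licks <- lick_session(
    animal_id = cf$animal_id, sex = cf$sex, fluid = cf$fluid,
    session_index = cf$session_index, week = week,
    duration = cf$session_duration, records = records,
    bottle_pre = cf$bottle_pre, bottle_post = cf$bottle_pre - cf$intake_g,
    body_weight = cf$body_weight, homecage_pre = cf$homecage_pre,
    homecage_post = cf$homecage_pre - cf$intersession_g)

  ## bout -> drink bookkeeping (post-binning) and TTL-grade onsets
  n_bouts <- length(unique(stream$bout))
  onsets <- numeric(0)
  if (n_bouts > 0) {
    first_lick <- tapply(stream$onset, stream$bout, min)
    onsets <- round(as.numeric(first_lick) / dt) * dt
  }
  drinks <- bin_to_drinks(licks)
  bout_drink <- integer(n_bouts)
  if (n_bouts > 0 && nrow(drinks) > 0) {
    for (b in seq_len(n_bouts)) {
      fl <- as.numeric(first_lick[b])
      hit <- which(drinks$start <= fl & drinks$end > fl)
      bout_drink[b] <- if (length(hit)) hit[1L] else NA_integer_
    }
  }

  n_frames <- round(cf$frame_rate * cf$session_duration)
  t <- (seq_len(n_frames) - 1L) * dt
  p <- cf$bleach
  bleach <- p["A1"] * exp(-t / p["tau1"]) + p["A2"] * exp(-t / p["tau2"]) + p["C"]
  names(bleach) <- NULL

  amp_mean <- function(side) {
    m <- cf$amplitude_map
    row <- m[m$sex == cf$sex & m$fluid == cf$fluid & m$side == side, , drop = FALSE]
    if (nrow(row) != 1L) stopf("amplitude_map has no unique entry for %s/%s/%s",
                               cf$sex, cf$fluid, side)
    row$amplitude
  }

  make_side <- function(side) {
    sd_seed <- derive_seed(cf$seed, "photometry", side)
    with_seed(sd_seed, {
      n_mot <- stats::rpois(1, cf$motion$rate / 60 * cf$session_duration)
      mot_t <- sort(stats::runif(n_mot, 0, cf$session_duration - cf$motion$duration))
      motion <- numeric(n_frames)
      for (m0 in mot_t) {
        i0 <- ceiling(m0 / dt)
        i1 <- min(ceiling((m0 + cf$motion$duration) / dt) - 1L, n_frames - 1L)
        if (i1 >= i0) {
          idx <- (i0:i1) + 1L
          motion[idx] <- motion[idx] + cf$motion$amplitude *
            0.5 * (1 - cos(2 * pi * (t[idx] - m0) / cf$motion$duration))
        }
      }
      amps <- numeric(length(onsets))
      if (length(onsets)) {
        amps <- pmax(stats::rnorm(length(onsets), amp_mean(side),
                                  cf$amplitude_cv * amp_mean(side)), 0)
      }
      transients <- numeric(n_frames)
      for (i in seq_along(onsets)) {
        i0 <- round(onsets[i] / dt)
        span <- min(round(8 * cf$kernel$decay_tau / dt), n_frames - 1L - i0)
        if (span < 1) next
        idx <- i0 + seq_len(span)
        tt <- (idx - i0) * dt
        k <- exp(-tt / cf$kernel$decay_tau) - exp(-tt / cf$kernel$rise_tau)
        transients[idx + 1L] <- transients[idx + 1L] + amps[i] * k / kernel_norm(cf)
      }
      e415 <- stats::rnorm(n_frames, 0, cf$noise_sigma)
      e470 <- stats::rnorm(n_frames, 0, cf$noise_sigma)
      rec <- photometry_recording(
        time = t,
        F415 = bleach + motion + e415,
        F470 = cf$channel_scale * bleach + motion + transients + e470,
        fiber_side = side, frame_rate = cf$frame_rate,
        meta = list(animal_id = cf$animal_id, session_index = cf$session_index,
                    sex = cf$sex, fluid = cf$fluid, week = week))
      list(rec = rec, amps = amps, motion_times = mot_t)
    })
  }
  L <- make_side("left")
  R <- make_side("right")

  truth <- list(
    bleach = p, channel_scale = cf$channel_scale, kernel = cf$kernel,
    drink_onsets = onsets, bout_drink = bout_drink,
    amplitude_left = L$amps, amplitude_right = R$amps,
    motion_left = L$motion_times, motion_right = R$motion_times,
    leak_drinks = bout_drink[inj$leak_bouts],
    chew_drinks = bout_drink[inj$chew_bouts],
    intake_g = cf$intake_g, intersession_g = cf$intersession_g)

  list(left = L$rec, right = R$rec, licks = licks, truth = truth)
}

## sampled-max normalisation constant of the config's kernel at its frame step
kernel_norm <- function(cf) {
  dt <- 1 / cf$frame_rate
  tt <- seq(dt, 8 * cf$kernel$decay_tau, by = dt)
  max(exp(-tt / cf$kernel$decay_tau) - exp(-tt / cf$kernel$rise_tau))
}
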