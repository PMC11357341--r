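#' Configure a simulated drinking cohort
#'
#' Lays out the weekly limited-access schedule for a cohort: five sessions
#' per drinking week (four 2-h sessions Monday-Thursday and one 4-h session
#' Friday), water in weeks 1-3 and 20\% alcohol in weeks 4-6, with 9 males
#' and 5 females by default. Per-session intended intakes carry a
#' configurable coupling between the inter-session home-cage water intake
#' and the session intake (negative by default: animals that drank more
#' water between sessions drink less during the session), and the number of
#' drinking bouts scales with the intended intake so lick microstructure
#' and intake cohere.
#'
#' @param n_male,n_female animals per sex.
#' @param n_weeks drinking weeks (default 6; weeks 1-3 water, from week 4
#'   alcohol).
#' @param master_seed integer; every session seed derives from it.
#' @param intake_coupling named vector (male, female): correlation between
#'   the standardised inter-session water intake and the session intake
#'   deviation.
#' @param base_bouts mean bouts per 2-h session at the base intake.
#' @param session_args named list of overrides passed to every
#'   \code{\link{sim_config}} (e.g. \code{frame_rate}, \code{noise_sigma},
#'   \code{session_duration} to scale sessions down).
#' @return object of class \code{cohort_config}: \code{animals} data.frame
#'   and list of per-session \code{sim_config}s.
#' @export
cohort_config <- function(n_male = 9, n_female = 5, n_weeks = 6,
                          master_seed = 1L,
                          intake_coupling = c(male = -0.25, female = -0.25),
                          base_bouts = 25, session_args = list()) {
  ids <- c(sprintf("M%02d", seq_len(n_male)), sprintf("F%02d", seq_len(n_female)))
  sexes <- rep(c("male", "female"), c(n_male, n_female))
  bw <- with_seed(derive_seed(master_seed, "animals"), {
    pmax(stats::rnorm(length(ids),
                      ifelse(sexes == "male", 27, 21),
                      ifelse(sexes == "male", 1.5, 1.2)), 15)
  })
  animals <- data.frame(animal_id = ids, sex = sexes, body_weight = bw,
                        stringsAsFactors = FALSE)
  n_sessions <- 5L * n_weeks
  configs <- list()
  for (a in seq_along(ids)) {
    rho <- unname(intake_coupling[sexes[a]])
    zs <- with_seed(derive_seed(master_seed, "intake", ids[a]), {
      list(z = stats::rnorm(n_sessions), eta = stats::rnorm(n_sessions))
    })
    for (k in seq_len(n_sessions)) {
      week <- (k - 1L) %/% 5L + 1L
      fluid <- if (week <= 3L) "water" else "alcohol"
      dur <- if (k %% 5L == 0L) 14400 else 7200
      base <- (if (fluid == "water") 1.2 else 0.35) * dur / 7200
      mult <- max(0.2, 1 + 0.2 * (rho * zs$z[k] +
                                    sqrt(1 - rho^2) * zs$eta[k]))
      args <- utils::modifyList(list(
        session_duration = dur,
        sex = sexes[a], fluid = fluid, animal_id = ids[a], session_index = k,
        body_weight = bw[a],
        intake_g = base * mult,
        intersession_g = max(0.5, 3 * (1 + 0.25 * zs$z[k])),
        bout_model = list(n_bouts = max(3L, round(base_bouts * dur / 7200 * mult))),
        seed = derive_seed(master_seed, "session", ids[a], k)),
        session_args)
      if (!is.null(session_args$session_duration)) {
        sd2 <- session_args$session_duration
        args$session_duration <- if (k %% 5L == 0L) 2 * sd2 else sd2
        args$bout_model$n_bouts <-
          max(3L, round(base_bouts * args$session_duration / 7200 * mult))
        args$intake_g <- base * mult * args$session_duration / dur
      }
      configs[[length(configs) + 1L]] <- do.call(sim_config, args)
    }
  }
  structure(list(animals = animals, configs = configs,
                 master_seed = as.integer(master_seed), n_weeks = n_weeks),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("<cohort_config> %d animals (%d M / %d F), %d weeks, %d sessions, seed %d\n",
              nrow(x$animals), sum(x$animals$sex == "male"),
              sum(x$animals$sex == "female"), x$n_weeks,
              length(x$configs), x$master_seed))
  invisible(x)
}

#' Run the full analysis pipeline end to end
#'
#' For every session, processes the lickometer log (drink binning, artifact
#' cleaning, microstructure, intakes) and both fibers' photometry (trim,
#' bleach fit, RANSAC scaling, low-pass, dF/F, z-score, QC), aligns the
#' z-scored traces to drink starts, computes per-drink transient metrics,
#' and assembles the cohort-level products: group mean +/- SEM traces,
#' weekly intake aggregates, quartile assignments of drink length and
#' drinks per session, and the inter-session water intake correlation.
#'
#' Sessions come either from a \code{\link{cohort_config}} (simulation
#' mode, fully seeded and byte-reproducible) or from an input directory of
#' session bundles as written by \code{\link{write_session_bundle}}.
#'
#' @param cohort a \code{\link{cohort_config}}, or NULL when reading from
#'   disk.
#' @param input_dir directory of session bundle subdirectories (ignored
#'   when \code{cohort} is given).
#' @param out_dir output directory for the report bundle; NULL returns the
#'   tables without writing.
#' @param dff_mode,control,qc passed to \code{\link{process_recording}}.
#' @param clean apply lick artifact cleaning (default TRUE).
#' @param threshold residual threshold for cleaning.
#' @param window,n_bins peri-event window and grid.
#' @param trim_n frames trimmed from each recording.
#' @param verbose print per-session progress.
#' @return (invisibly) list with \code{microstructure},
#'   \code{metrics}, \code{group_traces}, \code{weekly_intake},
#'   \code{quartiles}, \code{correlations}, \code{qc},
#'   \code{perievent} (pooled matrix).
#' @export
run_pipeline <- function(cohort = NULL, input_dir = NULL, out_dir = NULL,
                         dff_mode = "ratio", control = "scaled_isosbestic",
                         qc = list(), clean = TRUE, threshold = 3,
                         window = c(-5, 5), n_bins = 150, trim_n = 300,
                         verbose = FALSE) {
  sessions <- if (!is.null(cohort)) {
    stopifnot(inherits(cohort, "cohort_config"))
    lapply(cohort$configs, function(cf) list(config = cf))
  } else {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stopf("either a cohort_config or an existing input_dir is required")
    dirs <- list.dirs(input_dir, recursive = FALSE)
    if (!length(dirs)) stopf("no session directories under %s", input_dir)
    lapply(dirs, function(d) list(dir = d))
  }
  master <- if (!is.null(cohort)) cohort$master_seed else 0L
  micro_rows <- list()
  metric_rows <- list()
  pems <- list()
  qc_report <- list()

  for (i in seq_along(sessions)) {
    ses <- sessions[[i]]
    if (!is.null(ses$config)) {
      sim <- simulate_session(ses$config)
      licks <- sim$licks
      recs <- list(left = sim$left, right = sim$right)
      onsets <- sim$truth$drink_onsets
    } else {
      licks <- read_lick_log(file.path(ses$dir, "licks.csv"))
      recs <- read_photometry_csv(
        file.path(ses$dir, "photometry.csv"),
        meta = list(animal_id = licks$animal_id, sex = licks$sex,
                    fluid = licks$fluid, week = licks$week,
                    session_index = licks$session_index))
      ev <- utils::read.csv(file.path(ses$dir, "events.csv"))
      onsets <- ev$onset_s
    }
    if (verbose)
      message(sprintf("[%d/%d] %s session %d", i, length(sessions),
                      licks$animal_id, licks$session_index))
    micro_rows[[i]] <- microstructure(licks, clean = clean,
                                      threshold = threshold)
    drinks <- bin_to_drinks(licks)
    kept_ids <- drinks$drink
    if (clean && nrow(drinks) >= 3L)
      kept_ids <- clean_events(drinks, threshold)$kept$drink
    ## map TTL drink-start timestamps onto kept (cleaned) drinks
    ev_meta <- NULL
    if (length(onsets) && nrow(drinks)) {
      di <- vapply(onsets, function(o) {
        hit <- which(drinks$start <= o & drinks$end > o)
        if (length(hit)) hit[1L] else NA_integer_
      }, integer(1))
      keep <- !is.na(di) & di %in% kept_ids
      if (any(keep))
        ev_meta <- data.frame(
          animal_id = licks$animal_id, sex = licks$sex, fluid = licks$fluid,
          week = licks$week, session = licks$session_index,
          drink = di[keep], onset = onsets[keep],
          length = drinks$length[di[keep]])
    }
    for (side in names(recs)) {
      tr <- process_recording(
        recs[[side]],
        seed = derive_seed(master, "ransac", licks$animal_id,
                           licks$session_index, side),
        trim_n = trim_n, dff_mode = dff_mode, control = control, qc = qc)
      qc_report[[length(qc_report) + 1L]] <- list(
        animal_id = licks$animal_id, session = licks$session_index,
        side = side, passed = tr$qc$passed, reason = tr$qc$reason,
        r_squared = tr$bleach_fit$r_squared,
        inlier_fraction = mean(tr$scale$inlier_mask),
        slope = tr$scale$slope, intercept = tr$scale$intercept)
      if (!tr$qc$passed || is.null(ev_meta)) next
      ev_side <- ev_meta
      ev_side$side <- side
      ev_side$start <- ev_side$onset - tr$trim_offset
      pem <- align_to_drinks(tr, ev_side, window = window, n_bins = n_bins)
      if (nrow(pem$values)) {
        pems[[length(pems) + 1L]] <- pem
        metric_rows[[length(metric_rows) + 1L]] <- transient_metrics(pem)
      }
    }
  }

  micro <- do.call(rbind, micro_rows)
  metrics <- if (length(metric_rows)) do.call(rbind, metric_rows) else NULL
  pooled <- if (length(pems)) pool_perievents(pems) else NULL
  traces <- if (!is.null(pooled)) group_mean_trace(pooled) else NULL
  weekly <- weekly_aggregate(micro, "intake_gkg")
  quart_len <- if (!is.null(metrics) && nrow(metrics) >= 4L)
    quartile_bin(metrics$length) else NULL
  quart_nd <- if (sum(is.finite(micro$n_drinks)) >= 4L)
    quartile_bin(micro$n_drinks) else NULL
  correlations <- tryCatch(
    correlate_intersession(micro, seed = derive_seed(master, "shepherd")),
    error = function(e) {
      warnf("inter-session correlation skipped: %s", conditionMessage(e))
      NULL
    })

  out <- list(microstructure = micro, metrics = metrics,
              group_traces = traces, weekly_intake = weekly,
              quartile_drink_length = quart_len,
              quartile_n_drinks = quart_nd,
              correlations = correlations, qc = qc_report,
              perievent = pooled)
  if (!is.null(out_dir)) write_report_bundle(out, out_dir, master)
  invisible(out)
}

## write the tidy report bundle; deterministic byte-for-byte given the same
## tables (no timestamps, fixed number formatting)
write_report_bundle <- function(out, out_dir, master_seed) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, name) {
    if (!is.null(d)) utils::write.csv(d, file.path(out_dir, name),
                                      row.names = FALSE)
  }
  wcsv(out$microstructure, "microstructure.csv")
  if (!is.null(out$metrics)) {
    m <- out$metrics
    m$onset <- NULL
    wcsv(m, "perievent_metrics.csv")
  }
  wcsv(out$group_traces, "group_traces.csv")
  wcsv(out$weekly_intake$animal, "weekly_intake_animal.csv")
  wcsv(out$weekly_intake$group, "weekly_intake_group.csv")
  if (!is.null(out$quartile_drink_length)) {
    q <- out$quartile_drink_length
    wcsv(data.frame(variable = "drink_length",
                    value = out$metrics$length,
                    quartile = as.character(q$labels)), "quartiles_drink_length.csv")
  }
  if (!is.null(out$quartile_n_drinks)) {
    q <- out$quartile_n_drinks
    wcsv(data.frame(variable = "n_drinks",
                    value = out$microstructure$n_drinks,
                    quartile = as.character(q$labels)), "quartiles_n_drinks.csv")
  }
  wcsv(out$correlations, "correlations.csv")
  if (!is.null(out$perievent)) {
    pe <- cbind(out$perievent$events,
                as.data.frame(out$perievent$values))
    names(pe)[(ncol(out$perievent$events) + 1L):ncol(pe)] <-
      sprintf("t%03d", seq_along(out$perievent$t_rel))
    pe$onset <- NULL
    wcsv(pe, "perievent_matrix.csv")
  }
  jsonlite::write_json(out$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  n_rec <- length(out$qc)
  writeLines(c(
    sprintf("photolick %s", as.character(utils::packageVersion("photolick"))),
    sprintf("master_seed: %d", master_seed),
    sprintf("sessions: %d", nrow(out$microstructure)),
    sprintf("recordings: %d (passed QC: %d)", n_rec,
            sum(vapply(out$qc, `[[`, logical(1), "passed"))),
    sprintf("perievent rows: %d",
            if (is.null(out$perievent)) 0L else nrow(out$perievent$values))),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
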