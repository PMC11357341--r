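#' Write a dual-fiber photometry frame table as CSV
#'
#' Long format with columns \code{frame_index}, \code{time_s},
#' \code{region} (fiber side), \code{channel_nm} (415 or 470),
#' \code{fluorescence}.
#'
#' @param recordings list of \code{\link{photometry_recording}} objects.
#' @param path output path.
#' @export
write_photometry_csv <- function(recordings, path) {
  parts <- lapply(recordings, function(r) {
    n <- length(r$time)
    data.frame(frame_index = rep(seq_len(n) - 1L, 2L),
               time_s = rep(r$time, 2L),
               region = r$fiber_side,
               channel_nm = rep(c(415L, 470L), each = n),
               fluorescence = c(r$F415, r$F470))
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE)
  invisible(path)
}

#' Read a dual-fiber photometry frame CSV
#'
#' Inverse of \code{\link{write_photometry_csv}}.
#'
#' @param path file path.
#' @param meta optional metadata list attached to each recording.
#' @return named list of \code{\link{photometry_recording}} objects, one
#'   per region.
#' @export
read_photometry_csv <- function(path, meta = list()) {
  d <- utils::read.csv(path)
  need <- c("frame_index", "time_s", "region", "channel_nm", "fluorescence")
  if (!all(need %in% names(d)))
    stopf("%s: missing columns %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  out <- lapply(split(d, d$region), function(dr) {
    ch <- split(dr, dr$channel_nm)
    if (!all(c("415", "470") %in% names(ch)))
      stopf("%s: region %s lacks a 415/470 channel pair", path, dr$region[1L])
    a <- ch[["415"]][order(ch[["415"]]$frame_index), ]
    b <- ch[["470"]][order(ch[["470"]]$frame_index), ]
    fr <- 1 / stats::median(diff(a$time_s))
    photometry_recording(time = a$time_s, F415 = a$fluorescence,
                         F470 = b$fluorescence, fiber_side = dr$region[1L],
                         frame_rate = fr, meta = meta)
  })
  out
}

#' Write simulation ground truth as JSON
#' @param truth ground-truth list from \code{\link{simulate_session}}.
#' @param path output path.
#' @export
write_ground_truth <- function(truth, path) {
  # named atomic vectors become JSON objects, not bare arrays
  enc <- lapply(truth, function(x) {
    if (is.atomic(x) && !is.null(names(x))) as.list(x) else x
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read simulation ground truth JSON
#' @param path file path.
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a simulation configuration as YAML
#' @param config a \code{\link{sim_config}}.
#' @param path output path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$bleach <- as.list(x$bleach)
  x$amplitude_map <- as.list(x$amplitude_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration YAML
#' @param path file path.
#' @return a \code{\link{sim_config}}.
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$bleach <- unlist(x$bleach)
  x$amplitude_map <- as.data.frame(x$amplitude_map,
                                   stringsAsFactors = FALSE)
  do.call(sim_config, x)
}

#' Write one simulated session as an on-disk bundle
#'
#' Creates \code{<dir>/licks.csv}, \code{photometry.csv},
#' \code{events.csv} (TTL drink-start timestamps, column \code{onset_s})
#' and \code{truth.json}, the layout \code{\link{run_pipeline}} reads in
#' input-directory mode.
#'
#' @param sim result of \code{\link{simulate_session}}.
#' @param dir output directory (created if needed).
#' @export
write_session_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lick_log(sim$licks, file.path(dir, "licks.csv"))
  write_photometry_csv(list(sim$left, sim$right),
                       file.path(dir, "photometry.csv"))
  utils::write.csv(data.frame(onset_s = sim$truth$drink_onsets),
                   file.path(dir, "events.csv"), row.names = FALSE)
  write_ground_truth(sim$truth, file.path(dir, "truth.json"))
  invisible(dir)
}
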