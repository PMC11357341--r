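# Shared fixtures and independent oracles. Everything is generated in code;
# oracles deliberately use naive loops, not the package's vectorised paths.

# small quiet session: short, no artifacts unless asked
quick_config <- function(seed, duration = 1200, n_bouts = 8,
                         n_leak = 0, n_chew = 0, ...) {
  sim_config(session_duration = duration,
             bout_model = list(n_bouts = n_bouts),
             artifacts = list(n_leak = n_leak, n_chew = n_chew),
             seed = seed, ...)
}

# brute-force drink merge: walk occupied windows one by one
oracle_merge <- function(records) {
  occ <- records[records$n_events > 0 | records$event_duration > 0, ,
                 drop = FALSE]
  if (!nrow(occ)) return(NULL)
  drinks <- list()
  cur <- NULL
  for (i in seq_len(nrow(occ))) {
    b <- occ[i, ]
    if (!is.null(cur) && b$bin_start == cur$end) {
      cur$end <- b$bin_start + 3
      cur$n_events <- cur$n_events + b$n_events
      cur$event_duration <- cur$event_duration + b$event_duration
    } else {
      if (!is.null(cur)) drinks[[length(drinks) + 1L]] <- cur
      cur <- data.frame(start = b$bin_start, end = b$bin_start + 3,
                        n_events = b$n_events,
                        event_duration = b$event_duration)
    }
  }
  drinks[[length(drinks) + 1L]] <- cur
  do.call(rbind, drinks)
}

# random record table on the 3-s grid
random_records <- function(n_bins = 40, p_occ = 0.3) {
  occ <- which(runif(n_bins) < p_occ)
  if (!length(occ)) occ <- sample(n_bins, 1)
  data.frame(bin_start = (occ - 1L) * 3,
             n_events = rpois(length(occ), 4) + 1L,
             event_duration = round(runif(length(occ), 0.05, 2.9), 3))
}

random_session <- function(n_bins = 40, p_occ = 0.3, duration = n_bins * 3) {
  lick_session(animal_id = "rnd", sex = "male", fluid = "water",
               session_index = 1, week = 1, duration = duration,
               records = random_records(n_bins, p_occ),
               bottle_pre = 100, bottle_post = 99, body_weight = 25)
}

# a scaled-down cohort in which every sex x fluid x side cell is populated:
# one short water and one short alcohol session per animal
effect_cohort_peaks <- function(master, n_male = 9, n_female = 5,
                                duration = 900, n_bouts = 12) {
  ids <- c(sprintf("M%d", seq_len(n_male)), sprintf("F%d", seq_len(n_female)))
  sexes <- rep(c("male", "female"), c(n_male, n_female))
  pems <- list()
  for (a in seq_along(ids)) for (fl in c("water", "alcohol")) {
    cf <- sim_config(session_duration = duration, sex = sexes[a], fluid = fl,
                     animal_id = ids[a],
                     bout_model = list(n_bouts = n_bouts),
                     artifacts = list(n_leak = 0, n_chew = 0),
                     seed = derive_seed(master, ids[a], fl))
    sim <- simulate_session(cf)
    dr <- bin_to_drinks(sim$licks)
    on <- sim$truth$drink_onsets
    di <- vapply(on, function(o) which(dr$start <= o & dr$end > o)[1L],
                 integer(1))
    for (side in c("left", "right")) {
      tr <- process_recording(sim[[side]],
                              seed = derive_seed(master, ids[a], fl, side))
      if (!tr$qc$passed) next
      ev <- data.frame(sex = sexes[a], fluid = fl, side = side,
                       start = on - tr$trim_offset, length = dr$length[di])
      pems[[length(pems) + 1L]] <- align_to_drinks(tr, ev)
    }
  }
  g <- group_mean_trace(pool_perievents(pems))
  vapply(split(g, interaction(g$sex, g$fluid, g$side)),
         function(d) max(d$mean[d$t_rel >= 0 & d$t_rel <= 5]), numeric(1))
}
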