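#' Weekly aggregation with the animal as the experimental unit
#'
#' Averages a per-session measure to one value per animal and week first,
#' then summarises across animals within each sex x week cell
#' (mean +/- SEM), so unequal session counts never weight animals unevenly.
#'
#' @param table tidy per-session data.frame with columns \code{animal_id},
#'   \code{sex}, \code{week}, and the measure.
#' @param measure name of the measure column.
#' @return list with \code{animal} (per animal-week means) and \code{group}
#'   (per sex-week mean, SEM, n animals).
#' @export
weekly_aggregate <- function(table, measure) {
  if (!measure %in% names(table)) stopf("no column '%s' in table", measure)
  tab <- table[is.finite(table[[measure]]), , drop = FALSE]
  if (!nrow(tab)) stopf("no finite values of '%s'", measure)
  an <- stats::aggregate(tab[[measure]],
                         by = list(animal_id = tab$animal_id, sex = tab$sex,
                                   week = tab$week),
                         FUN = mean)
  names(an)[4L] <- "mean"
  grp <- do.call(rbind, lapply(split(an, list(an$sex, an$week), drop = TRUE),
    function(d) data.frame(sex = d$sex[1L], week = d$week[1L],
                           mean = mean(d$mean),
                           sem = if (nrow(d) >= 2L)
                             stats::sd(d$mean) / sqrt(nrow(d)) else NA_real_,
                           n = nrow(d))))
  grp <- grp[order(grp$week, grp$sex), , drop = FALSE]
  rownames(grp) <- NULL
  list(animal = an, group = grp)
}

#' Quartile binning of a pooled measure
#'
#' Breakpoints are the 25th/50th/75th percentiles (linear interpolation
#' between order statistics) computed over all supplied values - e.g. every
#' drink length across all water and alcohol sessions pooled. A value lying
#' exactly on a breakpoint goes to the lower quartile.
#'
#' @param values numeric vector, at least 4 finite values.
#' @return list of class \code{quartile_assignment}: \code{breakpoints}
#'   (3 values), \code{labels} (factor Q1..Q4 per value).
#' @export
quartile_bin <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 4L) stopf("need at least 4 values for quartile binning")
  bp <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  if (bp[1L] == bp[3L]) {
    warnf("degenerate quartiles: all breakpoints equal; labelling all Q1")
    labels <- factor(rep("Q1", length(values)), levels = paste0("Q", 1:4))
  } else {
    idx <- 1L + (values > bp[1L]) + (values > bp[2L]) + (values > bp[3L])
    labels <- factor(paste0("Q", idx), levels = paste0("Q", 1:4))
  }
  structure(list(breakpoints = bp, labels = labels),
            class = "quartile_assignment")
}

#' @export
print.quartile_assignment <- function(x, ...) {
  cat(sprintf("<quartile_assignment> breakpoints %.4g / %.4g / %.4g; counts %s\n",
              x$breakpoints[1L], x$breakpoints[2L], x$breakpoints[3L],
              paste(table(x$labels), collapse = "/")))
  invisible(x)
}

#' Shepherd's pi robust correlation
#'
#' Spearman correlation after removing bivariate outliers. Outliers are
#' identified by the bootstrapped squared Mahalanobis distance: for each of
#' \code{n_boot} bootstrap resamples, every original point's squared
#' Mahalanobis distance from the resample's centroid and covariance is
#' computed, and the distances are averaged over resamples. Points with an
#' average squared distance of \code{threshold} (6) or more are removed, the
#' Spearman correlation is computed on the remainder, and the p-value is
#' doubled (capped at 1) to pay for the outlier removal. Deterministic
#' given \code{seed}.
#'
#' @param x,y paired numeric vectors, n >= 10 after NA removal.
#' @param n_boot bootstrap resamples (default 200).
#' @param seed integer seed.
#' @param threshold squared-distance cutoff (default 6).
#' @return object of class \code{shepherds_pi}: \code{pi} (the correlation),
#'   \code{p.value}, \code{outlier_mask} (TRUE = removed), \code{distance}
#'   (mean squared Mahalanobis distances), \code{n_retained}.
#' @export
shepherds_pi <- function(x, y, n_boot = 200, seed = 1L, threshold = 6) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10L) stopf("need at least 10 paired values (got %d)", n)
  X <- cbind(x, y)
  d <- bsmahal(X, n_boot, seed)
  mask <- d >= threshold
  if (n - sum(mask) < 10L)
    stopf("fewer than 10 pairs retained after outlier removal")
  ct <- stats::cor.test(x[!mask], y[!mask], method = "spearman",
                        exact = FALSE)
  structure(list(pi = unname(ct$estimate), p.value = min(1, 2 * ct$p.value),
                 outlier_mask = mask, distance = d,
                 n_retained = n - sum(mask), n_boot = n_boot,
                 threshold = threshold),
            class = "shepherds_pi")
}

## mean squared Mahalanobis distance of each row of X over bootstrap
## resamples of the centroid/covariance
bsmahal <- function(X, n_boot, seed) {
  n <- nrow(X)
  with_seed(seed, {
    acc <- numeric(n)
    used <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- colMeans(X[idx, , drop = FALSE])
      S <- stats::cov(X[idx, , drop = FALSE])
      d <- tryCatch(stats::mahalanobis(X, m, S), error = function(e) NULL)
      if (is.null(d)) {
        S <- S + diag(1e-8 * (sum(diag(S)) + 1), 2L)
        d <- stats::mahalanobis(X, m, S)
      }
      acc <- acc + d
      used <- used + 1L
    }
    acc / used
  })
}

#' @export
print.shepherds_pi <- function(x, ...) {
  cat(sprintf("<shepherds_pi> pi = %.4f, p = %.4g (n = %d retained, %d removed)\n",
              x$pi, x$p.value, x$n_retained, sum(x$outlier_mask)))
  invisible(x)
}

#' Correlate inter-session water intake with session intake
#'
#' Pairs each water session's drinking-in-the-dark intake with the
#' inter-session home-cage water intake measured over the interval ending at
#' that session, per animal, then applies Shepherd's pi overall and within
#' each sex.
#'
#' @param table tidy per-session table with \code{animal_id}, \code{sex},
#'   \code{fluid}, \code{intake_gkg}, \code{intersession_gkg}.
#' @param n_boot,seed,threshold passed to \code{\link{shepherds_pi}}.
#' @return data.frame with one row per stratum (\code{overall},
#'   \code{male}, \code{female}): \code{pi}, \code{p}, \code{n},
#'   \code{n_outliers}. Strata with fewer than 10 pairs are skipped; an
#'   error is raised if even the overall stratum is too small.
#' @export
correlate_intersession <- function(table, n_boot = 200, seed = 1L,
                                   threshold = 6) {
  w <- table[table$fluid == "water" &
               is.finite(table$intake_gkg) &
               is.finite(table$intersession_gkg), , drop = FALSE]
  if (nrow(w) < 10L)
    stopf("insufficient consecutive-session pairs (%d < 10)", nrow(w))
  strata <- list(overall = w,
                 male = w[w$sex == "male", , drop = FALSE],
                 female = w[w$sex == "female", , drop = FALSE])
  rows <- lapply(names(strata), function(nm) {
    d <- strata[[nm]]
    if (nrow(d) < 10L) return(NULL)
    sp <- shepherds_pi(d$intersession_gkg, d$intake_gkg, n_boot = n_boot,
                       seed = derive_seed(seed, "intersession", nm),
                       threshold = threshold)
    data.frame(stratum = nm, pi = sp$pi, p = sp$p.value, n = sp$n_retained,
               n_outliers = sum(sp$outlier_mask))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
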