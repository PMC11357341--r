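#' Evaluate an expression under a temporary RNG seed
#'
#' Runs \code{expr} with the global RNG seeded to \code{seed}, restoring the
#' caller's RNG state afterwards so library code never perturbs user
#' randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a child seed from a master seed and labels
#'
#' All stochastic stages (simulation, RANSAC, bootstrap) draw their seeds from
#' one master seed through this deterministic integer mix, so a single seed
#' reproduces a whole run while stages stay decorrelated.
#'
#' @param master integer master seed.
#' @param ... character or integer labels identifying the consumer
#'   (e.g. animal id, session index, stage name).
#' @return a single integer in \code{[1, 2^31 - 2]}.
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(c(master, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483629
  as.integer(h + 1L)
}

#' Trapezoidal integral on an irregular grid
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
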