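# Internal numerical helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so generators behave as pure functions of their
#' configuration.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Central finite differences with one-sided ends; x need not be uniform.
central_diff <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3L, length(y) == n)
  d <- numeric(n)
  d[1] <- (y[2] - y[1]) / (x[2] - x[1])
  d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  d[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  d
}

# Assert two profiles share a grid (within tolerance).
check_shared_grid <- function(x1, x2, what = "profiles") {
  if (length(x1) != length(x2) || max(abs(x1 - x2)) > 1e-8) {
    stop(sprintf("%s must share a common position grid; resample first", what),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Linear resampling of a profile onto a new grid.
resample_profile <- function(x, y, grid) {
  stats::approx(x, y, xout = grid, rule = 2)$y
}

path_extdata <- function(file) {
  p <- system.file("extdata", file, package = "rootkin", mustWork = FALSE)
  if (!nzchar(p)) stop("packaged data file not found: ", file, call. = FALSE)
  p
}
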