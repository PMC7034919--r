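# Angular and RNG helpers shared across modules.
#
# Conventions (used everywhere): positions in metres, x east / y north;
# headings in degrees counter-clockwise from +x, kept in [0, 360);
# azimuth column 0 of a view is the heading direction and columns
# increase clockwise in the visual field (i.e. decreasing world azimuth).

#' Wrap angles into [0, 360)
#' @param x angles in degrees.
#' @return angles wrapped into [0, 360).
#' @keywords internal
wrap360 <- function(x) x %% 360

#' Signed angular difference a - b wrapped into (-180, 180]
#' @param a,b angles in degrees.
#' @keywords internal
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  ifelse(d > 180, d - 360, d)
}

#' Absolute angular distance between two angles, in [0, 180]
#' @param a,b angles in degrees.
#' @keywords internal
ang_dist <- function(a, b) abs(ang_diff(a, b))

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Bearing (degrees CCW from +x) from point `from` to point `to`
#' @keywords internal
bearing_to <- function(from, to) {
  wrap360(rad2deg(atan2(to[2] - from[2], to[1] - from[1])))
}

#' Evaluate code with a temporary RNG seed, restoring global RNG state
#'
#' All stochastic operations in the package take an explicit integer seed
#' and run under this helper, so that package calls never disturb the
#' caller's random number stream and identical seeds give identical output.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation; keeps results < 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 16807) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)
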