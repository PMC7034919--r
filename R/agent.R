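# The closed-loop oscillatory walker.
#
# At each time step the agent (1) renders the view at its current
# position and heading and converts it into the overall drive (opponent
# or attractive-only), (2) turns on the spot by an amplitude of
# baseline - gain * drive (clipped to [0, 180] degrees), in the
# direction given by a left/right oscillator that flips every step
# regardless of the drive, plus angular noise, and (3) walks one step
# forward. Familiar views therefore inhibit turning; unfamiliar or
# repulsive-matching views amplify it.

#' Heading-noise models
#'
#' `heading_noise_gaussian` draws Gaussian noise (the default model,
#' mu = 0, sd = 10 degrees, emulating real-world motor noise);
#' `heading_noise_uniform` draws uniform noise in +/- `halfwidth`
#' degrees (used with infinite gain, where turns are pinned to 0 or 180
#' degrees and noise is the only source of new directions);
#' `heading_noise_none` disables noise.
#'
#' @param sd standard deviation in degrees, >= 0.
#' @param halfwidth half-width in degrees, >= 0.
#' @return a noise-model list consumed by [agent_params()].
#' @export
heading_noise_gaussian <- function(sd = 10) {
  stopifnot(sd >= 0)
  list(kind = "gaussian", sd = sd)
}

#' @rdname heading_noise_gaussian
#' @export
heading_noise_uniform <- function(halfwidth = 20) {
  stopifnot(halfwidth >= 0)
  list(kind = "uniform", halfwidth = halfwidth)
}

#' @rdname heading_noise_gaussian
#' @export
heading_noise_none <- function() list(kind = "none")

draw_noise <- function(noise) {
  switch(noise$kind,
         gaussian = stats::rnorm(1, 0, noise$sd),
         uniform = stats::runif(1, -noise$halfwidth, noise$halfwidth),
         none = 0,
         stop_invalid("unknown heading-noise kind: ", noise$kind))
}

#' Agent parameters
#'
#' @param baseline turn amplitude in degrees at zero drive, in [0, 180].
#'   Default 90.
#' @param gain conversion from drive (familiarity units) to degrees of
#'   turn modulation, >= 0; `Inf` is a legal value and pins turns to 0
#'   degrees (positive drive) or 180 degrees (negative drive). Default
#'   3000 (mid-range, on a log scale, of the operational gain region on
#'   the default open world).
#' @param step_length forward step in metres, > 0. Default 0.2 (one ant
#'   step).
#' @param heading_noise a noise model from [heading_noise_gaussian()],
#'   [heading_noise_uniform()] or [heading_noise_none()].
#' @param max_steps number of steps per run, >= 0. Default 320 (a 64 m
#'   path budget).
#' @param memory_mode `"opponent"` (both banks, drive = attractive -
#'   repulsive familiarity) or `"attractive_only"` (drive = attractive
#'   familiarity minus the calibrated world average).
#' @param seed integer seed for the run (initial heading if unset,
#'   initial oscillator sign, noise draws).
#' @return an object of class `agent_params`.
#' @export
agent_params <- function(baseline = 90, gain = 3000, step_length = 0.2,
                         heading_noise = heading_noise_gaussian(10),
                         max_steps = 320L,
                         memory_mode = c("opponent", "attractive_only"),
                         seed = 1L) {
  memory_mode <- match.arg(memory_mode)
  if (baseline < 0 || baseline > 180)
    stop_invalid("baseline must lie in [0, 180] degrees")
  if (gain < 0) stop_invalid("gain must be >= 0 (Inf allowed)")
  if (step_length <= 0) stop_invalid("step_length must be > 0")
  if (max_steps < 0) stop_invalid("max_steps must be >= 0")
  structure(list(baseline = baseline, gain = gain,
                 step_length = step_length, heading_noise = heading_noise,
                 max_steps = as.integer(max_steps),
                 memory_mode = memory_mode, seed = as.integer(seed)),
            class = "agent_params")
}

#' Turn amplitude from the overall drive
#'
#' `baseline - gain * drive`, clipped to [0, 180] degrees. For infinite
#' gain the limit rule applies: 0 degrees for positive drive, 180 for
#' negative drive, and the baseline at drive exactly 0 (continuity with
#' finite gain).
#'
#' @param drive overall drive (any finite real).
#' @param params an [agent_params()] object.
#' @return turn amplitude in degrees, in [0, 180].
#' @examples
#' turn_amplitude(0.3, agent_params(baseline = 90, gain = 100))  # 60
#' @export
turn_amplitude <- function(drive, params) {
  if (is.infinite(params$gain)) {
    return(ifelse(drive > 0, 0, ifelse(drive < 0, 180, params$baseline)))
  }
  pmin(pmax(params$baseline - params$gain * drive, 0), 180)
}

#' Initial agent state
#'
#' @param position numeric length-2, metres.
#' @param theta heading in degrees.
#' @param oscillator_sign +1 or -1; the side of the first turn.
#' @return an object of class `agent_state`.
#' @export
agent_state <- function(position, theta, oscillator_sign = 1L) {
  stopifnot(oscillator_sign %in% c(-1L, 1L))
  structure(list(position = as.numeric(position), theta = wrap360(theta),
                 t = 0L, oscillator_sign = as.integer(oscillator_sign)),
            class = "agent_state")
}

# Drive computation shared by step_agent and run_agent.
compute_drive <- function(view_px, banks, ctx, memory_mode) {
  att <- bank_familiarity(view_px, banks$attractive, ctx)
  if (memory_mode == "opponent") {
    rep_ <- bank_familiarity(view_px, banks$repulsive, ctx)
    opponent_drive(att, rep_)
  } else {
    attractive_only_drive(att, ctx)
  }
}

#' Advance the agent by one step
#'
#' Applies the three per-step rules: sense (render the view, compute the
#' drive), turn (oscillator-signed clipped amplitude plus noise), step
#' forward. Noise is drawn from the current RNG stream; wrap the call in
#' a seeded context (or use [heading_noise_none()]) for determinism.
#'
#' @param state an [agent_state()].
#' @param world a `world_model`.
#' @param banks list with `attractive` (and, in opponent mode,
#'   `repulsive`) memory banks.
#' @param ctx a [familiarity_context()].
#' @param params an [agent_params()].
#' @param vp a [view_params()] object.
#' @return the new `agent_state`, with attribute `record` (the step's
#'   drive readouts) and attribute `out_of_world` set if the step left
#'   the arena (position is then the truncation point).
#' @export
step_agent <- function(state, world, banks, ctx, params, vp = view_params()) {
  view <- render_panorama(world, state$position, state$theta, vp)
  ds <- compute_drive(as.numeric(view$pixels), banks, ctx,
                      params$memory_mode)
  amp <- turn_amplitude(ds$overall_drive, params)
  noise <- draw_noise(params$heading_noise)
  theta_new <- wrap360(state$theta + amp * state$oscillator_sign + noise)
  pos_new <- state$position + params$step_length *
    c(cos(deg2rad(theta_new)), sin(deg2rad(theta_new)))
  out <- any(abs(pos_new) > world$bounds)
  st <- structure(list(position = if (out) state$position else pos_new,
                       theta = theta_new, t = state$t + 1L,
                       oscillator_sign = -state$oscillator_sign),
                  class = "agent_state")
  attr(st, "record") <- list(turn_amplitude = amp, noise = noise,
                             drive = ds)
  if (out) attr(st, "out_of_world") <- TRUE
  st
}

#' Run the agent from a release point
#'
#' Releases the agent and iterates the per-step rules for
#' `params$max_steps` steps (or until it would leave the world, in which
#' case the run is truncated with status `"out_of_world"`). All
#' randomness (initial heading when `initial_heading = NULL`, initial
#' oscillator side, heading noise) is drawn under `params$seed`.
#'
#' @param world a `world_model`.
#' @param banks memory banks from [build_memory_banks()].
#' @param ctx a [familiarity_context()]; must be calibrated for
#'   `memory_mode = "attractive_only"`.
#' @param params an [agent_params()].
#' @param release numeric length-2 release point, inside bounds.
#' @param initial_heading degrees, or `NULL` for a uniform-random draw.
#' @param vp a [view_params()] object.
#' @return an object of class `homing_path`: a list with `steps` (a data
#'   frame with one row per time step: `t`, `x`, `y`, `theta`,
#'   `turn_amplitude`, `oscillator_sign`, `attractive_familiarity`,
#'   `repulsive_familiarity`, `overall_drive`; row t = 0 is the release
#'   state), `release`, `nest`, `status` (`"completed"` or
#'   `"out_of_world"`), `arrival_distance` (final distance to the nest,
#'   metres) and a parameter echo.
#' @examples
#' \donttest{
#' w <- generate_world(1, "open_distant")
#' banks <- build_memory_banks(w, learning_walk_spec(), route_spec())
#' p <- run_agent(w, banks, familiarity_context(),
#'                agent_params(max_steps = 120), release = c(4, 0))
#' p$arrival_distance
#' }
#' @export
run_agent <- function(world, banks, ctx, params, release,
                      initial_heading = NULL, vp = view_params()) {
  check_in_bounds(world, release)
  n <- params$max_steps
  with_seed(params$seed, {
    theta0 <- if (is.null(initial_heading)) stats::runif(1, 0, 360)
              else wrap360(initial_heading)
    sign0 <- if (stats::runif(1) < 0.5) -1L else 1L
    xs <- ys <- th <- amp <- osc <- att <- rp <- drv <- rep(NA_real_, n + 1)
    xs[1] <- release[1]; ys[1] <- release[2]; th[1] <- theta0
    state <- agent_state(release, theta0, sign0)
    status <- "completed"
    k <- 0L
    while (k < n) {
      osc[k + 2] <- state$oscillator_sign
      state <- step_agent(state, world, banks, ctx, params, vp)
      rec <- attr(state, "record")
      k <- k + 1L
      xs[k + 1] <- state$position[1]; ys[k + 1] <- state$position[2]
      th[k + 1] <- state$theta
      amp[k + 1] <- rec$turn_amplitude
      att[k + 1] <- rec$drive$attractive_familiarity
      rp[k + 1] <- rec$drive$repulsive_familiarity
      drv[k + 1] <- rec$drive$overall_drive
      if (isTRUE(attr(state, "out_of_world"))) {
        status <- "out_of_world"
        break
      }
    }
    keep <- seq_len(k + 1)
    steps <- data.frame(t = 0:k, x = xs[keep], y = ys[keep],
                        theta = th[keep], turn_amplitude = amp[keep],
                        oscillator_sign = osc[keep],
                        attractive_familiarity = att[keep],
                        repulsive_familiarity = rp[keep],
                        overall_drive = drv[keep])
    structure(list(steps = steps, release = as.numeric(release),
                   nest = world$nest, status = status,
                   arrival_distance = sqrt(sum((state$position -
                                                  world$nest)^2)),
                   params = params, initial_heading = theta0),
              class = "homing_path")
  })
}

#' @export
print.homing_path <- function(x, ...) {
  cat("<homing_path>", nrow(x$steps) - 1, "steps,", x$status, "\n")
  cat("  release (", paste(signif(x$release, 4), collapse = ", "),
      ") -> arrival", signif(x$arrival_distance, 4), "m from nest\n")
  invisible(x)
}

#' @export
summary.homing_path <- function(object, ...) {
  s <- object$steps
  cat("Oscillatory homing run (", object$params$memory_mode, ")\n", sep = "")
  cat("  steps:", nrow(s) - 1, " status:", object$status, "\n")
  cat("  arrival distance:", signif(object$arrival_distance, 4), "m\n")
  cat("  mean |drive|:", signif(mean(abs(s$overall_drive), na.rm = TRUE), 3),
      " mean turn:", signif(mean(s$turn_amplitude, na.rm = TRUE), 3),
      "deg\n")
  invisible(object)
}

#' @export
plot.homing_path <- function(x, ...) {
  s <- x$steps
  graphics::plot(s$x, s$y, type = "l", asp = 1, xlab = "x (m)",
                 ylab = "y (m)", ...)
  graphics::points(x$nest[1], x$nest[2], pch = 3, cex = 1.5)
  graphics::points(x$release[1], x$release[2], pch = 16, col = "orange")
  graphics::points(s$x[nrow(s)], s$y[nrow(s)], pch = 4)
  invisible(x)
}

#' Write a path as CSV plus a JSON sidecar
#'
#' The CSV holds the per-step records (column order as in the `steps`
#' data frame); the sidecar echoes parameters, seed, status and arrival
#' distance.
#'
#' @param path a `homing_path`.
#' @param file CSV file path; the sidecar is written next to it with a
#'   `.json` extension.
#' @export
path_to_csv <- function(path, file) {
  utils::write.csv(path$steps, file, row.names = FALSE)
  sidecar <- sub("\\.csv$", ".json", file)
  if (identical(sidecar, file)) sidecar <- paste0(file, ".json")
  params <- path$params
  params$heading_noise <- params$heading_noise
  jsonlite::write_json(
    list(release = path$release, nest = path$nest, status = path$status,
         arrival_distance = path$arrival_distance,
         initial_heading = path$initial_heading,
         params = unclass(params)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
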