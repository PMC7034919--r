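# Release protocols, gain x baseline parameter sweeps, and the
# robustness-condition battery.
#
# Sweep success is summarised per parameter cell by the median arrival
# distance of M agents released around the nest: the median indicates
# whether the majority of agents reached the nest, where a mean would be
# dominated by the few lost agents.

#' Equally spaced release points around the nest
#'
#' `M` points at the given distance, spaced exactly 360/M degrees apart,
#' the whole ring rotated by a seeded random phase.
#'
#' @param nest numeric length-2.
#' @param distance release distance in metres, >= 0.
#' @param M number of release points, >= 1. Default 10 (one every 36
#'   degrees).
#' @param seed integer seed for the phase.
#' @return a matrix with `M` rows and columns `x`, `y`.
#' @export
release_points <- function(nest, distance, M = 10, seed = 1L) {
  if (distance < 0) stop_invalid("distance must be >= 0")
  if (M < 1) stop_invalid("M must be >= 1")
  phase <- with_seed(seed, stats::runif(1, 0, 360))
  ang <- phase + (seq_len(M) - 1) * 360 / M
  cbind(x = nest[1] + distance * cos(deg2rad(ang)),
        y = nest[2] + distance * sin(deg2rad(ang)))
}

#' Did a run home successfully?
#'
#' @param path a `homing_path`.
#' @param nest goal position; defaults to the path's nest.
#' @param radius success radius in metres; a run succeeds iff its final
#'   position lies within (<=) this distance of the nest. Default 1.
#' @return logical.
#' @export
homing_success <- function(path, nest = path$nest, radius = 1.0) {
  s <- path$steps
  final <- c(s$x[nrow(s)], s$y[nrow(s)])
  sqrt(sum((final - nest)^2)) <= radius
}

#' Sweep specification
#'
#' @param gain_values numeric vector of gains (log-spaced is typical;
#'   `Inf` allowed). Default `c(0, 100, 300, 1000, 3000, Inf)`.
#' @param baseline_values numeric vector of baselines in [0, 180]
#'   degrees. Default `c(0, 30, 60, 90, 120, 150)`.
#' @param release_distance metres from the nest. Default 4.
#' @param M release points per cell, >= 1. Default 10.
#' @param steps steps per run. Default 320 (64 m of travel at 0.2
#'   m/step).
#' @param success_radius metres. Default 1.
#' @param step_length metres per step. Default 0.2.
#' @param heading_noise a heading-noise model. Default Gaussian sd 10.
#' @param seed integer master seed; every run's seed derives from it.
#' @return an object of class `sweep_spec`.
#' @export
sweep_spec <- function(gain_values = c(0, 100, 300, 1000, 3000, Inf),
                       baseline_values = c(0, 30, 60, 90, 120, 150),
                       release_distance = 4, M = 10, steps = 320,
                       success_radius = 1.0, step_length = 0.2,
                       heading_noise = heading_noise_gaussian(10),
                       seed = 1L) {
  if (M < 1) stop_invalid("M must be >= 1")
  if (any(baseline_values < 0 | baseline_values > 180))
    stop_invalid("baselines must lie in [0, 180]")
  if (any(gain_values < 0)) stop_invalid("gains must be >= 0")
  structure(list(gain_values = gain_values,
                 baseline_values = baseline_values,
                 release_distance = release_distance, M = as.integer(M),
                 steps = as.integer(steps),
                 success_radius = success_radius,
                 step_length = step_length, heading_noise = heading_noise,
                 seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run a gain x baseline parameter sweep
#'
#' For every (gain, baseline) cell, releases `M` agents at equally
#' spaced points around the nest with random initial headings and stores
#' the median arrival distance. Fully deterministic given the spec's
#' seed; failures in a cell are recorded without aborting the sweep.
#'
#' @param world a `world_model`.
#' @param banks memory banks.
#' @param ctx a [familiarity_context()] (calibrated for
#'   `attractive_only`).
#' @param spec a [sweep_spec()].
#' @param memory_mode `"opponent"` or `"attractive_only"`.
#' @param vp a [view_params()] object.
#' @return an object of class `homing_sweep`: `median_matrix` (gains x
#'   baselines), a per-run data frame `runs`, the spec and mode.
#' @export
run_sweep <- function(world, banks, ctx, spec = sweep_spec(),
                      memory_mode = c("opponent", "attractive_only"),
                      vp = view_params()) {
  memory_mode <- match.arg(memory_mode)
  rel <- release_points(world$nest, spec$release_distance, spec$M,
                        seed = derive_seed(spec$seed, 0L))
  ng <- length(spec$gain_values)
  nb <- length(spec$baseline_values)
  med <- matrix(NA_real_, ng, nb,
                dimnames = list(gain = spec$gain_values,
                                baseline = spec$baseline_values))
  runs <- vector("list", ng * nb)
  cell <- 0L
  for (gi in seq_len(ng)) for (bi in seq_len(nb)) {
    cell <- cell + 1L
    d <- rep(NA_real_, spec$M)
    status <- character(spec$M)
    for (m in seq_len(spec$M)) {
      params <- agent_params(baseline = spec$baseline_values[bi],
                             gain = spec$gain_values[gi],
                             step_length = spec$step_length,
                             heading_noise = spec$heading_noise,
                             max_steps = spec$steps,
                             memory_mode = memory_mode,
                             seed = derive_seed(spec$seed,
                                                cell * 1000L + m))
      res <- tryCatch(run_agent(world, banks, ctx, params, rel[m, ],
                                vp = vp),
                      error = function(e) e)
      if (inherits(res, "error")) {
        status[m] <- paste("error:", conditionMessage(res))
      } else {
        d[m] <- res$arrival_distance
        status[m] <- res$status
      }
    }
    med[gi, bi] <- stats::median(d, na.rm = TRUE)
    runs[[cell]] <- data.frame(gain = spec$gain_values[gi],
                               baseline = spec$baseline_values[bi],
                               run = seq_len(spec$M),
                               arrival_distance = d, status = status)
  }
  structure(list(median_matrix = med, runs = do.call(rbind, runs),
                 spec = spec, memory_mode = memory_mode,
                 release_points = rel, nest = world$nest),
            class = "homing_sweep")
}

#' Fraction of sweep cells whose median run homed
#'
#' @param sweep a `homing_sweep`.
#' @param radius success radius in metres; defaults to the spec's.
#' @return fraction in [0, 1] of (gain, baseline) cells with median
#'   arrival distance <= radius.
#' @export
sweep_success_fraction <- function(sweep, radius = sweep$spec$success_radius) {
  mean(sweep$median_matrix <= radius, na.rm = TRUE)
}

#' @export
print.homing_sweep <- function(x, ...) {
  cat("<homing_sweep>", x$memory_mode, "-",
      nrow(x$median_matrix), "gains x", ncol(x$median_matrix),
      "baselines, M =", x$spec$M, "\n")
  cat("  cell success fraction (median <=", x$spec$success_radius, "m):",
      signif(sweep_success_fraction(x), 3), "\n")
  cat("  best cell median:", signif(min(x$median_matrix, na.rm = TRUE), 3),
      "m\n")
  invisible(x)
}

#' @export
plot.homing_sweep <- function(x, ...) {
  m <- x$median_matrix
  graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), m, axes = FALSE,
                  xlab = "gain", ylab = "baseline (deg)",
                  main = paste("median arrival distance,", x$memory_mode),
                  ...)
  graphics::axis(1, seq_len(nrow(m)), rownames(m))
  graphics::axis(2, seq_len(ncol(m)), colnames(m))
  invisible(x)
}

#' Base configuration for the robustness conditions
#'
#' Defaults follow the full release protocol: 3 nest placements x 100
#' release points at 5 m around each nest, every run walking a 30 m
#' travel budget (the step count adapts to the step length, so slower
#' conditions take more, shorter steps over the same distance).
#'
#' @param world_seed seed of the generated world.
#' @param n_nests number of nest placements.
#' @param n_releases release points per nest.
#' @param release_distance metres.
#' @param travel_budget metres of travel per run.
#' @param lw a [learning_walk_spec()].
#' @param route a [route_spec()].
#' @param vp a [view_params()] object.
#' @param baseline,gain agent parameters for the runs.
#' @param seed master seed for nest placement, release phases and runs.
#' @return a list of class `condition_config`.
#' @export
condition_config <- function(world_seed = 1L, n_nests = 3L,
                             n_releases = 100L, release_distance = 5,
                             travel_budget = 30,
                             lw = learning_walk_spec(),
                             route = route_spec(), vp = view_params(),
                             baseline = 90, gain = 2000, seed = 1L) {
  structure(list(world_seed = as.integer(world_seed),
                 n_nests = as.integer(n_nests),
                 n_releases = as.integer(n_releases),
                 release_distance = release_distance,
                 travel_budget = travel_budget,
                 lw = lw, route = route, vp = vp,
                 baseline = baseline, gain = gain,
                 seed = as.integer(seed)),
            class = "condition_config")
}

#' Names of the robustness conditions
#' @export
condition_names <- function() {
  c("baseline_default", "decoupled", "noisy_learning_90",
    "half_memories_10", "coarse_resolution_10deg",
    "small_learning_walk_10cm", "cluttered_world", "unfamiliar_release")
}

# Apply a named condition's overrides to a config; returns the modified
# config plus per-condition extras.
apply_condition <- function(condition, cfg) {
  extras <- list(archetype = "open_distant", n_objects = 20L, bounds = 32,
                 step_length = 0.2, fictive_nest = FALSE)
  switch(condition,
         baseline_default = NULL,
         decoupled = { cfg$lw$decoupled <- TRUE },
         noisy_learning_90 = { cfg$lw$orientation_noise_halfwidth <- 90 },
         half_memories_10 = { cfg$lw$n_views <- 10L },
         coarse_resolution_10deg = {
           cfg$vp <- view_params(az_resolution = 10,
                                 elev_min = cfg$vp$elev_min,
                                 elev_max = cfg$vp$elev_max,
                                 elev_resolution = 10)
         },
         small_learning_walk_10cm = {
           cfg$lw$span_radius <- 0.1
           extras$step_length <- 0.05   # 4x shorter steps, 4x as many
         },
         cluttered_world = {
           extras$archetype <- "cluttered_local"
           extras$n_objects <- 250L
           extras$bounds <- 16
           extras$step_length <- 0.05   # views change fast in clutter
         },
         unfamiliar_release = { extras$fictive_nest <- TRUE },
         stop_invalid("unknown condition: ", condition,
                      " (see condition_names())"))
  list(cfg = cfg, extras = extras)
}

# Seeded nest placements, kept far enough from the arena edge for the
# route and releases to stay in bounds.
draw_nests <- function(cfg, bounds, seed) {
  margin <- max(cfg$route$length, cfg$release_distance +
                  cfg$lw$span_radius) + 2
  half <- max(bounds - margin, 1)
  half <- min(half, bounds / 2)
  with_seed(seed, matrix(stats::runif(2 * cfg$n_nests, -half, half),
                         cfg$n_nests, 2))
}

# A fictive nest in an unvisited region: far from the true nest and the
# route, inside bounds.
draw_fictive_nest <- function(nest, route, bounds, release_distance, seed) {
  u <- c(cos(deg2rad(route$start_bearing)), sin(deg2rad(route$start_bearing)))
  route_pts <- rbind(nest, t(nest + outer(u, seq(0, route$length,
                                                 length.out = 11))))
  lim <- bounds - release_distance - 1
  with_seed(seed, {
    repeat {
      cand <- stats::runif(2, -lim, lim)
      dmin <- min(sqrt(rowSums(sweep(route_pts, 2, cand)^2)))
      if (dmin > 12) return(cand)
    }
  })
}

#' Run one robustness condition
#'
#' Executes the release protocol under a named manipulation of the
#' opponent-memory agent. Each condition touches only its documented
#' overrides of the base configuration:
#' \describe{
#'   \item{baseline_default}{no change.}
#'   \item{decoupled}{attractive and repulsive views taken on two
#'     independent spirals.}
#'   \item{noisy_learning_90}{+/- 90 degree uniform noise on memorised
#'     facing directions.}
#'   \item{half_memories_10}{10 learning-walk views instead of 25.}
#'   \item{coarse_resolution_10deg}{10 deg/pixel views instead of 5.}
#'   \item{small_learning_walk_10cm}{learning walk spans a 0.1 m radius;
#'     the agent walks 4x shorter steps (and thus 4x as many within the
#'     travel budget).}
#'   \item{cluttered_world}{dense-clutter world with no distant
#'     panorama; shorter steps.}
#'   \item{unfamiliar_release}{releases around a fictive nest in an
#'     unvisited region (memory banks are uninformative there).}
#' }
#'
#' @param condition a name from [condition_names()].
#' @param cfg a [condition_config()].
#' @return an object of class `condition_result`: per-run data frame
#'   (`nest`, `run`, `arrival_distance`, `status`) and summary
#'   quantiles of the arrival distance.
#' @export
run_condition <- function(condition, cfg = condition_config()) {
  ac <- apply_condition(condition, cfg)
  cfg <- ac$cfg
  ex <- ac$extras
  world <- generate_world(cfg$world_seed, ex$archetype,
                          n_objects = ex$n_objects, bounds = ex$bounds)
  nests <- draw_nests(cfg, ex$bounds, derive_seed(cfg$seed, 1L))
  steps <- as.integer(round(cfg$travel_budget / ex$step_length))
  out <- vector("list", cfg$n_nests)
  for (ni in seq_len(cfg$n_nests)) {
    wn <- world
    wn$nest <- nests[ni, ]
    lw <- cfg$lw
    lw$seed <- derive_seed(cfg$seed, 100L + ni)
    banks <- build_memory_banks(wn, lw, cfg$route, cfg$vp)
    goal <- if (ex$fictive_nest) {
      draw_fictive_nest(wn$nest, cfg$route, ex$bounds,
                        cfg$release_distance,
                        derive_seed(cfg$seed, 200L + ni))
    } else wn$nest
    rel <- release_points(goal, cfg$release_distance, cfg$n_releases,
                          seed = derive_seed(cfg$seed, 300L + ni))
    d <- rep(NA_real_, cfg$n_releases)
    status <- character(cfg$n_releases)
    for (m in seq_len(cfg$n_releases)) {
      params <- agent_params(baseline = cfg$baseline, gain = cfg$gain,
                             step_length = ex$step_length,
                             max_steps = steps,
                             memory_mode = "opponent",
                             seed = derive_seed(cfg$seed,
                                                ni * 10000L + m))
      res <- tryCatch(run_agent(wn, banks, familiarity_context(), params,
                                rel[m, ], vp = cfg$vp),
                      error = function(e) e)
      if (inherits(res, "error")) {
        status[m] <- paste("error:", conditionMessage(res))
      } else {
        final <- utils::tail(res$steps, 1)
        d[m] <- sqrt(sum((c(final$x, final$y) - goal)^2))
        status[m] <- res$status
      }
    }
    out[[ni]] <- data.frame(nest = ni, run = seq_len(cfg$n_releases),
                            arrival_distance = d, status = status)
  }
  runs <- do.call(rbind, out)
  structure(list(condition = condition, runs = runs,
                 quantiles = stats::quantile(runs$arrival_distance,
                                             c(0.25, 0.5, 0.75),
                                             na.rm = TRUE),
                 n_runs = nrow(runs), config = cfg),
            class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat("<condition_result>", x$condition, "-", x$n_runs, "runs\n")
  q <- signif(x$quantiles, 3)
  cat("  arrival distance quartiles:", paste(q, collapse = " / "), "m\n")
  invisible(x)
}
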