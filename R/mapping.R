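# Exhaustive familiarity-landscape sampling.
#
# A familiarity map stores, for every position of a square lattice
# centred on the nest and every heading of a regular angular grid, the
# familiarity of the view against each memory bank and the opponent
# difference. When headings are multiples of the view's azimuthal
# resolution, one 360-degree render per position is reused by column
# shifts, so the full map costs one render per lattice position.

#' Sampling-grid specification
#'
#' Defaults sample a 30 x 30 m square centred on the nest every 0.5 m
#' (60 x 60 = 3600 positions, at cell centres) in 72 headings (every 5
#' degrees).
#'
#' @param extent square side in metres; must be an integer multiple of
#'   `spacing`.
#' @param spacing lattice spacing in metres.
#' @param centre grid centre (normally the nest).
#' @param headings_step angular step in degrees; must divide 360.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(extent = 30, spacing = 0.5, centre = c(0, 0),
                      headings_step = 5) {
  n <- extent / spacing
  if (abs(n - round(n)) > 1e-9)
    stop_invalid("extent must be an integer multiple of spacing")
  if (headings_step <= 0 || 360 %% headings_step != 0)
    stop_invalid("headings_step must divide 360")
  structure(list(extent = extent, spacing = spacing,
                 centre = as.numeric(centre),
                 headings_step = headings_step,
                 n_side = as.integer(round(n)),
                 headings = seq(0, 360 - headings_step, by = headings_step)),
            class = "grid_spec")
}

grid_positions <- function(grid) {
  half <- grid$extent / 2
  ax <- grid$centre[1] - half + (seq_len(grid$n_side) - 0.5) * grid$spacing
  ay <- grid$centre[2] - half + (seq_len(grid$n_side) - 0.5) * grid$spacing
  expand.grid(x = ax, y = ay, KEEP.OUT.ATTRS = FALSE)
}

#' Sample the familiarity landscape
#'
#' For every lattice position and every heading, computes the
#' familiarity of the rendered view against the attractive and repulsive
#' banks and their difference (the opponent value). Lattice positions
#' outside the world bounds are skipped and masked. Deterministic.
#'
#' @param world a `world_model`.
#' @param banks memory banks from [build_memory_banks()].
#' @param ctx a [familiarity_context()].
#' @param grid a [grid_spec()].
#' @param vp a [view_params()] object.
#' @return an object of class `familiarity_map`: positions data frame
#'   (with `in_bounds` mask), heading vector, and three
#'   positions x headings matrices `attractive`, `repulsive`,
#'   `opponent` (`NA` rows where masked).
#' @export
sample_familiarity_map <- function(world, banks, ctx = familiarity_context(),
                                   grid = grid_spec(), vp = view_params()) {
  pos <- grid_positions(grid)
  inb <- abs(pos$x) <= world$bounds & abs(pos$y) <= world$bounds
  nh <- length(grid$headings)
  att <- rp <- matrix(NA_real_, nrow(pos), nh)
  K <- ctx$normalization_constant
  for (i in which(inb)) {
    V <- render_headings_matrix(world, c(pos$x[i], pos$y[i]),
                                grid$headings, vp)
    ma <- mismatch_matrix(V, banks$attractive)
    mr <- mismatch_matrix(V, banks$repulsive)
    att[i, ] <- 1 - pmax(pmin(apply(ma, 1, min) / K, 1), 0)
    rp[i, ] <- 1 - pmax(pmin(apply(mr, 1, min) / K, 1), 0)
  }
  structure(list(grid = grid,
                 positions = cbind(pos, in_bounds = inb),
                 headings = grid$headings,
                 attractive = att, repulsive = rp,
                 opponent = att - rp,
                 nest = world$nest),
            class = "familiarity_map")
}

#' @export
print.familiarity_map <- function(x, ...) {
  cat("<familiarity_map>", nrow(x$positions), "positions x",
      length(x$headings), "headings (",
      sum(!x$positions$in_bounds), "masked )\n")
  invisible(x)
}

map_values <- function(map, mode) {
  switch(mode,
         attractive_only = map$attractive,
         opponent = map$opponent,
         repulsive = map$repulsive,
         stop_invalid("unknown map mode: ", mode))
}

#' Best-direction field and directional specificity
#'
#' Per lattice position, the heading with maximum familiarity (ties
#' broken by the lowest heading) and its directional specificity,
#' max minus median familiarity over headings. The reported specificity
#' is clipped into [0, 0.5]; the raw value is kept alongside.
#'
#' @param map a `familiarity_map`.
#' @param mode `"attractive_only"` or `"opponent"`.
#' @return a data frame with `x`, `y`, `best_heading`,
#'   `specificity_raw`, `specificity` (clipped).
#' @export
best_direction_field <- function(map, mode = c("opponent", "attractive_only")) {
  mode <- match.arg(mode)
  vals <- map_values(map, mode)
  best <- apply(vals, 1, function(r) {
    if (all(is.na(r))) return(c(NA_real_, NA_real_))
    c(map$headings[which.max(r)], max(r) - stats::median(r))
  })
  data.frame(x = map$positions$x, y = map$positions$y,
             best_heading = best[1, ], specificity_raw = best[2, ],
             specificity = pmin(pmax(best[2, ], 0), 0.5))
}

#' Familiarity map for one fixed heading
#'
#' Extracts the per-position values for a single sampled heading.
#' Opponent values may be negative: the view at that location then
#' matches the repulsive bank better than the attractive one.
#'
#' @param map a `familiarity_map`.
#' @param heading one of the sampled headings, degrees.
#' @param mode `"attractive_only"` or `"opponent"`.
#' @return a data frame with `x`, `y`, `value`.
#' @export
single_heading_map <- function(map, heading,
                               mode = c("opponent", "attractive_only")) {
  mode <- match.arg(mode)
  j <- match(wrap360(heading), map$headings)
  if (is.na(j))
    stop_invalid("heading ", heading, " was not sampled (step ",
                 map$grid$headings_step, " deg)")
  data.frame(x = map$positions$x, y = map$positions$y,
             value = map_values(map, mode)[, j])
}

#' Transect through the nest
#'
#' Extracts a single-heading map along the lattice row (or column)
#' passing through the nest.
#'
#' @param map a `familiarity_map`.
#' @param heading one of the sampled headings.
#' @param mode `"attractive_only"` or `"opponent"`.
#' @param axis `"x"` (west-east transect) or `"y"` (south-north).
#' @return a data frame with the transect coordinate and `value`, one
#'   row per lattice position along the line.
#' @export
map_transect <- function(map, heading, mode = c("opponent", "attractive_only"),
                         axis = c("x", "y")) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  shm <- single_heading_map(map, heading, mode)
  fixed <- if (axis == "x") shm$y else shm$x
  target <- if (axis == "x") map$nest[2] else map$nest[1]
  # single lattice line closest to the nest (first one on a tie)
  line <- fixed == fixed[which.min(abs(fixed - target))]
  out <- shm[line, , drop = FALSE]
  out[order(if (axis == "x") out$x else out$y), , drop = FALSE]
}

spearman_or_zero <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3 || stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
    return(list(rho = 0, degenerate = TRUE))
  list(rho = unname(stats::cor(a[ok], b[ok], method = "spearman")),
       degenerate = FALSE)
}

#' Angular-error statistics of a single-heading map
#'
#' For each lattice position, relates the map value at a fixed heading
#' to (a) the angular distance between that heading and the nest bearing
#' and (b) the Euclidean distance to the nest, and summarises both with
#' Spearman rank correlations, for the attractive-only and opponent
#' values. The opponent signal is expected to track the angular error
#' and not the distance; the attractive-only signal the reverse.
#'
#' @param map a `familiarity_map`.
#' @param heading one of the sampled headings; default 90 ("north",
#'   +y). Any fixed heading gives qualitatively similar orderings.
#' @return an object of class `angular_error_stats`: per-position data
#'   frame plus a correlation summary (`rho`, with `degenerate` flags
#'   where a variable is constant; degenerate correlations are reported
#'   as 0).
#' @export
angular_error_stats <- function(map, heading = 90) {
  j <- match(wrap360(heading), map$headings)
  if (is.na(j)) stop_invalid("heading ", heading, " was not sampled")
  pos <- map$positions
  bearing <- wrap360(rad2deg(atan2(map$nest[2] - pos$y,
                                   map$nest[1] - pos$x)))
  angerr <- ang_dist(heading, bearing)
  dist <- sqrt((pos$x - map$nest[1])^2 + (pos$y - map$nest[2])^2)
  df <- data.frame(x = pos$x, y = pos$y, angular_error = angerr,
                   nest_distance = dist,
                   attractive = map$attractive[, j],
                   opponent = map$opponent[, j])
  cors <- list(
    opponent_vs_angular_error = spearman_or_zero(df$opponent, df$angular_error),
    opponent_vs_distance = spearman_or_zero(df$opponent, df$nest_distance),
    attractive_vs_angular_error = spearman_or_zero(df$attractive,
                                                   df$angular_error),
    attractive_vs_distance = spearman_or_zero(df$attractive,
                                              df$nest_distance))
  structure(list(data = df, heading = wrap360(heading),
                 correlations = cors),
            class = "angular_error_stats")
}

#' @export
print.angular_error_stats <- function(x, ...) {
  cat("<angular_error_stats> heading", x$heading, "deg,",
      nrow(x$data), "positions\n")
  for (nm in names(x$correlations)) {
    co <- x$correlations[[nm]]
    cat(sprintf("  %-28s rho = %+.3f%s\n", nm, co$rho,
                if (co$degenerate) " (degenerate)" else ""))
  }
  invisible(x)
}

#' Export a familiarity map as long-format CSV
#'
#' One row per (position, heading): `x`, `y`, `heading`, `attractive`,
#' `repulsive`, `opponent`. Masked positions are omitted.
#'
#' @param map a `familiarity_map`.
#' @param file output CSV path.
#' @export
map_to_csv <- function(map, file) {
  keep <- map$positions$in_bounds
  nh <- length(map$headings)
  idx <- which(keep)
  df <- data.frame(
    x = rep(map$positions$x[idx], each = nh),
    y = rep(map$positions$y[idx], each = nh),
    heading = rep(map$headings, times = length(idx)),
    attractive = as.numeric(t(map$attractive[idx, , drop = FALSE])),
    repulsive = as.numeric(t(map$repulsive[idx, , drop = FALSE])),
    opponent = as.numeric(t(map$opponent[idx, , drop = FALSE])))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Export one heading of a map as a position-matrix CSV
#'
#' Writes the per-position values for a single heading as an
#' `n_side` x `n_side` matrix (rows = increasing y, columns =
#' increasing x), convenient for heatmap tools.
#'
#' @param map a `familiarity_map`.
#' @param heading one of the sampled headings.
#' @param file output CSV path.
#' @param mode `"opponent"` or `"attractive_only"`.
#' @export
map_matrix_to_csv <- function(map, heading, file,
                              mode = c("opponent", "attractive_only")) {
  mode <- match.arg(mode)
  shm <- single_heading_map(map, heading, mode)
  n <- map$grid$n_side
  z <- matrix(shm$value, n, n)    # positions expand x fastest
  utils::write.table(t(z), file, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(file)
}

#' @export
plot.familiarity_map <- function(x, heading = 90,
                                 mode = "opponent", ...) {
  shm <- single_heading_map(x, heading, mode)
  n <- x$grid$n_side
  z <- matrix(shm$value, n, n)
  graphics::image(unique(shm$x), unique(shm$y), z, asp = 1,
                  xlab = "x (m)", ylab = "y (m)",
                  main = paste(mode, "familiarity, heading", heading), ...)
  graphics::points(x$nest[1], x$nest[2], pch = 3)
  invisible(x)
}
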