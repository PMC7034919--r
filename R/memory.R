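# Attractive and repulsive memory banks.
#
# The attractive bank holds nest-facing views sampled along a learning-walk
# spiral around the nest plus nest-ward views along a straight homing
# route; the repulsive bank holds anti-nest-facing views at the same
# spiral positions (or at an independent spiral when decoupled). Banks are
# constructed, not learned: no plasticity is simulated.

#' Learning-walk specification
#'
#' Parameters of the spiral of view-sampling positions around the nest.
#' Defaults follow observed learning walks of *Myrmecia* ants: 25 views
#' along a spiral spanning a 2 m radius.
#'
#' @param span_radius outer spiral radius in metres, > 0. Default 2.
#' @param n_views number of learning-walk views, >= 1. Default 25.
#' @param spiral_turns revolutions of the spiral. Default 2.
#' @param orientation_noise_halfwidth half-width in degrees of the uniform
#'   noise applied to each memorised facing direction, in [0, 180].
#'   Default 0 (views point exactly at / away from the nest).
#' @param decoupled if `TRUE`, repulsive views are taken at positions from
#'   a second, independently generated spiral rather than at the
#'   attractive positions.
#' @param seed integer seed for the orientation noise and the decoupled
#'   spiral phase.
#' @return an object of class `learning_walk_spec`.
#' @export
learning_walk_spec <- function(span_radius = 2.0, n_views = 25,
                               spiral_turns = 2.0,
                               orientation_noise_halfwidth = 0,
                               decoupled = FALSE, seed = 1L) {
  if (span_radius <= 0) stop_invalid("span_radius must be > 0")
  if (n_views < 1) stop_invalid("n_views must be >= 1")
  if (orientation_noise_halfwidth < 0 || orientation_noise_halfwidth > 180)
    stop_invalid("orientation_noise_halfwidth must lie in [0, 180]")
  structure(list(span_radius = span_radius, n_views = as.integer(n_views),
                 spiral_turns = spiral_turns,
                 orientation_noise_halfwidth = orientation_noise_halfwidth,
                 decoupled = isTRUE(decoupled), seed = as.integer(seed)),
            class = "learning_walk_spec")
}

#' Homing-route specification
#'
#' @param length route length in metres, >= 0 (0 disables route views).
#'   Default 10.
#' @param start_bearing bearing from the nest along which the route runs
#'   outward, degrees. Default 0.
#' @param view_spacing distance between consecutive route views in
#'   metres, > 0. Default 0.5.
#' @param include_outbound_repulsive if `TRUE`, outward-facing route views
#'   are appended to the repulsive bank. Default `FALSE`.
#' @return an object of class `route_spec`.
#' @export
route_spec <- function(length = 10.0, start_bearing = 0, view_spacing = 0.5,
                       include_outbound_repulsive = FALSE) {
  if (length < 0) stop_invalid("route length must be >= 0")
  if (view_spacing <= 0) stop_invalid("view_spacing must be > 0")
  structure(list(length = length, start_bearing = wrap360(start_bearing),
                 view_spacing = view_spacing,
                 include_outbound_repulsive = isTRUE(include_outbound_repulsive)),
            class = "route_spec")
}

#' Positions along the learning-walk spiral
#'
#' An Archimedean spiral centred on the nest: radius increases linearly
#' from `span_radius / n_views` to `span_radius`, the angle advances
#' uniformly over `spiral_turns` revolutions. Deterministic (the seed in
#' the spec affects only orientation noise and decoupling).
#'
#' @param nest nest position, numeric length-2.
#' @param spec a [learning_walk_spec()].
#' @param phase_deg angular offset of the spiral start, degrees.
#' @return a matrix with `n_views` rows and columns `x`, `y`.
#' @examples
#' p <- spiral_positions(c(0, 0), learning_walk_spec())
#' max(sqrt(rowSums(p^2)))  # 2 m
#' @export
spiral_positions <- function(nest, spec, phase_deg = 0) {
  i <- seq_len(spec$n_views)
  r <- spec$span_radius * i / spec$n_views
  a <- phase_deg + (i - 1) * spec$spiral_turns * 360 / spec$n_views
  cbind(x = nest[1] + r * cos(deg2rad(a)),
        y = nest[2] + r * sin(deg2rad(a)))
}

new_memory_bank <- function(valence, views, provenance, vp) {
  if (length(views) == 0)
    stop_invalid("memory bank construction produced an empty '", valence,
                 "' bank; check the learning-walk and route specs")
  pixmat <- do.call(rbind, lapply(views, function(v) as.numeric(v$pixels)))
  structure(list(valence = valence, views = views, provenance = provenance,
                 pixmat = pixmat, view_params = vp),
            class = "memory_bank")
}

#' @export
print.memory_bank <- function(x, ...) {
  cat("<memory_bank>", x$valence, "-", length(x$views), "views (",
      sum(x$provenance$kind == "spiral"), "spiral,",
      sum(x$provenance$kind == "route"), "route )\n")
  invisible(x)
}

#' Build attractive and repulsive memory banks
#'
#' The attractive bank holds nest-facing views at the learning-walk spiral
#' positions (facing = bearing from the sample point to the nest, plus
#' uniform noise of half-width `lw$orientation_noise_halfwidth`) and
#' nest-ward-facing views every `route$view_spacing` metres along the
#' straight homing route running outward from the nest. The repulsive bank
#' holds anti-nest-facing views (180 degrees from the noiseless attractive
#' facing, plus independent noise) at the same spiral positions, or at a
#' second independently-placed spiral when `lw$decoupled` is set. With
#' `route$include_outbound_repulsive`, outward-facing route views are
#' appended to the repulsive bank.
#'
#' @param world a `world_model`.
#' @param lw a [learning_walk_spec()].
#' @param route a [route_spec()]; use `length = 0` for no route views.
#' @param vp a [view_params()] object.
#' @return a list with elements `attractive` and `repulsive`, each a
#'   `memory_bank` carrying per-view provenance (sample position, intended
#'   facing, applied noise).
#' @examples
#' w <- generate_world(1, "open_distant")
#' banks <- build_memory_banks(w, learning_walk_spec(), route_spec())
#' length(banks$attractive$views)  # 25 spiral + 20 route
#' @export
build_memory_banks <- function(world, lw = learning_walk_spec(),
                               route = route_spec(), vp = view_params()) {
  att_pos <- spiral_positions(world$nest, lw)
  rep_pos <- if (lw$decoupled) {
    phase <- with_seed(derive_seed(lw$seed, 211L), stats::runif(1, 30, 330))
    spiral_positions(world$nest, lw, phase_deg = phase)
  } else att_pos
  n <- lw$n_views
  noise <- if (lw$orientation_noise_halfwidth > 0) {
    with_seed(derive_seed(lw$seed, 17L), matrix(
      stats::runif(2 * n, -lw$orientation_noise_halfwidth,
                   lw$orientation_noise_halfwidth), n, 2))
  } else matrix(0, n, 2)

  att_face0 <- vapply(seq_len(n), function(i)
    bearing_to(att_pos[i, ], world$nest), numeric(1))
  rep_face0 <- if (lw$decoupled) {
    wrap360(vapply(seq_len(n), function(i)
      bearing_to(rep_pos[i, ], world$nest), numeric(1)) + 180)
  } else wrap360(att_face0 + 180)
  att_face <- wrap360(att_face0 + noise[, 1])
  rep_face <- wrap360(rep_face0 + noise[, 2])

  take <- function(pos, face)
    lapply(seq_len(nrow(pos)), function(i)
      render_panorama(world, pos[i, ], face[i], vp))

  att_views <- take(att_pos, att_face)
  rep_views <- take(rep_pos, rep_face)
  att_prov <- data.frame(x = att_pos[, 1], y = att_pos[, 2],
                         facing = att_face, intended_facing = att_face0,
                         noise = noise[, 1], kind = "spiral")
  rep_prov <- data.frame(x = rep_pos[, 1], y = rep_pos[, 2],
                         facing = rep_face, intended_facing = rep_face0,
                         noise = noise[, 2], kind = "spiral")

  if (route$length > 0) {
    d <- seq(route$view_spacing, route$length, by = route$view_spacing)
    if (length(d) > 0) {
      u <- c(cos(deg2rad(route$start_bearing)),
             sin(deg2rad(route$start_bearing)))
      rpos <- cbind(x = world$nest[1] + d * u[1],
                    y = world$nest[2] + d * u[2])
      home_face <- wrap360(route$start_bearing + 180)
      att_views <- c(att_views,
                     take(rpos, rep(home_face, length(d))))
      att_prov <- rbind(att_prov, data.frame(
        x = rpos[, 1], y = rpos[, 2], facing = home_face,
        intended_facing = home_face, noise = 0, kind = "route"))
      if (route$include_outbound_repulsive) {
        rep_views <- c(rep_views,
                       take(rpos, rep(route$start_bearing, length(d))))
        rep_prov <- rbind(rep_prov, data.frame(
          x = rpos[, 1], y = rpos[, 2], facing = route$start_bearing,
          intended_facing = route$start_bearing, noise = 0, kind = "route"))
      }
    }
  }
  list(attractive = new_memory_bank("attractive", att_views, att_prov, vp),
       repulsive = new_memory_bank("repulsive", rep_views, rep_prov, vp))
}

#' Save / load a memory bank
#'
#' A bank is written as a directory of per-view CSV pixel grids plus a
#' JSON manifest recording valence, provenance and view geometry.
#'
#' @param bank a `memory_bank`.
#' @param dir directory to write into (created if needed).
#' @return `bank_load` returns a `memory_bank`.
#' @export
bank_save <- function(bank, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("view_%03d.csv", seq_along(bank$views))
  for (i in seq_along(bank$views))
    view_to_csv(bank$views[[i]], file.path(dir, files[i]))
  manifest <- list(valence = bank$valence,
                   files = files,
                   provenance = bank$provenance,
                   headings = vapply(bank$views, `[[`, numeric(1), "heading"),
                   positions = t(vapply(bank$views, `[[`, numeric(2),
                                        "position")),
                   view_params = unclass(bank$view_params))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname bank_save
#' @export
bank_load <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  p <- man$view_params
  vp <- view_params(p$az_resolution, p$elev_min, p$elev_max,
                    p$elev_resolution)
  views <- lapply(seq_along(man$files), function(i) {
    px <- as.matrix(utils::read.csv(file.path(dir, man$files[i]),
                                    header = FALSE))
    dimnames(px) <- NULL
    structure(list(pixels = px, position = as.numeric(man$positions[i, ]),
                   heading = man$headings[i],
                   az_resolution = vp$az_resolution,
                   elev_span = c(vp$elev_min, vp$elev_max),
                   elev_resolution = vp$elev_resolution),
              class = "panorama_view")
  })
  new_memory_bank(man$valence, views, as.data.frame(man$provenance), vp)
}
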