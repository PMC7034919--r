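# Procedural virtual worlds and panoramic rendering.
#
# A world is a flat ground plane carrying opaque vertical cylinders
# ("objects": trees or clutter) plus a distant skyline -- a periodic
# per-azimuth elevation/luminance profile standing at infinity. Views are
# rendered by a column-wise occlusion painter: for each azimuth column the
# nearest object subtending that azimuth (else the distant skyline) sets
# the occluding edge; every elevation bin whose centre lies below the edge
# takes the occluder's luminance, bins above take the sky luminance.
# Only the above-horizon panorama is rendered.

#' Agent eye height above ground, in metres
#'
#' Enters rendering only through the apparent angular height of objects.
#' @export
EYE_HEIGHT_M <- 0.02

#' View geometry parameters
#'
#' @param az_resolution horizontal resolution, degrees per pixel; must
#'   divide 360 exactly. Default 5 (a typical ant eye).
#' @param elev_min,elev_max vertical span in degrees of elevation;
#'   `elev_min` must be >= 0 (below-horizon content is not rendered).
#'   Defaults 0 and 60.
#' @param elev_resolution vertical resolution, degrees per pixel; defaults
#'   to `az_resolution`. Must divide `elev_max - elev_min`.
#' @return an object of class `view_params`.
#' @examples
#' vp <- view_params()            # 72 x 12 pixels
#' vp10 <- view_params(az_resolution = 10)  # coarse-eye variant
#' @export
view_params <- function(az_resolution = 5, elev_min = 0, elev_max = 60,
                        elev_resolution = az_resolution) {
  if (az_resolution <= 0 || 360 %% az_resolution != 0)
    stop_invalid("az_resolution must be positive and divide 360 exactly")
  if (elev_min < 0) stop_invalid("elev_min must be >= 0 (above-horizon only)")
  if (elev_max <= elev_min) stop_invalid("elev_max must exceed elev_min")
  span <- elev_max - elev_min
  if (elev_resolution <= 0 || abs(span / elev_resolution -
                                  round(span / elev_resolution)) > 1e-9)
    stop_invalid("elev_resolution must divide the elevation span")
  structure(list(az_resolution = az_resolution,
                 elev_min = elev_min, elev_max = elev_max,
                 elev_resolution = elev_resolution,
                 n_cols = as.integer(360 / az_resolution),
                 n_rows = as.integer(round(span / elev_resolution))),
            class = "view_params")
}

#' Scene objects (opaque vertical cylinders)
#'
#' @param x,y centre position in metres.
#' @param radius cylinder radius in metres, > 0.
#' @param height cylinder height in metres, > 0.
#' @param luminance surface luminance in [0, 1].
#' @return a data frame with one row per object.
#' @export
scene_objects <- function(x, y, radius, height, luminance) {
  n <- length(x)
  stopifnot(length(y) == n, length(radius) == n,
            length(height) == n, length(luminance) == n)
  if (n > 0) {
    if (any(radius <= 0)) stop_invalid("object radius must be > 0")
    if (any(height <= 0)) stop_invalid("object height must be > 0")
    if (any(luminance < 0 | luminance > 1))
      stop_invalid("object luminance must lie in [0, 1]")
  }
  data.frame(x = as.numeric(x), y = as.numeric(y),
             radius = as.numeric(radius), height = as.numeric(height),
             luminance = as.numeric(luminance))
}

#' Construct a world model
#'
#' Normally called through [generate_world()]; exposed for custom worlds.
#'
#' @param nest goal position, numeric length-2 (metres).
#' @param objects data frame from [scene_objects()] (may have zero rows).
#' @param skyline data frame with columns `azimuth_deg` (covering 360
#'   degrees), `elevation_deg` (>= 0) and `luminance` in [0, 1); the
#'   distant panorama profile, linearly interpolated periodically.
#' @param ground_luminance,sky_luminance luminances in [0, 1];
#'   `sky_luminance` must exceed `ground_luminance` so that views are
#'   non-constant somewhere.
#' @param bounds square half-width of the navigable area, metres > 0.
#' @param seed integer seed recorded for provenance.
#' @param archetype optional label recorded for provenance.
#' @return an object of class `world_model`.
#' @export
world_model <- function(nest, objects, skyline, ground_luminance = 0.3,
                        sky_luminance = 1.0, bounds, seed = NA_integer_,
                        archetype = "custom") {
  if (bounds <= 0) stop_invalid("bounds must be > 0")
  if (!all(c("azimuth_deg", "elevation_deg", "luminance") %in% names(skyline)))
    stop_invalid("skyline needs columns azimuth_deg, elevation_deg, luminance")
  if (nrow(skyline) < 1) stop_invalid("skyline profile must be non-empty")
  if (any(skyline$elevation_deg < 0))
    stop_invalid("skyline elevation must be >= 0")
  if (any(skyline$luminance < 0 | skyline$luminance > 1))
    stop_invalid("skyline luminance must lie in [0, 1]")
  if (sky_luminance <= ground_luminance)
    stop_invalid("sky_luminance must exceed ground_luminance")
  skyline <- skyline[order(skyline$azimuth_deg), , drop = FALSE]
  w <- structure(list(nest = as.numeric(nest),
                      objects = objects,
                      skyline = skyline,
                      ground_luminance = ground_luminance,
                      sky_luminance = sky_luminance,
                      bounds = as.numeric(bounds),
                      seed = seed,
                      archetype = archetype),
                 class = "world_model")
  w
}

#' Generate a procedural world
#'
#' Two archetypes emulate contrasting natural habitats. `open_distant`
#' is an open eucalypt woodland: a smooth random harmonic skyline on the
#' horizon plus a surrounding stand of large trees at middle distances
#' (an annulus between 40% and 95% of the bounds). Because every tree is
#' far from the central foraging area, views decorrelate smoothly and
#' without saturating over tens of metres of displacement -- the regime
#' in which a single glance carries usable directional information.
#' `cluttered_local` is a dense scrub habitat: a flat zero-elevation
#' distant skyline (no distal panorama) and many small objects
#' everywhere, so views change rapidly with small displacements. Both
#' are deterministic in `seed`.
#'
#' @param seed integer seed; the same seed always regenerates an
#'   identical world.
#' @param archetype `"open_distant"` or `"cluttered_local"`.
#' @param n_objects number of scene objects, >= 0. Defaults: 25 for
#'   `open_distant`, 150 for `cluttered_local`.
#' @param bounds square half-width of the navigable area in metres, > 0.
#'   Defaults: 32 for `open_distant` (a ~64 m wide world), 10 for
#'   `cluttered_local`.
#' @param nest nest position, default the origin.
#' @return a `world_model`.
#' @examples
#' w <- generate_world(1, "open_distant")
#' @export
generate_world <- function(seed, archetype = c("open_distant", "cluttered_local"),
                           n_objects = NULL, bounds = NULL, nest = c(0, 0)) {
  archetype <- match.arg(archetype)
  if (is.null(n_objects))
    n_objects <- if (archetype == "open_distant") 25L else 150L
  if (is.null(bounds))
    bounds <- if (archetype == "open_distant") 32 else 10
  if (bounds <= 0) stop_invalid("bounds must be > 0")
  if (n_objects < 0) stop_invalid("n_objects must be >= 0")
  with_seed(seed, {
    az <- 0:359
    if (archetype == "open_distant") {
      # smooth periodic skyline: random low-order harmonics, clipped at 0
      amps <- stats::runif(4, 0.5, 3.5)
      phases <- stats::runif(4, 0, 360)
      elev <- 4 + Reduce(`+`, lapply(1:4, function(k)
        amps[k] * sin(deg2rad(k * az + phases[k]))))
      elev <- pmax(elev, 0)
      lum <- 0.3 + 0.1 * sin(deg2rad(az + stats::runif(1, 0, 360)))
    } else {
      elev <- rep(0, 360)
      lum <- rep(0.3, 360)
    }
    objs <- if (n_objects > 0) {
      if (archetype == "open_distant") {
        # large trees on an annulus around the central foraging area
        ang <- stats::runif(n_objects, 0, 360)
        rad <- sqrt(stats::runif(n_objects, (0.4 * bounds)^2,
                                 (0.95 * bounds)^2))
        scene_objects(nest[1] + rad * cos(deg2rad(ang)),
                      nest[2] + rad * sin(deg2rad(ang)),
                      radius = stats::runif(n_objects, 1.5, 3.5),
                      height = stats::runif(n_objects, 10, 25),
                      luminance = stats::runif(n_objects, 0.1, 0.45))
      } else {
        # dense small clutter everywhere except the nest entrance
        xs <- ys <- numeric(n_objects)
        for (i in seq_len(n_objects)) {
          repeat {
            p <- stats::runif(2, -0.95 * bounds, 0.95 * bounds) + nest
            if (sqrt(sum((p - nest)^2)) > 0.3) break
          }
          xs[i] <- p[1]; ys[i] <- p[2]
        }
        scene_objects(xs, ys,
                      radius = stats::runif(n_objects, 0.05, 0.25),
                      height = stats::runif(n_objects, 0.2, 1.2),
                      luminance = stats::runif(n_objects, 0.1, 0.45))
      }
    } else scene_objects(numeric(0), numeric(0), numeric(0),
                         numeric(0), numeric(0))
    world_model(nest = nest, objects = objs,
                skyline = data.frame(azimuth_deg = az, elevation_deg = elev,
                                     luminance = lum),
                ground_luminance = 0.3, sky_luminance = 1.0,
                bounds = bounds, seed = as.integer(seed),
                archetype = archetype)
  })
}

#' @export
print.world_model <- function(x, ...) {
  cat("<world_model>", x$archetype, "\n")
  cat("  bounds: +/-", x$bounds, "m; nest at (",
      paste(signif(x$nest, 4), collapse = ", "), ")\n")
  cat("  objects:", nrow(x$objects),
      "; max skyline elevation:", signif(max(x$skyline$elevation_deg), 3),
      "deg\n")
  invisible(x)
}

# Periodic linear interpolation of the skyline profile at world azimuths.
skyline_at <- function(world, az) {
  sk <- world$skyline
  az <- wrap360(az)
  if (nrow(sk) == 1) {
    return(list(elevation = rep(sk$elevation_deg, length(az)),
                luminance = rep(sk$luminance, length(az))))
  }
  # extend grid periodically so every az falls inside [first, first + 360]
  xs <- c(sk$azimuth_deg, sk$azimuth_deg[1] + 360)
  el <- c(sk$elevation_deg, sk$elevation_deg[1])
  lu <- c(sk$luminance, sk$luminance[1])
  azq <- ifelse(az < xs[1], az + 360, az)
  list(elevation = stats::approx(xs, el, xout = azq, rule = 2)$y,
       luminance = stats::approx(xs, lu, xout = azq, rule = 2)$y)
}

# Occluding edge (elevation + luminance) for a set of world azimuths, at a
# position. Nearest object subtending an azimuth wins; else the skyline.
occluding_edge <- function(world, position, world_az) {
  sky <- skyline_at(world, world_az)
  edge_elev <- sky$elevation
  edge_lum <- sky$luminance
  ob <- world$objects
  if (nrow(ob) > 0) {
    dx <- ob$x - position[1]
    dy <- ob$y - position[2]
    d <- sqrt(dx * dx + dy * dy)
    inside <- d <= ob$radius
    obj_az <- rad2deg(atan2(dy, dx))
    half <- ifelse(inside, 180, rad2deg(asin(pmin(ob$radius / d, 1))))
    elev <- ifelse(inside, 90,
                   rad2deg(atan((ob$height - EYE_HEIGHT_M) / d)))
    nc <- length(world_az)
    no <- nrow(ob)
    dmat <- abs(((matrix(obj_az, nc, no, byrow = TRUE) - world_az + 180)
                 %% 360) - 180)
    subt <- dmat <= matrix(half, nc, no, byrow = TRUE)
    distm <- matrix(d, nc, no, byrow = TRUE)
    distm[!subt] <- Inf
    hit <- rowSums(subt) > 0
    if (any(hit)) {
      nearest <- max.col(-distm[hit, , drop = FALSE], ties.method = "first")
      edge_elev[hit] <- elev[nearest]
      edge_lum[hit] <- ob$luminance[nearest]
    }
  }
  list(elevation = edge_elev, luminance = edge_lum)
}

#' Render a panoramic view
#'
#' Column-wise occlusion rendering of the above-horizon panorama seen from
#' `position` facing `heading`. Column 1 of the pixel grid corresponds to
#' the heading direction; columns advance clockwise in the visual field
#' (decreasing world azimuth). Row 1 is the highest elevation bin. Per
#' column, the nearest object subtending that azimuth (else the distant
#' skyline) sets an occluding edge; elevation bins with centres below the
#' edge take the occluder's luminance, bins above take the sky luminance.
#'
#' @param world a `world_model`.
#' @param position numeric length-2, must lie inside the world bounds.
#' @param heading facing direction, degrees CCW from +x.
#' @param vp a [view_params()] object.
#' @return an object of class `panorama_view`: list with `pixels`
#'   (n_rows x n_cols matrix in [0, 1]), `position`, `heading`, and the
#'   view geometry.
#' @examples
#' w <- generate_world(1, "open_distant")
#' v <- render_panorama(w, c(2, 0), heading = 90)
#' dim(v$pixels)  # 12 x 72
#' @export
render_panorama <- function(world, position, heading, vp = view_params()) {
  check_in_bounds(world, position)
  world_az <- wrap360(heading - (0:(vp$n_cols - 1)) * vp$az_resolution)
  edge <- occluding_edge(world, position, world_az)
  new_view_from_edge(world, edge, position, heading, vp)
}

new_view_from_edge <- function(world, edge, position, heading, vp) {
  centres <- vp$elev_min + (seq_len(vp$n_rows) - 0.5) * vp$elev_resolution
  below <- outer(centres, edge$elevation, `<`)      # rows ascending elevation
  px <- matrix(world$sky_luminance, vp$n_rows, vp$n_cols)
  lum <- matrix(edge$luminance, vp$n_rows, vp$n_cols, byrow = TRUE)
  px[below] <- lum[below]
  px <- px[vp$n_rows:1, , drop = FALSE]             # row 1 = highest elevation
  structure(list(pixels = px, position = as.numeric(position),
                 heading = wrap360(heading),
                 az_resolution = vp$az_resolution,
                 elev_span = c(vp$elev_min, vp$elev_max),
                 elev_resolution = vp$elev_resolution),
            class = "panorama_view")
}

check_in_bounds <- function(world, position) {
  if (any(abs(position) > world$bounds))
    stop_invalid("position (", paste(signif(position, 4), collapse = ", "),
                 ") is outside the world bounds (+/-", world$bounds, " m)")
  invisible(TRUE)
}

#' Render views at many headings from one position
#'
#' When every heading is a multiple of the azimuthal resolution, a single
#' 360-degree render is reused by circular column shifts (rotation on the
#' spot is exactly a column shift of the panorama); otherwise each heading
#' is rendered independently. Used by the familiarity-mapping module.
#'
#' @inheritParams render_panorama
#' @param headings numeric vector of headings in degrees.
#' @return a matrix with one row per heading, each row a flattened pixel
#'   grid (row-major over the view's rows), plus attribute `headings`.
#' @export
render_headings_matrix <- function(world, position, headings,
                                   vp = view_params()) {
  check_in_bounds(world, position)
  npx <- vp$n_rows * vp$n_cols
  res <- vp$az_resolution
  shifts_ok <- all(abs(headings / res - round(headings / res)) < 1e-9)
  out <- matrix(NA_real_, length(headings), npx)
  if (shifts_ok) {
    base <- render_panorama(world, position, heading = 0, vp = vp)$pixels
    for (i in seq_along(headings)) {
      k <- as.integer(round(wrap360(headings[i]) / res))
      # heading h column c = world az h - c*res = base column (c - ...) ;
      # rotating the agent CCW by k*res shifts content right by k columns
      idx <- ((seq_len(vp$n_cols) - 1 - k) %% vp$n_cols) + 1
      out[i, ] <- as.numeric(base[, idx, drop = FALSE])
    }
  } else {
    for (i in seq_along(headings))
      out[i, ] <- as.numeric(
        render_panorama(world, position, headings[i], vp)$pixels)
  }
  attr(out, "headings") <- headings
  out
}

#' Save / load a world as JSON
#'
#' @param world a `world_model`.
#' @param path file path.
#' @return `world_from_json` returns a `world_model`.
#' @export
world_to_json <- function(world, path) {
  obj <- list(nest = world$nest,
              objects = world$objects,
              skyline = world$skyline,
              ground_luminance = world$ground_luminance,
              sky_luminance = world$sky_luminance,
              bounds = world$bounds,
              seed = world$seed,
              archetype = world$archetype)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname world_to_json
#' @export
world_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  objs <- obj$objects
  if (is.null(objs) || length(objs) == 0 || NROW(objs) == 0)
    objs <- scene_objects(numeric(0), numeric(0), numeric(0),
                          numeric(0), numeric(0))
  world_model(nest = obj$nest, objects = as.data.frame(objs),
              skyline = as.data.frame(obj$skyline),
              ground_luminance = obj$ground_luminance,
              sky_luminance = obj$sky_luminance,
              bounds = obj$bounds,
              seed = if (is.null(obj$seed)) NA_integer_ else obj$seed,
              archetype = if (is.null(obj$archetype)) "custom" else obj$archetype)
}

#' Build a world from a custom skyline profile
#'
#' Reads a JSON file containing a list of
#' `{azimuth_deg, elevation_deg, luminance}` records describing a distant
#' skyline, and returns an object-free world with that panorama.
#'
#' @param path JSON file path.
#' @param bounds navigable half-width in metres.
#' @param nest nest position.
#' @return a `world_model` with no objects.
#' @export
world_from_skyline_json <- function(path, bounds = 32, nest = c(0, 0)) {
  sk <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  world_model(nest = nest,
              objects = scene_objects(numeric(0), numeric(0), numeric(0),
                                      numeric(0), numeric(0)),
              skyline = sk, bounds = bounds, archetype = "custom")
}

#' Export a view as CSV or PGM
#'
#' `view_to_csv` writes the pixel grid as a plain CSV (no header, row 1 =
#' highest elevation). `view_to_pgm` writes a portable greymap (P2,
#' 8-bit) for quick visual inspection.
#'
#' @param view a `panorama_view`.
#' @param path output file path.
#' @export
view_to_csv <- function(view, path) {
  utils::write.table(view$pixels, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname view_to_csv
#' @export
view_to_pgm <- function(view, path) {
  px <- round(view$pixels * 255)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), "255"), con)
  utils::write.table(px, con, sep = " ", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @export
print.panorama_view <- function(x, ...) {
  cat("<panorama_view>", nrow(x$pixels), "x", ncol(x$pixels),
      "px,", x$az_resolution, "deg/px\n")
  cat("  at (", paste(signif(x$position, 4), collapse = ", "),
      ") facing", signif(x$heading, 4), "deg\n")
  invisible(x)
}

#' @export
plot.panorama_view <- function(x, ...) {
  graphics::image(t(x$pixels[nrow(x$pixels):1, , drop = FALSE]),
                  col = grDevices::grey.colors(64, 0, 1), axes = FALSE,
                  main = "panorama (left = heading, rows = elevation)", ...)
  invisible(x)
}
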