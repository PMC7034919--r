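# Shared fixtures, generated in code. The open fixture world (seed 1)
# and its default banks are the reference arena for behavioural tests;
# both are deterministic so they are built once per test run.

fixture_world <- local({
  w <- NULL
  function() {
    if (is.null(w)) w <<- generate_world(1, "open_distant")
    w
  }
})

fixture_banks <- local({
  b <- NULL
  function() {
    if (is.null(b)) b <<- build_memory_banks(fixture_world(),
                                             learning_walk_spec(),
                                             route_spec())
    b
  }
})

# A tiny object-free world with a flat skyline: every view is all sky.
flat_world <- function(bounds = 10, sky_lum = 1, ground_lum = 0.3) {
  world_model(nest = c(0, 0),
              objects = scene_objects(numeric(0), numeric(0), numeric(0),
                                      numeric(0), numeric(0)),
              skyline = data.frame(azimuth_deg = 0:359, elevation_deg = 0,
                                   luminance = ground_lum),
              ground_luminance = ground_lum, sky_luminance = sky_lum,
              bounds = bounds)
}

# A world with a single cylinder, for closed-form angular-size checks.
one_object_world <- function(x, y, radius, height, bounds = 30,
                             lum = 0.2) {
  world_model(nest = c(0, 0),
              objects = scene_objects(x, y, radius, height, lum),
              skyline = data.frame(azimuth_deg = 0:359, elevation_deg = 0,
                                   luminance = 0.3),
              ground_luminance = 0.3, sky_luminance = 1, bounds = bounds)
}

# Random pixel grid in [0,1], for oracle tests.
random_view_matrix <- function(nr, nc) matrix(stats::runif(nr * nc), nr, nc)

# Brute-force RMS mismatch: scalar double loop, kept deliberately naive
# and independent of the package's vectorised path.
brute_rms <- function(a, b) {
  s <- 0
  n <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    s <- s + (a[i, j] - b[i, j])^2
    n <- n + 1
  }
  sqrt(s / n)
}

# Brute-force bank familiarity: loop over bank views, no linear algebra.
brute_bank_familiarity <- function(px, bank_mats, K) {
  best <- Inf
  for (m in bank_mats) {
    v <- brute_rms(px, m)
    if (v < best) best <- v
  }
  1 - min(max(best / K, 0), 1)
}

# Wrap plain matrices into a memory_bank-alike accepted by
# bank_familiarity (same structure as the constructor output).
matrix_bank <- function(mats) {
  views <- lapply(mats, function(m)
    structure(list(pixels = m, position = c(0, 0), heading = 0,
                   az_resolution = 360 / ncol(m), elev_span = c(0, 60),
                   elev_resolution = 60 / nrow(m)),
              class = "panorama_view"))
  structure(list(valence = "attractive", views = views,
                 provenance = data.frame(), view_params = NULL,
                 pixmat = do.call(rbind, lapply(mats, as.numeric))),
            class = "memory_bank")
}
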