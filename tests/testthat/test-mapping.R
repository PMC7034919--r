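# A small map on the fixture world is reused by several blocks.
small_map <- local({
  m <- NULL
  function() {
    if (is.null(m))
      m <<- sample_familiarity_map(
        fixture_world(), fixture_banks(), familiarity_context(),
        grid_spec(extent = 12, spacing = 2, headings_step = 30))
    m
  }
})

test_that("map dimensions follow the grid spec and values stay in range", {
  g <- grid_spec(extent = 2, spacing = 1, headings_step = 90)
  m <- sample_familiarity_map(fixture_world(), fixture_banks(),
                              familiarity_context(), g)
  expect_equal(dim(m$attractive), c(4, 4))     # 2x2 positions, 4 headings
  expect_equal(m$headings, c(0, 90, 180, 270))
  expect_true(all(m$attractive >= 0 & m$attractive <= 1))
  expect_true(all(m$opponent >= -1 & m$opponent <= 1))
  # default spec counts: 60x60 = 3600 positions, 72 headings
  gd <- grid_spec()
  expect_equal(gd$n_side^2, 3600)
  expect_equal(length(gd$headings), 72)
  expect_error(grid_spec(extent = 10, spacing = 3), "multiple")
})

test_that("the opponent map is exactly attractive minus repulsive", {
  m <- small_map()
  expect_identical(m$opponent, m$attractive - m$repulsive)
})

test_that("a memorised (position, facing) pair maps to familiarity 1", {
  w <- fixture_world()
  banks <- fixture_banks()
  # grid centred on a route view at (2, 0) facing 180 (home-ward)
  g <- grid_spec(extent = 4, spacing = 4, centre = c(4, 2),
                 headings_step = 180)
  # choose a lattice that contains exactly the route-view position
  m <- sample_familiarity_map(w, banks, familiarity_context(),
                              grid_spec(extent = 8, spacing = 4,
                                        centre = c(0, 2),
                                        headings_step = 180))
  at <- which(m$positions$x == 2 & m$positions$y == 0)
  expect_length(at, 1)
  expect_equal(m$attractive[at, match(180, m$headings)], 1.0)
})

test_that("out-of-bounds lattice positions are masked, not errors", {
  w <- flat_world(bounds = 3)
  bank <- matrix_bank(list(matrix(1, 12, 72)))
  m <- sample_familiarity_map(w, list(attractive = bank, repulsive = bank),
                              familiarity_context(),
                              grid_spec(extent = 10, spacing = 2,
                                        headings_step = 120))
  expect_true(any(!m$positions$in_bounds))
  expect_true(all(is.na(m$attractive[!m$positions$in_bounds, ])))
  expect_true(all(!is.na(m$attractive[m$positions$in_bounds, ])))
})

test_that("best-direction field handles constant and one-hot heading profiles", {
  m <- small_map()
  # synthetic override: constant across headings -> specificity 0
  mc <- m
  mc$attractive[] <- 0.5
  mc$repulsive[] <- 0.25
  bd <- best_direction_field(mc, "attractive_only")
  expect_true(all(bd$specificity == 0))
  expect_true(all(bd$best_heading == m$headings[1]))
  # one heading at 1, the rest 0: specificity 1 raw, clipped to 0.5
  mh <- m
  mh$attractive[] <- 0
  mh$attractive[, 3] <- 1
  bd2 <- best_direction_field(mh, "attractive_only")
  expect_true(all(bd2$best_heading == m$headings[3]))
  expect_true(all(bd2$specificity_raw == 1))
  expect_true(all(bd2$specificity == 0.5))
})

test_that("on-route positions point home along the route", {
  w <- fixture_world()
  banks <- fixture_banks()
  # lattice of on-route positions (route runs east, home-ward facing 180)
  m <- sample_familiarity_map(w, banks, familiarity_context(),
                              grid_spec(extent = 6, spacing = 1,
                                        centre = c(5, 0.5),
                                        headings_step = 30))
  bd <- best_direction_field(m, "opponent")
  on_route <- abs(bd$y - 0) < 0.6 & bd$x > 2 & bd$x < 8
  share <- mean(abs(((bd$best_heading[on_route] - 180 + 180) %% 360) - 180)
                <= 30)
  expect_gte(share, 0.5)
})

test_that("single-heading extraction and transects behave", {
  m <- small_map()
  sh <- single_heading_map(m, 90, "opponent")
  expect_equal(nrow(sh), nrow(m$positions))
  expect_equal(sh$value, m$opponent[, match(90, m$headings)])
  expect_error(single_heading_map(m, 45), "not sampled")
  tr <- map_transect(m, 90, "opponent", axis = "x")
  expect_equal(nrow(tr), m$grid$n_side)
  expect_true(all(diff(tr$x) > 0))
})

test_that("angular-error statistics flag degenerate maps and expose both correlations", {
  m <- small_map()
  st <- angular_error_stats(m, 90)
  expect_true(all(c("opponent_vs_angular_error", "attractive_vs_distance")
                  %in% names(st$correlations)))
  expect_true(all(st$data$angular_error >= 0 & st$data$angular_error <= 180))
  # constant map -> correlations reported as 0 with the degenerate flag
  mc <- m
  mc$attractive[] <- 0.5
  mc$repulsive[] <- 0.5
  mc$opponent[] <- 0
  st0 <- angular_error_stats(mc, 90)
  expect_equal(st0$correlations$opponent_vs_angular_error$rho, 0)
  expect_true(st0$correlations$opponent_vs_angular_error$degenerate)
})

test_that("north of the nest, a north-facing view has negative opponent value", {
  m <- small_map()
  sh <- single_heading_map(m, 90, "opponent")
  north <- sh$x == 1 & sh$y > 2    # off-route northern positions
  expect_lt(mean(sh$value[north]), 0)
})

test_that("per-heading matrix export lays positions out as a square grid", {
  m <- small_map()
  f <- withr::local_tempfile(fileext = ".csv")
  map_matrix_to_csv(m, 90, f, "opponent")
  z <- as.matrix(utils::read.csv(f, header = FALSE))
  n <- m$grid$n_side
  expect_equal(dim(z), c(n, n))
  sh <- single_heading_map(m, 90, "opponent")
  # row 1 = smallest y, column 1 = smallest x
  expect_equal(z[1, 2], sh$value[sh$x == sort(unique(sh$x))[2] &
                                   sh$y == min(sh$y)],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("maps export as long-format CSV", {
  m <- small_map()
  f <- withr::local_tempfile(fileext = ".csv")
  map_to_csv(m, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), sum(m$positions$in_bounds) * length(m$headings))
  i <- which(df$x == m$positions$x[1] & df$y == m$positions$y[1] &
               df$heading == 90)
  expect_equal(df$opponent[i], m$opponent[1, match(90, m$headings)],
               tolerance = 1e-12)
})
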