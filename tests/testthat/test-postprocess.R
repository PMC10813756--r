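test_that("curve validation enforces its invariants", {
  expect_error(load_displacement_curve(c(0, 1), c(0, 1)), "at least 3")
  expect_error(load_displacement_curve(c(0.1, 0.2, 0.3), c(0, 1, 2)),
               "start at 0")
  expect_error(load_displacement_curve(c(0, 0.2, 0.1), c(0, 1, 2)),
               "non-decreasing")
  expect_error(load_displacement_curve(c(0, 1, 2), c(0, 1)), "equal length")
})

test_that("bilinear experimental-style curves yield their construction values", {
  d <- seq(0, 2, by = 0.02)
  cv <- load_displacement_curve(d, pmin(9.54 * d, 10.2))
  expect_equal(extract_stiffness(cv)$stiffness, 9.54, tolerance = 1e-12)
  expect_equal(extract_strength(cv), 10.2)
})

test_that("a perfectly linear curve returns its slope for any window", {
  d <- seq(0, 3, length.out = 40)
  cv <- load_displacement_curve(d, 4.2 * d)
  for (w in list(c(0.2, 0.8), c(0.1, 0.9), c(0.3, 0.6))) {
    expect_equal(extract_stiffness(cv, window = w)$stiffness, 4.2,
                 tolerance = 1e-12)
  }
})

test_that("noisy stiffness fits equal the closed-form OLS oracle", {
  set.seed(14)
  d <- seq(0, 2, by = 0.05)
  load <- 8 * d + c(0, rnorm(length(d) - 1, 0, 0.05))
  load <- cummax(load)  # keep it a valid monotone curve
  cv <- load_displacement_curve(d, load)
  st <- extract_stiffness(cv)
  x <- d[st$window]; y <- load[st$window]
  n <- length(x)
  slope_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
                  (n * sum(x^2) - sum(x)^2)
  expect_equal(st$stiffness, slope_oracle, tolerance = 1e-12)
  # window loads lie within the requested band
  peak <- max(load)
  expect_true(all(y >= 0.2 * peak & y <= 0.8 * peak))
})

test_that("strength handles monotone and post-peak curves", {
  d <- seq(0, 1, length.out = 11)
  expect_equal(extract_strength(load_displacement_curve(d, d * 2)), 2)
  drop <- c(seq(0, 5, length.out = 6), c(4.5, 4, 3.5, 3, 2.5))
  expect_equal(extract_strength(load_displacement_curve(d, drop)), 5)
})

test_that("stiffness and strength scale linearly with load units", {
  d <- seq(0, 2, by = 0.05)
  base <- pmin(7 * d, 9)
  cv1 <- load_displacement_curve(d, base)
  cv2 <- load_displacement_curve(d, 3 * base)
  expect_equal(extract_stiffness(cv2)$stiffness,
               3 * extract_stiffness(cv1)$stiffness, tolerance = 1e-10)
  expect_equal(extract_strength(cv2), 3 * extract_strength(cv1))
})

test_that("curves round-trip through CSV", {
  d <- seq(0, 2, by = 0.1)
  cv <- load_displacement_curve(d, pmin(5 * d, 6))
  f <- tempfile(fileext = ".csv")
  write_curve(cv, f)
  back <- read_curve(f)
  expect_equal(back$displacement, cv$displacement)
  expect_equal(back$load, cv$load)
})

test_that("sector labels follow the angular rule", {
  # synthetic solution with hand-placed centroids at 0, 90, 180, 270 deg
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  base <- structure(list(nodes = nodes, tets = matrix(1:4, 1),
                         element_density = 1, element_voxel = 1L,
                         node_sets = list(), spacing = c(1, 1, 1)),
                    class = "tet_mesh")
  place_at <- function(center) {
    m <- base
    m$nodes <- sweep(sweep(nodes, 2, colMeans(nodes[1:4, ])), 2, -center)
    m
  }
  frame <- structure(list(center_of_mass = c(0, 0, 0),
                          anterior_direction = c(0, 1, 0),
                          mediolateral_direction = c(1, 0, 0)),
                     class = "anatomical_frame")
  sol <- structure(list(peeq = 1, n_completed = 1L),
                   class = "solution_record")
  angles <- list(anterior = c(0, 5, 0), posterior = c(0, -5, 0),
                 `lateral-right` = c(5, 0, 0), `lateral-left` = c(-5, 0, 0))
  for (nm in names(angles)) {
    fm <- fracture_map(sol, place_at(angles[[nm]]), frame)
    expect_equal(as.character(fm$element$sector), nm)
  }
})

test_that("sector fractions partition all elements", {
  fx <- vertebra_fixture(seed = 41, n_increments = 4)
  lc <- place_control_point(fx$frame, fx$mesh, displacement = 0.5,
                            n_increments = 4)
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
  fm <- fracture_map(sol, fx$mesh, fx$frame)
  expect_equal(sum(fm$sectors$n), nrow(fx$mesh$tets))
  expect_true(all(fm$sectors$fraction_yielded >= 0 &
                  fm$sectors$fraction_yielded <= 1))
  expect_error(fracture_map(sol, fx$mesh, fx$frame, peeq_threshold = -1),
               "peeq_threshold")
})

test_that("an unloaded state has no yielded sectors", {
  fx <- bar_fixture()
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0.1,
                            displacement = 1e-4, n_increments = 3)
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
  fm <- fracture_map(sol, fx$mesh, fx$frame)
  expect_true(all(fm$sectors$fraction_yielded == 0))
})
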