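test_that("radial return leaves elastic trial states untouched", {
  s <- diag(c(2, -1, 0.5))
  out <- radial_return(s, sigma_y = 100, shear_modulus = 500)
  expect_equal(out$stress, s)
  expect_equal(out$dpeeq, 0)
})

test_that("radial return maps a uniaxial overstress back to the yield surface", {
  sy <- 10
  s <- diag(c(2 * sy, 0, 0))  # q_trial = 2 sy
  out <- radial_return(s, sigma_y = sy, shear_modulus = 700)
  dev <- out$stress - diag(mean(diag(out$stress)), 3)
  q <- sqrt(1.5 * sum(dev^2))
  expect_equal(q, sy, tolerance = 1e-14)
  expect_equal(out$dpeeq, (2 * sy - sy) / (3 * 700), tolerance = 1e-14)
  # hydrostatic part untouched
  expect_equal(mean(diag(out$stress)), mean(diag(s)))
})

test_that("radial return rejects non-symmetric input", {
  s <- matrix(rnorm(9), 3, 3)
  s[1, 2] <- s[2, 1] + 1
  expect_error(radial_return(s, 10, 100), "symmetric")
})

test_that("plastic strain increments are deviatoric", {
  set.seed(5)
  G <- 800
  for (i in 1:20) {
    a <- matrix(rnorm(9, sd = 50), 3, 3)
    s <- (a + t(a)) / 2
    out <- radial_return(s, sigma_y = 20, shear_modulus = G)
    if (out$dpeeq > 0) {
      dep <- (s - out$stress) / (2 * G)  # elastic strain released
      expect_equal(sum(diag(dep)), 0, tolerance = 1e-12)
    }
  }
})

test_that("single-tet stiffness matches an independent dense assembly", {
  x <- rbind(c(0, 0, 0), c(1.2, 0.1, 0), c(0.2, 1.1, 0.05),
             c(0.1, 0.2, 0.9))
  vol <- NULL
  mesh <- structure(list(nodes = x, tets = matrix(1:4, 1),
                         element_density = 1, element_voxel = 1L,
                         node_sets = list(), spacing = c(1, 1, 1)),
                    class = "tet_mesh")
  cards <- data.frame(element = 1, rho = 1, E = 2100, nu = 0.3,
                      sigma_y = 1e9, bin = 1)
  sys <- assemble_system(mesh, cards)
  K_oracle <- dense_tet_stiffness(x, E = 2100, nu = 0.3)
  expect_equal(as.matrix(sys$K), K_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(max(abs(sys$K - Matrix::t(sys$K))), 0)
})

test_that("zero displacement and rigid translations produce no force", {
  fx <- bar_fixture()
  sys0 <- assemble_system(fx$mesh, fx$cards)
  expect_equal(max(abs(sys0$fint)), 0)
  u_rigid <- rep(c(0.3, -0.2, 0.5), nrow(fx$mesh$nodes))
  sys1 <- assemble_system(fx$mesh, fx$cards, u = u_rigid)
  expect_lt(max(abs(sys1$fint)), 1e-9 * max(abs(sys1$K)))
})

test_that("an affine displacement field reproduces constant stress exactly", {
  vol <- make_bar_phantom(3, c(2, 2), voxel = 1)
  mesh <- voxels_to_tets(vol)
  cards <- data.frame(element = seq_len(nrow(mesh$tets)), rho = 1,
                      E = 1500, nu = 0.25, sigma_y = 1e9,
                      bin = 1)
  A <- matrix(c(1e-3, 2e-4, -1e-4,
                3e-4, -5e-4, 1e-4,
                -2e-4, 1e-4, 8e-4), 3, 3, byrow = TRUE)
  u <- t(A %*% t(mesh$nodes))
  sys <- assemble_system(mesh, cards, u = as.vector(t(u)))
  eps <- (A + t(A)) / 2
  lam <- 1500 * 0.25 / (1.25 * 0.5)
  mu <- 1500 / 2.5
  sig <- lam * sum(diag(eps)) * diag(3) + 2 * mu * eps
  expected <- c(sig[1, 1], sig[2, 2], sig[3, 3], sig[1, 2], sig[1, 3],
                sig[2, 3])
  for (i in 1:6) {
    expect_equal(sys$stress[, i], rep(expected[i], nrow(mesh$tets)),
                 tolerance = 1e-12)
  }
})

test_that("inverted elements are reported by index", {
  x <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, -1))
  mesh <- structure(list(nodes = x, tets = matrix(1:4, 1),
                         element_density = 1, element_voxel = 1L,
                         node_sets = list(), spacing = c(1, 1, 1)),
                    class = "tet_mesh")
  cards <- data.frame(element = 1, rho = 1, E = 1, nu = 0.3, sigma_y = 1,
                      bin = 1)
  expect_error(assemble_system(mesh, cards), "element 1")
})

test_that("bar stiffness matches EA/L and the plateau matches sigma_y A", {
  fx <- bar_fixture()
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0,
                            displacement = 0.4, n_increments = 40,
                            coupling = "uniform_axial")
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
  expect_true(sol$converged)
  k_exact <- fx$E * fx$area / fx$length / 1000  # kN/mm
  st <- extract_stiffness(sol$curve)
  expect_equal(st$stiffness, k_exact, tolerance = 1e-8)
  plateau <- fx$sigma_y * fx$area / 1000
  expect_equal(max(sol$load_kN), plateau, tolerance = 0.005)
})

test_that("doubling the yield scale doubles the bar plateau", {
  fx <- bar_fixture()
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0,
                            displacement = 0.6, n_increments = 20,
                            coupling = "uniform_axial")
  sol1 <- solve_quasistatic(fx$mesh, fx$cards, lc)
  sol2 <- solve_quasistatic(fx$mesh, rescale_yield(fx$cards, 2), lc)
  expect_equal(max(sol2$load_kN), 2 * max(sol1$load_kN), tolerance = 1e-6)
})

test_that("PEEQ is non-negative and non-decreasing over increments", {
  fx <- bar_fixture()
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0.1,
                            displacement = 0.6, n_increments = 8,
                            coupling = "rigid")
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
  expect_true(sol$converged)
  expect_true(all(sol$peeq_history >= 0))
  expect_true(all(apply(sol$peeq_history, 1, function(r) all(diff(r) >= -1e-14))))
})

test_that("the global tangent is symmetric in elastic and plastic states", {
  vol <- make_bar_phantom(3, c(2, 2), voxel = 1)
  mesh <- voxels_to_tets(vol)
  cards <- data.frame(element = seq_len(nrow(mesh$tets)), rho = 1,
                      E = 1000, nu = 0.3, sigma_y = 3, bin = 1)
  set.seed(2)
  u <- rnorm(3 * nrow(mesh$nodes), sd = 0.01)
  sys <- assemble_system(mesh, cards, u = u)
  expect_gt(sum(sys$dpeeq), 0)  # some elements beyond yield
  expect_equal(max(abs(sys$K - Matrix::t(sys$K))), 0)
  expect_true(all(sys$vm <= cards$sigma_y * (1 + 1e-8)))
})

test_that("anterior offset produces a forward tilt of matching sign", {
  fx <- vertebra_fixture(seed = 31, yield_scale = 1, n_increments = 6)
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0.10,
                            displacement = 1.0, n_increments = 6)
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
  expect_true(sol$converged)
  tilt <- forward_tilt(sol, fx$frame)
  expect_true(all(tilt > 0))
})

test_that("bar stiffness is invariant under mesh refinement", {
  k <- sapply(c(1, 0.5), function(v) {
    fx <- bar_fixture(voxel = v)
    lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0,
                              displacement = 0.05, n_increments = 10,
                              coupling = "uniform_axial")
    sol <- solve_quasistatic(fx$mesh, fx$cards, lc)
    extract_stiffness(sol$curve)$stiffness
  })
  expect_equal(k[1], k[2], tolerance = 1e-8)
})

test_that("non-convergence returns a flagged partial record", {
  fx <- bar_fixture()
  lc <- place_control_point(fx$frame, fx$mesh, offset_fraction = 0,
                            displacement = 2, n_increments = 2,
                            coupling = "uniform_axial")
  sol <- solve_quasistatic(fx$mesh, fx$cards, lc, max_iter = 1L)
  expect_false(sol$converged)
  expect_lt(sol$n_completed, 2L)
})
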