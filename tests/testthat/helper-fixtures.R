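# Shared fixtures, all generated in code at test time.

# homogeneous verification bar: 10 x 4 x 4 mm at 1 mm voxels
bar_fixture <- function(hu = 500, voxel = 1) {
  vol <- make_bar_phantom(10, c(4, 4), hu_value = hu, voxel = voxel)
  rho <- hu_to_density(vol, calibration_line())
  mesh <- label_surfaces(voxels_to_tets(vol, rho))
  frame <- build_frame(mesh)
  cards <- assign_materials(mesh$element_density, material_law())
  list(vol = vol, rho = rho, mesh = mesh, frame = frame, cards = cards,
       area = 16, length = 10,
       E = cards$E[1], sigma_y = cards$sigma_y[1])
}

# coarse vertebra phantom used by solver-level tests (2 mm voxels)
vertebra_fixture <- function(seed = 101, yield_scale = 1,
                             n_increments = 12, voxel = 2) {
  spec <- phantom_spec(height = 22, semi_axis_ap = 11, semi_axis_ml = 13,
                       voxel = voxel, seed = seed)
  vol <- make_vertebra_phantom(spec)
  rho <- hu_to_density(vol, calibration_line())
  mesh <- label_surfaces(voxels_to_tets(vol, rho))
  frame <- build_frame(mesh)
  cards <- assign_materials(mesh$element_density,
                            material_law(yield_scale = yield_scale))
  lc <- place_control_point(frame, mesh, n_increments = n_increments)
  list(spec = spec, vol = vol, mesh = mesh, frame = frame, cards = cards,
       loadcase = lc)
}

# independent dense single-tet stiffness: shape-function gradients from a
# linear solve, B assembled by hand, K = V * B' D B
dense_tet_stiffness <- function(x, E, nu) {
  V <- det(cbind(x[2, ] - x[1, ], x[3, ] - x[1, ], x[4, ] - x[1, ])) / 6
  A <- cbind(1, x)
  # coefficients of N_a solve A c = e_a; gradient = linear coefficients
  grads <- solve(A, diag(4))[2:4, , drop = FALSE]  # column a = grad N_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[, a]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1]
    B[2, c0 + 2] <- g[2]
    B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 1] <- g[3]; B[5, c0 + 3] <- g[1]
    B[6, c0 + 2] <- g[3]; B[6, c0 + 3] <- g[2]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  V * t(B) %*% D %*% B
}
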