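test_that("a single voxel becomes 8 nodes and 6 positive tets of volume 1/6", {
  vol <- make_bar_phantom(1, c(1, 1), voxel = 1)
  mesh <- voxels_to_tets(vol)
  expect_equal(nrow(mesh$nodes), 8L)
  expect_equal(nrow(mesh$tets), 6L)
  v <- tet_volumes(mesh)
  expect_true(all(v > 0))
  expect_equal(v, rep(1 / 6, 6))
})

test_that("meshing partitions the masked volume exactly", {
  vol <- make_vertebra_phantom(phantom_spec(voxel = 2, seed = 4))
  rho <- hu_to_density(vol, calibration_line())
  mesh <- voxels_to_tets(vol, rho)
  n_vox <- sum(vol$mask)
  expect_equal(nrow(mesh$tets), 6L * n_vox)
  expect_equal(sum(tet_volumes(mesh)), n_vox * 8, tolerance = 1e-12)
  expect_true(all(tet_volumes(mesh) > 0))
  # element densities inherited from voxels
  expect_equal(mesh$element_density[1:6],
               rep(rho$values[vol$mask][1], 6))
})

test_that("the mesh is conforming: interior faces shared by exactly 2 tets", {
  vol <- make_vertebra_phantom(phantom_spec(height = 10, semi_axis_ap = 6,
                                            semi_axis_ml = 7, voxel = 2,
                                            seed = 2))
  mesh <- voxels_to_tets(vol)
  faces <- rbind(mesh$tets[, c(2, 3, 4)], mesh$tets[, c(1, 4, 3)],
                 mesh$tets[, c(1, 2, 4)], mesh$tets[, c(1, 3, 2)])
  key <- paste(pmin(faces[, 1], faces[, 2], faces[, 3]),
               faces[, 1] + faces[, 2] + faces[, 3] -
                 pmin(faces[, 1], faces[, 2], faces[, 3]) -
                 pmax(faces[, 1], faces[, 2], faces[, 3]),
               pmax(faces[, 1], faces[, 2], faces[, 3]))
  counts <- table(key)
  expect_true(all(counts %in% c(1L, 2L)))
  # no orphan nodes
  expect_setequal(sort(unique(as.vector(mesh$tets))),
                  seq_len(nrow(mesh$nodes)))
})

test_that("empty masks are rejected", {
  vol <- voxel_volume(array(-1000, c(3, 3, 3)), spacing = 1,
                      mask = array(FALSE, c(3, 3, 3)))
  expect_error(voxels_to_tets(vol), "empty mask")
})

test_that("surface labelling finds the expected bar end nodes", {
  fx <- bar_fixture()
  # 4x4 cross-section at 1 mm voxels: (4+1)^2 nodes on each flat end
  expect_length(fx$mesh$node_sets$cranial, 25L)
  expect_length(fx$mesh$node_sets$caudal, 25L)
  expect_length(intersect(fx$mesh$node_sets$cranial,
                          fx$mesh$node_sets$caudal), 0L)
  zc <- fx$mesh$nodes[fx$mesh$node_sets$cranial, 3]
  expect_true(all(zc == max(fx$mesh$nodes[, 3])))
})

test_that("waisted phantom lateral walls join neither surface set", {
  vol <- make_vertebra_phantom(phantom_spec(voxel = 2, seed = 6))
  mesh <- label_surfaces(voxels_to_tets(vol))
  # oracle: per-face outward-normal test on boundary faces
  bf <- boundary_faces(mesh)
  lateral_faces <- abs(bf$normal[, 3]) < cos(30 * pi / 180)
  zr <- range(mesh$nodes[, 3])
  mid <- bf$centroid[, 3] > zr[1] + 0.2 * diff(zr) &
         bf$centroid[, 3] < zr[2] - 0.2 * diff(zr)
  wall_nodes <- unique(as.vector(bf$faces[lateral_faces & mid, ]))
  expect_length(intersect(wall_nodes, mesh$node_sets$cranial), 0L)
  expect_length(intersect(wall_nodes, mesh$node_sets$caudal), 0L)
})

test_that("bar frame aligns with the axial axis and geometric centre", {
  fx <- bar_fixture()
  fr <- fx$frame
  expect_equal(fr$transverse_plane$normal, c(0, 0, 1), tolerance = 1e-9)
  # homogeneous bar: COM at the geometric centre (x, y at pad + 2, z at 5)
  expect_equal(unname(fr$center_of_mass[3]), 5, tolerance = 1e-9)
  expect_equal(fr$body_width, 4)
  # orthonormal frame
  expect_equal(sum(fr$anterior_direction^2), 1, tolerance = 1e-12)
  expect_equal(sum(fr$anterior_direction * fr$transverse_plane$normal), 0,
               tolerance = 1e-9)
  expect_equal(sum(fr$anterior_direction * fr$mediolateral_direction), 0,
               tolerance = 1e-9)
})

test_that("uniform density rescaling leaves the centre of mass unchanged", {
  vol <- make_vertebra_phantom(phantom_spec(voxel = 2, seed = 8))
  rho <- hu_to_density(vol, calibration_line())
  mesh <- label_surfaces(voxels_to_tets(vol, rho))
  f1 <- build_frame(mesh)
  mesh2 <- mesh
  mesh2$element_density <- 2 * mesh$element_density
  f2 <- build_frame(mesh2)
  expect_equal(f1$center_of_mass, f2$center_of_mass, tolerance = 1e-12)
})

test_that("phantom body width matches the generated node extent", {
  spec <- phantom_spec(semi_axis_ap = 14, semi_axis_ml = 18, voxel = 2,
                       seed = 3)
  vol <- make_vertebra_phantom(spec)
  mesh <- label_surfaces(voxels_to_tets(vol))
  fr <- build_frame(mesh)
  # oracle: direct anteroposterior extent of the node cloud
  expect_equal(fr$body_width, diff(range(mesh$nodes[, 2])))
  expect_lt(abs(fr$body_width - 2 * 14), 2 * spec$voxel + 1e-9)
})

test_that("control point sits on the cranial plane at 10% of width", {
  fx <- vertebra_fixture(seed = 21)
  fr <- fx$frame
  lc <- place_control_point(fr, fx$mesh, offset_fraction = 0.10)
  offset <- sum((lc$control_point - fr$center_of_mass) *
                fr$anterior_direction)
  expect_equal(offset / fr$body_width, 0.10, tolerance = 1e-9)
  expect_equal(unname(lc$control_point[3]),
               unname(fr$cranial_plane$point[3]), tolerance = 1e-9)
  # zero offset reduces to the centre-of-mass projection (centric load)
  lc0 <- place_control_point(fr, fx$mesh, offset_fraction = 0)
  expect_equal(sum((lc0$control_point - fr$center_of_mass) *
                   fr$anterior_direction), 0, tolerance = 1e-9)
})

test_that("body width of 40 mm places the point 4 mm anterior", {
  fx <- bar_fixture()
  fr <- fx$frame
  fr$body_width <- 40
  lc <- place_control_point(fr, fx$mesh, offset_fraction = 0.10)
  offset <- sum((lc$control_point - fr$center_of_mass) *
                fr$anterior_direction)
  expect_equal(offset, 4.0, tolerance = 1e-9)
})

test_that("meshes round-trip through the INP dialect", {
  fx <- vertebra_fixture(seed = 22)
  cards <- assign_materials(fx$mesh$element_density, material_law(),
                            n_bins = 4)
  f <- tempfile(fileext = ".inp")
  write_inp(fx$mesh, cards, fx$loadcase, f)
  back <- read_inp(f)
  expect_equal(back$nodes, unname(fx$mesh$nodes), tolerance = 1e-8)
  expect_equal(back$tets, fx$mesh$tets)
  expect_equal(back$node_sets$cranial, fx$mesh$node_sets$cranial)
  expect_equal(back$node_sets$caudal, fx$mesh$node_sets$caudal)
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$offset_fraction, 0.1)
})

test_that("volume is conserved under voxel refinement", {
  v1 <- make_vertebra_phantom(phantom_spec(height = 12, semi_axis_ap = 7,
                                           semi_axis_ml = 8, voxel = 2,
                                           seed = 1))
  v2 <- make_vertebra_phantom(phantom_spec(height = 12, semi_axis_ap = 7,
                                           semi_axis_ml = 8, voxel = 1,
                                           seed = 1))
  m1 <- voxels_to_tets(v1)
  m2 <- voxels_to_tets(v2)
  vol1 <- sum(tet_volumes(m1))
  vol2 <- sum(tet_volumes(m2))
  # one voxel layer on the lateral surface bounds the change
  lateral_area <- 2 * pi * sqrt(7 * 8) * 12
  expect_lt(abs(vol1 - vol2), lateral_area * 2)
})
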