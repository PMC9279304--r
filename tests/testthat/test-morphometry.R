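test_that("airway extraction needs airway voxels and keeps the largest component", {
  empty <- label_volume(array(0L, c(6, 6, 6)), 6)
  expect_error(extract_airway(empty), "no airway in bounds")

  lab <- array(0L, c(20, 8, 8))
  lab[1:6, 2:4, 2:4] <- 5L    # 54 voxels
  lab[10:12, 2:4, 2:4] <- 5L  # 27 voxels
  lab[16:17, 2:3, 2:3] <- 5L  # 8 voxels
  lv <- label_volume(lab, 6)
  mask <- extract_airway(lv)
  expect_equal(sum(mask), 54L)
  expect_true(all(which(mask, arr.ind = TRUE)[, 1] <= 6))

  # axial bounds restrict by physical z before component analysis
  lab2 <- array(0L, c(4, 4, 12))
  lab2[2:3, 2:3, 2:5] <- 5L
  lab2[2:3, 2:3, 8:11] <- 5L
  lv2 <- label_volume(lab2, 6, spacing = c(1, 1, 2)) # z spacing 2 mm
  m2 <- extract_airway(lv2, airway_bounds(superior_z = 23, inferior_z = 13))
  expect_true(all(which(m2, arr.ind = TRUE)[, 3] >= 8))
  expect_error(airway_bounds(1, 5), "superior")
})

test_that("airway volume converts voxel counts to cc", {
  expect_equal(airway_volume_cc(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)
  m <- array(FALSE, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(airway_volume_cc(m, c(1, 1, 1)), 1.0)
  cyl <- digitize_cylinder(c(40, 40, 50), rep(0.5, 3), r_mm = 8,
                           z_range_mm = c(2, 21.5), centre_mm = c(9.75, 9.75))
  expect_equal(airway_volume_cc(cyl, rep(0.5, 3)), pi * 64 * 20 / 1000,
               tolerance = 0.02)
})

test_that("cross-sectional areas: units, cylinder symmetry, hourglass waist", {
  one <- array(FALSE, c(8, 8, 1)); one[1:5, 1:2, 1] <- TRUE
  expect_equal(cross_sectional_areas(one, c(0.5, 0.5, 1)), 2.5)

  cyl <- digitize_cylinder(c(30, 30, 20), c(1, 1, 1), 8, c(0, 19), c(14.5, 14.5))
  areas <- cross_sectional_areas(cyl, c(1, 1, 1))
  expect_equal(length(unique(areas[areas > 0])), 1L)

  # hourglass: two cones tip to tip, waist at slice 11 of 21
  hour <- array(FALSE, c(21, 21, 21))
  for (k in 1:21) {
    r <- 1 + 8 * abs(k - 11) / 10
    hour[, , k] <- matrix(outer(1:21, 1:21, function(i, j)
      (i - 11)^2 + (j - 11)^2 <= r^2), 21, 21)
  }
  a <- cross_sectional_areas(hour, c(1, 1, 1))
  expect_equal(which.min(a), 11L)
  expect_error(cross_sectional_areas(array(FALSE, c(2, 2, 2)), c(1, 1, 1)),
               "empty")
})

test_that("narrowest point: analytic diameter, constructed waist, single voxel", {
  cyl <- digitize_cylinder(c(30, 30, 12), c(1, 1, 1), 5, c(0, 11), c(14.5, 14.5))
  np <- narrowest_point(cyl, c(1, 1, 1))
  expect_equal(np$narrowest_mm, 10, tolerance = 1 / 10) # within one voxel

  hour <- array(FALSE, c(15, 15, 9))
  for (k in 1:9) {
    half <- if (k == 5) 1L else 3L # 2-voxel-wide waist at slice 5
    hour[(8 - half):(7 + half), (8 - half):(7 + half), k] <- TRUE
  }
  nph <- narrowest_point(hour, c(0.5, 0.5, 0.5))
  expect_equal(nph$narrowest_mm, 1.0)
  expect_equal(nph$narrow_slice_z, (5 - 1) * 0.5)

  single <- array(FALSE, c(4, 4, 4)); single[2, 2, 2] <- TRUE
  expect_equal(narrowest_point(single, rep(0.25, 3))$narrowest_mm, 0.25)
})

test_that("slice areas integrate exactly to the voxel volume (discrete Fubini)", {
  for (s in 1:5) {
    mask <- withr::with_seed(s, array(runif(10 * 9 * 8) < 0.3, c(10, 9, 8)))
    if (!any(mask)) next
    sp <- withr::with_seed(s + 10, runif(3, 0.3, 2))
    areas <- cross_sectional_areas(mask, sp)
    expect_equal(sum(areas) * sp[3], sum(mask) * prod(sp), tolerance = 1e-12)
    np <- narrowest_point(mask, sp)
    expect_equal(np$min_csa_mm2, min(areas[areas > 0]))
  }
})

test_that("volume and min CSA are invariant to in-plane 90-degree rotation", {
  ph <- generate_head_phantom(phantom_config(shape = c(32, 32, 32), seed = 6,
                                             r_end = 4, r_waist = 2.5))
  mask <- extract_airway(ph$labels)
  rot <- array(FALSE, dim(mask))
  n <- dim(mask)[1]
  for (k in seq_len(dim(mask)[3]))
    rot[, , k] <- t(mask[, , k])[, n:1] # 90-degree in-plane rotation
  expect_equal(airway_volume_cc(rot, c(1, 1, 1)),
               airway_volume_cc(mask, c(1, 1, 1)))
  expect_equal(narrowest_point(rot, c(1, 1, 1))$min_csa_mm2,
               narrowest_point(mask, c(1, 1, 1))$min_csa_mm2)
})

test_that("STL export: cube area, sphere signed volume, closed orientable mesh", {
  cube <- array(FALSE, c(14, 14, 14)); cube[3:12, 3:12, 3:12] <- TRUE
  path <- withr::local_tempfile(fileext = ".stl")
  res <- export_stl(cube, c(1, 1, 1), path)
  mesh <- attr(res, "mesh")
  expect_equal(cbctseg:::mesh_area(mesh), 600, tolerance = 0.10)
  expect_true(file.exists(path))
  # binary STL: 80-byte header + 4-byte count + 50 bytes per triangle
  expect_equal(file.size(path), 84 + 50 * nrow(mesh$triangles))

  sph <- digitize_sphere(c(24, 24, 24), c(1, 1, 1), 8, c(11.5, 11.5, 11.5))
  msh <- cbctseg:::mask_to_mesh(sph, c(1, 1, 1))
  vox_cc <- airway_volume_cc(sph, c(1, 1, 1))
  expect_equal(cbctseg:::mesh_signed_volume(msh) / 1000, vox_cc,
               tolerance = 0.05)
  expect_error(export_stl(array(FALSE, c(3, 3, 3)), c(1, 1, 1),
                          tempfile()), "empty")
})

test_that("airway_metrics bundles the individual measures consistently", {
  ph <- generate_head_phantom(phantom_config(seed = 4))
  m <- airway_metrics(ph$labels)
  mask <- extract_airway(ph$labels)
  expect_equal(m$volume_cc, airway_volume_cc(mask, ph$labels$spacing))
  expect_equal(m$min_csa_mm2, min(m$areas_mm2[m$areas_mm2 > 0]))
  expect_true(all(m$min_csa_mm2 <= m$areas_mm2[m$areas_mm2 > 0]))
})
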