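test_that("voxelwise average of identical masks is the mask itself", {
  m <- ellipsoid_mask(11, 10, 10)
  tm <- voxelwise_average(list(m, m, m))
  expect_true(all(tm$probability_volume %in% c(0, 1)))
  expect_equal(sum(tm$probability_volume), sum(m$voxels))
  # thresholding at 0.5 reproduces the mask voxel count exactly
  expect_equal(sum(tm$probability_volume >= 0.5), sum(m$voxels))
})

test_that("partially overlapping masks average to 0.5 where one contributes", {
  a <- array(FALSE, c(9, 9, 9)); a[4:6, 5, 5] <- TRUE  # row along x
  b <- array(FALSE, c(9, 9, 9)); b[5, 4:6, 5] <- TRUE  # row along y
  tm <- voxelwise_average(list(eye_mask(a), eye_mask(b)), grid_shape = c(9, 9, 9))
  p <- tm$probability_volume
  expect_equal(p[5, 5, 5], 1)          # shared center after centering
  expect_equal(p[4, 5, 5], 0.5)        # contributed by one mask only
  expect_equal(p[5, 4, 5], 0.5)
  expect_equal(sort(unique(as.vector(p))), c(0, 0.5, 1))
  expect_error(voxelwise_average(list()), "no masks")
})

test_that("centered random-orientation phantoms pile probability at the center", {
  set.seed(12)
  masks <- lapply(1:10, function(i)
    ellipsoid_mask(12.8, 12.15, 11.8, rotation = runif(3, -15, 15)))
  tm <- voxelwise_average(masks)
  ctr <- (dim(tm$probability_volume) + 1) / 2
  expect_gte(tm$probability_volume[ctr[1], ctr[2], ctr[3]], 0.9)
})

test_that("self-alignment returns the identity transform", {
  m <- ellipsoid_mask(13, 11.5, 10)
  tm <- voxelwise_average(list(m))
  tr <- rigid_align(m, tm)
  expect_lt(max(abs(tr$translation)), 0.35)  # half a voxel
  expect_lt(max(abs(tr$rotation)), 1)
})

test_that("a known translation is recovered", {
  m <- ellipsoid_mask(13, 11.5, 10)
  tm <- voxelwise_average(list(m))
  shifted <- make_eye_mask(eye_phantom_spec(
    13, 11.5, 10, center = c(3, -2, 1) * 0.7, grid_shape = c(49, 49, 49)))
  tr <- rigid_align(shifted, tm)
  # centroid matching plus refinement must land the shape on the template
  resampled <- apply_rigid_transform(shifted, tr, tm)
  expect_gt(dice(resampled >= 0.5, tm$probability_volume >= 0.5), 0.98)
  expect_lt(rotation_residual_deg(tr$rotation, c(0, 0, 0)), 1)
})

test_that("a 15-degree rotation is recovered within 2 degrees", {
  m <- ellipsoid_mask(13, 11.5, 10)
  tm <- voxelwise_average(list(m))
  rotated <- ellipsoid_mask(13, 11.5, 10, rotation = c(0, 0, 15))
  tr <- rigid_align(rotated, tm)
  expect_lt(rotation_residual_deg(tr$rotation, c(0, 0, 15)), 2)
  expect_false(tr$warning_flag)
})

test_that("translated copies of one shape rebuild it as a group template", {
  src <- ellipsoid_mask(12.8, 12.15, 11.8)
  masks <- lapply(list(c(0, 0, 0), c(2.1, -1.4, 0.7), c(-1.4, 0.7, 2.1),
                       c(0.7, 2.1, -0.7)), function(ctr)
    make_eye_mask(eye_phantom_spec(12.8, 12.15, 11.8, center = ctr,
                                   grid_shape = c(47, 47, 47))))
  tm <- build_group_template(masks)
  g <- dim(tm$final_mask)
  ref <- array(FALSE, g)
  d <- dim(src$voxels); off <- floor((g - d) / 2)
  ref[off[1] + 1:d[1], off[2] + 1:d[2], off[3] + 1:d[3]] <- src$voxels
  expect_gte(dice(tm$final_mask, ref), 0.98)
  expect_true(all(tm$probability_volume >= 0 & tm$probability_volume <= 1))
  expect_error(build_group_template(masks[1]), "insufficient masks")
})

test_that("template building is invariant to the order of the masks", {
  set.seed(21)
  masks <- lapply(1:4, function(i)
    ellipsoid_mask(12.8, 12.15, 11.8, rotation = runif(3, -10, 10)))
  t1 <- build_group_template(masks)
  t2 <- build_group_template(rev(masks))
  expect_equal(t1$probability_volume, t2$probability_volume, tolerance = 1e-12)
  expect_identical(t1$final_mask, t2$final_mask)
})

test_that("template morphometry recovers the common phantom geometry", {
  set.seed(33)
  masks <- lapply(1:4, function(i)
    ellipsoid_mask(12.8, 12.15, 12.15, rotation = runif(3, -10, 10)))
  tm <- build_group_template(masks)
  res <- measure_eye(template_to_mask(tm))
  expect_lt(abs(res$axial_length - 25.6), 0.7)
  expect_lt(abs(res$transverse_length - 24.3), 0.7)
})

test_that("group templates separate myopic elongation from control sphericity", {
  set.seed(44)
  mk <- function(ap, eq, n) lapply(1:n, function(i)
    ellipsoid_mask(ap / 2, eq / 2, eq / 2, rotation = runif(3, -10, 10)))
  masks <- c(mk(23.2, 23.2, 4), mk(25.6, 24.3, 4))
  groups <- rep(c("control", "myopia"), each = 4)
  t_con <- build_group_template(masks, groups, "control")
  t_myo <- build_group_template(masks, groups, "myopia")
  a_con <- measure_eye(template_to_mask(t_con))$anisotropy
  a_myo <- measure_eye(template_to_mask(t_myo))$anisotropy
  expect_gt(a_myo, a_con)
})

test_that("a posterior bump survives into the group template surface", {
  set.seed(55)
  bumped <- lapply(1:4, function(i)
    make_eye_mask(eye_phantom_spec(12.3, 12.1, 12.1, bump_amplitude = 1.2,
                                   bump_direction = c(-0.5, -1, -0.5),
                                   rotation = runif(3, -8, 8))))
  plain <- lapply(1:4, function(i)
    make_eye_mask(eye_phantom_spec(12.3, 12.1, 12.1,
                                   rotation = runif(3, -8, 8))))
  masks <- c(bumped, plain)
  groups <- rep(c("glaucoma", "control"), each = 4)
  t_g <- build_group_template(masks, groups, "glaucoma")
  t_c <- build_group_template(masks, groups, "control")
  # max radial surface extent along the bump direction, from the grid center
  reach <- function(tm) {
    pts <- eyemorph:::voxel_centers_mm(
      tm$final_mask, tm$voxel_size,
      -(dim(tm$final_mask) - 1) / 2 * tm$voxel_size)
    u <- eyemorph:::unit_vector(c(-0.5, -1, -0.5))
    proj <- as.vector(pts %*% u)
    r <- sqrt(rowSums(pts^2))
    ang_ok <- r > 1 & proj / pmax(r, 1e-9) > cos(30 * pi / 180)
    max(proj[ang_ok])
  }
  expect_gt(reach(t_g), reach(t_c) + 0.35)
})
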