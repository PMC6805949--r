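test_that("surface extraction is subvoxel-accurate on a digitized sphere", {
  m <- sphere_mask(11.6)
  s <- extract_surface(m)
  radii <- sqrt(rowSums(s^2))
  expect_lt(abs(mean(radii) - 11.6), 0.35)
  expect_lt(max(abs(radii - 11.6)), 0.7)
})

test_that("degenerate masks are rejected", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_error(extract_surface(eye_mask(one)), "invalid mask")
  two <- array(FALSE, c(21, 21, 21))
  two[5:8, 5:8, 5:8] <- TRUE
  two[14:17, 14:17, 14:17] <- TRUE
  expect_error(compute_volume(eye_mask(two)), "invalid mask")
  touching <- array(TRUE, c(4, 4, 4))
  expect_error(validate_eye_mask(eye_mask(touching)), "boundary")
})

test_that("a single interior voxel has the voxel volume", {
  one <- array(FALSE, c(5, 5, 5)); one[3, 3, 3] <- TRUE
  expect_equal(compute_volume(eye_mask(one, voxel_size = 0.7)), 0.7^3)
})

test_that("the corneal apex sits at the anterior pole", {
  m <- strip_landmarks(ellipsoid_mask(12.8, 12.15, 12.15))
  apex <- find_corneal_apex(m)
  expect_lt(max(abs(apex - c(0, 12.8, 0))), 0.5 * 0.7 + 1e-9)
  # generator landmark agrees within a voxel
  m2 <- ellipsoid_mask(12.8, 12.15, 12.15)
  expect_lt(sqrt(sum((find_corneal_apex(m2) - m2$landmarks$apex)^2)), 0.7)
})

test_that("the optic-disk point passes through or falls back to the posterior pole", {
  m <- ellipsoid_mask(12.8, 12.15, 12.15)
  expect_equal(find_optic_disk(m), m$landmarks$disk)  # passthrough
  mf <- strip_landmarks(m)
  expect_lt(sqrt(sum((find_optic_disk(mf) - c(0, -12.8, 0))^2)), 0.7)
  sp <- strip_landmarks(sphere_mask(11.6))
  apex <- find_corneal_apex(sp)
  disk <- find_optic_disk(sp)
  expect_lt(sqrt(sum((disk + apex)^2)), 0.7)  # antipode of the apex
})

test_that("the eye axis matches the anatomical axis and rotates equivariantly", {
  m <- ellipsoid_mask(12.8, 11.8, 11.8)
  fr <- build_axis_frame(m)
  ang <- acos(abs(sum(fr$eye_axis * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 1)
  # rotate the phantom 10 degrees about the superoinferior axis
  mr <- ellipsoid_mask(12.8, 11.8, 11.8, rotation = c(0, 0, 10))
  frr <- build_axis_frame(mr)
  ang10 <- acos(abs(sum(frr$eye_axis *
                          c(-sin(10 * pi / 180), cos(10 * pi / 180), 0)))) * 180 / pi
  expect_lt(ang10, 1)
  # sphere: axis passes near the center
  sp <- sphere_mask(11.6)
  fs <- build_axis_frame(sp)
  d_center <- sqrt(sum((fs$apex - sum(fs$apex * fs$eye_axis) * fs$eye_axis)^2))
  expect_lt(d_center, 0.5 * 0.7 + 1e-9)
})

test_that("near-coincident landmarks are rejected", {
  m <- ellipsoid_mask()
  expect_error(build_axis_frame(m, apex = c(0, 12.15, 0), disk = c(0, 9, 0)),
               "degenerate landmarks")
})

test_that("axial length recovers known diameters within one voxel", {
  expect_lt(abs(measure_axial_length_of(sphere_mask(11.6)) - 23.2), 0.7)
  expect_lt(abs(measure_axial_length_of(ellipsoid_mask(12.8, 12.15, 12.15)) -
                  25.6), 0.7)
})

test_that("length measurement is homogeneous under scaling", {
  a <- make_eye_mask(eye_phantom_spec(11, 10, 10, voxel_size = 0.7))
  b <- make_eye_mask(eye_phantom_spec(22, 20, 20, voxel_size = 1.4))
  fa <- build_axis_frame(a); fb <- build_axis_frame(b)
  expect_equal(measure_axial_length(b, fb),
               2 * measure_axial_length(a, fa), tolerance = 1e-6)
})

test_that("transverse length recovers the equatorial diameter and symmetries", {
  m <- ellipsoid_mask(12.8, 12.15, 12.15)
  fr <- build_axis_frame(m)
  expect_lt(abs(measure_transverse_length(m, fr) - 24.3), 0.7)
  sp <- sphere_mask(11.6)
  fs <- build_axis_frame(sp)
  expect_lt(abs(measure_transverse_length(sp, fs) -
                  measure_axial_length(sp, fs)), 0.7)
  # swapping the anteroposterior and equatorial semi-axes swaps the readings
  pro <- measure_eye(ellipsoid_mask(12.5, 11.0, 11.0))
  obl <- measure_eye(ellipsoid_mask(11.0, 12.5, 12.5))
  expect_lt(abs(pro$axial_length - obl$transverse_length), 0.7)
  expect_lt(abs(pro$transverse_length - obl$axial_length), 0.7)
})

test_that("whole-eye measurement composes its parts consistently", {
  r <- measure_eye(sphere_mask(11.6))
  expect_lt(abs(r$anisotropy - 1), 0.01)
  r2 <- measure_eye(ellipsoid_mask(12.8, 12.15, 12.15))
  expect_lt(abs(r2$anisotropy - 25.6 / 24.3), 0.01)
  expect_identical(r2$anisotropy, r2$axial_length / r2$transverse_length)
  expect_gt(r2$axial_length, r2$transverse_length)  # anisotropy > 1
})

test_that("measurements are stable under rigid rotation of the mask", {
  base <- measure_eye(ellipsoid_mask(12.8, 12.15, 11.8))
  set.seed(31)
  for (i in 1:6) {
    r <- measure_eye(ellipsoid_mask(12.8, 12.15, 11.8,
                                    rotation = runif(3, -40, 40)))
    expect_lt(abs(r$axial_length - base$axial_length), 0.7)
    expect_lt(abs(r$transverse_length - base$transverse_length), 0.7)
    expect_lt(abs(r$volume - base$volume) / base$volume, 0.02)
  }
})

test_that("random ellipsoids are digitized and measured consistently", {
  set.seed(17)
  for (i in 1:4) {
    ax <- sort(runif(3, 10, 14), decreasing = TRUE)
    m <- ellipsoid_mask(ax[1], ax[2], ax[3])
    r <- measure_eye(m)
    expect_lt(abs(r$axial_length - 2 * ax[1]), 0.7)
    expect_lt(abs(r$transverse_length - 2 * ax[2]), 0.7)
    analytic <- 4 / 3 * pi * prod(ax)
    expect_lt(abs(r$volume - analytic) / analytic, 0.02)
  }
})

test_that("refining the voxel grid reduces the worst-case length error", {
  set.seed(5)
  worst <- sapply(c(1.4, 0.7), function(v) {
    errs <- sapply(1:3, function(i) {
      ax <- sort(runif(3, 10, 14), decreasing = TRUE)
      m <- make_eye_mask(eye_phantom_spec(ax[1], ax[2], ax[3], voxel_size = v))
      r <- measure_eye(m)
      max(abs(r$axial_length - 2 * ax[1]),
          abs(r$transverse_length - 2 * ax[2]))
    })
    max(errs)
  })
  expect_lt(worst[2], worst[1])
})
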