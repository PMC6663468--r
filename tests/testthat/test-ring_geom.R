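presets <- strain_presets()

test_that("radial profile peaks at a torus radius and is flat for uniform input", {
  tor <- torus_volume(28, d = 80, voxel_size_nm = 1, sigma_nm = 1.5)
  prof <- radial_profile(tor, c(-3, 3))
  peak <- prof$radius_nm[which.max(prof$density)]
  expect_lt(abs(peak - 28), 0.5)
  expect_equal(as.numeric(measure_ring_diameter(prof, c(20, 36))), 56,
               tolerance = 0.02)

  unif <- volume(array(3.7, rep(32, 3)))
  pu <- radial_profile(unif, c(-5, 5))
  expect_equal(sd(pu$density), 0)
  expect_error(radial_profile(unif, c(100, 120)), "empty slab")
})

test_that("cylindrical averaging commutes with symmetrization", {
  # smooth subunits: the identity is exact for continuous resampling and
  # holds to interpolation error on the grid
  cfg <- strain_config(cring_tilt_deg = 3, blob_sigma_nm = 2.5)
  ph <- build_motor_phantom(cfg)
  p0 <- radial_profile(ph, c(-15, -4))
  p16 <- radial_profile(symmetrize(ph, 16), c(-15, -4))
  expect_lt(max(abs(p0$density - p16$density)) / max(p0$density), 0.02)
})

test_that("diameter measurement is robust to voxel size and z translation", {
  d1 <- measure_ring_diameter(
    radial_profile(torus_volume(28, d = 80, voxel_size_nm = 1), c(-3, 3)),
    c(20, 36))
  d2 <- measure_ring_diameter(
    radial_profile(torus_volume(28, d = 40, voxel_size_nm = 2), c(-3, 3)),
    c(20, 36))
  expect_lt(abs(as.numeric(d1) - as.numeric(d2)), 2)

  shifted <- torus_volume(28, d = 80, voxel_size_nm = 1, z_nm = 6)
  d3 <- measure_ring_diameter(radial_profile(shifted, c(3, 9)), c(20, 36))
  expect_equal(as.numeric(d3), as.numeric(d1), tolerance = 1e-6)
})

test_that("a boundary peak raises the boundary flag", {
  tor <- torus_volume(28, d = 80, voxel_size_nm = 1)
  prof <- radial_profile(tor, c(-3, 3))
  expect_warning(dm <- measure_ring_diameter(prof, c(28, 36)), "boundary")
  expect_true(attr(dm, "boundary"))
})

test_that("tilt estimator: untilted wall reads zero, extreme angle recovered", {
  flat <- strain_config(name = "flat", cring_tilt_deg = 0)
  expect_lt(cring_tilt_angle(build_motor_phantom(flat))$tilt_deg, 0.5)

  # 45 degree wall: shorten the wall so the top radius stays in the box
  steep <- strain_config(name = "steep", cring_tilt_deg = 45,
                         cring_wall_height_nm = 8)
  tr <- cring_tilt_angle(build_motor_phantom(steep),
                         tilt_config(z_window = c(-12, -4)))
  expect_lt(abs(tr$tilt_deg - 45), 1)
})

test_that("left and right walls agree on a symmetrized map", {
  tr <- cring_tilt_angle(build_motor_phantom(presets$D24N))
  expect_lt(abs(tr$left_deg - tr$right_deg), 1)
  expect_false(tr$quality_flag)
})

test_that("moments and algebraic conic fits agree on noiseless phantoms", {
  for (s in c("WT", "dmotB")) {
    tr <- cring_tilt_angle(build_motor_phantom(presets[[s]]))
    for (side in c("left", "right")) {
      pts <- tr$points[[side]]
      conic <- motoret:::conic_ellipse_angle(pts$x, pts$z, pts$w)
      expect_lt(abs(conic - tr$fit[[side]]$major_axis_angle_deg), 0.5)
    }
  }
})

test_that("the tilt estimator errors on empty density", {
  expect_error(cring_tilt_angle(volume(array(0, rep(64, 3)),
                                       voxel_size_nm = 1.25)),
               "insufficient|Insufficient")
})

test_that("unrolled maps transfer symmetry and uniformity", {
  ring8 <- ring_volume(8, radius_nm = 20, d = 64)
  un <- unroll_map(ring8, c(16, 24), c(-4, 4), angular_samples = 256)
  theta_profile <- apply(unclass(un), 1, mean)
  ft <- Mod(fft(theta_profile))^2
  orders <- ft[2:33]
  expect_equal(which.max(orders), 8L)   # period 360/8
  # autocorrelation peak at one period
  shift <- 256 / 8
  expect_gt(cor(theta_profile, c(theta_profile[-(1:shift)],
                                 theta_profile[1:shift])), 0.99)

  # WT phantom unrolled at the stator radius shows 16 maxima
  ph <- build_motor_phantom(presets$WT, rep(TRUE, 16))
  unw <- unroll_map(ph, c(36, 44), c(-7, 1), angular_samples = 256)
  prof <- apply(unclass(unw), 1, mean)
  expect_equal(which.max((Mod(fft(prof))^2)[2:41]), 16L)

  unif <- volume(array(2, rep(32, 3)))
  uu <- unroll_map(unif, c(4, 10), c(-4, 4), angular_samples = 64)
  expect_lt(max(abs(uu - 2)), 1e-9)

  expect_error(unroll_map(unif, c(0, 10), c(-4, 4)), "axis")
})
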