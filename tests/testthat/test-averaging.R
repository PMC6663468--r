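w60 <- wedge_spec()

test_that("constrained cross-correlation has the expected fixed points", {
  set.seed(31)
  a <- noise_volume(32)
  expect_equal(constrained_cc(a, a, wedge_a = w60, wedge_b = w60), 1,
               tolerance = 1e-6)
  expect_equal(constrained_cc(a, volume(-a$data)), -1, tolerance = 1e-6)
  b <- noise_volume(64)
  a64 <- noise_volume(64)
  expect_lt(abs(constrained_cc(a64, b)), 0.05)
})

test_that("an empty wedge intersection is an error", {
  d <- rep(16L, 3)
  m1 <- array(FALSE, d); m1[2, 1, 1] <- TRUE
  m2 <- array(FALSE, d); m2[3, 1, 1] <- TRUE
  v <- noise_volume(16)
  expect_error(constrained_cc(v, v, wedge_a = m1, wedge_b = m2),
               "wedge intersection")
})

test_that("alignment recovers known transforms within the grid resolution", {
  set.seed(32)
  d <- 32
  ref <- blob_volume(d, rbind(c(20, 16, 16), c(16, 16, 22), c(12, 18, 14)),
                     sigma = 2)
  # pure z rotation: expect the inverse back
  part <- apply_pose(ref, pose(c(10, 0, 0)))
  res <- align_particle(part, ref,
                        search_spec(angular_grid_deg = 2,
                                    max_axis_rot_deg = 16))
  expect_lt(abs(z_rotation_deg(res$pose) - (-10)), 1)
  expect_gt(res$score, 0.99)
  # identity in, identity out
  res_id <- align_particle(ref, ref,
                           search_spec(angular_grid_deg = 4,
                                       max_axis_rot_deg = 8))
  expect_equal(res_id$pose$euler_deg, c(0, 0, 0))
  expect_equal(res_id$pose$shift_voxels, c(0, 0, 0))
  expect_equal(res_id$score, 1, tolerance = 1e-3)
  # shifts
  part_s <- apply_pose(ref, pose(c(0, 0, 0), c(2, -1, 0)))
  res_s <- align_particle(part_s, ref,
                          search_spec(angular_grid_deg = 4,
                                      max_axis_rot_deg = 4,
                                      max_shift_voxels = 3))
  expect_equal(res_s$pose$shift_voxels, c(-2, 1, 0))
})

test_that("alignment under the missing wedge recovers the transform", {
  set.seed(33)
  d <- 32
  ref <- blob_volume(d, rbind(c(20, 16, 16), c(16, 16, 22), c(12, 18, 14)),
                     sigma = 2)
  part <- apply_missing_wedge(apply_pose(ref, pose(c(10, 0, 0))), w60)
  res <- align_particle(part, ref,
                        search_spec(angular_grid_deg = 2,
                                    max_axis_rot_deg = 16), wedge = w60)
  expect_lt(abs(z_rotation_deg(res$pose) - (-10)), 1)
})

test_that("the focused axis-rotation cap is never exceeded", {
  set.seed(34)
  d <- 24
  ref <- blob_volume(d, rbind(c(15, 12, 12), c(10, 12, 16)), sigma = 2)
  part <- apply_pose(ref, pose(c(5, 0, 0)))   # outside the cap
  res <- align_particle(part, ref,
                        search_spec(angular_grid_deg = 1,
                                    max_axis_rot_deg = 1.9))
  expect_lte(abs(z_rotation_deg(res$pose)), 2)
  # within-cap perturbation is recovered
  part2 <- apply_pose(ref, pose(c(1.5, 0, 0)))
  res2 <- align_particle(part2, ref,
                         search_spec(angular_grid_deg = 1,
                                     max_axis_rot_deg = 1.9))
  expect_lt(abs(z_rotation_deg(res2$pose) - (-1.5)), 0.75)
  expect_gt(res2$score, res$score)            # clamped pose scores worse
})

test_that("fourier average of one particle is the wedge-filtered particle", {
  set.seed(35)
  v <- noise_volume(32)
  avg <- fourier_average(list(v), list(pose()), w60)
  expect_equal(avg$density$data, apply_missing_wedge(v, w60)$data,
               tolerance = 1e-10)
  expect_identical(avg$coverage > 0, wedge_mask(w60, rep(32L, 3)))
})

test_that("z-rotation series pools coverage far beyond a single wedge", {
  ph <- blob_volume(32, rbind(c(22, 16, 16), c(16, 16, 10)), sigma = 2.5)
  poses <- lapply(seq(0, 165, by = 15), function(a) pose(c(a, 0, 0)))
  parts <- lapply(poses, function(p)
    apply_missing_wedge(apply_pose(ph, pose_inverse(p)), w60))
  avg <- fourier_average(parts, poses, w60)
  covered <- mean(avg$coverage > 0)
  expect_gt(covered, 0.90)  # only the polar double cone stays dark
  expect_gt(covered, mean(wedge_mask(w60, rep(32L, 3))) + 0.15)
  # coverage conservation: pooled coverage equals the summed rotated masks
  man <- Reduce(`+`, lapply(poses, function(p)
    wedge_mask(w60, rep(32L, 3), rot = euler_to_matrix(p$euler_deg))))
  expect_equal(avg$coverage, man, ignore_attr = TRUE)
})

test_that("averaging noisy copies reduces the error like 1/sqrt(N)", {
  set.seed(36)
  d <- 24
  ph <- blob_volume(d, rbind(c(15, 12, 12), c(9, 14, 12)), sigma = 2.5)
  errs <- vapply(c(4, 16, 64), function(N) {
    ps <- lapply(seq_len(N), function(i)
      volume(ph$data + array(rnorm(d^3), rep(d, 3))))
    sqrt(mean((fourier_average(ps)$density$data - ph$data)^2))
  }, numeric(1))
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.2)
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.2)
})

test_that("fourier averaging is equivariant under a common rotation", {
  set.seed(37)
  ph <- blob_volume(32, rbind(c(21, 16, 16), c(16, 16, 11)), sigma = 3)
  poses <- lapply(c(0, 40, 75, 160), function(a) pose(c(a, 0, 0)))
  parts <- lapply(poses, function(p)
    apply_missing_wedge(apply_pose(ph, pose_inverse(p)), w60))
  avg1 <- fourier_average(parts, poses, w60)
  common <- pose(c(30, 0, 0))
  poses2 <- lapply(poses, function(p) pose_compose(common, p))
  avg2 <- fourier_average(parts, poses2, w60)
  rot1 <- apply_pose(avg1$density, common)
  # compare away from the box boundary (rotation truncates corners)
  ctr <- 9:24
  expect_lt(rel_rms(rot1$data[ctr, ctr, ctr], avg2$density$data[ctr, ctr, ctr]),
            0.15)
})

test_that("half-set FSC behaves at its fixed points", {
  set.seed(38)
  v <- noise_volume(32)
  dup <- rep(list(v), 10)
  fsc <- split_half_fsc(dup, wedge = w60, seed = 5)
  expect_true(all(abs(fsc$correlation - 1) < 1e-6))

  pure <- lapply(1:10, function(i) noise_volume(32))
  fscn <- split_half_fsc(pure, seed = 6)
  expect_lt(abs(mean(fscn$correlation[-(1:3)])), 0.1)

  # estimator is symmetric in the two halves
  a1 <- fourier_average(pure[1:5])
  a2 <- fourier_average(pure[6:10])
  expect_equal(motoret:::fsc_between(a1, a2)$correlation,
               motoret:::fsc_between(a2, a1)$correlation)
  expect_error(split_half_fsc(pure[1]), "two particles")
})

test_that("resolution_at crosses thresholds like a brute-force scan", {
  curve <- structure(data.frame(shell_radius = seq(0, 0.4, by = 0.025),
                                correlation = 1), class = c("fsc_curve", "data.frame"))
  expect_equal(resolution_at(curve, 0.5), 0.4)  # never crosses -> Nyquist

  step <- curve
  step$correlation <- ifelse(step$shell_radius < 0.2, 1, 0)
  expect_lt(abs(resolution_at(step, 0.5) - 0.2), 0.025)

  mono <- curve
  mono$correlation <- seq(1, 0, length.out = nrow(mono))
  # brute-force linear scan oracle
  oracle <- function(cv, thr) {
    r <- cv$shell_radius[-1]; cc <- cv$correlation[-1]
    for (i in seq_along(cc)) {
      if (cc[i] < thr) {
        if (i == 1) return(r[1])
        return(r[i - 1] + (cc[i - 1] - thr) / (cc[i - 1] - cc[i]) *
                 (r[i] - r[i - 1]))
      }
    }
    max(r)
  }
  for (thr in c(0.143, 0.5, 0.9))
    expect_equal(resolution_at(mono, thr), oracle(mono, thr))
  expect_error(resolution_at(mono, 1.5), "threshold")
  expect_error(resolution_at(mono[0, ], 0.5), "empty")
})
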