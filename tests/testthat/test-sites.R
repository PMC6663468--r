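presets <- strain_presets()

test_that("site subvolumes of a fully occupied motor are interchangeable", {
  ph <- build_motor_phantom(presets$CCCP)
  sites <- extract_site_subvolumes(ph)
  expect_length(sites, 16)
  ref <- as.numeric(sites[[1]]$data)
  for (k in 2:16)
    expect_gt(cor(ref, as.numeric(sites[[k]]$data)), 0.99)
})

test_that("a single occupied site stands out against fifteen empty ones", {
  flags <- rep(FALSE, 16); flags[1] <- TRUE
  ph <- build_motor_phantom(presets$CCCP, flags)
  sites <- extract_site_subvolumes(ph)
  smask <- stator_site_mask(sites[[1]])
  scores <- vapply(sites, motoret:::site_score, numeric(1),
                   stator_mask = smask)
  others <- scores[-1]
  expect_gt(scores[1], max(others) + 5 * (sd(others) + 1e-9))
})

test_that("extraction commutes with a global collar rotation", {
  ph <- build_motor_phantom(presets$CCCP)
  rot <- apply_pose(ph, pose(c(360 / 16, 0, 0)))
  sites0 <- extract_site_subvolumes(ph)
  sites1 <- extract_site_subvolumes(rot)
  # a rotation by one site spacing shifts the site list cyclically
  for (k in 1:16) {
    partner <- (k %% 16) + 1
    expect_gt(cor(as.numeric(sites1[[k]]$data),
                  as.numeric(sites0[[partner]]$data)), 0.98)
  }
})

test_that("an out-of-bounds site box is rejected", {
  ph <- build_motor_phantom(presets$CCCP)
  expect_error(extract_site_subvolumes(ph, site_radius_nm = 55, box_nm = 30),
               "outside")
})

test_that("focused site alignment honours and enforces the 2 degree cap", {
  ph <- build_motor_phantom(presets$CCCP)
  sites <- extract_site_subvolumes(ph)[1:3]
  sch <- search_spec(angular_grid_deg = 0.5, max_axis_rot_deg = 1.9,
                     max_shift_voxels = 1)
  expect_error(focused_align_sites(sites, sites[[1]],
                                   search_spec(max_axis_rot_deg = 5)),
               "max_axis_rot_deg < 2")
  # already aligned -> identity refinements
  al <- focused_align_sites(sites, sites[[1]], sch)
  for (a in al) {
    expect_equal(a$pose$euler_deg, c(0, 0, 0))
    expect_equal(a$pose$shift_voxels, c(0, 0, 0))
  }
  # a 1.5 degree perturbation is recovered within the grid step
  pert <- apply_pose(sites[[1]], pose(c(1.5, 0, 0)))
  a <- focused_align_sites(list(pert), sites[[1]], sch)[[1]]
  expect_lt(abs(z_rotation_deg(a$pose) - (-1.5)), 0.5)
  # a 5 degree perturbation clamps at the boundary with a worse score
  pert5 <- apply_pose(sites[[1]], pose(c(5, 0, 0)))
  a5 <- focused_align_sites(list(pert5), sites[[1]], sch)[[1]]
  expect_lte(abs(z_rotation_deg(a5$pose)), 2)
  expect_lt(a5$score, a$score)
})

test_that("mixture classification separates well-separated score classes", {
  set.seed(51)
  truth <- runif(1000) < 0.5
  scores <- ifelse(truth, rnorm(1000, 6, 1), rnorm(1000, 0, 1))
  labels <- classify_sites(scores)
  wrong <- sum((labels == "occupied") != truth & labels != "ambiguous")
  expect_lt(wrong / 1000, 0.01)
  # agrees with an independent mixture fit (mclust)
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  fit <- Mclust(scores, G = 2, modelNames = "V", verbose = FALSE)
  hi <- which.max(fit$parameters$mean)
  conf <- fit$z[, hi] >= 0.8
  agree <- mean((labels == "occupied")[conf] == (truth)[conf])
  expect_gt(agree, 0.99)
})

test_that("classification handles degenerate and unimodal score sets", {
  expect_true(all(classify_sites(rep(1.3, 20)) == "ambiguous"))
  set.seed(52)
  # unimodal near zero -> all empty (background-subtracted convention)
  expect_true(all(classify_sites(rnorm(100, 0, 1)) == "empty"))
  # unimodal far above its own spread -> all occupied
  expect_true(all(classify_sites(rnorm(100, 8, 1)) == "occupied"))
})

test_that("a single occupied site among fifteen is found at SNR 1", {
  cfg <- strain_config(name = "one", stator_occupancy = 1,
                       occupancy_kind = "count")
  spec <- simulation_spec(cfg, n_motors = 2, box_voxels = 80, snr = 1,
                          seed = 53)
  sim <- simulate_ensemble(spec)
  res <- analyze_stator_sites(sim$stack, sim$particles, cfg, seed = 53)
  truth <- unlist(sim$truth$flags)
  expect_true(all(res$labels[truth] == "occupied"))
  expect_equal(sum(res$labels == "occupied"), sum(truth))
})

test_that("occupancy follows its definition, order-free and monotone", {
  lab <- c(rep("occupied", 10), rep("empty", 6))
  est <- estimate_occupancy(lab)
  expect_equal(est$occupancy, 0.625)
  expect_equal(est$mean_stators_per_motor, 10)

  est16 <- estimate_occupancy(rep("occupied", 16))
  expect_equal(est16$occupancy, 1)
  expect_equal(est16$mean_stators_per_motor, 16)

  # ambiguous sites stay in the denominator
  mixed <- c(rep("occupied", 5), rep("empty", 3), rep("ambiguous", 2))
  expect_equal(estimate_occupancy(mixed)$occupancy, 0.5)

  # permutation invariance
  set.seed(54)
  shuf <- sample(mixed)
  expect_equal(estimate_occupancy(shuf)$occupancy, 0.5)

  expect_error(estimate_occupancy(character(0)), "at least one")
  expect_error(estimate_occupancy(c("occupied", "bad")), "invalid")

  # raising the posterior threshold never adds committed labels
  set.seed(55)
  scores <- c(rnorm(100, 0, 1), rnorm(100, 4, 1))
  committed <- vapply(c(0.8, 0.9, 0.99), function(thr) {
    lab <- classify_sites(scores, posterior_threshold = thr)
    sum(lab != "ambiguous")
  }, numeric(1))
  expect_true(all(diff(committed) <= 0))
})
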