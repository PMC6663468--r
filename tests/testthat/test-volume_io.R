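test_that("MRC volumes round-trip bit-exactly and carry the header voxel size", {
  d <- 16L
  ramp <- array(as.numeric(seq_len(d^3)), rep(d, 3))
  vol <- volume(ramp, voxel_size_nm = 0.25)   # 2.5 Angstrom pixels
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(back$data, vol$data)
  expect_equal(back$voxel_size_nm, 0.25)
  expect_equal(back$origin_voxel, vol$origin_voxel)

  # arbitrary float32-representable data: zero loss
  set.seed(1)
  v2 <- volume(array(round(rnorm(32^3) * 1024) / 1024, rep(32, 3)),
               voxel_size_nm = 1)
  write_volume(v2, path)
  expect_equal(max(abs(read_volume(path)$data - v2$data)), 0)

  # header cell = dims * 10 Angstrom for a 1 nm voxel
  con <- file(path, "rb")
  hdr <- readBin(con, "numeric", n = 13, size = 4, endian = "little")
  close(con)
  expect_equal(hdr[11:13], rep(320, 3))  # 32 voxels * 10 A
})

test_that("malformed MRC inputs are rejected", {
  path <- withr::local_tempfile(fileext = ".mrc")
  write_volume(volume(array(0, rep(16, 3))), path)
  raw_all <- readBin(path, "raw", n = file.size(path))
  writeBin(raw_all[1:2000], path)          # truncated data block
  expect_error(read_volume(path), "truncated")
  writeBin(raw_all[1:100], path)           # truncated header
  expect_error(read_volume(path), "truncated|malformed")
  expect_error(read_volume(file.path(tempdir(), "does-not-exist.mrc")),
               "exist")
  bad <- array(1, rep(16, 3)); bad[1] <- NaN
  expect_error(volume(bad), "finite")
})

test_that("particle tables round-trip through TSV with extra columns preserved", {
  tab <- particle_table(data.frame(
    particle_id = sprintf("p%02d", 1:10),
    motor_id = rep(c("m1", "m2"), 5),
    site_index = c(0:7, NA, 15L),
    phi = seq(-170, 190, length.out = 10),  # 190 wraps to -170
    theta = 5, psi = -12.5, dx = 0.5, dy = -1, dz = 0,
    score = runif(10), class_label = "unset",
    tomogram = sprintf("tomo%d", 1:10),     # unknown column
    stringsAsFactors = FALSE))
  expect_equal(tab$phi[10], -170)           # euler normalized to [-180, 180)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_particles(tab, path)
  back <- read_particles(path)
  expect_equal(as.data.frame(back), as.data.frame(tab))
  expect_true("tomogram" %in% names(back))
})

test_that("particle table invariants are enforced", {
  expect_error(particle_table(data.frame(particle_id = c("a", "a"))),
               "duplicate")
  expect_error(particle_table(data.frame(particle_id = "a", site_index = 16L)),
               "site_index")
  expect_error(particle_table(data.frame(particle_id = "a",
                                         class_label = "maybe")),
               "class_label")
  # header-only table reads back as an empty table
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("particle_id", "motor_id", "site_index", "phi", "theta",
                     "psi", "dx", "dy", "dz", "score", "class_label"),
                   collapse = "\t"), path)
  expect_equal(nrow(read_particles(path)), 0L)
})

test_that("pose transform followed by its inverse recovers a smooth blob", {
  d <- 48   # blob well inside the box so rotation never truncates it
  ctr <- expand.grid(x = 0:(d - 1), y = 0:(d - 1), z = 0:(d - 1))
  blob <- array(exp(-((ctr$x - 24)^2 + (ctr$y - 21)^2 + (ctr$z - 26)^2) /
                      (2 * 25)), rep(d, 3))
  vol <- volume(blob, voxel_size_nm = 1)
  for (p in list(pose(c(25, 10, -40), c(1.5, -2, 0.5)),
                 pose(c(-120, 35, 80), c(0, 1, -1)))) {
    rt <- apply_pose(apply_pose(vol, p), pose_inverse(p))
    expect_lt(rel_rms(rt, vol), 0.02)
  }
})

test_that("pose algebra: compose and invert are consistent", {
  p1 <- pose(c(30, 20, -10), c(1, 2, 3))
  p2 <- pose(c(-45, 5, 60), c(-2, 0, 1))
  comp <- pose_compose(p2, p1)
  # matrices agree
  expect_equal(euler_to_matrix(comp$euler_deg),
               euler_to_matrix(p2$euler_deg) %*% euler_to_matrix(p1$euler_deg),
               tolerance = 1e-12)
  ident <- pose_compose(pose_inverse(p1), p1)
  expect_equal(euler_to_matrix(ident$euler_deg), diag(3), tolerance = 1e-12)
  expect_equal(ident$shift_voxels, c(0, 0, 0), tolerance = 1e-12)
})
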