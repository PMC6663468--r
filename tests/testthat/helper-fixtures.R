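# Small volumes built in code; all fixtures are generated at test time.

# volume made of Gaussian blobs at voxel-coordinate centres
blob_volume <- function(d = 32, centers, sigma = 2.5, amp = 1,
                        voxel_size_nm = 1) {
  centers <- matrix(centers, ncol = 3)
  arr <- array(
    motoret:::render_blobs_cpp(rep(as.integer(d), 3), centers,
                               rep(sigma, nrow(centers)),
                               rep(amp, nrow(centers))),
    rep(d, 3))
  volume(arr, voxel_size_nm = voxel_size_nm)
}

# ring of n blobs of radius r (nm) at height z (nm), centred on the grid
ring_volume <- function(n, radius_nm, d = 64, voxel_size_nm = 1,
                        sigma_nm = 2, z_nm = 0, phase = 0) {
  th <- (seq_len(n) - 1) * 2 * pi / n + phase
  ctr <- floor(d / 2)
  centers <- cbind(radius_nm * cos(th) / voxel_size_nm + ctr,
                   radius_nm * sin(th) / voxel_size_nm + ctr,
                   z_nm / voxel_size_nm + ctr)
  blob_volume(d, centers, sigma = sigma_nm / voxel_size_nm,
              voxel_size_nm = voxel_size_nm)
}

# near-continuous torus: a very dense ring
torus_volume <- function(radius_nm, d = 64, voxel_size_nm = 1,
                         sigma_nm = 2, z_nm = 0) {
  ring_volume(2048, radius_nm, d, voxel_size_nm, sigma_nm, z_nm)
}

noise_volume <- function(d = 32, sd = 1, voxel_size_nm = 1) {
  volume(array(rnorm(d^3, sd = sd), rep(d, 3)), voxel_size_nm)
}

rel_rms <- function(a, b) {
  da <- if (is_vol <- inherits(a, "volume")) a$data else a
  db <- if (inherits(b, "volume")) b$data else b
  sqrt(mean((da - db)^2)) / sqrt(mean(db^2))
}

# fraction of Fourier voxels covered, measured over the Nyquist ball
ball_fraction <- function(mask) {
  d <- dim(mask)
  kr <- motoret:::freq_radius(d)
  ball <- kr <= min(d) / 2 - 1
  mean(mask[ball])
}

# net rotation about the z axis encoded in a pose (degrees)
z_rotation_deg <- function(p) {
  R <- euler_to_matrix(p$euler_deg)
  atan2(R[2, 1] - R[1, 2], R[1, 1] + R[2, 2]) * 180 / pi
}
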