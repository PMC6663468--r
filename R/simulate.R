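#' Simulation specification for a subtomogram ensemble
#'
#' @param strain a [strain_config()] (or a preset name, see
#'   [strain_presets()]).
#' @param wedge a [wedge_spec()].
#' @param n_motors number of motors to simulate (>= 1).
#' @param box_voxels cubic grid side; the box must contain the stator ring
#'   diameter plus a 20 percent margin.
#' @param voxel_size_nm voxel size (nm).
#' @param snr signal-to-noise ratio: signal variance inside a cylindrical
#'   signal mask divided by the white-noise variance. `Inf` for noiseless.
#' @param jitter_rot_deg maximum random perturbation of each Euler angle
#'   (degrees, uniform in +/- this value).
#' @param jitter_shift_voxels maximum random shift per axis (voxels).
#' @param random_azimuth give every motor a random azimuth (rotation about
#'   z, uniform in \[0, 360)), as motors picked from tomograms have; the
#'   azimuth is part of the initial pose guess, so the per-particle wedge
#'   orientations differ and the pooled Fourier coverage fills. Default
#'   `TRUE`.
#' @param seed integer RNG seed; the full simulation is reproducible.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(strain, wedge = wedge_spec(), n_motors = 32,
                            box_voxels = 96, voxel_size_nm = 1.25,
                            snr = 0.5, jitter_rot_deg = 2,
                            jitter_shift_voxels = 1, random_azimuth = TRUE,
                            seed = 1) {
  if (is.character(strain)) {
    presets <- strain_presets()
    if (!strain %in% names(presets))
      stop("unknown strain preset: ", strain, call. = FALSE)
    strain <- presets[[strain]]
  }
  if (!inherits(strain, "strain_config"))
    stop("`strain` must be a strain_config or preset name", call. = FALSE)
  if (n_motors < 1) stop("n_motors must be >= 1", call. = FALSE)
  if (!is.finite(snr) && !identical(snr, Inf)) stop("snr must be > 0", call. = FALSE)
  if (snr <= 0) stop("snr must be > 0", call. = FALSE)
  if (box_voxels * voxel_size_nm < 1.2 * 2 * strain$stator_ring_radius_nm)
    stop("box must contain the stator ring diameter plus 20% margin",
         call. = FALSE)
  structure(list(strain = strain, wedge = wedge,
                 n_motors = as.integer(n_motors),
                 box_voxels = as.integer(box_voxels),
                 voxel_size_nm = voxel_size_nm, snr = snr,
                 jitter_rot_deg = jitter_rot_deg,
                 jitter_shift_voxels = jitter_shift_voxels,
                 random_azimuth = isTRUE(random_azimuth),
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# cylindrical mask over the motor body, used to define the signal variance
signal_mask <- function(vol, strain) {
  g <- coord_grids_nm(vol)
  r2 <- g$x^2 + g$y^2
  rmax <- strain$stator_ring_radius_nm + 3 * strain$stator_sigma_nm
  z_lo <- strain$cring_z_top_nm - strain$cring_wall_height_nm - 3
  z_hi <- strain$membrane_z_nm + strain$membrane_thickness_nm + 6
  r2 <= rmax^2 & g$z >= z_lo & g$z <= z_hi
}

#' Simulate a noisy, wedge-filtered subtomogram ensemble
#'
#' For each motor: sample stator occupancy, build the phantom, rotate it
#' to a random azimuth (if `random_azimuth`), perturb the pose by the
#' jitter, apply the missing wedge in the perturbed (lab) frame, and add
#' white Gaussian noise scaled to the requested SNR. The returned particle
#' table carries the *initial* pose guesses (the azimuth without the
#' jitter, as a picker would supply); the ground truth carries the exact
#' alignment poses and occupancy flags. Fully reproducible under the
#' spec's seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with elements `stack` (list of [volume()]), `particles`
#'   (a [particle_table()]), `truth` (list: `poses` = exact alignment
#'   [pose()] per motor, `flags` = occupancy flags per motor,
#'   `tilt_deg`, `n_cring`), and `spec`.
#' @export
simulate_ensemble <- function(spec) {
  if (!inherits(spec, "simulation_spec"))
    stop("`spec` must be a simulation_spec", call. = FALSE)
  set.seed(spec$seed)
  strain <- spec$strain
  flags <- sample_occupancy_impl(strain, spec$n_motors)
  mask <- wedge_mask(spec$wedge, rep(spec$box_voxels, 3))
  stack <- vector("list", spec$n_motors)
  true_poses <- vector("list", spec$n_motors)
  smask <- NULL
  guess_poses <- vector("list", spec$n_motors)
  for (i in seq_len(spec$n_motors)) {
    az <- if (spec$random_azimuth) runif(1, 0, 360) else 0
    base <- pose(c(az, 0, 0))
    jit <- pose(runif(3, -spec$jitter_rot_deg, spec$jitter_rot_deg),
                runif(3, -spec$jitter_shift_voxels, spec$jitter_shift_voxels))
    lab_pose <- pose_compose(jit, base)
    phantom <- build_motor_phantom(strain, flags[[i]],
                                   spec$box_voxels, spec$voxel_size_nm)
    posed <- apply_pose(phantom, lab_pose)
    ft <- fft(posed$data) * mask
    sig <- Re(fft(ft, inverse = TRUE)) / length(ft)
    if (is.null(smask)) smask <- signal_mask(phantom, strain)
    if (is.finite(spec$snr)) {
      sigma_n <- sqrt(var(sig[smask]) / spec$snr)
      sig <- sig + rnorm(length(sig), sd = sigma_n)
    }
    stack[[i]] <- volume(array(sig, dim(phantom$data)),
                         spec$voxel_size_nm, phantom$origin_voxel)
    true_poses[[i]] <- pose_inverse(lab_pose)
    guess_poses[[i]] <- pose_inverse(base)
  }
  guess_euler <- t(vapply(guess_poses, function(p) p$euler_deg, numeric(3)))
  particles <- particle_table(data.frame(
    particle_id = sprintf("%s_motor%03d", strain$name, seq_len(spec$n_motors)),
    motor_id = sprintf("motor%03d", seq_len(spec$n_motors)),
    phi = guess_euler[, 1], theta = guess_euler[, 2], psi = guess_euler[, 3],
    stringsAsFactors = FALSE))
  list(stack = stack,
       particles = particles,
       truth = list(poses = true_poses, flags = flags,
                    tilt_deg = strain$cring_tilt_deg,
                    n_cring = strain$n_cring),
       spec = spec)
}
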