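#' Parametric motor model for one strain
#'
#' Describes the geometry and stator occupancy of a flagellar motor as a
#' sum of Gaussian blobs: an n-fold C-ring whose wall tilts away from the
#' rotation axis, a 16-fold periplasmic collar, a 16-site stator ring, and
#' optional inner-membrane slab, rod and MS-ring densities. The frame is
#' right-handed with z along the rotation axis pointing from the C-ring
#' toward the hook and the origin at the MS-ring centre, so the C-ring
#' lives at negative z.
#'
#' The C-ring wall is a frustum: bottom radius `cring_radius_bottom_nm`
#' at its lowest z, widening upward so that the top radius is
#' `cring_radius_bottom_nm + cring_wall_height_nm * tan(cring_tilt_deg)`.
#'
#' @param name strain name.
#' @param n_cring C-ring subunit count (>= 3).
#' @param n_collar collar / stator site count (>= 1).
#' @param cring_radius_bottom_nm radius of the C-ring bottom (nm).
#' @param cring_wall_height_nm height of the C-ring wall (nm).
#' @param cring_tilt_deg tilt of the C-ring wall away from the rotation
#'   axis (degrees).
#' @param cring_z_top_nm z of the top of the C-ring wall (nm; the wall
#'   extends downward by `cring_wall_height_nm`).
#' @param stator_ring_radius_nm radius of the stator ring (nm).
#' @param stator_z_nm z of the stator (cytoplasmic lobe) centre (nm).
#' @param stator_sigma_nm Gaussian sigma of a stator blob (nm).
#' @param stator_occupancy occupancy: with `occupancy_kind = "probability"`
#'   a per-site Bernoulli probability in \[0, 1\]; with `"count"` a fixed
#'   number of occupied sites per motor.
#' @param occupancy_kind `"probability"` or `"count"`.
#' @param stator_two_lobes if `TRUE` each stator gets a second, periplasmic
#'   lobe; default single blob.
#' @param collar_radius_nm,collar_z_nm,collar_sigma_nm collar ring geometry.
#' @param msring_radius_nm MS-ring radius (nm).
#' @param membrane_z_nm,membrane_thickness_nm inner-membrane slab position
#'   and thickness (nm).
#' @param blob_sigma_nm Gaussian sigma of a C-ring subunit blob (nm).
#' @param include_collar,include_rod,include_msring,include_membrane flags.
#' @param amp_cring,amp_stator,amp_collar,amp_msring,amp_rod,amp_membrane
#'   component amplitudes (arbitrary density units).
#' @return object of class `strain_config`.
#' @export
strain_config <- function(name = "custom",
                          n_cring = 46L,
                          n_collar = 16L,
                          cring_radius_bottom_nm = 28,
                          cring_wall_height_nm = 11,
                          cring_tilt_deg = 0,
                          cring_z_top_nm = -4,
                          stator_ring_radius_nm = 40,
                          stator_z_nm = -3,
                          stator_sigma_nm = 2.5,
                          stator_occupancy = 1,
                          occupancy_kind = c("probability", "count"),
                          stator_two_lobes = FALSE,
                          collar_radius_nm = 33,
                          collar_z_nm = 6,
                          collar_sigma_nm = 2,
                          msring_radius_nm = 10,
                          membrane_z_nm = 2,
                          membrane_thickness_nm = 4,
                          blob_sigma_nm = 1,
                          include_collar = TRUE,
                          include_rod = TRUE,
                          include_msring = TRUE,
                          include_membrane = TRUE,
                          amp_cring = 1,
                          amp_stator = 1.5,
                          amp_collar = 1.2,
                          amp_msring = 1,
                          amp_rod = 1,
                          amp_membrane = 0.4) {
  occupancy_kind <- match.arg(occupancy_kind)
  cfg <- as.list(environment())
  if (cfg$n_cring < 3) stop("n_cring must be >= 3", call. = FALSE)
  if (cfg$n_collar < 1) stop("n_collar must be >= 1", call. = FALSE)
  pos <- c("cring_radius_bottom_nm", "cring_wall_height_nm",
           "stator_ring_radius_nm", "stator_sigma_nm", "collar_radius_nm",
           "msring_radius_nm", "membrane_thickness_nm", "blob_sigma_nm")
  for (f in pos) if (cfg[[f]] <= 0) stop(f, " must be > 0", call. = FALSE)
  if (occupancy_kind == "probability" &&
      (stator_occupancy < 0 || stator_occupancy > 1))
    stop("occupancy probability must be in [0, 1]", call. = FALSE)
  if (occupancy_kind == "count" &&
      (stator_occupancy < 0 || stator_occupancy > n_collar ||
       stator_occupancy != round(stator_occupancy)))
    stop("occupancy count must be an integer in [0, n_collar]", call. = FALSE)
  if (cring_top_radius_nm_impl(cfg) <= 0)
    stop("derived C-ring top radius must be positive", call. = FALSE)
  structure(cfg, class = "strain_config")
}

cring_top_radius_nm_impl <- function(cfg) {
  cfg$cring_radius_bottom_nm +
    cfg$cring_wall_height_nm * tan(cfg$cring_tilt_deg * pi / 180)
}

#' Derived top radius of the C-ring wall
#' @param cfg a [strain_config()].
#' @return radius in nm.
#' @export
cring_top_radius_nm <- function(cfg) cring_top_radius_nm_impl(cfg)

#' @export
print.strain_config <- function(x, ...) {
  occ <- if (x$occupancy_kind == "count")
    sprintf("%d/%d sites", as.integer(x$stator_occupancy), x$n_collar)
  else sprintf("p = %.3g per site", x$stator_occupancy)
  cat(sprintf("<strain_config> %s: C-ring %d-fold (r %.3g -> %.3g nm, tilt %.2g deg), %d stator sites (r %.3g nm, %s)\n",
              x$name, x$n_cring, x$cring_radius_bottom_nm,
              cring_top_radius_nm(x), x$cring_tilt_deg, x$n_collar,
              x$stator_ring_radius_nm, occ))
  invisible(x)
}

#' Strain presets
#'
#' Parametric motor models for the five analysed conditions. All strains
#' share the 46-fold C-ring (bottom radius 28 nm, wall height 11 nm), the
#' 16-fold collar and the 16-site stator ring of radius 40 nm; they differ
#' in C-ring wall tilt and stator occupancy:
#' \describe{
#'   \item{WT}{tilt 1.8 deg, per-site occupancy probability 0.97}
#'   \item{D24E}{tilt 3.2 deg, exactly 10 of 16 sites occupied}
#'   \item{D24N}{tilt 6.6 deg, exactly 7 of 16 sites occupied}
#'   \item{dmotB}{tilt 7.8 deg, no stators}
#'   \item{CCCP}{tilt 5.1 deg, all 16 sites occupied (uncoupler-treated WT)}
#' }
#'
#' @return named list of [strain_config()] objects.
#' @export
strain_presets <- function() {
  base <- function(name, tilt, occ, kind)
    strain_config(name = name, cring_tilt_deg = tilt,
                  stator_occupancy = occ, occupancy_kind = kind)
  list(WT    = base("WT",    1.8, 0.97, "probability"),
       D24E  = base("D24E",  3.2, 10,   "count"),
       D24N  = base("D24N",  6.6, 7,    "count"),
       dmotB = base("dmotB", 7.8, 0,    "count"),
       CCCP  = base("CCCP",  5.1, 16,   "count"))
}

#' Sample per-motor stator occupancy flags
#'
#' With a fixed count k, each motor receives exactly k occupied sites drawn
#' uniformly without replacement; with a probability p, each site is an
#' independent Bernoulli(p).
#'
#' @param strain a [strain_config()].
#' @param n_motors number of motors (>= 1).
#' @param seed integer RNG seed.
#' @return list of `n_motors` logical vectors of length `n_collar`.
#' @export
sample_occupancy <- function(strain, n_motors, seed = 1) {
  if (n_motors < 1) stop("n_motors must be >= 1", call. = FALSE)
  set.seed(seed)
  sample_occupancy_impl(strain, n_motors)
}

# uses the current RNG stream (no reseed); shared with simulate_ensemble
sample_occupancy_impl <- function(strain, n_motors) {
  nc <- strain$n_collar
  lapply(seq_len(n_motors), function(i) {
    if (strain$occupancy_kind == "count") {
      k <- as.integer(strain$stator_occupancy)
      if (k > nc) stop("occupied-site count exceeds n_collar", call. = FALSE)
      flags <- rep(FALSE, nc)
      if (k > 0) flags[sample.int(nc, k)] <- TRUE
      flags
    } else {
      runif(nc) < strain$stator_occupancy
    }
  })
}

#' Build a noiseless motor phantom
#'
#' Renders the motor as a sum of isotropic Gaussian blobs on a cubic grid:
#' `n_cring` C-ring subunits (each a short stack of blobs tracing the
#' tilted frustum wall), `n_collar` collar blobs, stator blobs at the
#' flagged sites, plus optional rod, MS-ring and membrane-slab densities.
#' Deterministic for fixed inputs.
#'
#' @param strain a [strain_config()].
#' @param occupancy_flags logical vector of length `n_collar`; which stator
#'   sites carry density.
#' @param box_voxels cubic grid side (voxels).
#' @param voxel_size_nm voxel size (nm).
#' @return a [volume()].
#' @export
build_motor_phantom <- function(strain, occupancy_flags = NULL,
                                box_voxels = 96, voxel_size_nm = 1.25) {
  if (is.null(occupancy_flags)) {
    occupancy_flags <- if (strain$occupancy_kind == "count")
      seq_len(strain$n_collar) <= strain$stator_occupancy
    else rep(strain$stator_occupancy >= 0.5, strain$n_collar)
  }
  if (length(occupancy_flags) != strain$n_collar)
    stop("occupancy_flags must have length n_collar", call. = FALSE)
  half_nm <- box_voxels / 2 * voxel_size_nm
  r_max <- max(cring_top_radius_nm(strain), strain$cring_radius_bottom_nm,
               strain$stator_ring_radius_nm + 3 * strain$stator_sigma_nm,
               if (strain$include_collar) strain$collar_radius_nm else 0)
  if (r_max >= half_nm)
    stop("motor geometry exceeds the simulation box", call. = FALSE)

  centers <- NULL; sigmas <- NULL; amps <- NULL
  add <- function(pos_nm, sigma_nm, amp) {
    centers <<- rbind(centers, pos_nm)
    sigmas <<- c(sigmas, rep(sigma_nm, nrow(pos_nm)))
    amps <<- c(amps, rep(amp, nrow(pos_nm)))
  }
  ring_xy <- function(n, radius, phase = 0) {
    th <- (seq_len(n) - 1) * 2 * pi / n + phase
    cbind(radius * cos(th), radius * sin(th))
  }

  # C-ring: each subunit is a stack of blobs along the tilted wall
  h <- strain$cring_wall_height_nm
  n_ax <- max(2L, ceiling(h) + 1L)
  tfrac <- seq(0, 1, length.out = n_ax)
  z_bot <- strain$cring_z_top_nm - h
  tanb <- tan(strain$cring_tilt_deg * pi / 180)
  th <- (seq_len(strain$n_cring) - 1) * 2 * pi / strain$n_cring
  for (tt in tfrac) {
    r <- strain$cring_radius_bottom_nm + tt * h * tanb
    z <- z_bot + tt * h
    add(cbind(r * cos(th), r * sin(th), z), strain$blob_sigma_nm, strain$amp_cring)
  }

  site_phase <- (seq_len(strain$n_collar) - 1) * 2 * pi / strain$n_collar
  if (strain$include_collar)
    add(cbind(strain$collar_radius_nm * cos(site_phase),
              strain$collar_radius_nm * sin(site_phase),
              strain$collar_z_nm), strain$collar_sigma_nm, strain$amp_collar)

  occ <- which(occupancy_flags)
  if (length(occ)) {
    add(cbind(strain$stator_ring_radius_nm * cos(site_phase[occ]),
              strain$stator_ring_radius_nm * sin(site_phase[occ]),
              strain$stator_z_nm), strain$stator_sigma_nm, strain$amp_stator)
    if (strain$stator_two_lobes)
      add(cbind(strain$stator_ring_radius_nm * cos(site_phase[occ]),
                strain$stator_ring_radius_nm * sin(site_phase[occ]),
                strain$stator_z_nm + 8), 2, strain$amp_stator * 0.8)
  }

  if (strain$include_msring)
    add(cbind(ring_xy(32, strain$msring_radius_nm), 0), 1.5, strain$amp_msring)
  if (strain$include_rod)
    add(cbind(0, 0, seq(0, 20, by = 1)), 2, strain$amp_rod)

  d <- rep(as.integer(box_voxels), 3)
  origin <- floor(d / 2)
  centers_vox <- sweep(centers / voxel_size_nm, 2, origin, "+")
  data <- array(render_blobs_cpp(d, centers_vox, sigmas / voxel_size_nm, amps),
                dim = d)

  if (strain$include_membrane) {
    z_nm <- (seq_len(d[3]) - 1 - origin[3]) * voxel_size_nm
    prof <- strain$amp_membrane *
      exp(-(z_nm - strain$membrane_z_nm)^2 /
            (2 * (strain$membrane_thickness_nm / 2)^2))
    data <- data + rep(prof, each = d[1] * d[2])
  }
  volume(data, voxel_size_nm, origin)
}
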