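#' Alignment search specification
#'
#' Exhaustive search over a rotation grid and integer shifts. Rotations are
#' parameterized as a rotation `gamma` about the rod (z) axis, capped by
#' `max_axis_rot_deg`, optionally composed with an off-axis tilt of up to
#' `max_tilt_deg` (tilt azimuth sampled at 45 degree steps).
#'
#' @param angular_grid_deg grid step for the exhaustive Euler search
#'   (degrees, > 0).
#' @param max_axis_rot_deg cap on the rotation about the rod axis, in
#'   `(0, 180]`.
#' @param max_tilt_deg cap on the off-axis tilt searched (0 disables).
#' @param max_shift_voxels integer shift search window per axis.
#' @param mask optional real-space mask [volume()] (values in \[0, 1\])
#'   applied to both volumes before scoring.
#' @param lowpass_voxels Gaussian low-pass applied to the reference during
#'   alignment, expressed as a real-space length in voxels (cutoff
#'   frequency `1/lowpass_voxels` cycles/voxel); `NULL` disables.
#'   Default 4.
#' @return object of class `search_spec`.
#' @export
search_spec <- function(angular_grid_deg = 2, max_axis_rot_deg = 180,
                        max_tilt_deg = 0, max_shift_voxels = 1,
                        mask = NULL, lowpass_voxels = 4) {
  if (angular_grid_deg <= 0) stop("angular_grid_deg must be > 0", call. = FALSE)
  if (max_axis_rot_deg <= 0 || max_axis_rot_deg > 180)
    stop("max_axis_rot_deg must be in (0, 180]", call. = FALSE)
  if (max_tilt_deg < 0) stop("max_tilt_deg must be >= 0", call. = FALSE)
  if (max_shift_voxels < 0) stop("max_shift_voxels must be >= 0", call. = FALSE)
  structure(list(angular_grid_deg = angular_grid_deg,
                 max_axis_rot_deg = max_axis_rot_deg,
                 max_tilt_deg = max_tilt_deg,
                 max_shift_voxels = as.integer(max_shift_voxels),
                 mask = mask, lowpass_voxels = lowpass_voxels),
            class = "search_spec")
}

resolve_fourier_mask <- function(w, dims, rot = diag(3)) {
  if (is.null(w)) return(NULL)
  if (inherits(w, "wedge_spec")) return(wedge_mask(w, dims, rot = rot))
  if (is.array(w)) {
    if (identical(rot, diag(3))) return(w != 0)
    return(rotate_fourier_mask(w != 0, rot))
  }
  stop("wedge must be NULL, a wedge_spec, or a logical array", call. = FALSE)
}

# nearest-voxel rotation of a binary mask living on the FFT frequency grid
rotate_fourier_mask <- function(mask, rot) {
  d <- dim(mask)
  sh <- fftshift3(mask * 1)
  ctr <- floor(d / 2)
  Rinv <- t(rot)
  b <- as.numeric(ctr - Rinv %*% ctr)
  out <- affine_interp_cpp(sh, d, d, Rinv, b, nearest = TRUE)
  ifftshift3(array(out, d)) > 0.5
}

fftshift3 <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2)))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

ifftshift3 <- function(a) {
  d <- dim(a)
  idx <- lapply(d, function(n) c((n - floor(n / 2) + 1):n, 1:(n - floor(n / 2))))
  a[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

freq_radius <- function(dims) {
  kx <- fft_freqs(dims[1]); ky <- fft_freqs(dims[2]); kz <- fft_freqs(dims[3])
  r2 <- outer(kx^2, ky^2, "+")
  sqrt(outer(r2, kz^2, "+"))
}

lowpass_filter <- function(dims, lowpass_voxels) {
  if (is.null(lowpass_voxels)) return(1)
  kr <- freq_radius(dims)
  fc <- 1 / lowpass_voxels                # cycles/voxel
  exp(-(kr / (dims[1] * fc))^2 / 2)
}

apply_realspace_mask <- function(vol, mask) {
  if (is.null(mask)) return(vol)
  m <- if (is_volume(mask)) mask$data else mask
  volume(vol$data * m, vol$voxel_size_nm, vol$origin_voxel)
}

#' Missing-wedge-constrained cross-correlation
#'
#' Normalized cross-correlation between `a` and the pose-transformed `b`,
#' computed in Fourier space over the intersection of the two wedge
#' supports (with `b`'s support rotated along with the pose); the DC term
#' is excluded. An optional real-space mask is applied to both volumes
#' first.
#'
#' @param a,b [volume()]s on the same grid.
#' @param pose optional [pose()] applied to `b` before comparison.
#' @param wedge_a,wedge_b `NULL` (full coverage), a [wedge_spec()], or a
#'   logical Fourier-mask array, describing each volume's support.
#' @param mask optional real-space mask ([volume()] or array, values in
#'   \[0, 1\]).
#' @return correlation in \[-1, 1\].
#' @export
constrained_cc <- function(a, b, pose = NULL, wedge_a = NULL, wedge_b = NULL,
                           mask = NULL) {
  stopifnot_volume(a, "a"); stopifnot_volume(b, "b")
  if (!identical(dim(a$data), dim(b$data)))
    stop("volumes must share a grid", call. = FALSE)
  d <- dim(a$data)
  R <- if (is.null(pose)) diag(3) else euler_to_matrix(pose$euler_deg)
  bt <- if (is.null(pose)) b else apply_pose(b, pose)
  a <- apply_realspace_mask(a, mask)
  bt <- apply_realspace_mask(bt, mask)
  W <- combine_masks(resolve_fourier_mask(wedge_a, d),
                     resolve_fourier_mask(wedge_b, d, rot = R), d)
  W[1, 1, 1] <- FALSE
  if (!any(W)) stop("empty wedge intersection: score undefined", call. = FALSE)
  A <- fft(a$data)[W]
  B <- fft(bt$data)[W]
  den <- sqrt(sum(Mod(A)^2) * sum(Mod(B)^2))
  if (den == 0) return(0)
  sum(Re(A * Conj(B))) / den
}

combine_masks <- function(m1, m2, d) {
  if (is.null(m1) && is.null(m2)) return(array(TRUE, d))
  if (is.null(m1)) return(m2)
  if (is.null(m2)) return(m1)
  m1 & m2
}

# rotation grid for align_particle: list of (gamma, theta, phit) rows in
# lexicographic order
rotation_grid <- function(search, half_step = FALSE, center = c(0, 0, 0)) {
  step <- search$angular_grid_deg / (if (half_step) 2 else 1)
  if (half_step) {
    gam <- center[1] + c(-step, 0, step)
    gam <- gam[abs(gam) <= search$max_axis_rot_deg + 1e-9]
    gam <- pmin(pmax(gam, -search$max_axis_rot_deg), search$max_axis_rot_deg)
    th <- unique(pmax(0, center[2] + c(-step, 0, step)))
    th <- th[th <= search$max_tilt_deg + 1e-9]
    if (!length(th)) th <- 0
    ph <- if (all(th == 0)) 0 else unique(c(center[3] - 22.5, center[3], center[3] + 22.5))
  } else {
    gam <- if (search$max_axis_rot_deg >= 180) {
      seq(-180, 180 - step, by = step)
    } else {
      # symmetric about zero, with the cap itself included
      pos <- unique(c(seq(0, search$max_axis_rot_deg, by = step),
                      search$max_axis_rot_deg))
      sort(unique(c(-pos, pos)))
    }
    th <- if (search$max_tilt_deg > 0)
      unique(c(0, seq(step, search$max_tilt_deg, by = step))) else 0
    ph <- seq(0, 315, by = 45)
  }
  out <- do.call(rbind, lapply(sort(gam), function(g)
    do.call(rbind, lapply(sort(th), function(t) {
      phs <- if (t == 0) 0 else sort(ph %% 360)
      cbind(gamma = g, theta = t, phit = phs)
    }))))
  unique(out)
}

rotation_from_params <- function(gamma, theta, phit) {
  # z rotation by gamma composed with an off-axis tilt of theta about the
  # in-plane axis at azimuth phit; ZYZ euler = (phit, theta, gamma - phit)
  c(phit, theta, gamma - phit)
}

#' Align a particle to a reference
#'
#' Exhaustive search over the rotation grid and integer shifts, followed by
#' one local refinement pass at half the angular step. Scores are
#' missing-wedge-constrained cross-correlations, evaluated in the particle
#' frame: the full-band reference is rotated onto each candidate pose and
#' compared inside the particle's fixed wedge support, so the
#' wedge-filtered particle is never resampled. Shifts are scored for all
#' integer offsets at once through the Fourier correlation theorem.
#' Deterministic: ties are broken by the lexicographically smallest pose.
#'
#' @param particle,reference [volume()]s on the same grid.
#' @param search a [search_spec()].
#' @param wedge the particle's wedge (`NULL`, [wedge_spec()] or mask
#'   array).
#' @return list with `pose` (the alignment [pose()]: apply it to the
#'   particle to match the reference) and `score`.
#' @export
align_particle <- function(particle, reference, search = search_spec(),
                           wedge = NULL) {
  stopifnot_volume(particle, "particle"); stopifnot_volume(reference, "reference")
  d <- dim(particle$data)
  if (!identical(d, dim(reference$data)))
    stop("particle and reference must share a grid", call. = FALSE)
  W <- resolve_fourier_mask(wedge, d)
  if (is.null(W)) W <- array(TRUE, d)
  W[1, 1, 1] <- FALSE
  if (!any(W)) stop("empty wedge support", call. = FALSE)
  lp <- lowpass_filter(d, search$lowpass_voxels)
  part <- apply_realspace_mask(particle, search$mask)
  B <- fft(part$data) * lp     # low-pass both sides: a perfect match scores 1
  nB <- sum(Mod(B[W])^2)
  nrm_shift <- search$max_shift_voxels
  shifts <- as.matrix(expand.grid(sx = -nrm_shift:nrm_shift,
                                  sy = -nrm_shift:nrm_shift,
                                  sz = -nrm_shift:nrm_shift))
  shifts <- shifts[order(shifts[, 1], shifts[, 2], shifts[, 3]), , drop = FALSE]
  shift_idx <- (shifts %% matrix(d, nrow(shifts), 3, byrow = TRUE))
  lin_idx <- 1 + shift_idx[, 1] + d[1] * (shift_idx[, 2] + d[2] * shift_idx[, 3])

  # candidate rotation R of the alignment pose; the reference is brought
  # into the particle frame with Q = R^-1, shifted by u there; the
  # alignment pose is then the inverse of (Q, u)
  score_rotation <- function(params) {
    eul <- rotation_from_params(params[1], params[2], params[3])
    Q <- matrix_to_euler(t(euler_to_matrix(eul)))
    ar <- apply_pose(reference, pose(Q, c(0, 0, 0)))
    ar <- apply_realspace_mask(ar, search$mask)
    A <- fft(ar$data) * lp
    nA <- sum(Mod(A[W])^2)
    if (nA == 0 || nB == 0) return(list(score = -Inf, shift = c(0, 0, 0), euler = eul))
    G <- array(0i, d); G[W] <- B[W] * Conj(A[W])
    cc_map <- Re(fft(G, inverse = TRUE))
    sc <- cc_map[lin_idx] / sqrt(nA * nB)
    best <- which.max(sc)   # first (lexicographically smallest) maximum
    p_align <- pose_inverse(pose(Q, as.numeric(shifts[best, ])))
    list(score = sc[best], shift = p_align$shift_voxels,
         euler = p_align$euler_deg)
  }

  search_over <- function(grid, best = NULL) {
    for (i in seq_len(nrow(grid))) {
      cand <- score_rotation(grid[i, ])
      cand$params <- grid[i, ]
      if (is.null(best) || cand$score > best$score + 1e-12) best <- cand
    }
    best
  }

  grid <- rotation_grid(search)
  if (!nrow(grid)) stop("empty search space", call. = FALSE)
  best <- search_over(grid)
  fine <- rotation_grid(search, half_step = TRUE, center = best$params)
  best <- search_over(fine, best)
  list(pose = pose(best$euler, best$shift), score = best$score)
}

#' Fourier-space average with per-voxel coverage normalization
#'
#' Each particle is brought to the common frame by its pose, its Fourier
#' transform accumulated over its (rotated) wedge support, and the
#' per-voxel sum divided by the per-voxel coverage count; voxels never
#' covered are set to zero. This is the class-averaging scheme that
#' compensates the missing wedge.
#'
#' @param particles list of [volume()]s (or the `stack` of
#'   [simulate_ensemble()]).
#' @param poses list of [pose()]s (alignment transforms), or a
#'   [particle_table()].
#' @param wedge shared acquisition wedge (`NULL`, [wedge_spec()] or mask).
#' @return object of class `average_map`: list with `density` (a
#'   [volume()]), `coverage` (integer array of per-voxel Fourier sample
#'   counts) and `n_particles`.
#' @export
fourier_average <- function(particles, poses = NULL, wedge = NULL) {
  if (length(particles) < 1) stop("need at least one particle", call. = FALSE)
  if (inherits(poses, "particle_table")) poses <- particle_poses(poses)
  if (is.null(poses)) poses <- rep(list(pose()), length(particles))
  if (length(poses) != length(particles))
    stop("poses must match particles in length", call. = FALSE)
  d <- dim(particles[[1]]$data)
  num <- array(0i, d)
  cov <- array(0L, d)
  for (i in seq_along(particles)) {
    p <- particles[[i]]
    stopifnot_volume(p, sprintf("particles[[%d]]", i))
    ap <- apply_pose(p, poses[[i]])
    R <- euler_to_matrix(poses[[i]]$euler_deg)
    W <- resolve_fourier_mask(wedge, d, rot = R)
    if (is.null(W)) W <- array(TRUE, d)
    num[W] <- num[W] + fft(ap$data)[W]
    cov <- cov + W
  }
  avg_ft <- array(0i, d)
  nz <- cov > 0
  avg_ft[nz] <- num[nz] / cov[nz]
  den <- Re(fft(avg_ft, inverse = TRUE)) / prod(d)
  structure(list(density = volume(array(den, d),
                                  particles[[1]]$voxel_size_nm,
                                  particles[[1]]$origin_voxel),
                 coverage = cov,
                 n_particles = length(particles)),
            class = "average_map")
}

#' @export
print.average_map <- function(x, ...) {
  cat(sprintf("<average_map> %d particles, covered fraction %.3f\n",
              x$n_particles, mean(x$coverage > 0)))
  print(x$density)
  invisible(x)
}

#' Half-set Fourier shell correlation
#'
#' Randomly (seeded) splits the particles into two halves, averages each
#' with [fourier_average()], and correlates the two averages per spherical
#' frequency shell (one voxel wide), restricted to voxels covered in both
#' half-maps.
#'
#' @param particles list of [volume()]s.
#' @param poses list of [pose()]s or a [particle_table()].
#' @param wedge shared wedge (`NULL`, [wedge_spec()] or mask).
#' @param seed RNG seed for the random split.
#' @return data.frame of class `fsc_curve` with columns `shell_radius`
#'   (cycles/nm) and `correlation`.
#' @export
split_half_fsc <- function(particles, poses = NULL, wedge = NULL, seed = 1) {
  n <- length(particles)
  if (n < 2) stop("need at least two particles for a half-set FSC", call. = FALSE)
  if (inherits(poses, "particle_table")) poses <- particle_poses(poses)
  if (is.null(poses)) poses <- rep(list(pose()), n)
  set.seed(seed)
  idx <- sample.int(n)
  h1 <- idx[seq_len(floor(n / 2))]
  h2 <- setdiff(idx, h1)
  a1 <- fourier_average(particles[h1], poses[h1], wedge)
  a2 <- fourier_average(particles[h2], poses[h2], wedge)
  fsc_between(a1, a2)
}

fsc_between <- function(a1, a2) {
  d <- dim(a1$density$data)
  voxel <- a1$density$voxel_size_nm
  F1 <- fft(a1$density$data)
  F2 <- fft(a2$density$data)
  both <- a1$coverage > 0 & a2$coverage > 0
  shell <- round(freq_radius(d))
  n_shell <- floor(min(d) / 2)
  keep <- both & shell <= n_shell
  sid <- shell[keep] + 1L
  num <- rowsum(Re(F1[keep] * Conj(F2[keep])), sid)
  p1 <- rowsum(Mod(F1[keep])^2, sid)
  p2 <- rowsum(Mod(F2[keep])^2, sid)
  radii <- (as.integer(rownames(num)) - 1L) / (d[1] * voxel)
  corr <- as.numeric(num) / sqrt(pmax(as.numeric(p1) * as.numeric(p2), 1e-300))
  structure(data.frame(shell_radius = radii, correlation = corr),
            class = c("fsc_curve", "data.frame"))
}

#' Resolution at an FSC threshold
#'
#' First shell radius at which the curve drops below the threshold,
#' linearly interpolated between shells; the DC shell is excluded from the
#' search. Returns the Nyquist (largest tabulated) radius if the curve
#' never crosses.
#'
#' @param curve an `fsc_curve` (see [split_half_fsc()]).
#' @param threshold scalar in (0, 1), e.g. 0.5 or 0.143.
#' @return spatial frequency in cycles/nm.
#' @export
resolution_at <- function(curve, threshold) {
  if (!is.data.frame(curve) || nrow(curve) == 0)
    stop("empty FSC curve", call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must be in (0, 1)", call. = FALSE)
  r <- curve$shell_radius
  cc <- curve$correlation
  if (length(r) > 1) { r <- r[-1]; cc <- cc[-1] }  # drop DC shell
  below <- which(cc < threshold)
  if (!length(below)) return(max(r))
  i <- below[1]
  if (i == 1) return(r[1])
  r[i - 1] + (cc[i - 1] - threshold) / (cc[i - 1] - cc[i]) * (r[i] - r[i - 1])
}
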