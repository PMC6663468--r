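#' Tilt-range specification of a tomographic acquisition
#'
#' Single-axis tilting over `[tilt_min_deg, tilt_max_deg]` about
#' `tilt_axis` (default y), with the untilted beam along z. Frequencies
#' whose sampling plane is never reached form the missing wedge.
#'
#' @param tilt_min_deg,tilt_max_deg tilt range, `-90 < min < max < 90`.
#' @param tilt_axis unit 3-vector, the tilt axis (must not be parallel to
#'   the beam axis z).
#' @return object of class `wedge_spec`.
#' @export
wedge_spec <- function(tilt_min_deg = -60, tilt_max_deg = 60,
                       tilt_axis = c(0, 1, 0)) {
  if (!(tilt_min_deg > -90 && tilt_min_deg < tilt_max_deg && tilt_max_deg < 90))
    stop("need -90 < tilt_min_deg < tilt_max_deg < 90", call. = FALSE)
  a <- tilt_axis / sqrt(sum(tilt_axis^2))
  if (abs(a[3]) > 0.999)
    stop("tilt axis may not be parallel to the beam (z) axis", call. = FALSE)
  structure(list(tilt_min_deg = tilt_min_deg, tilt_max_deg = tilt_max_deg,
                 tilt_axis = a), class = "wedge_spec")
}

#' Enumerate the tilt angles of an acquisition scheme
#' @param wedge a [wedge_spec()].
#' @param step_deg tilt increment in degrees.
#' @return numeric vector of tilt angles.
#' @export
tilt_series <- function(wedge, step_deg = 2) {
  seq(wedge$tilt_min_deg, wedge$tilt_max_deg, by = step_deg)
}

#' Binary Fourier-domain wedge mask
#'
#' A frequency voxel is covered iff some tilt in the acquisition range
#' samples it: writing the beam at tilt alpha as `b(alpha)` (rotation of z
#' about the tilt axis), `k` is covered iff `k . b(alpha) = 0` for some
#' alpha in the range. Evaluated analytically on the integer frequency
#' grid, so the mask is exactly binary, Hermitian-symmetric, and covers DC.
#'
#' The mask is returned in unshifted FFT layout (DC at `[1, 1, 1]`),
#' matching [stats::fft()].
#'
#' @param wedge a [wedge_spec()].
#' @param dims integer 3-vector of grid dimensions.
#' @param rot optional 3x3 rotation: the mask of a volume that has been
#'   rotated by `rot` (its Fourier support rotates along).
#' @return logical 3D array.
#' @export
wedge_mask <- function(wedge, dims, rot = diag(3)) {
  dims <- as.integer(dims)
  kx <- fft_freqs(dims[1])
  ky <- fft_freqs(dims[2])
  kz <- fft_freqs(dims[3])
  a <- wedge$tilt_axis
  zp <- c(0, 0, 1) - sum(c(0, 0, 1) * a) * a
  zp <- zp / sqrt(sum(zp^2))
  xp <- c(a[2] * zp[3] - a[3] * zp[2],
          a[3] * zp[1] - a[1] * zp[3],
          a[1] * zp[2] - a[2] * zp[1])
  # rotated support: evaluate the base condition at rot^-1 k; fold the
  # frame vectors through so the test is two dot products per voxel
  M <- t(rot)
  v1 <- as.numeric(crossprod(M, xp))  # t(M) %*% xp
  v2 <- as.numeric(crossprod(M, zp))
  d <- dims
  p <- outer(kx * v1[1], ky * v1[2], "+")
  p <- outer(p, kz * v1[3], "+")
  q <- outer(kx * v2[1], ky * v2[2], "+")
  q <- outer(q, kz * v2[3], "+")
  gam <- atan2(p, q) * 180 / pi
  alpha <- normalize_angle(gam + 90)
  alpha <- ifelse(alpha >= 90, alpha - 180, ifelse(alpha < -90, alpha + 180, alpha))
  covered <- (alpha >= wedge$tilt_min_deg & alpha <= wedge$tilt_max_deg) |
    (p == 0 & q == 0)
  array(covered, d)
}

# integer FFT frequencies in stats::fft layout: 0, 1, ..., -1
fft_freqs <- function(n) {
  ((seq_len(n) - 1 + floor(n / 2)) %% n) - floor(n / 2)
}

#' Apply the missing wedge to a volume
#'
#' Multiplies the Fourier transform by the binary wedge mask and inverts;
#' the operation is an idempotent orthogonal projection.
#'
#' @param vol a [volume()].
#' @param wedge a [wedge_spec()].
#' @return the wedge-filtered [volume()].
#' @export
apply_missing_wedge <- function(vol, wedge) {
  stopifnot_volume(vol)
  mask <- wedge_mask(wedge, dim(vol$data))
  ft <- fft(vol$data) * mask
  out <- Re(fft(ft, inverse = TRUE)) / length(ft)
  volume(array(out, dim(vol$data)), vol$voxel_size_nm, vol$origin_voxel)
}
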