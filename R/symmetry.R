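#' Angular harmonic power spectrum of a cylindrical shell
#'
#' Resamples the density onto a cylindrical grid (theta x z x r) inside the
#' shell, averages over z and r, Fourier-transforms along theta, and
#' reports the normalized power at each integer rotational order. The
#' power of order m is the share of the total non-DC angular power, so the
#' reported powers sum to at most 1 and the statistic is invariant to
#' positive rescaling of the density.
#'
#' @param vol a [volume()] centred on the rotation axis.
#' @param shell numeric 4-vector `(r_min_nm, r_max_nm, z_min_nm, z_max_nm)`.
#' @param n_max largest order reported; the angular sampling is `4 * n_max`
#'   points, giving a Nyquist margin of 2x.
#' @return object of class `symmetry_spectrum`: list with `orders`
#'   (1..n_max), `power`, `shell`, and `dc_ratio` (total non-DC power over
#'   DC power, a measure of how azimuthally structured the shell is).
#' @export
angular_power_spectrum <- function(vol, shell, n_max = 60) {
  stopifnot_volume(vol)
  shell <- as.numeric(shell)
  if (length(shell) != 4 || shell[1] >= shell[2] || shell[3] >= shell[4])
    stop("shell must be (r_min, r_max, z_min, z_max) with min < max",
         call. = FALSE)
  half <- dim(vol$data) / 2 * vol$voxel_size_nm
  if (shell[2] > min(half[1:2]) || shell[3] < -half[3] || shell[4] > half[3])
    stop("shell exceeds the volume", call. = FALSE)
  n_theta <- 4L * as.integer(n_max)
  step <- vol$voxel_size_nm / 2
  rs <- seq(shell[1], shell[2], by = step)
  zs <- seq(shell[3], shell[4], by = step)
  if (!length(rs) || !length(zs)) stop("empty shell", call. = FALSE)
  th <- (seq_len(n_theta) - 1) * 2 * pi / n_theta
  pts <- cbind(
    x = as.vector(outer(cos(th), rep(rs, each = length(zs)))),
    y = as.vector(outer(sin(th), rep(rs, each = length(zs)))),
    z = rep(rep(zs, times = length(rs)), each = n_theta))
  # pts rows: theta varies fastest, then z, then r
  vals <- interp_nm(vol, pts)
  f_theta <- rowMeans(matrix(vals, nrow = n_theta))
  ft <- fft(f_theta)
  pw <- Mod(ft)^2
  total <- sum(pw[2:(n_theta %/% 2 + 1)])
  power <- if (total > 0) pw[2:(n_max + 1)] / total else rep(0, n_max)
  structure(list(orders = seq_len(n_max), power = power, shell = shell,
                 dc_ratio = if (pw[1] > 0) total / pw[1] else Inf),
            class = "symmetry_spectrum")
}

#' @export
print.symmetry_spectrum <- function(x, ...) {
  top <- order(x$power, decreasing = TRUE)[1:5]
  cat(sprintf("<symmetry_spectrum> orders 1..%d, shell r [%g, %g] nm, z [%g, %g] nm\n",
              max(x$orders), x$shell[1], x$shell[2], x$shell[3], x$shell[4]))
  cat("  top orders:", paste(sprintf("m=%d (%.3f)", x$orders[top], x$power[top]),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Detect the fundamental rotational symmetry order
#'
#' A ring of N subunits excites orders N, 2N, ... but never divisors of N,
#' so the fundamental is the order m maximizing
#' `power(m) + power(2m) / 2`; it is declared only if its power exceeds
#' 3x the median power over all candidate orders, otherwise 0 (no symmetry
#' detected) is returned.
#'
#' @param spectrum a `symmetry_spectrum` from [angular_power_spectrum()].
#' @return integer order, or 0 if no symmetry is detected.
#' @export
detect_symmetry_order <- function(spectrum) {
  pw <- spectrum$power
  if (!length(pw)) stop("empty spectrum", call. = FALSE)
  n_max <- length(pw)
  harmonic <- function(m) if (2 * m <= n_max) pw[2 * m] / 2 else 0
  score <- pw + vapply(seq_len(n_max), harmonic, numeric(1))
  m_star <- which.max(score)
  if (pw[m_star] > 3 * median(pw)) as.integer(m_star) else 0L
}

#' n-fold symmetrize a volume about the z axis
#'
#' Averages the volume over rotations by `k * 360 / n` degrees,
#' `k = 0 .. n-1`, about the rotation axis.
#'
#' @param vol a [volume()].
#' @param n symmetry order (>= 1).
#' @return the symmetrized [volume()].
#' @export
symmetrize <- function(vol, n) {
  stopifnot_volume(vol)
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("n must be >= 1", call. = FALSE)
  if (n == 1) return(vol)
  acc <- vol$data
  for (k in seq_len(n - 1))
    acc <- acc + apply_pose(vol, pose(c(k * 360 / n, 0, 0)))$data
  volume(acc / n, vol$voxel_size_nm, vol$origin_voxel)
}
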