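#' Radial density profile within a z slab
#'
#' Cylindrical average of the density over azimuth and the slab, binned by
#' radius in one-voxel bins.
#'
#' @param vol a [volume()] centred on the rotation axis.
#' @param z_slab numeric `(z_min_nm, z_max_nm)`.
#' @return data.frame of class `radial_profile` with columns `radius_nm`
#'   and `density`.
#' @export
radial_profile <- function(vol, z_slab) {
  stopifnot_volume(vol)
  if (length(z_slab) != 2 || z_slab[1] >= z_slab[2])
    stop("z_slab must be (z_min, z_max) with min < max", call. = FALSE)
  zc <- axis_coords_nm(vol, 3)
  zsel <- which(zc >= z_slab[1] & zc <= z_slab[2])
  if (!length(zsel)) stop("empty slab: no voxel centres inside", call. = FALSE)
  xs <- axis_coords_nm(vol, 1)
  ys <- axis_coords_nm(vol, 2)
  r <- sqrt(outer(xs^2, ys^2, "+"))
  bin <- as.integer(round(r / vol$voxel_size_nm))
  slab <- vol$data[, , zsel, drop = FALSE]
  vals <- rowsum(as.numeric(slab), rep(bin, length(zsel)))
  cnt <- rowsum(rep(1, length(slab)), rep(bin, length(zsel)))
  radii <- as.integer(rownames(vals)) * vol$voxel_size_nm
  structure(data.frame(radius_nm = radii,
                       density = as.numeric(vals) / as.numeric(cnt)),
            class = c("radial_profile", "data.frame"))
}

#' Ring diameter from a radial-profile peak
#'
#' Twice the sub-bin (parabolically interpolated) argmax radius inside the
#' window. If the peak sits on a window boundary, the result carries the
#' attribute `boundary = TRUE` and a warning is raised.
#'
#' @param profile a `radial_profile` (see [radial_profile()]).
#' @param r_window numeric `(r_lo_nm, r_hi_nm)` search window.
#' @return diameter in nm.
#' @export
measure_ring_diameter <- function(profile, r_window) {
  if (length(r_window) != 2 || r_window[1] >= r_window[2])
    stop("r_window must be (r_lo, r_hi) with lo < hi", call. = FALSE)
  sel <- which(profile$radius_nm >= r_window[1] &
                 profile$radius_nm <= r_window[2])
  if (length(sel) < 3)
    stop("r_window must contain at least three profile bins", call. = FALSE)
  r <- profile$radius_nm[sel]
  y <- profile$density[sel]
  i <- which.max(y)
  boundary <- i == 1 || i == length(y)
  if (boundary) {
    warning("profile peak lies on the window boundary")
    r_peak <- r[i]
  } else {
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (abs(denom) > 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    r_peak <- r[i] + delta * (r[2] - r[1])
  }
  structure(2 * r_peak, boundary = boundary)
}

#' Tilt-measurement settings for [cring_tilt_angle()]
#'
#' @param sym_order symmetry applied before the cross-section (default 16,
#'   the collar/stator order).
#' @param r_window radial window bracketing the C-ring wall (nm).
#' @param z_window z window spanning the C-ring wall (nm).
#' @param cap_nm height of the top cap excluded from the fit (removes the
#'   FliG-N density at the top of the wall).
#' @param density_quantile quantile (within the window) above which voxels
#'   enter the fit.
#' @param plane_halfwidth_nm half-width of the cross-section slab averaged
#'   over y (nm).
#' @param sample_step_nm in-plane sampling step of the cross-section (nm).
#' @return list of settings.
#' @export
tilt_config <- function(sym_order = 16, r_window = c(24, 34),
                        z_window = c(-15, -4), cap_nm = 2,
                        density_quantile = 0.75, plane_halfwidth_nm = 1.25,
                        sample_step_nm = 0.3125) {
  list(sym_order = sym_order, r_window = r_window, z_window = z_window,
       cap_nm = cap_nm, density_quantile = density_quantile,
       plane_halfwidth_nm = plane_halfwidth_nm, sample_step_nm = sample_step_nm)
}

# intensity-weighted second-moment ellipse of a point cloud; returns
# centre, semi-axes and the angle (deg, in [0, 90]) between the major axis
# and the z direction
moments_ellipse <- function(x, z, w) {
  W <- sum(w)
  cx <- sum(w * x) / W
  cz <- sum(w * z) / W
  sxx <- sum(w * (x - cx)^2) / W
  szz <- sum(w * (z - cz)^2) / W
  sxz <- sum(w * (x - cx) * (z - cz)) / W
  e <- eigen(matrix(c(sxx, sxz, sxz, szz), 2, 2), symmetric = TRUE)
  v <- e$vectors[, 1]
  angle <- atan2(abs(v[1]), abs(v[2])) * 180 / pi
  list(center = c(cx, cz),
       semi_major_nm = 2 * sqrt(max(e$values[1], 0)),
       semi_minor_nm = 2 * sqrt(max(e$values[2], 0)),
       major_axis_angle_deg = angle)
}

# direct least-squares (algebraic) conic fit; used as an independent
# cross-check of the moments estimator in the tests
conic_ellipse_angle <- function(x, z, w) {
  cx <- sum(w * x) / sum(w); cz <- sum(w * z) / sum(w)
  x <- x - cx; z <- z - cz
  D <- cbind(x^2, x * z, z^2, x, z, 1) * sqrt(w)
  S <- crossprod(D)
  C <- matrix(0, 6, 6)
  C[1, 3] <- C[3, 1] <- 2; C[2, 2] <- -1
  e <- eigen(solve(S + diag(1e-10, 6), C))
  vals <- Re(e$values)
  ok <- which(vals > 1e-9)
  if (!length(ok)) return(NA_real_)
  a <- Re(e$vectors[, ok[which.max(vals[ok])]])
  if (a[1] + a[3] < 0) a <- -a             # fix the overall conic sign
  theta <- 0.5 * atan2(a[2], a[1] - a[3])  # angle of an axis from x
  # convert to angle of the *major* axis from the z direction, in [0, 90]
  axes <- theta + c(0, pi / 2)
  lens <- vapply(axes, function(t) {
    ct <- cos(t); st <- sin(t)
    1 / (a[1] * ct^2 + a[2] * ct * st + a[3] * st^2)
  }, numeric(1))
  major <- axes[which.max(lens)]
  ang <- atan2(abs(cos(major)), abs(sin(major))) * 180 / pi
  ang
}

#' C-ring tilt angle by symmetrize-then-ellipse-fit
#'
#' The estimator mirrors the map-based measurement: (1) apply n-fold
#' symmetry (default 16) about the rotation axis; (2) resample the axial
#' cross-section plane (x-z, averaged over a thin y slab); (3) per wall
#' (left/right of the axis) select voxels inside the C-ring window,
#' excluding the top cap where the FliG-N density sits; (4) keep voxels
#' above a density quantile; (5) fit an ellipse through second moments
#' weighted by the density in excess of the threshold (so marginal
#' threshold-crossers carry almost no weight); (6) the tilt is the angle
#' between the ellipse's major
#' axis and the rotation-axis direction. The two walls are averaged.
#'
#' @param vol a [volume()] centred on the rotation axis.
#' @param config settings from [tilt_config()].
#' @return object of class `tilt_result`: list with `tilt_deg`, `side`
#'   (`"mean"`), `left_deg`, `right_deg`, `fit` (per-wall ellipses) and
#'   `quality_flag` (`TRUE` when the walls disagree by more than 2
#'   degrees).
#' @export
cring_tilt_angle <- function(vol, config = tilt_config()) {
  stopifnot_volume(vol)
  sym <- symmetrize(vol, config$sym_order)
  zs <- seq(config$z_window[1], config$z_window[2] - config$cap_nm,
            by = config$sample_step_nm)
  xs <- seq(config$r_window[1], config$r_window[2], by = config$sample_step_nm)
  ys <- seq(-config$plane_halfwidth_nm, config$plane_halfwidth_nm,
            by = vol$voxel_size_nm / 2)
  fit_wall <- function(sign_x) {
    grid <- as.matrix(expand.grid(x = sign_x * xs, z = zs))
    vals <- rowMeans(vapply(ys, function(y)
      interp_nm(sym, cbind(grid[, 1], y, grid[, 2])),
      numeric(nrow(grid))))
    thr <- quantile(vals, config$density_quantile)
    sel <- vals >= thr
    if (sum(sel) < 20 || !any(vals > min(vals)) || sum(vals[sel]) <= 0)
      stop("insufficient density in the C-ring window for an ellipse fit",
           call. = FALSE)
    # background-subtracted weights: tails that barely clear the threshold
    # (e.g. from the excluded cap) contribute almost nothing
    w <- vals[sel] - thr
    if (sum(w) <= 0) w <- vals[sel]
    list(ell = moments_ellipse(grid[sel, 1], grid[sel, 2], w),
         x = grid[sel, 1], z = grid[sel, 2], w = w)
  }
  right <- fit_wall(+1)
  left <- fit_wall(-1)
  lr <- c(left$ell$major_axis_angle_deg, right$ell$major_axis_angle_deg)
  structure(list(tilt_deg = mean(lr), side = "mean",
                 left_deg = lr[1], right_deg = lr[2],
                 fit = list(left = left$ell, right = right$ell),
                 points = list(left = left[c("x", "z", "w")],
                               right = right[c("x", "z", "w")]),
                 quality_flag = abs(diff(lr)) > 2),
            class = "tilt_result")
}

#' @export
print.tilt_result <- function(x, ...) {
  cat(sprintf("<tilt_result> C-ring tilt %.2f deg (left %.2f, right %.2f)%s\n",
              x$tilt_deg, x$left_deg, x$right_deg,
              if (x$quality_flag) " [wall discrepancy > 2 deg]" else ""))
  invisible(x)
}

#' Unroll a volume onto cylindrical coordinates
#'
#' Trilinear resampling onto a (theta x z x r) grid; theta covers
#' \[0, 360) degrees. Ring features at different radii appear side by side,
#' which is how symmetry mismatches between the C-ring and the collar are
#' displayed.
#'
#' @param vol a [volume()] centred on the rotation axis.
#' @param r_range numeric `(r_min_nm, r_max_nm)`, strictly positive (the
#'   axis itself has a degenerate Jacobian).
#' @param z_range numeric `(z_min_nm, z_max_nm)`.
#' @param angular_samples number of theta samples.
#' @return 3D array (theta x z x r) of class `unrolled_map` with
#'   attributes `theta_deg`, `z_nm`, `r_nm`.
#' @export
unroll_map <- function(vol, r_range, z_range, angular_samples = 360) {
  stopifnot_volume(vol)
  if (r_range[1] <= 0)
    stop("r_range must exclude the axis (r_min > 0)", call. = FALSE)
  if (r_range[1] >= r_range[2] || z_range[1] >= z_range[2])
    stop("degenerate r_range or z_range", call. = FALSE)
  step <- vol$voxel_size_nm
  th <- seq(0, 360 - 360 / angular_samples, length.out = angular_samples)
  zs <- seq(z_range[1], z_range[2], by = step)
  rs <- seq(r_range[1], r_range[2], by = step)
  pts <- cbind(
    x = as.vector(outer(cospi(th / 180), rep(rs, each = length(zs)))),
    y = as.vector(outer(sinpi(th / 180), rep(rs, each = length(zs)))),
    z = rep(rep(zs, times = length(rs)), each = angular_samples))
  vals <- interp_nm(vol, pts)
  out <- array(vals, c(angular_samples, length(zs), length(rs)))
  attr(out, "theta_deg") <- th
  attr(out, "z_nm") <- zs
  attr(out, "r_nm") <- rs
  class(out) <- "unrolled_map"
  out
}
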