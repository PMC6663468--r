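#' Pose: a rigid transform in the package's single convention
#'
#' A pose is a ZYZ-intrinsic Euler rotation (degrees) about the volume's
#' `origin_voxel`, followed by a shift in voxels: the transformed volume is
#' `T(v)(y) = v(R^-1 (y - c - s) + c)` with `c` the origin and `s` the
#' shift, i.e. points map as `y = R (x - c) + c + s`.
#'
#' Everywhere in the package a *stored* pose (particle tables, alignment
#' results, ground truth) is the alignment transform: applying it to the
#' particle brings the particle into the canonical/reference frame.
#'
#' @param euler_deg numeric 3-vector `(phi, theta, psi)`, ZYZ intrinsic,
#'   degrees.
#' @param shift_voxels numeric 3-vector, applied after the rotation.
#' @return object of class `pose`.
#' @export
pose <- function(euler_deg = c(0, 0, 0), shift_voxels = c(0, 0, 0)) {
  stopifnot(length(euler_deg) == 3L, length(shift_voxels) == 3L,
            all(is.finite(euler_deg)), all(is.finite(shift_voxels)))
  structure(list(euler_deg = normalize_angle(as.numeric(euler_deg)),
                 shift_voxels = as.numeric(shift_voxels)),
            class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> euler ZYZ (%.3g, %.3g, %.3g) deg, shift (%.3g, %.3g, %.3g) vox\n",
              x$euler_deg[1], x$euler_deg[2], x$euler_deg[3],
              x$shift_voxels[1], x$shift_voxels[2], x$shift_voxels[3]))
  invisible(x)
}

#' Normalize angles to [-180, 180) degrees
#' @param a numeric vector of angles in degrees.
#' @return normalized angles.
#' @export
normalize_angle <- function(a) ((a + 180) %% 360) - 180

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

#' Rotation matrix from ZYZ-intrinsic Euler angles
#' @param euler_deg `(phi, theta, psi)` in degrees.
#' @return 3x3 rotation matrix.
#' @export
euler_to_matrix <- function(euler_deg) {
  rot_z(euler_deg[1]) %*% rot_y(euler_deg[2]) %*% rot_z(euler_deg[3])
}

#' ZYZ-intrinsic Euler angles from a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return `(phi, theta, psi)` in degrees, normalized to \[-180, 180).
#' @export
matrix_to_euler <- function(R) {
  theta <- acos(max(-1, min(1, R[3, 3])))
  if (sin(theta) > 1e-9) {
    phi <- atan2(R[2, 3], R[1, 3])
    psi <- atan2(R[3, 2], -R[3, 1])
  } else {
    # theta ~ 0 or 180: only phi + psi (or phi - psi) determined; set psi = 0
    phi <- if (R[3, 3] > 0) atan2(R[2, 1], R[1, 1]) else atan2(-R[2, 1], -R[1, 1])
    psi <- 0
  }
  normalize_angle(c(phi, theta, psi) * 180 / pi)
}

#' Invert a pose
#' @param p a [pose()].
#' @return the inverse pose.
#' @export
pose_inverse <- function(p) {
  R <- euler_to_matrix(p$euler_deg)
  Rt <- t(R)
  pose(matrix_to_euler(Rt), as.numeric(-Rt %*% p$shift_voxels))
}

#' Compose two poses
#'
#' `pose_compose(p2, p1)` is the pose that applies `p1` first, then `p2`.
#' @param p2,p1 poses.
#' @return the composed pose.
#' @export
pose_compose <- function(p2, p1) {
  R1 <- euler_to_matrix(p1$euler_deg)
  R2 <- euler_to_matrix(p2$euler_deg)
  pose(matrix_to_euler(R2 %*% R1),
       as.numeric(R2 %*% p1$shift_voxels) + p2$shift_voxels)
}

#' Apply a pose to a volume
#'
#' Resamples with trilinear interpolation (zero outside the grid).
#'
#' @param vol a [volume()].
#' @param p a [pose()].
#' @return the transformed volume.
#' @export
apply_pose <- function(vol, p) {
  stopifnot_volume(vol)
  R <- euler_to_matrix(p$euler_deg)
  Rinv <- t(R)
  cvec <- vol$origin_voxel
  b <- as.numeric(cvec - Rinv %*% (cvec + p$shift_voxels))
  d <- dim(vol$data)
  out <- affine_interp_cpp(vol$data, d, d, Rinv, b, nearest = FALSE)
  volume(array(out, d), vol$voxel_size_nm, vol$origin_voxel)
}

identity_pose <- function() pose(c(0, 0, 0), c(0, 0, 0))

# Interpolate a volume at physical nm positions (n x 3 matrix, coordinates
# relative to the rotation-axis origin).
interp_nm <- function(vol, pts_nm, nearest = FALSE) {
  pts_vox <- sweep(pts_nm / vol$voxel_size_nm, 2, vol$origin_voxel, "+")
  interp_points_cpp(vol$data, dim(vol$data), pts_vox, nearest = nearest)
}
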