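#' Construct a density volume
#'
#' A `volume` is the universal currency of the pipeline: a 3D scalar grid
#' with a physical voxel size and an `origin_voxel` locating the rotation
#' axis centre (0-based voxel coordinates, voxel centres at integers).
#'
#' @param data numeric 3D array; every dimension must be at least 8 and all
#'   values finite.
#' @param voxel_size_nm positive scalar, edge length of a voxel in nm.
#' @param origin_voxel numeric 3-vector, 0-based voxel coordinate of the
#'   rotation-axis centre. Defaults to `floor(dim/2)`, which coincides with
#'   the FFT centre.
#' @return an object of class `volume`.
#' @export
volume <- function(data, voxel_size_nm = 1, origin_voxel = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (any(dim(data) < 8L))
    stop("grid dimensions must be >= 8 in every axis", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume data must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      !is.finite(voxel_size_nm) || voxel_size_nm <= 0)
    stop("`voxel_size_nm` must be a positive scalar", call. = FALSE)
  if (is.null(origin_voxel)) origin_voxel <- floor(dim(data) / 2)
  if (length(origin_voxel) != 3L || !all(is.finite(origin_voxel)))
    stop("`origin_voxel` must be a finite 3-vector", call. = FALSE)
  structure(list(data = data,
                 voxel_size_nm = as.numeric(voxel_size_nm),
                 origin_voxel = as.numeric(origin_voxel)),
            class = "volume")
}

#' @export
print.volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume> %d x %d x %d voxels, %.4g nm/voxel (%.3g x %.3g x %.3g nm)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * x$voxel_size_nm, d[2] * x$voxel_size_nm, d[3] * x$voxel_size_nm))
  cat(sprintf("  origin voxel: (%g, %g, %g); range [%.4g, %.4g]\n",
              x$origin_voxel[1], x$origin_voxel[2], x$origin_voxel[3],
              min(x$data), max(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, "volume")

stopifnot_volume <- function(x, arg = "vol") {
  if (!is_volume(x)) stop(sprintf("`%s` must be a volume", arg), call. = FALSE)
  invisible(x)
}

#' Physical axis coordinates of a volume
#'
#' Returns, for one axis, the nm coordinate of every voxel centre relative
#' to the rotation-axis origin.
#'
#' @param vol a [volume()].
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @return numeric vector of length `dim(vol$data)[axis]`.
#' @export
axis_coords_nm <- function(vol, axis) {
  stopifnot_volume(vol)
  n <- dim(vol$data)[axis]
  (seq_len(n) - 1 - vol$origin_voxel[axis]) * vol$voxel_size_nm
}

# nm coordinate grids for every voxel; returns list(x, y, z) of 3D arrays
coord_grids_nm <- function(vol) {
  d <- dim(vol$data)
  cx <- axis_coords_nm(vol, 1)
  cy <- axis_coords_nm(vol, 2)
  cz <- axis_coords_nm(vol, 3)
  list(x = array(cx, d),
       y = array(rep(cy, each = d[1]), d),
       z = array(rep(cz, each = d[1] * d[2]), d))
}

# --- MRC2014 I/O -----------------------------------------------------------
#
# Minimal little-endian MRC2014 subset: modes 0 (int8), 1 (int16),
# 2 (float32) and 6 (uint16); axis order honored via mapc/mapr/maps.
# Voxel size is cell length / sampling, stored in Angstrom, exposed in nm.

MRC_HEADER_BYTES <- 1024L

#' Read an MRC2014 volume
#'
#' @param path path to an MRC2014 file (little-endian, mode 0/1/2/6).
#' @return a [volume()]; voxel size is converted from the header's Angstrom
#'   cell dimensions to nm.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = MRC_HEADER_BYTES)
  if (length(hdr_raw) < MRC_HEADER_BYTES)
    stop("malformed MRC file (truncated header): ", path, call. = FALSE)
  ints  <- readBin(hdr_raw, "integer", n = 256, size = 4, endian = "little")
  flts  <- readBin(hdr_raw, "numeric", n = 256, size = 4, endian = "little")
  map_tag <- rawToChar(hdr_raw[209:212])
  if (!identical(substr(map_tag, 1, 3), "MAP"))
    stop("malformed MRC header (missing MAP tag): ", path, call. = FALSE)
  nxyz <- ints[1:3]
  mode <- ints[4]
  if (any(nxyz < 1) || any(nxyz > 1e4))
    stop("malformed MRC header (bad dimensions): ", path, call. = FALSE)
  mxyz  <- ints[8:10]
  cella <- flts[11:13]
  mapcrs <- ints[17:19]
  nsymbt <- ints[24]
  origin_ang <- flts[50:52]
  n_total <- prod(nxyz)
  if (nsymbt > 0) invisible(readBin(con, "raw", n = nsymbt))
  data <- switch(as.character(mode),
    "0" = as.numeric(readBin(con, "integer", n = n_total, size = 1, signed = TRUE,
                             endian = "little")),
    "1" = as.numeric(readBin(con, "integer", n = n_total, size = 2, signed = TRUE,
                             endian = "little")),
    "2" = readBin(con, "numeric", n = n_total, size = 4, endian = "little"),
    "6" = as.numeric(readBin(con, "integer", n = n_total, size = 2, signed = FALSE,
                             endian = "little")),
    stop("unsupported MRC mode ", mode, " (modes 0/1/2/6 supported)", call. = FALSE))
  if (length(data) < n_total)
    stop("malformed MRC file (truncated data block): ", path, call. = FALSE)
  arr <- array(data, dim = nxyz)
  # header axis mapping: mapc/mapr/maps give the axis (1=x,2=y,3=z) that
  # varies fastest/medium/slowest; permute into x-fastest order if needed
  if (!identical(mapcrs, c(1L, 2L, 3L))) {
    if (!setequal(mapcrs, 1:3))
      stop("malformed MRC header (bad axis mapping)", call. = FALSE)
    arr <- aperm(arr, order(mapcrs))
    cella <- cella[order(mapcrs)]  # cella already follows x,y,z; dims permute
  }
  m <- mxyz
  m[m <= 0] <- nxyz[m <= 0]
  vsz_ang <- cella / m
  if (any(!is.finite(vsz_ang)) || any(vsz_ang <= 0)) vsz_ang <- c(10, 10, 10)
  if (max(vsz_ang) - min(vsz_ang) > 1e-4 * max(vsz_ang))
    warning("anisotropic voxel size in header; using the x spacing")
  voxel_nm <- vsz_ang[1] / 10
  origin_voxel <- if (all(origin_ang == 0)) NULL else origin_ang / 10 / voxel_nm
  volume(arr, voxel_size_nm = voxel_nm, origin_voxel = origin_voxel)
}

#' Write a volume as MRC2014
#'
#' Writes little-endian mode-2 (32-bit float) MRC2014. Float32 data
#' round-trips bit-exactly.
#'
#' @param vol a [volume()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  if (!all(is.finite(vol$data)))
    stop("volume data must be finite before writing", call. = FALSE)
  d <- dim(vol$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                    # nx ny nz
  wi(2L)                   # mode 2 = float32
  wi(c(0L, 0L, 0L))        # nxstart
  wi(d)                    # mx my mz
  wf(d * vol$voxel_size_nm * 10)  # cella (Angstrom)
  wf(c(90, 90, 90))        # cellb
  wi(c(1L, 2L, 3L))        # mapc mapr maps
  wf(c(min(vol$data), max(vol$data), mean(vol$data)))  # dmin dmax dmean
  wi(1L)                   # ispg (volume)
  wi(0L)                   # nsymbt
  wi(integer(25))          # extra (words 26-50); nversion left 0 for brevity
  wf(vol$origin_voxel * vol$voxel_size_nm * 10)  # origin (Angstrom)
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(vol$data))  # rms
  wi(1L)                   # nlabl
  lab <- charToRaw(formatC("motoret volume", width = -80))
  writeBin(lab[1:80], con)
  writeBin(raw(720), con)  # remaining label slots
  wf(vol$data)
  invisible(path)
}
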