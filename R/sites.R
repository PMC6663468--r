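#' Extract the stator-site subvolumes of a motor
#'
#' For site k (k = 0..n_sites-1) the motor is first brought to the
#' canonical frame with its alignment pose, then rotated by
#' `-k * 360 / n_sites` about z so that every site lands at the canonical
#' stator position `(site_radius_nm, 0, site_z_nm)`; a cubic box centred
#' there is cropped. All subvolumes therefore share one canonical frame
#' and can be aligned, classified and averaged together.
#'
#' @param motor a [volume()] (one subtomogram).
#' @param pose the motor's alignment [pose()] (particle to canonical
#'   frame).
#' @param n_sites number of stator sites (default 16).
#' @param site_radius_nm radius of the stator ring (nm).
#' @param site_z_nm z of the canonical stator position (nm).
#' @param box_nm side length of the cubic site box (nm).
#' @return list of `n_sites` [volume()]s.
#' @export
extract_site_subvolumes <- function(motor, pose = NULL, n_sites = 16,
                                    site_radius_nm = 40, site_z_nm = -3,
                                    box_nm = 16) {
  stopifnot_volume(motor, "motor")
  if (is.null(pose)) pose <- identity_pose()
  voxel <- motor$voxel_size_nm
  nb <- 2L * as.integer(floor(box_nm / (2 * voxel))) + 1L
  ctr <- (nb - 1) / 2
  ax <- (seq_len(nb) - 1 - ctr) * voxel
  box <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  # canonical -> particle mapping of the alignment pose
  Rp <- euler_to_matrix(pose$euler_deg)
  shift_nm <- pose$shift_voxels * voxel
  d_nm <- dim(motor$data) * voxel
  sites <- vector("list", n_sites)
  for (k in seq_len(n_sites) - 1L) {
    thk <- k * 2 * pi / n_sites
    Rk <- matrix(c(cos(thk), sin(thk), 0, -sin(thk), cos(thk), 0, 0, 0, 1), 3, 3)
    canon <- t(Rk %*% t(sweep(box, 2, c(site_radius_nm, 0, site_z_nm), "+")))
    part <- t(t(Rp) %*% (t(canon) - shift_nm))
    lo <- -motor$origin_voxel * voxel
    hi <- (dim(motor$data) - 1 - motor$origin_voxel) * voxel
    if (any(part < matrix(lo, nrow(part), 3, byrow = TRUE) - voxel / 2) ||
        any(part > matrix(hi, nrow(part), 3, byrow = TRUE) + voxel / 2))
      stop("site box falls outside the motor volume", call. = FALSE)
    vals <- interp_nm(motor, part)
    sites[[k + 1]] <- volume(array(vals, rep(nb, 3)), voxel,
                             rep(ctr, 3))
  }
  sites
}

#' Spherical mask at the canonical stator position
#'
#' @param template a site subvolume ([volume()]) defining grid and voxel
#'   size; the mask is centred on the grid centre.
#' @param radius_nm sphere radius (nm); default 6, bracketing the ~8 nm
#'   cytoplasmic portion of the stator.
#' @param offset_nm optional 3-vector displacing the sphere centre (nm),
#'   e.g. to build a background mask beside the site.
#' @return a [volume()] with values in {0, 1}.
#' @export
stator_site_mask <- function(template, radius_nm = 6, offset_nm = c(0, 0, 0)) {
  stopifnot_volume(template, "template")
  g <- coord_grids_nm(template)
  m <- (g$x - offset_nm[1])^2 + (g$y - offset_nm[2])^2 +
    (g$z - offset_nm[3])^2 <= radius_nm^2
  volume(m * 1, template$voxel_size_nm, template$origin_voxel)
}

#' Focused alignment of stator-site subvolumes
#'
#' Per-site local alignment against a reference under a real-space mask,
#' with the rotation about the rod axis capped below 2 degrees (the
#' focused-classification constraint). A search spec whose cap is >= 2
#' degrees is rejected.
#'
#' @param sites list of site [volume()]s (see [extract_site_subvolumes()]).
#' @param reference reference [volume()] on the site grid.
#' @param search a [search_spec()] with `max_axis_rot_deg < 2`.
#' @param wedge optional wedge of the sites.
#' @return list with one `(pose, score)` element per site.
#' @export
focused_align_sites <- function(sites, reference, search, wedge = NULL) {
  if (search$max_axis_rot_deg >= 2)
    stop("focused alignment requires max_axis_rot_deg < 2", call. = FALSE)
  lapply(sites, align_particle, reference = reference,
         search = search, wedge = wedge)
}

# two-component 1D Gaussian mixture EM, initialized at the 10th/90th
# percentiles; returns component means/sds/weights and posteriors of the
# high component
# EM from several deterministic starts (10th/90th percentiles first, then
# starts anchored at the extremes for very unbalanced mixtures); the
# highest-likelihood fit wins
gmm2_em <- function(x, max_iter = 200, tol = 1e-10) {
  starts <- list(as.numeric(quantile(x, c(0.1, 0.9))),
                 range(x),
                 best_split_start(x))
  fits <- lapply(starts, function(s) {
    if (is.list(s)) gmm2_em_one(x, s$mu, max_iter, tol, sg = s$sigma, w = s$weight)
    else gmm2_em_one(x, s, max_iter, tol)
  })
  fits[[which.max(vapply(fits, function(f) f$loglik, numeric(1)))]]
}

# exhaustive 1D threshold scan: the maximum-likelihood hard split of the
# scores, used as a global-structure start for EM (EM alone can settle in
# a local optimum when the mixture is very unbalanced)
best_split_start <- function(x) {
  xs <- sort(x)
  n <- length(xs)
  s_floor <- max(0.05 * sd(x), 1e-12)
  cuts <- unique(round(seq(2, n - 1, length.out = min(n - 2, 256))))
  best <- NULL
  for (k in cuts) {
    lo <- xs[1:k]; hi <- xs[(k + 1):n]
    mu <- c(mean(lo), mean(hi))
    sg <- pmax(c(sd(lo), sd(hi)), s_floor)
    if (anyNA(sg)) next
    w <- c(k, n - k) / n
    ll <- sum(log(w[1] * stats::dnorm(x, mu[1], sg[1]) +
                    w[2] * stats::dnorm(x, mu[2], sg[2]) +
                    .Machine$double.xmin))
    if (is.null(best) || ll > best$ll)
      best <- list(mu = mu, sigma = sg, weight = w, ll = ll)
  }
  best
}

gmm2_em_one <- function(x, mu, max_iter = 200, tol = 1e-10, sg = NULL,
                        w = c(0.5, 0.5)) {
  s_floor <- max(0.05 * sd(x), 1e-12)   # guards the unbounded-likelihood collapse
  sg <- if (is.null(sg)) rep(max(sd(x) / 2, s_floor), 2) else pmax(sg, s_floor)
  ll <- ll_old <- -Inf
  r2 <- rep(0.5, length(x))
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r2 <- d2 / tot
    ll <- sum(log(tot))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
    n2 <- sum(r2); n1 <- length(x) - n2
    if (n1 < 1e-8 || n2 < 1e-8) break
    mu <- c(sum((1 - r2) * x) / n1, sum(r2 * x) / n2)
    sg <- sqrt(c(sum((1 - r2) * (x - mu[1])^2) / n1,
                 sum(r2 * (x - mu[2])^2) / n2))
    sg <- pmax(sg, s_floor)
    w <- c(n1, n2) / length(x)
  }
  if (mu[2] < mu[1]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w); r2 <- 1 - r2 }
  list(mu = mu, sigma = sg, weight = w, posterior_high = r2, loglik = ll)
}

#' Classify stator sites as occupied / empty / ambiguous
#'
#' Each site is scored by its mean density inside the stator mask (minus
#' the mean inside an optional background mask); a two-component 1D
#' Gaussian mixture is fitted to the scores (EM, initialized at the
#' 10th/90th percentiles) and a site is labelled `occupied` when its
#' posterior for the high-score component is at least
#' `posterior_threshold`, `empty` when the posterior for the low component
#' is, and `ambiguous` otherwise.
#'
#' Degenerate cases: identical scores give all-`ambiguous`; if the
#' two-component fit does not beat a single Gaussian by BIC the score
#' distribution is treated as unimodal and all sites are labelled
#' `occupied` when the mean score exceeds twice the score sd (scores are
#' background-subtracted, so empty sites score near zero), otherwise
#' `empty`.
#'
#' @param sites list of site [volume()]s, or directly a numeric vector of
#'   scores.
#' @param stator_mask a mask [volume()] (see [stator_site_mask()]);
#'   required when `sites` are volumes.
#' @param seed RNG seed (kept for interface stability; the EM is
#'   deterministic).
#' @param background_mask optional mask whose mean is subtracted from each
#'   score.
#' @param posterior_threshold posterior needed to commit to a class
#'   (default 0.8).
#' @return character vector of labels (`occupied`/`empty`/`ambiguous`)
#'   with the scores attached as attribute `scores`.
#' @export
classify_sites <- function(sites, stator_mask = NULL, seed = 1,
                           background_mask = NULL, posterior_threshold = 0.8) {
  if (is.numeric(sites)) {
    scores <- as.numeric(sites)
  } else {
    if (is.null(stator_mask))
      stop("stator_mask is required when sites are volumes", call. = FALSE)
    scores <- vapply(sites, site_score, numeric(1),
                     stator_mask = stator_mask, background_mask = background_mask)
  }
  if (length(scores) < 2) stop("need at least two sites", call. = FALSE)
  if (posterior_threshold <= 0.5 || posterior_threshold > 1)
    stop("posterior_threshold must be in (0.5, 1]", call. = FALSE)
  labels <- rep("ambiguous", length(scores))
  if (diff(range(scores)) == 0) {
    attr(labels, "scores") <- scores
    return(labels)
  }
  set.seed(seed)
  fit <- gmm2_em(scores)
  # model selection: accept the two-component split only if it beats a
  # single Gaussian by BIC; otherwise the scores are unimodal and all
  # sites share one state
  n <- length(scores)
  ll1 <- sum(stats::dnorm(scores, mean(scores),
                          max(sd(scores), 1e-12), log = TRUE))
  bic1 <- -2 * ll1 + 2 * log(n)
  bic2 <- -2 * fit$loglik + 5 * log(n)
  if (bic1 <= bic2) {
    lab <- if (mean(scores) > 2 * sd(scores)) "occupied" else "empty"
    labels <- rep(lab, length(scores))
  } else {
    hi <- fit$posterior_high
    labels[hi >= posterior_threshold] <- "occupied"
    labels[hi <= 1 - posterior_threshold] <- "empty"
  }
  attr(labels, "scores") <- scores
  attr(labels, "fit") <- fit[c("mu", "sigma", "weight")]
  labels
}

site_score <- function(site, stator_mask, background_mask = NULL) {
  m <- if (is_volume(stator_mask)) stator_mask$data else stator_mask
  s <- sum(site$data * m) / sum(m)
  if (!is.null(background_mask)) {
    b <- if (is_volume(background_mask)) background_mask$data else background_mask
    s <- s - sum(site$data * b) / sum(b)
  }
  s
}

#' Extract, focus-align and classify the stator sites of an ensemble
#'
#' Convenience wrapper over [extract_site_subvolumes()],
#' [focused_align_sites()] and [classify_sites()] for a whole subtomogram
#' ensemble: all sites of all motors are pooled in the canonical site
#' frame, locally aligned against their own pooled average (rod-axis
#' rotation capped below 2 degrees, +/- 1 voxel shifts), scored inside the
#' stator mask against a background sphere midway between neighbouring
#' sites, and classified into occupied / empty / ambiguous.
#'
#' @param stack list of motor [volume()]s (e.g. from
#'   [simulate_ensemble()]).
#' @param poses list of alignment [pose()]s or a [particle_table()].
#' @param strain a [strain_config()] supplying the site count and
#'   canonical stator position.
#' @param align run the focused alignment pass (default `TRUE`).
#' @param seed RNG seed forwarded to [classify_sites()].
#' @return list with `labels`, `scores`, `occupancy` (an
#'   [estimate_occupancy()] result) and `n_sites`.
#' @export
analyze_stator_sites <- function(stack, poses, strain, align = TRUE,
                                 seed = 1) {
  if (inherits(poses, "particle_table")) poses <- particle_poses(poses)
  sites <- list()
  for (i in seq_along(stack))
    sites <- c(sites, extract_site_subvolumes(
      stack[[i]], poses[[i]], n_sites = strain$n_collar,
      site_radius_nm = strain$stator_ring_radius_nm,
      site_z_nm = strain$stator_z_nm))
  if (align) {
    ref <- fourier_average(sites)$density
    sch <- search_spec(angular_grid_deg = 1, max_axis_rot_deg = 1.9,
                       max_shift_voxels = 1,
                       mask = stator_site_mask(sites[[1]], radius_nm = 7.5))
    al <- focused_align_sites(sites, ref, sch)
    sites <- lapply(seq_along(sites), function(i)
      apply_pose(sites[[i]], al[[i]]$pose))
  }
  smask <- stator_site_mask(sites[[1]])
  half_site <- pi / strain$n_collar
  bmask <- stator_site_mask(sites[[1]], offset_nm = c(
    strain$stator_ring_radius_nm * (cos(half_site) - 1),
    strain$stator_ring_radius_nm * sin(half_site), 0))
  labels <- classify_sites(sites, smask, seed = seed,
                           background_mask = bmask)
  list(labels = labels, scores = attr(labels, "scores"),
       occupancy = estimate_occupancy(labels, strain$n_collar),
       n_sites = length(sites))
}

#' Occupancy statistic from site labels
#'
#' Occupancy is the number of occupied-class sites divided by the *total*
#' number of sites (ambiguous sites count in the denominator);
#' `mean_stators_per_motor` is occupancy times the number of sites per
#' motor.
#'
#' @param labels character vector from [classify_sites()].
#' @param n_collar stator sites per motor (default 16).
#' @return object of class `occupancy_estimate`: list with `n_occupied`,
#'   `n_empty`, `n_ambiguous`, `occupancy` and `mean_stators_per_motor`.
#' @export
estimate_occupancy <- function(labels, n_collar = 16) {
  if (length(labels) < 1) stop("need at least one label", call. = FALSE)
  bad <- setdiff(unique(labels), c("occupied", "empty", "ambiguous"))
  if (length(bad)) stop("invalid labels: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n_occ <- sum(labels == "occupied")
  n_emp <- sum(labels == "empty")
  n_amb <- sum(labels == "ambiguous")
  occ <- n_occ / length(labels)
  structure(list(n_occupied = n_occ, n_empty = n_emp, n_ambiguous = n_amb,
                 occupancy = occ,
                 mean_stators_per_motor = occ * n_collar),
            class = "occupancy_estimate")
}

#' @export
print.occupancy_estimate <- function(x, ...) {
  cat(sprintf("<occupancy_estimate> %d occupied / %d empty / %d ambiguous: occupancy %.1f%% (~%.1f stators/motor)\n",
              x$n_occupied, x$n_empty, x$n_ambiguous, 100 * x$occupancy,
              x$mean_stators_per_motor))
  invisible(x)
}
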