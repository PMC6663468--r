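with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
}

resolve_run_config <- function(config, seed) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    config <- yaml::read_yaml(config)
  if (is.character(config)) config <- list(strain = config)
  if (inherits(config, "strain_config")) config <- list(strain = config)
  if (inherits(config, "simulation_spec")) return(config)
  if (!is.list(config) || is.null(config$strain))
    stop("config must name a preset or provide a `strain` entry", call. = FALSE)
  strain <- config$strain
  if (is.list(strain) && !inherits(strain, "strain_config"))
    strain <- do.call(strain_config, strain)
  args <- config[setdiff(names(config), c("strain", "wedge"))]
  wedge <- if (is.null(config$wedge)) wedge_spec()
  else if (inherits(config$wedge, "wedge_spec")) config$wedge
  else do.call(wedge_spec, config$wedge)
  do.call(simulation_spec,
          c(list(strain = strain, wedge = wedge, seed = seed), args))
}

#' Run the full per-strain analysis
#'
#' simulate -> average -> symmetry -> FSC -> site classification ->
#' occupancy -> tilt -> diameters, for one strain, with every stage fed by
#' the previous one. Identical `(config, seed)` give identical reports.
#'
#' @param config a preset name (see [strain_presets()]), a
#'   [strain_config()], a [simulation_spec()], a list with a `strain`
#'   entry plus [simulation_spec()] overrides, or the path of a YAML file
#'   with the same keys.
#' @param seed integer seed governing every random stage.
#' @param out_dir optional directory: the average map (MRC2014), the
#'   per-site classification table (TSV), the FSC curve (TSV) and the
#'   report (YAML) are written there.
#' @return object of class `strain_report`.
#' @export
run_strain <- function(config, seed = 1, out_dir = NULL) {
  spec <- with_stage("config", resolve_run_config(config, seed))
  strain <- spec$strain
  sim <- with_stage("simulate", simulate_ensemble(spec))
  poses <- particle_poses(sim$particles)

  avg <- with_stage("average",
                    fourier_average(sim$stack, poses, spec$wedge))
  z_top <- strain$cring_z_top_nm
  z_bot <- z_top - strain$cring_wall_height_nm
  cring_shell <- c(24, 32, z_bot, z_top)
  collar_shell <- c(34, 46, strain$stator_z_nm - 5, strain$collar_z_nm + 4)
  orders <- with_stage("symmetry", list(
    cring = detect_symmetry_order(
      angular_power_spectrum(avg$density, cring_shell)),
    collar = detect_symmetry_order(
      angular_power_spectrum(avg$density, collar_shell))))

  fsc <- with_stage("fsc",
                    split_half_fsc(sim$stack, poses, spec$wedge, seed = seed))

  site_res <- with_stage("classify",
                         analyze_stator_sites(sim$stack, poses, strain,
                                              seed = seed))
  labels <- site_res$labels
  occupancy <- site_res$occupancy

  tilt <- with_stage("tilt", cring_tilt_angle(
    avg$density, tilt_config(sym_order = strain$n_collar,
                             z_window = c(z_bot, z_top))))

  diameters <- with_stage("diameter", {
    prof_bot <- radial_profile(avg$density, c(z_bot, z_bot + 3))
    prof_top <- radial_profile(avg$density, c(z_top - 3, z_top))
    prof_st <- radial_profile(avg$density,
                              strain$stator_z_nm + c(-4, 4))
    list(bottom_nm = as.numeric(measure_ring_diameter(prof_bot, c(24, 34))),
         top_nm = as.numeric(measure_ring_diameter(prof_top, c(24, 34))),
         stator_nm = if (occupancy$n_occupied > 0)
           as.numeric(measure_ring_diameter(prof_st, c(34, 46)))
         else NA_real_)
  })

  report <- structure(list(
    strain = strain$name,
    n_motors = spec$n_motors,
    seed = seed,
    detected_cring_order = orders$cring,
    detected_collar_order = orders$collar,
    occupancy = occupancy,
    tilt = tilt,
    diameters = diameters,
    fsc_resolution = list(at_0.5 = resolution_at(fsc, 0.5),
                          at_0.143 = resolution_at(fsc, 0.143)),
    snr = spec$snr,
    box_voxels = spec$box_voxels,
    voxel_size_nm = spec$voxel_size_nm),
    class = "strain_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_volume(avg$density, file.path(out_dir, "average.mrc"))
    site_tab <- particle_table(data.frame(
      particle_id = sprintf("%s_m%03d_s%02d", strain$name,
                            rep(seq_len(spec$n_motors),
                                each = strain$n_collar),
                            rep(seq_len(strain$n_collar) - 1L,
                                spec$n_motors)),
      motor_id = rep(sim$particles$motor_id, each = strain$n_collar),
      site_index = rep(seq_len(strain$n_collar) - 1L, spec$n_motors),
      score = attr(labels, "scores"),
      class_label = as.character(labels),
      stringsAsFactors = FALSE))
    write_particles(site_tab, file.path(out_dir, "sites.tsv"))
    write.table(fsc, file.path(out_dir, "fsc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    yaml::write_yaml(report_to_list(report), file.path(out_dir, "report.yaml"))
  }
  report
}

report_to_list <- function(r) {
  list(strain = r$strain, n_motors = r$n_motors, seed = r$seed,
       detected_cring_order = r$detected_cring_order,
       detected_collar_order = r$detected_collar_order,
       occupancy_pct = 100 * r$occupancy$occupancy,
       n_occupied = r$occupancy$n_occupied,
       n_empty = r$occupancy$n_empty,
       n_ambiguous = r$occupancy$n_ambiguous,
       mean_stators_per_motor = r$occupancy$mean_stators_per_motor,
       tilt_deg = r$tilt$tilt_deg,
       tilt_left_deg = r$tilt$left_deg,
       tilt_right_deg = r$tilt$right_deg,
       diameter_bottom_nm = r$diameters$bottom_nm,
       diameter_top_nm = r$diameters$top_nm,
       diameter_stator_nm = r$diameters$stator_nm,
       fsc_resolution_0.5 = r$fsc_resolution$at_0.5,
       fsc_resolution_0.143 = r$fsc_resolution$at_0.143,
       snr = r$snr, box_voxels = r$box_voxels,
       voxel_size_nm = r$voxel_size_nm)
}

#' @export
print.strain_report <- function(x, ...) {
  cat(sprintf("<strain_report> %s (%d motors, SNR %s, seed %d)\n",
              x$strain, x$n_motors, format(x$snr), x$seed))
  cat(sprintf("  symmetry: C-ring %d-fold, collar/stator %d-fold\n",
              x$detected_cring_order, x$detected_collar_order))
  cat(sprintf("  occupancy: %.1f%% (~%.1f stators/motor; %d occ / %d empty / %d amb)\n",
              100 * x$occupancy$occupancy, x$occupancy$mean_stators_per_motor,
              x$occupancy$n_occupied, x$occupancy$n_empty,
              x$occupancy$n_ambiguous))
  cat(sprintf("  C-ring tilt: %.2f deg\n", x$tilt$tilt_deg))
  cat(sprintf("  diameters: bottom %.1f nm, top %.1f nm, stator %s nm\n",
              x$diameters$bottom_nm, x$diameters$top_nm,
              ifelse(is.na(x$diameters$stator_nm), "--",
                     sprintf("%.1f", x$diameters$stator_nm))))
  cat(sprintf("  FSC resolution: %.3f (0.5) / %.3f (0.143) cycles/nm\n",
              x$fsc_resolution$at_0.5, x$fsc_resolution$at_0.143))
  invisible(x)
}

#' Cross-strain comparison table
#'
#' Tabulates occupancy, stators per motor, tilt and diameters per strain
#' and checks the expected tilt ordering (WT < D24E < D24N < dmotB) when
#' those four strains are present.
#'
#' @param reports list of `strain_report`s (>= 2, unique strain names).
#' @return data.frame of class `strain_comparison` with attribute
#'   `tilt_ordering` (`"pass"`, `"fail"`, or `NA` when the four reference
#'   strains are not all present).
#' @export
compare_strains <- function(reports) {
  if (length(reports) < 2)
    stop("need at least two strain reports to compare", call. = FALSE)
  names_ <- vapply(reports, function(r) r$strain, character(1))
  if (anyDuplicated(names_))
    stop("duplicate strain names in reports", call. = FALSE)
  tab <- do.call(rbind, lapply(reports, function(r) data.frame(
    strain = r$strain,
    n_motors = r$n_motors,
    cring_order = r$detected_cring_order,
    collar_order = r$detected_collar_order,
    occupancy_pct = 100 * r$occupancy$occupancy,
    stators_per_motor = r$occupancy$mean_stators_per_motor,
    tilt_deg = r$tilt$tilt_deg,
    diameter_bottom_nm = r$diameters$bottom_nm,
    diameter_top_nm = r$diameters$top_nm,
    diameter_stator_nm = r$diameters$stator_nm,
    stringsAsFactors = FALSE)))
  ref <- c("WT", "D24E", "D24N", "dmotB")
  ordering <- NA_character_
  if (all(ref %in% tab$strain)) {
    tilts <- tab$tilt_deg[match(ref, tab$strain)]
    ordering <- if (all(diff(tilts) > 0)) "pass" else "fail"
  }
  attr(tab, "tilt_ordering") <- ordering
  class(tab) <- c("strain_comparison", "data.frame")
  tab
}

#' @export
print.strain_comparison <- function(x, ...) {
  print.data.frame(x, digits = 3, row.names = FALSE)
  ord <- attr(x, "tilt_ordering")
  if (!is.na(ord))
    cat(sprintf("tilt ordering WT < D24E < D24N < dmotB: %s\n", ord))
  invisible(x)
}
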