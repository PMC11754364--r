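# package-session state: per-channel phasor cache + solver call counter
.ph_env <- new.env(parent = emptyenv())
.ph_env$cache <- new.env(parent = emptyenv())
.ph_env$solver_calls <- 0L

#' Solver invocation counter
#'
#' Number of full FDTD channel solves since the last reset (mirrored or
#' cached channels do not count). Used to verify channel-field reuse across
#' drive settings.
#' @param reset reset the counter to zero.
#' @return integer count (before any reset).
#' @export
solver_call_count <- function(reset = FALSE) {
  n <- .ph_env$solver_calls
  if (reset) .ph_env$solver_calls <- 0L
  n
}

#' Clear the in-session channel-field cache
#' @export
clear_field_cache <- function() {
  .ph_env$cache <- new.env(parent = emptyenv())
  invisible(NULL)
}

#' Published validation scenarios
#'
#' Loads the scenario families shipped as YAML data (one file per published
#' measurement set-up: AMC-2 phase sweep, AMC-4 homogeneous and inhomogeneous
#' set-ups, Sigma-30 equal drive, Sigma-60 frequency/focus grid). Settings
#' are data, not code.
#'
#' @return named list of `scenario` objects.
#' @export
scenario_registry <- function() {
  dir <- system.file("scenarios", package = "phasedheat")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  out <- lapply(files, read_scenario_yaml)
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Read / write a scenario as YAML
#'
#' @param path YAML file path.
#' @return a `scenario` object (reader); `path` (writer).
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(!is.null(y$name), !is.null(y$device), !is.null(y$phantom))
  y$drives <- lapply(y$drives, function(d) {
    d$channels <- lapply(d$channels, function(ch) {
      ch$power <- as.numeric(ch$power)
      if (!is.null(ch$phase_deg)) ch$phase_deg <- as.numeric(ch$phase_deg)
      ch
    })
    d
  })
  structure(y, class = "scenario")
}

#' @rdname read_scenario_yaml
#' @param scenario a `scenario` object.
#' @export
write_scenario_yaml <- function(scenario, path) {
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario %s: device %s, phantom %s, %d drive(s)>\n",
              x$name, x$device, x$phantom, length(x$drives)))
  invisible(x)
}

# resolve a scenario drive entry into a drive_setting (computing focal-point
# phases when requested; a drive may not list both phases and a focal point)
.resolve_drive <- function(drv, device) {
  chans <- names(drv$channels)
  power <- vapply(drv$channels, function(c) c$power, 0)
  names(power) <- chans
  listed <- vapply(drv$channels, function(c) !is.null(c$phase_deg), logical(1))
  if (!is.null(drv$focal_point_cm)) {
    if (any(listed))
      stop(sprintf("drive '%s': phases must not be listed when focal_point_cm is given",
                   drv$name))
    ph <- focal_phases(as.numeric(drv$focal_point_cm), drv$f_MHz,
                       device$ring_radius_cm)$phase_deg[chans]
  } else {
    ph <- vapply(drv$channels, function(c)
      if (is.null(c$phase_deg)) 0 else c$phase_deg, 0)
    names(ph) <- chans
  }
  drive_setting(drv$f_MHz, power, ph, total_power_W = drv$total_power_W)
}

# build the phantom spec named in a scenario
.scenario_phantom <- function(scenario) {
  switch(scenario$phantom,
    amc_homog = build_amc_elliptical(TRUE, 1.15,
                                     muscle = scenario$muscle %||% "muscle_amc4",
                                     model_length_m = scenario$model_length_m %||% 0.60),
    amc_fatcore = build_amc_elliptical(FALSE, 0.50, muscle = "muscle_amc4"),
    sigma30_cyl = build_sigma30_cylinder(),
    cdrh = build_cdrh_phantom(),
    stop(sprintf("unknown phantom '%s'", scenario$phantom)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# domain half-extent (m) per device around its phantom
.scenario_domain <- function(device_name, phantom, spacing) {
  z_ph <- phantom$half_extent[3]
  switch(device_name,
    amc2 = c(0.18 + 2 * spacing,
             0.12 + 0.06 + 0.12 + 3 * spacing,
             max(0.21, z_ph) + 2 * spacing),
    amc4 = c(0.18 + 0.04 + 0.12 + 3 * spacing,
             0.12 + 0.04 + 0.12 + 3 * spacing,
             max(0.21, z_ph) + 2 * spacing),
    sigma30 = c(0.16 + 3 * spacing, 0.16 + 3 * spacing,
                max(0.15, z_ph) + 2 * spacing),
    sigma60 = c(0.30 + 3 * spacing, 0.30 + 3 * spacing,
                max(0.25, z_ph) + 2 * spacing),
    stop(sprintf("unknown device '%s'", device_name)))
}

# build scene + device for a scenario at a resolution
.scenario_build <- function(scenario, resolution, f_MHz, n_pml = 16L) {
  phantom <- .scenario_phantom(scenario)
  half <- .scenario_domain(scenario$device, phantom, resolution)
  grid <- scene_grid(resolution, half, n_pml = n_pml)
  scene <- phantom_scene(phantom, grid, f_MHz)
  device <- switch(scenario$device,
    amc2 = build_amc2(scene, top_aperture_cm = scenario$top_aperture_cm %||% 20,
                      phantom = phantom),
    amc4 = build_amc4(scene, bolus_cm = scenario$bolus_cm %||% 4,
                      phantom = phantom),
    sigma30 = build_sigma_ring(scene, "sigma30"),
    sigma60 = build_sigma_ring(scene, "sigma60",
                               bolus_length_m = scenario$bolus_length_m %||% NULL))
  list(phantom = phantom, device = device)
}

# scene mirror-symmetry check along axis (1 = x, 2 = y)
.scene_symmetric <- function(scene, axis) {
  lab <- scene$labels
  d <- dim(lab)
  if (d[axis] %% 2L == 0L) return(FALSE)
  flipped <- if (axis == 1) lab[rev(seq_len(d[1])), , , drop = FALSE]
             else lab[, rev(seq_len(d[2])), , drop = FALSE]
  identical(as.integer(lab), as.integer(flipped))
}

#' Solve (or reuse) all channel fields of a device
#'
#' Runs the FDTD solver once per independent channel at the given frequency
#' and reuses results across drives: fields are cached in the session keyed
#' by scenario, frequency and solver configuration, and channels that are
#' exact mirror images of a solved channel (per the device's mirror map, for
#' mirror-symmetric scenes) are obtained by reflection instead of a new
#' solve.
#'
#' @param device a `device_model`.
#' @param config a [solver_config()].
#' @param f_MHz frequency (MHz).
#' @param cache_key character scoping key (e.g. the scenario name);
#'   `NULL` disables caching.
#' @param use_mirror reuse mirror-image channels (default TRUE).
#' @param strict error on unconverged channels.
#' @return named list of `phasor_field`s, one per channel.
#' @export
solve_channels <- function(device, config, f_MHz, cache_key = NULL,
                           use_mirror = TRUE, strict = TRUE) {
  ids <- device_channels(device)
  mirrors <- device$mirror_map
  if (use_mirror) {
    mirrors <- Filter(function(m) .scene_symmetric(device$scene, m$axis), mirrors)
  } else mirrors <- list()
  solve_ids <- setdiff(ids, names(mirrors))
  key_of <- function(id) paste(cache_key, device$name, id, f_MHz,
                               config$spacing, config$n_pml,
                               config$max_periods, config$convergence_tol,
                               config$courant_factor, sep = "|")
  fields <- list()
  for (id in solve_ids) {
    k <- key_of(id)
    if (!is.null(cache_key) && !is.null(.ph_env$cache[[k]])) {
      fields[[id]] <- .ph_env$cache[[k]]
    } else {
      fields[[id]] <- run_channel(device$scene, device, id, config, f_MHz,
                                  strict = strict)
      .ph_env$solver_calls <- .ph_env$solver_calls + 1L
      if (!is.null(cache_key)) .ph_env$cache[[k]] <- fields[[id]]
    }
  }
  for (id in names(mirrors)) {
    m <- mirrors[[id]]
    fields[[id]] <- mirror_phasor_field(fields[[m$src]], m$axis, id)
  }
  fields[ids]
}

#' Run a published scenario end to end
#'
#' Builds the phantom and device scene, solves (or reuses) the per-channel
#' unit-drive phasors, superposes each drive setting, computes SAR and its
#' 1 cc average, applies the scenario's published normalization convention,
#' and extracts the requested measurement-axis profiles.
#'
#' @param scenario a `scenario` (from [scenario_registry()]).
#' @param resolution voxel size in m (default 0.01; published fidelity is
#'   0.0025).
#' @param config optional [solver_config()] overriding the defaults (its
#'   spacing is forced to `resolution`).
#' @param use_mirror reuse mirror-symmetric channels (default TRUE).
#' @param cache use the in-session channel cache (default TRUE).
#' @param strict error on unconverged channels.
#' @param out_dir optional directory: writes profile CSVs, SAR NIfTI and a
#'   JSON log.
#' @return list with `scenario`, `device`, `fields` (per frequency),
#'   `results` (per drive: `drive`, `sar`, `profiles`), and `log`.
#' @export
run_scenario <- function(scenario, resolution = 0.01, config = NULL,
                         use_mirror = TRUE, cache = TRUE, strict = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(scenario, "scenario"))
  if (abs(0.01 / resolution - round(0.01 / resolution)) > 1e-9)
    stop("resolution must divide 10 mm (1 cc averaging contract)")
  if (is.null(config)) config <- solver_config(spacing = resolution)
  config$spacing <- resolution
  t0 <- proc.time()[["elapsed"]]
  freqs <- unique(vapply(scenario$drives, function(d) d$f_MHz, 0))
  fields_by_f <- list()
  builds <- list()
  log <- list(scenario = scenario$name, resolution = resolution,
              scaled_down = resolution > 0.0025, stages = list())
  for (f in freqs) {
    bld <- .scenario_build(scenario, resolution, f, n_pml = config$n_pml)
    builds[[as.character(f)]] <- bld
    fields_by_f[[as.character(f)]] <-
      solve_channels(bld$device, config, f,
                     cache_key = if (cache) scenario$name else NULL,
                     use_mirror = use_mirror, strict = strict)
    log$stages[[length(log$stages) + 1L]] <- list(
      stage = "solve", f_MHz = f, dims = bld$device$scene$grid$dims,
      residuals = lapply(fields_by_f[[as.character(f)]], function(x) x$residual))
  }
  results <- list()
  for (drv in scenario$drives) {
    bld <- builds[[as.character(drv$f_MHz)]]
    drive <- .resolve_drive(drv, bld$device)
    E <- superpose(fields_by_f[[as.character(drv$f_MHz)]], drive)
    sar <- sar_from_efield(E, bld$device$scene)
    if (!is.null(drive$total_power_W))
      sar <- scale_to_total_power(sar, drive$total_power_W)
    sar <- sar_1cc_average(sar)
    profs <- list()
    for (pr in scenario$profiles) {
      nm <- sprintf("%s_z%g", pr$axis, pr$z_offset_cm)
      profs[[nm]] <- extract_profile(sar, pr$axis, pr$z_offset_cm)
    }
    results[[drv$name]] <- list(name = drv$name, drive = drive, sar = sar,
                                profiles = profs)
  }
  # normalization conventions
  norm <- scenario$normalization %||% list(kind = "per_drive_center")
  if (identical(norm$kind, "family_reference")) {
    # one scalar from the reference drive's reference profile center,
    # applied to every profile of every drive in the family
    refp <- results[[norm$reference_drive]]$profiles[[norm$reference_profile]]
    scale <- 100 / .profile_at(refp, 0)
    for (nm in names(results)) {
      results[[nm]]$profiles <- lapply(results[[nm]]$profiles, function(p) {
        p$values <- p$values * scale
        p$normalization <- list(kind = "percent_of_reference",
                                reference = norm$reference_drive)
        p
      })
    }
  } else if (identical(norm$kind, "per_drive_center")) {
    # each drive normalized to 100 at the center of its z = 0 reference
    for (nm in names(results)) {
      profs <- results[[nm]]$profiles
      ref_idx <- which(vapply(profs, function(p) p$z_offset_cm == 0, logical(1)))[1]
      results[[nm]]$profiles <- normalize_profiles(profs, reference = ref_idx)
    }
  } # "absolute": keep W/kg (total-power scaling already applied)
  log$elapsed_s <- proc.time()[["elapsed"]] - t0
  log$solver_calls <- solver_call_count()
  out <- list(scenario = scenario, device = builds[[1]]$device,
              fields = fields_by_f, results = results, log = log)
  if (!is.null(out_dir)) .write_scenario_outputs(out, out_dir)
  out
}

.write_scenario_outputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(out$results)) {
    res <- out$results[[nm]]
    for (pn in names(res$profiles)) {
      write_profile_csv(res$profiles[[pn]],
                        file.path(out_dir, sprintf("%s_%s.csv", nm, pn)))
    }
    if (requireNamespace("RNifti", quietly = TRUE)) {
      write_sar_nifti(res$sar, file.path(out_dir, sprintf("%s_sar.nii.gz", nm)))
    }
  }
  jsonlite::write_json(out$log, file.path(out_dir, "log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
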