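#' FDTD solver configuration
#'
#' @param spacing voxel edge length (m); must match the scene.
#' @param courant_factor fraction of the 3-D stability limit
#'   `dx / (c0 * sqrt(3))`; `0 < courant_factor < 1`.
#' @param n_pml number of convolutional PML layers on every face (default 16).
#' @param ramp_periods carrier periods of the raised-cosine drive ramp.
#' @param max_periods hard cap on simulated carrier periods.
#' @param min_periods minimum periods before convergence may be declared
#'   (default `ramp_periods + 3`).
#' @param convergence_tol relative per-period change of monitor-point |E|
#'   below which the run is steady (default 1e-3).
#' @param kappa_max,alpha_max,grade_m CPML grading parameters (cubic
#'   polynomial grading).
#' @param pml_sigma_scale multiplier on the standard-opacity conductivity
#'   optimum `0.8 (m+1) / (eta0 dx)`. The classic optimum balances theoretical
#'   transmission against profile-discretization error at 10-30 cells per
#'   wavelength; the scenes here are sampled far finer than that, where a
#'   smaller sigma_max reflects less.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(spacing = 0.0025, courant_factor = 0.95,
                          n_pml = 16L, ramp_periods = 3L,
                          max_periods = 60L,
                          min_periods = ramp_periods + 3L,
                          convergence_tol = 1e-3,
                          kappa_max = 8, alpha_max = 0.002, grade_m = 3,
                          pml_sigma_scale = 1) {
  stopifnot(spacing > 0, courant_factor > 0, courant_factor < 1,
            n_pml >= 1, ramp_periods >= 1, max_periods >= 3,
            convergence_tol > 0)
  structure(list(spacing = spacing, courant_factor = courant_factor,
                 n_pml = as.integer(n_pml),
                 ramp_periods = as.integer(ramp_periods),
                 max_periods = as.integer(max_periods),
                 min_periods = as.integer(max(min_periods, 2L)),
                 convergence_tol = convergence_tol,
                 kappa_max = kappa_max, alpha_max = alpha_max,
                 grade_m = grade_m, pml_sigma_scale = pml_sigma_scale),
            class = "solver_config")
}

# time step with an exact integer number of steps per carrier period
.time_step <- function(f_MHz, spacing, courant_factor, ndim = 3) {
  dt0 <- courant_factor * spacing / (.c0 * sqrt(ndim))
  period <- 1 / (f_MHz * 1e6)
  n <- ceiling(period / dt0)
  list(dt = period / n, steps_per_period = as.integer(n))
}

#' Source excitation waveform
#'
#' Unit-amplitude sinusoid at the drive frequency, smoothly ramped from zero
#' with a raised-cosine envelope over `ramp_periods` carrier periods, then
#' constant amplitude. Continuous with continuous first derivative; the ramp
#' keeps the transient spectrum inside the band the grid resolves.
#'
#' @param t time (s), scalar or vector, `>= 0`.
#' @param f_MHz drive frequency (MHz).
#' @param ramp_periods ramp length in carrier periods (default 3).
#' @return drive value(s) in \[-1, 1\].
#' @export
excitation_waveform <- function(t, f_MHz, ramp_periods = 3) {
  stopifnot(all(t >= 0), f_MHz > 0, ramp_periods >= 0)
  f <- f_MHz * 1e6
  t_ramp <- ramp_periods / f
  env <- ifelse(t < t_ramp, 0.5 * (1 - cos(pi * t / t_ramp)), 1)
  env * cos(2 * pi * f * t)
}

#' Complex phasor from a steady-state time series
#'
#' Discrete Fourier projection at the drive frequency over an integer number
#' of periods, under the `exp(+j w t)` convention: the returned `A` satisfies
#' `x(t) = Re(A * exp(1i * w * t))` (peak, not RMS, amplitude).
#'
#' @param samples real time series sampled at spacing `dt`, spanning an
#'   integer number of periods of `f_MHz` in steady state.
#' @param f_MHz frequency (MHz).
#' @param dt sample spacing (s).
#' @return complex scalar amplitude.
#' @export
extract_phasor <- function(samples, f_MHz, dt) {
  n <- length(samples)
  w <- 2 * pi * f_MHz * 1e6
  cycles <- n * dt * f_MHz * 1e6
  if (abs(cycles - round(cycles)) > 1e-6 || round(cycles) < 1)
    stop("sample window must span an integer number of periods")
  t <- (seq_len(n) - 1) * dt
  (2 / n) * sum(samples * exp(-1i * w * t))
}

#' Convergence check between successive phasor fields
#'
#' Residual = maximum absolute change of collocated |E| over the monitor
#' voxels (phantom center plus its six axis-aligned face points), relative to
#' the largest monitor |E|. Converged when the residual is below `tol`.
#'
#' @param previous,current `phasor_field` objects on the same grid.
#' @param tol relative tolerance (default 1e-3).
#' @param monitors optional integer matrix of 0-based voxel indices (rows);
#'   defaults to the fields' stored monitor set, else the grid center +
#'   face points.
#' @return list with `converged` flag and `residual`.
#' @export
check_convergence <- function(previous, current, tol = 1e-3, monitors = NULL) {
  stopifnot(inherits(previous, "phasor_field"), inherits(current, "phasor_field"))
  if (!identical(previous$grid$dims, current$grid$dims))
    stop("phasor fields on different grids")
  if (is.null(monitors)) monitors <- current$monitors
  if (is.null(monitors)) {
    d <- current$grid$dims
    ctr <- floor(d / 2)
    monitors <- rbind(ctr,
                      ctr + c(1, 0, 0) * floor(d[1] / 4), ctr - c(1, 0, 0) * floor(d[1] / 4),
                      ctr + c(0, 1, 0) * floor(d[2] / 4), ctr - c(0, 1, 0) * floor(d[2] / 4),
                      ctr + c(0, 0, 1) * floor(d[3] / 4), ctr - c(0, 0, 1) * floor(d[3] / 4))
  }
  magnitude <- function(fld, ijk) {
    i <- ijk[1] + 1L; j <- ijk[2] + 1L; k <- ijk[3] + 1L
    sqrt(Mod(fld$Ex[i, j, k])^2 + Mod(fld$Ey[i, j, k])^2 + Mod(fld$Ez[i, j, k])^2)
  }
  m_prev <- apply(monitors, 1, magnitude, fld = previous)
  m_cur <- apply(monitors, 1, magnitude, fld = current)
  ref <- max(m_cur, m_prev)
  residual <- if (ref > 0) max(abs(m_cur - m_prev)) / ref else 0
  list(converged = residual < tol, residual = residual)
}

# monitor set: phantom center voxel + 6 face points midway to the phantom surface
.default_monitors <- function(scene, phantom_labels = NULL) {
  d <- scene$grid$dims
  if (is.null(phantom_labels)) {
    ctr <- floor(d / 2)
    off <- pmax(floor(d / 4), 1L)
  } else {
    ctr <- world_to_index(scene$grid, c(0, 0, 0))
    inside <- scene$labels %in% phantom_labels
    idx <- which(array(inside, d), arr.ind = TRUE) - 1L
    half <- floor((apply(idx, 2, max) - apply(idx, 2, min)) / 4)
    off <- pmax(half, 1L)
  }
  m <- rbind(ctr,
             ctr + c(off[1], 0, 0), ctr - c(off[1], 0, 0),
             ctr + c(0, off[2], 0), ctr - c(0, off[2], 0),
             ctr + c(0, 0, off[3]), ctr - c(0, 0, off[3]))
  m[, 1] <- pmin(pmax(m[, 1], 1L), d[1] - 2L)
  m[, 2] <- pmin(pmax(m[, 2], 1L), d[2] - 2L)
  m[, 3] <- pmin(pmax(m[, 3], 1L), d[3] - 2L)
  storage.mode(m) <- "integer"
  unname(m)
}

#' Run the FDTD solver for one drive channel
#'
#' Time-steps Maxwell's curl equations on the staggered grid with per-edge
#' material coefficients, drives the named channel's feed sites with the
#' ramped sinusoid at unit amplitude and zero phase, presents 50 Ohm resistive
#' loads at every other channel's feed sites, and returns the converged
#' single-frequency complex E-field phasor (cell-centered, V/m per volt of
#' drive) extracted by discrete Fourier projection over one steady period.
#'
#' @param scene a [material_grid()] containing phantom + device geometry.
#' @param device a `device_model` (see [build_amc2()] etc.).
#' @param channel_id one of the device's channel ids.
#' @param config a [solver_config()]; its spacing must equal the scene's.
#' @param f_MHz drive frequency (MHz); must lie in the device band.
#' @param drive_amplitude source amplitude multiplier (default 1, the
#'   unit-drive convention).
#' @param strict error on non-convergence (default TRUE).
#' @return object of class `phasor_field`: complex arrays `Ex`, `Ey`, `Ez`
#'   over the grid, plus `channel_id`, `f_MHz`, `residual`, `periods_run`.
#' @export
run_channel <- function(scene, device, channel_id, config, f_MHz,
                        drive_amplitude = 1, strict = TRUE) {
  stopifnot(inherits(scene, "material_grid"), inherits(config, "solver_config"))
  if (abs(config$spacing - scene$grid$spacing) > 1e-12)
    stop("solver_config spacing does not match the scene grid")
  if (f_MHz < device$operating_band[1] || f_MHz > device$operating_band[2])
    stop(sprintf("%g MHz outside the %s operating band [%g, %g]",
                 f_MHz, device$name, device$operating_band[1],
                 device$operating_band[2]))
  ids <- vapply(device$channels, `[[`, "", "id")
  if (!channel_id %in% ids)
    stop(sprintf("unknown channel '%s'; device has: %s", channel_id,
                 paste(ids, collapse = ", ")))
  # scene margin check: device content must keep PML clearance
  occ <- which(array(scene$labels != 0L, scene$grid$dims), arr.ind = TRUE)
  lo <- apply(occ, 2, min) - 1L; hi <- scene$grid$dims - apply(occ, 2, max)
  if (any(c(lo, hi) < config$n_pml))
    stop("scene does not keep n_pml voxels of clearance on every side")

  ts <- .time_step(f_MHz, config$spacing, config$courant_factor)
  tvec <- (seq_len(config$max_periods * ts$steps_per_period) - 0.5) * ts$dt
  wave <- excitation_waveform(tvec, f_MHz, config$ramp_periods)

  src <- .device_source_table(device, channel_id, drive_amplitude)
  monitors <- .default_monitors(scene, device$phantom_labels)

  pal_sigma <- vapply(scene$palette, `[[`, 0, "sigma")
  pal_eps <- vapply(scene$palette, `[[`, 0, "eps_r")
  pal_pec <- vapply(scene$palette, function(m) isTRUE(m$pec), logical(1))

  out <- .fdtd_run_3d(scene$labels, scene$grid$dims,
                      pal_sigma, pal_eps, pal_pec,
                      config$spacing, ts$dt, ts$steps_per_period, wave,
                      as.matrix(src[, c("i", "j", "k")]),
                      as.integer(src$comp), as.numeric(src$resistance),
                      as.numeric(src$amp),
                      config$n_pml, config$kappa_max, config$alpha_max,
                      config$grade_m, config$pml_sigma_scale, monitors,
                      config$convergence_tol, config$max_periods,
                      config$min_periods)
  if (strict && !out$converged)
    stop(sprintf("channel '%s' did not converge in %d periods (residual %.3g)",
                 channel_id, out$periods_run, out$residual))
  d <- scene$grid$dims
  structure(list(grid = scene$grid,
                 Ex = array(out$Ex, d), Ey = array(out$Ey, d),
                 Ez = array(out$Ez, d),
                 channel_id = channel_id, f_MHz = f_MHz,
                 residual = out$residual, converged = out$converged,
                 periods_run = out$periods_run, monitors = monitors),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  cat(sprintf("<phasor_field channel '%s' @ %g MHz, %d x %d x %d, residual %.3g (%d periods)>\n",
              x$channel_id, x$f_MHz, x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3], x$residual, x$periods_run))
  invisible(x)
}

# flat table of feed edges for a run: all channels contribute resistor loads;
# the driven channel's edges additionally carry the source amplitude
.device_source_table <- function(device, driven_id, drive_amplitude = 1) {
  rows <- lapply(device$channels, function(ch) {
    edges <- do.call(rbind, lapply(ch$source_sites, `[[`, "edges"))
    edges$amp <- if (identical(ch$id, driven_id)) drive_amplitude else 0
    edges
  })
  do.call(rbind, rows)
}

#' Mirror a phasor field across a coordinate plane
#'
#' For a scene whose label array is mirror symmetric about the grid center
#' plane normal to `axis`, the field of the mirrored channel equals the
#' mirror image of the solved channel: positions are reflected and the E
#' component along `axis` flips sign. Exact (to solver roundoff) for
#' symmetric scenes; requires an odd voxel count along `axis` so centers map
#' to centers.
#'
#' @param field a `phasor_field`.
#' @param axis 1 (x) or 2 (y).
#' @param channel_id id to assign to the mirrored field.
#' @return a new `phasor_field`.
#' @export
mirror_phasor_field <- function(field, axis, channel_id) {
  stopifnot(inherits(field, "phasor_field"), axis %in% c(1, 2))
  d <- field$grid$dims
  if (d[axis] %% 2L == 0L)
    stop("mirroring requires an odd voxel count along the mirror axis")
  flip <- function(a) {
    idx <- rev(seq_len(d[axis]))
    if (axis == 1) a[idx, , , drop = FALSE] else a[, idx, , drop = FALSE]
  }
  out <- field
  out$Ex <- flip(field$Ex) * (if (axis == 1) -1 else 1)
  out$Ey <- flip(field$Ey) * (if (axis == 2) -1 else 1)
  out$Ez <- flip(field$Ez)
  out$channel_id <- channel_id
  out
}

#' Write / read a per-channel phasor field (raw binary + JSON sidecar)
#'
#' One file per channel: six little-endian float64 volumes (Ex/Ey/Ez real and
#' imaginary, column-major) concatenated, with a JSON sidecar carrying the
#' channel, frequency, grid geometry and convergence residual, so cached
#' fields can be superposed without re-running the solver.
#'
#' @param field a `phasor_field`.
#' @param path output path (`.bin`); sidecar at `<path>.json`.
#' @export
write_phasor_field <- function(field, path) {
  stopifnot(inherits(field, "phasor_field"))
  con <- file(path, "wb")
  on.exit(close(con))
  for (a in list(Re(field$Ex), Im(field$Ex), Re(field$Ey), Im(field$Ey),
                 Re(field$Ez), Im(field$Ez)))
    writeBin(as.numeric(a), con, size = 8L, endian = "little")
  meta <- list(format = "phasedheat-phasor-v1",
               channel_id = field$channel_id, f_MHz = field$f_MHz,
               spacing = field$grid$spacing, dims = field$grid$dims,
               origin = field$grid$origin,
               residual = field$residual, converged = isTRUE(field$converged),
               periods_run = field$periods_run)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_phasor_field
#' @export
read_phasor_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "phasedheat-phasor-v1"))
    stop("not a phasedheat phasor file")
  d <- as.integer(meta$dims)
  n <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  vols <- lapply(1:6, function(i)
    readBin(con, "numeric", n = n, size = 8L, endian = "little"))
  grid <- voxel_grid(meta$spacing, d, as.numeric(meta$origin))
  structure(list(grid = grid,
                 Ex = array(complex(real = vols[[1]], imaginary = vols[[2]]), d),
                 Ey = array(complex(real = vols[[3]], imaginary = vols[[4]]), d),
                 Ez = array(complex(real = vols[[5]], imaginary = vols[[6]]), d),
                 channel_id = meta$channel_id, f_MHz = meta$f_MHz,
                 residual = meta$residual, converged = meta$converged,
                 periods_run = meta$periods_run, monitors = NULL),
            class = "phasor_field")
}
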