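#' Phase-amplitude drive setting
#'
#' Channel amplitudes are `sqrt(power_ratio)` (power is proportional to the
#' amplitude squared); phases are in degrees under the `exp(+j w t)` phasor
#' convention, so a negative phase delays a channel. Absolute wattage enters
#' only through [scale_to_total_power()].
#'
#' @param f_MHz operating frequency (MHz).
#' @param power_ratio named numeric vector of per-channel power ratios (>= 0,
#'   at least one positive).
#' @param phase_deg named numeric vector of per-channel phases (degrees);
#'   defaults to 0 for every channel in `power_ratio`.
#' @param total_power_W optional absolute net absorbed power (W).
#' @return object of class `drive_setting`.
#' @export
drive_setting <- function(f_MHz, power_ratio, phase_deg = NULL,
                          total_power_W = NULL) {
  stopifnot(is.numeric(power_ratio), !is.null(names(power_ratio)),
            all(power_ratio >= 0), any(power_ratio > 0))
  if (is.null(phase_deg)) {
    phase_deg <- setNames(rep(0, length(power_ratio)), names(power_ratio))
  }
  stopifnot(!is.null(names(phase_deg)),
            setequal(names(phase_deg), names(power_ratio)))
  phase_deg <- phase_deg[names(power_ratio)] %% 360
  structure(list(f_MHz = f_MHz, power_ratio = power_ratio,
                 phase_deg = phase_deg, total_power_W = total_power_W),
            class = "drive_setting")
}

#' @export
print.drive_setting <- function(x, ...) {
  cat(sprintf("<drive_setting @ %g MHz>\n", x$f_MHz))
  for (ch in names(x$power_ratio))
    cat(sprintf("  %-7s power %-6g phase %g deg\n", ch,
                x$power_ratio[[ch]], x$phase_deg[[ch]]))
  if (!is.null(x$total_power_W))
    cat(sprintf("  total power %g W\n", x$total_power_W))
  invisible(x)
}

#' Superpose unit-drive channel fields under a drive setting
#'
#' `E_total = sum_i sqrt(power_ratio_i) * exp(1i * phase_i) * E_i` over the
#' per-channel unit-drive phasor fields.
#'
#' @param fields named list of `phasor_field` objects (one per channel), all
#'   on the same grid and frequency.
#' @param drive a [drive_setting()] whose channel names exist in `fields`.
#' @return a `phasor_field` (channel_id `"total"`).
#' @export
superpose <- function(fields, drive) {
  stopifnot(inherits(drive, "drive_setting"), length(fields) >= 1)
  chans <- names(drive$power_ratio)
  missing <- setdiff(chans[drive$power_ratio > 0], names(fields))
  if (length(missing) > 0)
    stop(sprintf("missing channel fields: %s", paste(missing, collapse = ", ")))
  ref <- fields[[1]]
  for (f in fields) {
    if (!identical(f$grid$dims, ref$grid$dims) ||
        abs(f$grid$spacing - ref$grid$spacing) > 1e-12)
      stop("channel fields on different grids")
    if (abs(f$f_MHz - drive$f_MHz) > 1e-9)
      stop(sprintf("field '%s' solved at %g MHz but drive is %g MHz",
                   f$channel_id, f$f_MHz, drive$f_MHz))
  }
  d <- ref$grid$dims
  Ex <- array(0i, d); Ey <- array(0i, d); Ez <- array(0i, d)
  for (ch in chans) {
    w <- sqrt(drive$power_ratio[[ch]]) *
      exp(1i * drive$phase_deg[[ch]] * pi / 180)
    if (Mod(w) == 0) next
    f <- fields[[ch]]
    Ex <- Ex + w * f$Ex; Ey <- Ey + w * f$Ey; Ez <- Ez + w * f$Ez
  }
  structure(list(grid = ref$grid, Ex = Ex, Ey = Ey, Ez = Ez,
                 channel_id = "total", f_MHz = drive$f_MHz,
                 residual = max(vapply(fields, function(f)
                   ifelse(is.null(f$residual), NA_real_, f$residual), 0)),
                 converged = all(vapply(fields, function(f)
                   isTRUE(f$converged), logical(1))),
                 periods_run = NA_integer_, monitors = ref$monitors),
            class = "phasor_field")
}

#' SAR distribution from a total E-field
#'
#' Per voxel, `SAR = sigma / (2 rho) * (|Ex|^2 + |Ey|^2 + |Ez|^2)` with sigma
#' and rho of that voxel's material and peak (not RMS) phasor magnitudes —
#' the factor 1/2 carries the time average. Air, PVC and metal have sigma = 0
#' and absorb nothing.
#'
#' @param E a `phasor_field` (e.g. from [superpose()]).
#' @param scene the [material_grid()] the field was solved on.
#' @return object of class `sar_grid`: `values` (W/kg per voxel), grid,
#'   labels and normalization metadata.
#' @export
sar_from_efield <- function(E, scene) {
  stopifnot(inherits(E, "phasor_field"), inherits(scene, "material_grid"))
  if (!identical(E$grid$dims, scene$grid$dims))
    stop("field and scene grids differ")
  sig <- vapply(scene$palette, `[[`, 0, "sigma")
  rho <- vapply(scene$palette, `[[`, 0, "rho")
  sig_v <- sig[scene$labels + 1L]
  rho_v <- rho[scene$labels + 1L]
  val <- sig_v / (2 * rho_v) * (Mod(E$Ex)^2 + Mod(E$Ey)^2 + Mod(E$Ez)^2)
  structure(list(grid = scene$grid, values = array(val, scene$grid$dims),
                 labels = scene$labels,
                 phantom_labels = attr(scene, "phantom_labels"),
                 rho = rho, averaged = FALSE,
                 normalization = list(kind = "absolute"),
                 f_MHz = E$f_MHz),
            class = "sar_grid")
}

#' @export
print.sar_grid <- function(x, ...) {
  cat(sprintf("<sar_grid %d x %d x %d, %s, %s, max %.3g W/kg>\n",
              x$grid$dims[1], x$grid$dims[2], x$grid$dims[3],
              if (x$averaged) "1cc-averaged" else "raw",
              x$normalization$kind, max(x$values)))
  invisible(x)
}

# sliding window sum along dim 1 over offsets [-lo_off, +hi_off], clipped
.boxsum_dim1 <- function(a, lo_off, hi_off) {
  n1 <- dim(a)[1]
  cs <- apply(a, c(2, 3), cumsum)
  hi <- cs[pmin(seq_len(n1) + hi_off, n1), , , drop = FALSE]
  lo <- array(0, dim(a))
  pos <- seq_len(n1) - lo_off - 1L
  sel <- pos >= 1L
  if (any(sel)) lo[sel, , ] <- cs[pos[sel], , , drop = FALSE]
  hi - lo
}

# window sum over an npc-voxel-per-axis cube (npc^3 voxels).  An even npc
# window cannot be centered on a voxel; using one offset window would bias
# every profile half a voxel, so the two half-voxel-offset windows are
# averaged, which is symmetric and keeps the window mass at npc^3.
.boxsum_dim1_sym <- function(a, npc) {
  hi_off <- npc %/% 2L
  lo_off <- npc - 1L - hi_off
  if (hi_off == lo_off) return(.boxsum_dim1(a, lo_off, hi_off))
  0.5 * (.boxsum_dim1(a, lo_off, hi_off) + .boxsum_dim1(a, hi_off, lo_off))
}

.boxsum3 <- function(a, npc) {
  a <- .boxsum_dim1_sym(a, npc)
  a <- aperm(.boxsum_dim1_sym(aperm(a, c(2, 3, 1)), npc), c(3, 1, 2))
  aperm(.boxsum_dim1_sym(aperm(a, c(3, 1, 2)), npc), c(2, 3, 1))
}

#' 1 cc cube-averaged SAR
#'
#' Replaces each voxel by the mean over the centered cube of 1 cm^3 (e.g.
#' 4x4x4 voxels at 2.5 mm), restricted to voxels of the same phantom medium:
#' averaging never smears across the fat/muscle interface or into the bolus.
#' Voxels whose cube extends outside their medium use the shrunk
#' intersection. Non-phantom voxels are left unaveraged.
#'
#' @param sar a `sar_grid` with raw per-voxel SAR.
#' @return a `sar_grid` with `averaged = TRUE`.
#' @export
sar_1cc_average <- function(sar) {
  stopifnot(inherits(sar, "sar_grid"))
  h <- sar$grid$spacing
  npc <- 0.01 / h
  if (abs(npc - round(npc)) > 1e-9)
    stop("1 cc averaging requires the spacing to divide 10 mm")
  npc <- as.integer(round(npc))
  out <- sar
  if (npc == 1L) { out$averaged <- TRUE; return(out) }  # 10 mm voxel is 1 cc
  vals <- sar$values
  res <- vals
  for (m in sar$phantom_labels) {
    mask <- (sar$labels == m) * 1
    if (!any(mask > 0)) next
    s <- .boxsum3(vals * mask, npc)
    cnt <- .boxsum3(mask, npc)
    sel <- mask > 0
    res[sel] <- s[sel] / cnt[sel]
  }
  out$values <- res
  out$averaged <- TRUE
  out
}

#' SAR from temperature rise, and back
#'
#' `SAR = c * dT / dt`: the initial temperature rise after a short power
#' pulse, before conduction blurs the distribution.
#'
#' @param dT temperature rise (degC).
#' @param dt pulse duration (s), > 0.
#' @param c specific heat capacity (J/kg/degC), > 0.
#' @return SAR in W/kg (or dT in degC for the inverse).
#' @export
sar_from_deltaT <- function(dT, dt, c) {
  stopifnot(dt > 0, c > 0)
  c * dT / dt
}

#' @rdname sar_from_deltaT
#' @param sar SAR (W/kg).
#' @export
deltaT_from_sar <- function(sar, dt, c) {
  stopifnot(dt > 0, c > 0)
  sar * dt / c
}

#' Focal-point phase settings for a quadrant ring
#'
#' Phases that focus a symmetric ring of antenna pairs on a transverse target:
#' `phi_i = 0.1 * f * (D_i - D_max)` with `f` in MHz, `D_i` the transverse
#' distance (cm) from the focal point to quadrant `i` and `D_max` the
#' distance to the furthest quadrant (the 0 degree reference). Nearer
#' channels get negative (delayed) phases.
#'
#' @param focal_xy_cm focal point (x, y) in cm.
#' @param f_MHz operating frequency (MHz).
#' @param ring_radius_cm ring radius in cm, or a device_model.
#' @param antenna_positions_cm optional named list of per-channel (x, y)
#'   positions in cm; defaults to top/bottom/left/right on the ring.
#' @return list with `phase_deg` (integer degrees, as printed on the
#'   consoles) and `phase_deg_exact`.
#' @export
focal_phases <- function(focal_xy_cm, f_MHz, ring_radius_cm,
                         antenna_positions_cm = NULL) {
  if (inherits(ring_radius_cm, "device_model")) {
    ring_radius_cm <- ring_radius_cm$ring_radius_cm
  }
  if (is.null(antenna_positions_cm)) {
    r <- ring_radius_cm
    antenna_positions_cm <- list(top = c(0, r), bottom = c(0, -r),
                                 left = c(-r, 0), right = c(r, 0))
  }
  D <- vapply(antenna_positions_cm, function(p)
    sqrt(sum((p - focal_xy_cm)^2)), 0)
  exact <- 0.1 * f_MHz * (D - max(D))
  list(phase_deg = round(exact), phase_deg_exact = exact, distance_cm = D)
}

#' Scale a SAR grid to an absolute total power
#'
#' Multiplies the SAR by the scalar that makes the volume integral of
#' `SAR * rho` over the whole lossy domain equal `total_power_W`.
#'
#' @param sar a `sar_grid` (raw or averaged; scaling uses the stored raw
#'   integral of the same grid).
#' @param total_power_W net absorbed power (W), > 0.
#' @return rescaled `sar_grid` with normalization metadata.
#' @export
scale_to_total_power <- function(sar, total_power_W) {
  stopifnot(inherits(sar, "sar_grid"), total_power_W > 0)
  h3 <- sar$grid$spacing^3
  rho_v <- sar$rho[sar$labels + 1L]
  absorbed <- sum(sar$values * rho_v) * h3
  if (absorbed <= 0) stop("zero absorbed power; cannot scale")
  out <- sar
  out$values <- sar$values * (total_power_W / absorbed)
  out$normalization <- list(kind = "absolute_watts",
                            total_power_W = total_power_W)
  out
}

#' Write a SAR volume as NIfTI + JSON metadata
#'
#' @param sar a `sar_grid`.
#' @param path output `.nii` / `.nii.gz` path; metadata to `<path>.json`.
#' @export
write_sar_nifti <- function(sar, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output")
  sp_mm <- sar$grid$spacing * 1000
  img <- RNifti::asNifti(sar$values)
  aff <- diag(c(sp_mm, sp_mm, sp_mm, 1))
  aff[1:3, 4] <- sar$grid$origin * 1000
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(format = "phasedheat-sar-v1",
                            spacing = sar$grid$spacing,
                            dims = sar$grid$dims, origin = sar$grid$origin,
                            averaged = sar$averaged,
                            normalization = sar$normalization,
                            f_MHz = sar$f_MHz),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
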