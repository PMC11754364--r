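#' 1-D SAR profile along a measurement axis
#'
#' Samples SAR at voxel centers along the major (x) or minor (y) axis through
#' `(0, 0, z_offset)`, restricted to phantom voxels. Positions are in cm
#' relative to the phantom center.
#'
#' @param sar a `sar_grid` (conventionally 1 cc-averaged; see
#'   [sar_1cc_average()]).
#' @param axis `"major_x"` or `"minor_y"`.
#' @param z_offset_cm axial offset of the measurement line (cm).
#' @return object of class `sar_profile` with `positions_cm`, `values`,
#'   `axis`, `z_offset_cm` and normalization metadata.
#' @export
extract_profile <- function(sar, axis = c("major_x", "minor_y"),
                            z_offset_cm = 0) {
  stopifnot(inherits(sar, "sar_grid"))
  axis <- match.arg(axis)
  g <- sar$grid
  ctr <- world_to_index(g, c(0, 0, z_offset_cm / 100)) + 1L
  co <- .axis_coords(g)
  if (axis == "major_x") {
    vals <- sar$values[, ctr[2], ctr[3]]
    labs <- sar$labels[, ctr[2], ctr[3]]
    pos <- co[[1]] * 100
  } else {
    vals <- sar$values[ctr[1], , ctr[3]]
    labs <- sar$labels[ctr[1], , ctr[3]]
    pos <- co[[2]] * 100
  }
  sel <- labs %in% sar$phantom_labels
  if (!any(sel)) stop("measurement line does not intersect the phantom")
  structure(list(axis = axis, z_offset_cm = z_offset_cm,
                 positions_cm = pos[sel], values = vals[sel],
                 media = labs[sel],
                 normalization = sar$normalization),
            class = "sar_profile")
}

#' @export
print.sar_profile <- function(x, ...) {
  cat(sprintf("<sar_profile %s @ z=%g cm: %d points, [%g, %g] cm, max %.3g>\n",
              x$axis, x$z_offset_cm, length(x$values),
              min(x$positions_cm), max(x$positions_cm), max(x$values)))
  invisible(x)
}

# linear interpolation of a profile at arbitrary positions
.profile_at <- function(profile, pos_cm) {
  stats::approx(profile$positions_cm, profile$values, xout = pos_cm,
                rule = 1)$y
}

#' Normalize a set of profiles to a common reference
#'
#' One global scalar maps the reference profile's value at the reference
#' position to 100 percent; the same scalar is applied to every profile in
#' the set, so ratios between profiles (the steering information) are
#' preserved.
#'
#' @param profiles list of `sar_profile` objects.
#' @param reference index or name of the reference profile in `profiles`
#'   (default 1).
#' @param position_cm reference position (default 0, the phantom center).
#' @return list of rescaled profiles with attribute `"scale"`.
#' @export
normalize_profiles <- function(profiles, reference = 1, position_cm = 0) {
  stopifnot(length(profiles) >= 1)
  ref_val <- .profile_at(profiles[[reference]], position_cm)
  if (is.na(ref_val) || ref_val <= 0)
    stop("reference profile value at the reference position must be > 0")
  scale <- 100 / ref_val
  out <- lapply(profiles, function(p) {
    p$values <- p$values * scale
    p$normalization <- list(kind = "percent_of_reference",
                            reference = reference,
                            position_cm = position_cm)
    p
  })
  attr(out, "scale") <- scale
  out
}

# discrete local extrema with 3-point parabolic refinement
.local_minima <- function(pos, val) {
  n <- length(val)
  if (n < 3) return(NULL)
  idx <- which(val[2:(n - 1)] <= val[1:(n - 2)] &
               val[2:(n - 1)] <= val[3:n]) + 1L
  # drop plateau duplicates (keep the first of a run)
  if (length(idx) > 1) idx <- idx[c(TRUE, diff(idx) > 1)]
  if (length(idx) == 0) return(NULL)
  t(vapply(idx, function(i) {
    y1 <- val[i - 1]; y2 <- val[i]; y3 <- val[i + 1]
    den <- y1 - 2 * y2 + y3
    off <- if (den > 0) 0.5 * (y1 - y3) / den else 0
    off <- max(min(off, 0.5), -0.5)
    h <- pos[i + 1] - pos[i]
    c(pos = pos[i] + off * h, value = y2 - 0.25 * (y1 - y3) * off)
  }, c(pos = 0, value = 0)))
}

#' Focus metrics of a SAR profile
#'
#' The focus size is the distance between the two local minima flanking the
#' central maximum. Minima are located by discrete neighbour comparison and
#' refined by 3-point parabolic interpolation; minima within
#' `border_exclusion_cm` of the profile ends (where border effects dominate)
#' do not count as flanking minima. A profile without two interior flanking
#' minima (e.g. monotone) yields `defined = FALSE`, not an error.
#'
#' @param profile a `sar_profile`.
#' @param border_exclusion_cm window at each profile end excluded from the
#'   minima search (default 2 cm).
#' @return object of class `focus_metrics`: `focus_size_cm`,
#'   `minima_positions_cm`, `center_value`, `defined`.
#' @export
focus_metrics <- function(profile, border_exclusion_cm = 2) {
  stopifnot(inherits(profile, "sar_profile"))
  pos <- profile$positions_cm; val <- profile$values
  ctr_val <- .profile_at(profile, 0)
  mins <- .local_minima(pos, val)
  und <- structure(list(focus_size_cm = NA_real_,
                        minima_positions_cm = c(NA_real_, NA_real_),
                        center_value = ctr_val, defined = FALSE),
                   class = "focus_metrics")
  if (is.null(mins)) return(und)
  lo <- min(pos) + border_exclusion_cm
  hi <- max(pos) - border_exclusion_cm
  mins <- mins[mins[, "pos"] > lo & mins[, "pos"] < hi, , drop = FALSE]
  left <- mins[mins[, "pos"] < 0, , drop = FALSE]
  right <- mins[mins[, "pos"] > 0, , drop = FALSE]
  if (nrow(left) == 0 || nrow(right) == 0) return(und)
  # flanking minima: ties broken toward the position nearer the center
  lpos <- left[which.max(left[, "pos"]), "pos"]
  rpos <- right[which.min(right[, "pos"]), "pos"]
  structure(list(focus_size_cm = unname(rpos - lpos),
                 minima_positions_cm = unname(c(lpos, rpos)),
                 center_value = ctr_val, defined = TRUE),
            class = "focus_metrics")
}

#' @export
print.focus_metrics <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("<focus: %.2f cm (minima at %.2f / %.2f cm), center %.3g>\n",
                x$focus_size_cm, x$minima_positions_cm[1],
                x$minima_positions_cm[2], x$center_value))
  } else {
    cat("<focus: undefined (no interior flanking minima)>\n")
  }
  invisible(x)
}

#' Compare a simulated profile against a measured one
#'
#' Interpolates the simulated profile onto the measured positions and
#' reports per-point deviations in percentage points of the reference (100
#' percent) level, their max and mean absolute values, and the same
#' statistics excluding `border_cm` at each end of the overlap (profile
#' borders are where measurements are least reliable).
#'
#' @param simulated,measured `sar_profile` objects on a common normalization.
#' @param border_cm interior-exclusion window (default 2 cm).
#' @return list with `positions_cm`, `deviation` (sim - meas), `max_dev`,
#'   `mean_dev`, `max_dev_interior`, `mean_dev_interior`.
#' @export
compare_profiles <- function(simulated, measured, border_cm = 2) {
  stopifnot(inherits(simulated, "sar_profile"), inherits(measured, "sar_profile"))
  lo <- max(min(simulated$positions_cm), min(measured$positions_cm))
  hi <- min(max(simulated$positions_cm), max(measured$positions_cm))
  if (lo >= hi) stop("profiles have disjoint position ranges")
  sel <- measured$positions_cm >= lo & measured$positions_cm <= hi
  pos <- measured$positions_cm[sel]
  dev <- .profile_at(simulated, pos) - measured$values[sel]
  interior <- pos >= lo + border_cm & pos <= hi - border_cm
  list(positions_cm = pos, deviation = dev,
       max_dev = max(abs(dev)), mean_dev = mean(abs(dev)),
       max_dev_interior = if (any(interior)) max(abs(dev[interior])) else NA_real_,
       mean_dev_interior = if (any(interior)) mean(abs(dev[interior])) else NA_real_)
}

#' Read / write measured profiles as CSV
#'
#' CSV dialect: header `position_cm,value`, decimal point, UTF-8. The reader
#' sorts by position and rejects duplicate positions.
#'
#' @param path CSV path.
#' @return a `sar_profile` (reader); `path` invisibly (writer).
#' @export
read_measured_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("position_cm", "value") %in% names(df)))
    stop("expected columns: position_cm,value")
  if (anyDuplicated(df$position_cm))
    stop("duplicate positions in measured profile")
  ord <- order(df$position_cm)
  structure(list(axis = "measured", z_offset_cm = NA_real_,
                 positions_cm = df$position_cm[ord], values = df$value[ord],
                 media = NULL,
                 normalization = list(kind = "as_read")),
            class = "sar_profile")
}

#' @rdname read_measured_csv
#' @param profile a `sar_profile`.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "sar_profile"))
  write.csv(data.frame(position_cm = profile$positions_cm,
                       value = profile$values),
            path, row.names = FALSE)
  invisible(path)
}

#' Convert a normalized E-field profile to a SAR profile
#'
#' Published E-field measurements convert to SAR shape by squaring
#' (`SAR ~ sigma |E|^2 / (2 rho)`: within one medium the shape is the
#' squared E-field shape).
#'
#' @param profile a `sar_profile` holding E-field values.
#' @return a `sar_profile` with squared values.
#' @export
efield_profile_to_sar <- function(profile) {
  stopifnot(inherits(profile, "sar_profile"))
  profile$values <- profile$values^2
  profile$normalization <- list(kind = "squared_efield")
  profile
}
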