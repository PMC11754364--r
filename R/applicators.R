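#' Device models: waveguide and dipole phased arrays
#'
#' A device model couples the scene (phantom + boluses + antennas rasterized
#' into the label grid) with the drive channels. Each channel owns one or
#' more feed sites (sets of z-directed edges carrying lumped resistive
#' sources); undriven channels keep their 50 Ohm termination. Device
#' geometry is laid out in voxel-index space around the grid center so that
#' opposed channels are exact mirror images.
#'
#' @name applicators
NULL

.device_model <- function(name, channels, scene, operating_band,
                          ring_radius_cm = NA_real_, mirror_map = list()) {
  structure(list(name = name, channels = channels, scene = scene,
                 operating_band = operating_band,
                 ring_radius_cm = ring_radius_cm,
                 mirror_map = mirror_map,
                 phantom_labels = attr(scene, "phantom_labels")),
            class = "device_model")
}

#' @export
print.device_model <- function(x, ...) {
  cat(sprintf("<device_model %s: channels %s, band %g-%g MHz>\n", x$name,
              paste(vapply(x$channels, `[[`, "", "id"), collapse = "/"),
              x$operating_band[1], x$operating_band[2]))
  invisible(x)
}

# 1-based index ranges clamped to the grid
.set_box <- function(lab, xr, yr, zr, val) {
  d <- dim(lab)
  xr <- xr[xr >= 1 & xr <= d[1]]; yr <- yr[yr >= 1 & yr <= d[2]]
  zr <- zr[zr >= 1 & zr <= d[3]]
  lab[xr, yr, zr] <- val
  lab
}

.channel <- function(id, sites, load_ohms = 50) {
  stopifnot(length(sites) >= 1)
  list(id = id, source_sites = sites, load_ohms = load_ohms)
}

# One water-filled PEC waveguide with its feed, facing the origin.
# dir: "+y" (top), "-y" (bottom), "+x" (right), "-x" (left).
# ap_m: transverse aperture width (m); the 34 cm dimension is always axial.
# d_ap_m: distance of the aperture plane from the origin (m).
# Feed: z-directed resistive line source on the guide's transverse center
# plane, 3 cm behind the feed-side reference (i.e. 3 cm from the back wall).
.add_waveguide <- function(scene, dir, ap_m, d_ap_m, depth_m = 0.12,
                           axial_m = 0.34, feed_back_m = 0.03) {
  h <- scene$grid$spacing
  lab <- scene$labels
  c0 <- world_to_index(scene$grid, c(0, 0, 0)) + 1L  # 1-based center voxel
  pec <- .label_of(scene, "metal"); wat <- .label_of(scene, "water")
  nw <- round(ap_m / 2 / h); nzl <- round(axial_m / 2 / h)
  nd <- round(depth_m / h); na <- round(d_ap_m / h)
  sgn <- if (substr(dir, 1, 1) == "+") 1L else -1L
  ax <- if (substr(dir, 2, 2) == "x") 1L else 2L  # depth axis
  tr <- if (ax == 1L) 2L else 1L                  # transverse (aperture) axis
  # depth-axis index ranges (from aperture toward the back wall)
  dep_all <- c0[ax] + sgn * (na:(na + nd + 1L))
  dep_int <- c0[ax] + sgn * ((na - 1L):(na + nd))
  tr_all <- (c0[tr] - nw - 1L):(c0[tr] + nw + 1L)
  tr_int <- (c0[tr] - nw):(c0[tr] + nw)
  z_all <- (c0[3] - nzl - 1L):(c0[3] + nzl + 1L)
  z_int <- (c0[3] - nzl):(c0[3] + nzl)
  if (ax == 1L) {
    lab <- .set_box(lab, dep_all, tr_all, z_all, pec)
    lab <- .set_box(lab, dep_int, tr_int, z_int, wat)
  } else {
    lab <- .set_box(lab, tr_all, dep_all, z_all, pec)
    lab <- .set_box(lab, tr_int, dep_int, z_int, wat)
  }
  scene$labels <- lab
  # feed line: z-directed edges at the transverse center, 3 cm from the back
  # wall, spanning the central part of the axial extent
  j_feed <- c0[ax] + sgn * (na + nd + 1L - round(feed_back_m / h))
  nk <- max(nzl - 2L, 1L)
  ks <- (c0[3] - nk):(c0[3] + nk - 1L)      # Ez[k] spans z in [k, k+1]
  edges <- data.frame(
    i = if (ax == 1L) j_feed - 1L else c0[1] - 1L,
    j = if (ax == 2L) j_feed - 1L else c0[2] - 1L,
    k = ks - 1L, comp = 2L)
  edges$resistance <- 50 * nrow(edges)
  list(scene = scene, site = edges)
}

# water bolus slab between an aperture plane and the phantom
.add_bolus <- function(scene, dir, half_tr_m, d_out_m, thick_m, axial_m = 0.40) {
  h <- scene$grid$spacing
  c0 <- world_to_index(scene$grid, c(0, 0, 0)) + 1L
  wat <- .label_of(scene, "water")
  sgn <- if (substr(dir, 1, 1) == "+") 1L else -1L
  ax <- if (substr(dir, 2, 2) == "x") 1L else 2L
  tr <- if (ax == 1L) 2L else 1L
  n_out <- round(d_out_m / h)
  # slab extends from the aperture plane inwards past the phantom surface;
  # the phantom is painted afterwards and reclaims its own voxels
  n_in <- round((d_out_m - thick_m - 0.02) / h)
  dep <- c0[ax] + sgn * (n_in:n_out)
  trr <- (c0[tr] - round(half_tr_m / h)):(c0[tr] + round(half_tr_m / h))
  zr <- (c0[3] - round(axial_m / 2 / h)):(c0[3] + round(axial_m / 2 / h))
  scene$labels <- if (ax == 1L) .set_box(scene$labels, dep, trr, zr, wat)
                  else .set_box(scene$labels, trr, dep, zr, wat)
  scene
}

#' Build the AMC-2 double-waveguide system around a phantom scene
#'
#' Two opposed water-filled waveguides (aperture `top_aperture_cm` x 34 cm on
#' top, 20 x 34 cm on the bottom, depth 12 cm) above and below the elliptical
#' phantom, with 6 cm water boluses (32 x 40 cm top, 36 x 40 cm bottom)
#' between aperture and phantom. Channels: `top`, `bottom`.
#'
#' @param scene a [phantom_scene()] for the elliptical saline phantom.
#' @param top_aperture_cm top aperture width: 20, 15 or 8.5 (validation uses 20).
#' @param phantom a `phantom_spec` (for re-painting over the boluses).
#' @return a `device_model`.
#' @export
build_amc2 <- function(scene, top_aperture_cm = 20, phantom = NULL) {
  stopifnot(top_aperture_cm %in% c(20, 15, 8.5))
  b <- 0.12                       # phantom semi-minor axis
  bolus_t <- 0.06
  d_ap <- b + bolus_t
  scene <- .add_bolus(scene, "+y", 0.16, d_ap, bolus_t)
  scene <- .add_bolus(scene, "-y", 0.18, d_ap, bolus_t)
  if (!is.null(phantom)) scene <- .paint_primitives(scene, phantom$primitives)
  top <- .add_waveguide(scene, "+y", top_aperture_cm / 100, d_ap)
  scene <- top$scene
  bot <- .add_waveguide(scene, "-y", 0.20, d_ap)
  scene <- bot$scene
  .device_model("amc2",
                list(.channel("top", list(list(edges = top$site))),
                     .channel("bottom", list(list(edges = bot$site)))),
                scene, operating_band = c(70, 70))
}

#' Build the AMC-4 / ALBA-4D four-waveguide ring around a phantom scene
#'
#' Four 20 x 34 cm waveguides (depth 12 cm) at 90 degree spacing (top,
#' bottom, left, right), each with a water bolus of `bolus_cm` between
#' aperture and phantom. The 34 cm aperture dimension is axial for all four.
#'
#' @param scene a [phantom_scene()] for an elliptical AMC phantom.
#' @param bolus_cm bolus thickness in cm (4 for the homogeneous set-up).
#' @param phantom a `phantom_spec` (re-painted over the boluses).
#' @return a `device_model` with mirror metadata (bottom/left are exact
#'   mirrors of top/right).
#' @export
build_amc4 <- function(scene, bolus_cm = 4, phantom = NULL) {
  a <- 0.18; b <- 0.12
  bolus_t <- bolus_cm / 100
  scene <- .add_bolus(scene, "+y", 0.12, b + bolus_t, bolus_t)
  scene <- .add_bolus(scene, "-y", 0.12, b + bolus_t, bolus_t)
  scene <- .add_bolus(scene, "+x", 0.10, a + bolus_t, bolus_t)
  scene <- .add_bolus(scene, "-x", 0.10, a + bolus_t, bolus_t)
  if (!is.null(phantom)) scene <- .paint_primitives(scene, phantom$primitives)
  chans <- list()
  for (d in list(c("top", "+y"), c("bottom", "-y"),
                 c("left", "-x"), c("right", "+x"))) {
    d_ap <- if (substr(d[2], 2, 2) == "y") b + bolus_t else a + bolus_t
    wg <- .add_waveguide(scene, d[2], 0.20, d_ap)
    scene <- wg$scene
    chans[[d[1]]] <- .channel(d[1], list(list(edges = wg$site)))
  }
  .device_model("amc4", unname(chans), scene, operating_band = c(70, 70),
                mirror_map = list(bottom = list(src = "top", axis = 2L),
                                  left = list(src = "right", axis = 1L)))
}

#' Build a BSD Sigma dipole ring around a phantom scene
#'
#' Eight z-oriented cylindrical dipoles (one-voxel cross section) equally
#' spaced on the stated ring, grouped into four quadrant channels (top,
#' bottom, left, right) of two dipoles each at +-22.5 degrees from the
#' quadrant center. Each dipole has a central feed gap with a single driven
#' z-edge (the minimal drivable gap on the staggered grid); a water bolus
#' cylinder fills the space between phantom and ring. Undriven channels
#' terminate their gaps with 50 Ohm.
#'
#' @param scene a [phantom_scene()].
#' @param variant "sigma30" (ring radius 15 cm, dipoles 23 cm, bolus 25 cm)
#'   or "sigma60" (ring radius 29 cm, dipoles 45 cm, bolus 36 cm for the
#'   benchmark set-up).
#' @param bolus_length_m override of the bolus axial length (m).
#' @return a `device_model` with mirror metadata.
#' @export
build_sigma_ring <- function(scene, variant = c("sigma30", "sigma60"),
                             bolus_length_m = NULL) {
  variant <- match.arg(variant)
  p <- switch(variant,
    sigma30 = list(r = 0.15, dip_len = 0.23, bolus_len = 0.25, band = c(115, 135)),
    sigma60 = list(r = 0.29, dip_len = 0.45, bolus_len = 0.36, band = c(60, 120)))
  if (!is.null(bolus_length_m)) p$bolus_len <- bolus_length_m
  h <- scene$grid$spacing
  c0 <- world_to_index(scene$grid, c(0, 0, 0)) + 1L
  pec <- .label_of(scene, "metal")
  # bolus cylinder painted first, phantom re-painted, rods last
  spec_name <- attr(scene, "phantom_spec")
  scene$labels <- {
    lab <- scene$labels
    # bolus fills the annulus up to the dipole ring: the antennas sit at the
    # bolus surface, as in the physical applicator
    bol <- prim_cylinder_z(c(0, 0, 0), p$r, p$bolus_len)
    m <- .primitive_mask(scene$grid, bol)
    lab[m] <- .label_of(scene, "water")
    lab
  }
  ph_labels <- attr(scene, "phantom_labels")
  # re-rasterize the phantom over the bolus
  scene <- switch(spec_name,
    sigma30_cyl = .paint_primitives(scene, build_sigma30_cylinder()$primitives),
    cdrh = .paint_primitives(scene, build_cdrh_phantom()$primitives),
    stop("unsupported phantom for a Sigma ring"))
  # eight dipole rods; arm length in voxels on each side of the 2-voxel gap
  nlen <- max(round((p$dip_len / h - 2) / 2), 1L)
  kc <- c0[3]
  quads <- list(right = 0, top = 90, left = 180, bottom = 270)
  chans <- list()
  for (qn in names(quads)) {
    sites <- list()
    for (dth in c(-22.5, 22.5)) {
      th <- (quads[[qn]] + dth) * pi / 180
      xi <- c0[1] + round(p$r * cos(th) / h)
      yi <- c0[2] + round(p$r * sin(th) / h)
      lower <- (kc - nlen):(kc - 1L)
      upper <- (kc + 2L):(kc + nlen + 1L)
      scene$labels <- .set_box(scene$labels, xi, yi, c(lower, upper), pec)
      sites[[length(sites) + 1L]] <-
        list(edges = data.frame(i = xi - 1L, j = yi - 1L, k = kc - 1L,
                                comp = 2L, resistance = 50))
    }
    chans[[qn]] <- .channel(qn, sites)
  }
  attr(scene, "phantom_labels") <- ph_labels
  .device_model(variant, unname(chans), scene, operating_band = p$band,
                ring_radius_cm = p$r * 100,
                mirror_map = list(bottom = list(src = "top", axis = 2L),
                                  left = list(src = "right", axis = 1L)))
}

#' List device channel ids
#' @param device a `device_model`.
#' @return character vector of channel ids.
#' @export
device_channels <- function(device) {
  vapply(device$channels, `[[`, "", "id")
}
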