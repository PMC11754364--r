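#' Published QA phantom geometries
#'
#' A phantom spec is a device-independent recipe: an ordered list of
#' primitives with material names (painter's order), the media that count as
#' "phantom" for profile extraction and normalization, and the measurement
#' axes. Realize it on a grid with [phantom_scene()].
#'
#' @name phantoms
NULL

.phantom_spec <- function(name, primitives, phantom_media, muscle, fat = NULL,
                          axes, half_extent) {
  structure(list(name = name, primitives = primitives,
                 phantom_media = phantom_media, muscle = muscle, fat = fat,
                 measurement_axes = axes, half_extent = half_extent),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec %s: %d primitives, media %s>\n", x$name,
              length(x$primitives), paste(x$phantom_media, collapse = ", ")))
  invisible(x)
}

#' Elliptical saline / wallpaper-paste phantom of the AMC waveguide systems
#'
#' Elliptic cylinder with a 24 x 36 cm cross section (semi-axes 18 x 12 cm).
#' The homogeneous variant carries a thin PVC shell (one voxel on the grid)
#' and is filled with muscle-equivalent saline; the inhomogeneous variant is
#' the solid 50 cm wallpaper-paste phantom without shell, with a centered
#' 8 x 8 cm fat-equivalent rectangular tube running its full length.
#'
#' @param homogeneous logical; FALSE adds the fat core and drops the shell.
#' @param length_m phantom length (m): 1.15 for the saline phantoms, 0.50 for
#'   the inhomogeneous phantom. A shorter `model_length_m` may be given to
#'   truncate the geometry to the simulated domain.
#' @param muscle muscle-equivalent material name ("muscle_amc2" for the AMC-2
#'   set-up, "muscle_amc4" otherwise).
#' @param model_length_m optional modeled length (m), `<= length_m`.
#' @return a `phantom_spec`.
#' @export
build_amc_elliptical <- function(homogeneous = TRUE, length_m = 1.15,
                                 muscle = if (homogeneous) "muscle_amc4" else "muscle_amc4",
                                 model_length_m = NULL) {
  stopifnot(length_m %in% c(1.15, 0.50))
  L <- if (is.null(model_length_m)) length_m else min(model_length_m, length_m)
  a <- 0.18; b <- 0.12
  prims <- list()
  if (homogeneous) {
    # shell realized as a one-voxel PVC rind: the inner ellipse is shrunk by
    # one voxel at scene-build time (shell_voxels marker)
    prims <- c(prims, list(
      list(prim = prim_elliptic_cylinder_z(c(0, 0, 0), c(a, b), L),
           material = "pvc"),
      list(prim = prim_elliptic_cylinder_z(c(0, 0, 0), c(a, b), L),
           material = muscle, shrink_voxels = 1)))
    media <- c(muscle)
  } else {
    prims <- c(prims, list(
      list(prim = prim_elliptic_cylinder_z(c(0, 0, 0), c(a, b), L),
           material = muscle),
      list(prim = prim_box(c(0, 0, 0), c(0.08, 0.08, L)),
           material = "fat_core")))
    media <- c(muscle, "fat_core")
  }
  axes <- list(major = list(axis = "major_x", z_offset_cm = 0),
               minor = list(axis = "minor_y", z_offset_cm = 0),
               major_z10 = list(axis = "major_x", z_offset_cm = 10),
               minor_z10 = list(axis = "minor_y", z_offset_cm = 10))
  .phantom_spec(if (homogeneous) "amc_homog" else "amc_fatcore",
                prims, media, muscle,
                fat = if (homogeneous) NULL else "fat_core",
                axes, half_extent = c(a, b, L / 2))
}

#' Cylindrical agarose phantom of the Sigma-30 set-up
#'
#' 20 cm diameter, 30 cm long muscle-equivalent agarose cylinder.
#' @return a `phantom_spec`.
#' @export
build_sigma30_cylinder <- function() {
  prims <- list(list(prim = prim_cylinder_z(c(0, 0, 0), 0.10, 0.30),
                     material = "muscle_sigma30"))
  axes <- list(major = list(axis = "major_x", z_offset_cm = 0),
               minor = list(axis = "minor_y", z_offset_cm = 0))
  .phantom_spec("sigma30_cyl", prims, "muscle_sigma30", "muscle_sigma30",
                fat = NULL, axes, half_extent = c(0.10, 0.10, 0.15))
}

#' Elliptical CDRH phantom of the Sigma-60 set-up
#'
#' Muscle-equivalent elliptic cylinder (major/minor axes 35 / 25 cm) with a
#' 2 cm fat-equivalent outer layer. The length is not part of the published
#' record; 60 cm is used so the z = 10 cm measurement plane stays well
#' interior to the phantom.
#'
#' @param length_m phantom length (m), default 0.60.
#' @return a `phantom_spec`.
#' @export
build_cdrh_phantom <- function(length_m = 0.60) {
  stopifnot(length_m > 0.3)
  prims <- list(
    list(prim = prim_elliptic_cylinder_z(c(0, 0, 0), c(0.175, 0.125), length_m),
         material = "fat_cdrh"),
    list(prim = prim_elliptic_cylinder_z(c(0, 0, 0), c(0.155, 0.105), length_m),
         material = "muscle_cdrh"))
  axes <- list(major = list(axis = "major_x", z_offset_cm = 0),
               minor = list(axis = "minor_y", z_offset_cm = 0),
               major_z10 = list(axis = "major_x", z_offset_cm = 10))
  .phantom_spec("cdrh", prims, c("muscle_cdrh", "fat_cdrh"), "muscle_cdrh",
                fat = "fat_cdrh", axes, half_extent = c(0.175, 0.125, length_m / 2))
}

#' Build a centered voxel grid for a scene
#'
#' Symmetric cell-centered grid with odd voxel counts (so the world origin is
#' a voxel center and mirror reuse maps centers to centers), sized to the
#' content half-extent plus an air margin plus the PML and the outer PEC
#' shell.
#'
#' @param spacing voxel size (m).
#' @param half_extent content half-extent (m) along x, y, z.
#' @param n_pml PML layers (default 16).
#' @param margin_air air voxels between content and PML (default 3).
#' @return a [voxel_grid()].
#' @export
scene_grid <- function(spacing, half_extent, n_pml = 16L, margin_air = 3L) {
  half_n <- ceiling(round(half_extent / spacing, 6)) + margin_air + n_pml + 1L
  dims <- 2L * as.integer(half_n) + 1L
  voxel_grid(spacing, dims, origin = -half_n * spacing)
}

#' Rasterize a phantom spec into a labeled scene
#'
#' @param spec a `phantom_spec`.
#' @param grid a [voxel_grid()] (e.g. from [scene_grid()]); must enclose the
#'   phantom.
#' @param frequency_MHz operating frequency, selects the material table.
#' @return a [material_grid()] whose palette is the full [material_table()]
#'   at this frequency, with attribute `"phantom_labels"`.
#' @export
phantom_scene <- function(spec, grid, frequency_MHz) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(grid, "voxel_grid"))
  tab <- material_table(frequency_MHz)
  need <- unique(vapply(spec$primitives, `[[`, "", "material"))
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop(sprintf("materials not defined at %g MHz: %s", frequency_MHz,
                 paste(missing, collapse = ", ")))
  scene <- material_grid(grid, unname(tab))
  scene <- .paint_primitives(scene, spec$primitives)
  attr(scene, "phantom_labels") <-
    vapply(spec$phantom_media, function(nm) .label_of(scene, nm), 0L)
  attr(scene, "phantom_spec") <- spec$name
  scene
}

# painter's-order rasterization with optional one-voxel shrink (shell rind)
.paint_primitives <- function(scene, primitives) {
  h <- scene$grid$spacing
  for (p in primitives) {
    prim <- p$prim
    if (!is.null(p$shrink_voxels) && p$shrink_voxels > 0) {
      d <- p$shrink_voxels * h
      prim <- switch(prim$kind,
        elliptic_cylinder_z = prim_elliptic_cylinder_z(
          prim$center, pmax(prim$semi_axes - d, h), prim$length),
        cylinder_z = prim_cylinder_z(prim$center, max(prim$radius - d, h),
                                     prim$length),
        box = prim_box(prim$center, pmax(prim$extents - 2 * d, h)),
        stop("shrink not supported for this primitive"))
    }
    scene <- rasterize(scene, prim, p$material)
  }
  scene
}
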