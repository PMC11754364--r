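#' Uniform voxel grid
#'
#' Cell-centered uniform grid. The world coordinate of the center of voxel
#' `(i,j,k)` (0-based) is `origin + spacing * (i,j,k)`. Coordinate convention
#' throughout the package: x = left-right (major phantom axis), y = bottom-top
#' (minor axis), z = bore/longitudinal axis; the world origin sits at the
#' phantom center.
#'
#' @param spacing isotropic voxel edge length (m), `> 0`.
#' @param dims integer voxel counts along x, y, z (all `>= 1`).
#' @param origin world coordinate (m) of the center of voxel (0,0,0).
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(spacing, dims, origin = c(0, 0, 0)) {
  stopifnot(length(spacing) == 1L, spacing > 0,
            length(dims) == 3L, all(dims >= 1),
            length(origin) == 3L)
  structure(list(spacing = spacing, dims = as.integer(dims),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid %d x %d x %d @ %g mm, origin (%g, %g, %g) m>\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing * 1000,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel index from a world coordinate
#'
#' Nearest voxel-center index (0-based), the inverse of the center-coordinate
#' map. A point exactly between two centers resolves to the lower index.
#'
#' @param grid a [voxel_grid()].
#' @param point world coordinate (m), length 3.
#' @return integer index triple (0-based).
#' @export
world_to_index <- function(grid, point) {
  stopifnot(inherits(grid, "voxel_grid"), length(point) == 3L)
  u <- (as.numeric(point) - grid$origin) / grid$spacing
  # ceiling(u - 0.5): midpoints u = i + 0.5 resolve to the lower index i
  idx <- as.integer(ceiling(u - 0.5))
  if (any(idx < 0L) || any(idx > grid$dims - 1L)) {
    stop(sprintf("point (%g, %g, %g) outside grid bounds",
                 point[1], point[2], point[3]))
  }
  idx
}

#' World coordinate of a voxel center
#' @param grid a [voxel_grid()].
#' @param idx 0-based index triple.
#' @return world coordinate (m).
#' @export
index_to_world <- function(grid, idx) {
  stopifnot(inherits(grid, "voxel_grid"), length(idx) == 3L)
  grid$origin + grid$spacing * as.numeric(idx)
}

# voxel-center coordinate vectors per axis.  When the origin is an integer
# multiple of the spacing (centered grids), coordinates are computed as a
# single product so that mirrored positions are bitwise symmetric and
# boundary-tie voxels rasterize identically on both sides.
.axis_coords <- function(grid) {
  lapply(1:3, function(a) {
    n0 <- grid$origin[a] / grid$spacing
    if (abs(n0 - round(n0)) < 1e-6) {
      grid$spacing * (seq_len(grid$dims[a]) - 1 + round(n0))
    } else {
      grid$origin[a] + grid$spacing * (seq_len(grid$dims[a]) - 1)
    }
  })
}

#' Labeled voxel scene
#'
#' A [voxel_grid()] plus a per-voxel integer medium label and an ordered
#' material palette. Label 0 is always `air`; label L indexes `palette[[L+1]]`.
#'
#' @param grid a [voxel_grid()].
#' @param palette ordered list of [material()] records; first entry must be air.
#' @param labels optional integer array `dim = grid$dims`; default all 0 (air).
#' @return object of class `material_grid`.
#' @export
material_grid <- function(grid, palette, labels = NULL) {
  stopifnot(inherits(grid, "voxel_grid"), length(palette) >= 1)
  if (!identical(palette[[1]]$name, "air"))
    stop("palette entry 1 must be 'air' (label 0)")
  if (is.null(labels)) {
    labels <- array(0L, dim = grid$dims)
  } else {
    stopifnot(identical(dim(labels), grid$dims))
    labels <- array(as.integer(labels), dim = grid$dims)
    if (any(labels < 0L) || any(labels >= length(palette)))
      stop("labels must index into palette")
  }
  structure(list(grid = grid, labels = labels, palette = palette),
            class = "material_grid")
}

#' @export
print.material_grid <- function(x, ...) {
  print(x$grid)
  counts <- tabulate(x$labels + 1L, nbins = length(x$palette))
  for (i in seq_along(x$palette)) {
    if (counts[i] > 0)
      cat(sprintf("  [%d] %-16s %d voxels\n", i - 1L, x$palette[[i]]$name, counts[i]))
  }
  invisible(x)
}

# label value for a palette material name
.label_of <- function(scene, name) {
  i <- match(name, vapply(scene$palette, `[[`, "", "name"))
  if (is.na(i)) stop(sprintf("material '%s' not in palette", name))
  i - 1L
}

#' Geometric primitives for scene rasterization
#'
#' Primitives are rasterized by the voxel-center inclusion test: a voxel takes
#' the primitive's label iff its center lies inside the shape (boundary
#' inclusive).
#'
#' @param center world coordinate of the shape center (m).
#' @param extents full edge lengths (m) of the box along x, y, z.
#' @return object of class `hyp_primitive`.
#' @export
prim_box <- function(center, extents) {
  stopifnot(length(center) == 3L, length(extents) == 3L, all(extents > 0))
  structure(list(kind = "box", center = as.numeric(center),
                 extents = as.numeric(extents)), class = "hyp_primitive")
}

#' @rdname prim_box
#' @param radius cylinder radius (m).
#' @param length cylinder length (m) along its axis.
#' @export
prim_cylinder_z <- function(center, radius, length) {
  stopifnot(length(center) == 3L, radius > 0, length > 0)
  structure(list(kind = "cylinder_z", center = as.numeric(center),
                 radius = radius, length = length), class = "hyp_primitive")
}

#' @rdname prim_box
#' @param semi_axes semi-axes (m) of the elliptic cross section along x and y.
#' @export
prim_elliptic_cylinder_z <- function(center, semi_axes, length) {
  stopifnot(length(center) == 3L, length(semi_axes) == 2L,
            all(semi_axes > 0), length > 0)
  structure(list(kind = "elliptic_cylinder_z", center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), length = length),
            class = "hyp_primitive")
}

#' @rdname prim_box
#' @param axis unit direction of the cylinder axis (any length-3 vector,
#'   normalized internally).
#' @export
prim_cylinder_axis <- function(center, radius, length, axis) {
  stopifnot(length(center) == 3L, radius > 0, length > 0, length(axis) == 3L)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  structure(list(kind = "cylinder_axis", center = as.numeric(center),
                 radius = radius, length = length, axis = as.numeric(axis) / n),
            class = "hyp_primitive")
}

# logical mask of voxel centers inside a primitive (vectorized per axis).
# Inclusion is boundary-inclusive with a sub-nanometer tolerance so that
# dimensions that are exact voxel multiples rasterize identically on both
# sides of the center despite float rounding.
.primitive_mask <- function(grid, prim) {
  co <- .axis_coords(grid)
  x <- co[[1]] - prim$center[1]
  y <- co[[2]] - prim$center[2]
  z <- co[[3]] - prim$center[3]
  d <- grid$dims
  eps <- 1e-6 * grid$spacing
  switch(prim$kind,
    box = {
      mx <- abs(x) <= prim$extents[1] / 2 + eps
      my <- abs(y) <= prim$extents[2] / 2 + eps
      mz <- abs(z) <= prim$extents[3] / 2 + eps
      outer(outer(mx, my, `&`), mz, `&`)
    },
    cylinder_z = {
      r2 <- outer(x^2, y^2, `+`)
      mxy <- r2 <= (prim$radius + eps)^2
      mz <- abs(z) <= prim$length / 2 + eps
      outer(mxy, mz, `&`)
    },
    elliptic_cylinder_z = {
      qe <- 1 + eps / min(prim$semi_axes)
      q <- outer((x / prim$semi_axes[1])^2, (y / prim$semi_axes[2])^2, `+`)
      mxy <- q <= qe^2
      mz <- abs(z) <= prim$length / 2 + eps
      outer(mxy, mz, `&`)
    },
    cylinder_axis = {
      # general orientation: full 3-D point test
      pts <- cbind(rep(x, times = d[2] * d[3]),
                   rep(rep(y, each = d[1]), times = d[3]),
                   rep(z, each = d[1] * d[2]))
      t_ax <- pts %*% prim$axis
      perp2 <- rowSums(pts^2) - t_ax^2
      m <- (abs(t_ax) <= prim$length / 2 + eps) & (perp2 <= (prim$radius + eps)^2)
      array(m, dim = d)
    },
    stop(sprintf("unknown primitive kind '%s'", prim$kind)))
}

#' Rasterize a primitive into a scene
#'
#' Every voxel whose center lies inside the primitive gets `label`,
#' overwriting earlier labels (painter's order); all other voxels are
#' unchanged. A primitive with no overlap is a no-op with a warning.
#'
#' @param scene a [material_grid()].
#' @param prim a primitive (see [prim_box()]).
#' @param label integer medium label (must index into the palette) or a
#'   palette material name.
#' @return the updated `material_grid`.
#' @export
rasterize <- function(scene, prim, label) {
  stopifnot(inherits(scene, "material_grid"), inherits(prim, "hyp_primitive"))
  if (is.character(label)) label <- .label_of(scene, label)
  label <- as.integer(label)
  if (label < 0L || label >= length(scene$palette))
    stop("label must index into palette")
  m <- .primitive_mask(scene$grid, prim)
  if (!any(m)) {
    warning(sprintf("primitive '%s' lies entirely outside the grid; no-op",
                    prim$kind))
    return(scene)
  }
  scene$labels[m] <- label
  scene
}

#' Write / read a labeled scene (raw binary + JSON sidecar)
#'
#' Portable on-disk form: little-endian int32 voxel labels in column-major
#' (x fastest) order plus a JSON sidecar holding grid geometry and the
#' material palette. The round trip is bit-exact.
#'
#' @param scene a [material_grid()].
#' @param path output path for the label volume (`.bin`); the sidecar is
#'   written next to it as `<path>.json`.
#' @return `path`, invisibly (writer); a `material_grid` (reader).
#' @export
write_scene_raw <- function(scene, path) {
  stopifnot(inherits(scene, "material_grid"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(scene$labels), con, size = 4L, endian = "little")
  meta <- list(
    format = "phasedheat-scene-v1",
    spacing = scene$grid$spacing,
    dims = scene$grid$dims,
    origin = scene$grid$origin,
    palette = lapply(scene$palette, function(m)
      list(name = m$name, sigma = m$sigma, eps_r = m$eps_r,
           rho = m$rho, c = m$c, pec = isTRUE(m$pec)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scene_raw
#' @export
read_scene_raw <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "phasedheat-scene-v1"))
    stop("not a phasedheat scene file")
  dims <- as.integer(meta$dims)
  grid <- voxel_grid(meta$spacing, dims, as.numeric(meta$origin))
  palette <- lapply(seq_len(nrow(meta$palette)), function(i) {
    r <- meta$palette[i, ]
    m <- material(r$name, r$sigma, r$eps_r, r$rho, r$c)
    if (isTRUE(r$pec)) m$pec <- TRUE
    m
  })
  con <- file(path, "rb")
  on.exit(close(con))
  lab <- readBin(con, "integer", n = prod(dims), size = 4L, endian = "little")
  material_grid(grid, palette, array(lab, dim = dims))
}

#' Write a labeled scene as a NIfTI-1 volume + JSON palette sidecar
#'
#' Requires the `RNifti` package. The affine encodes the isotropic spacing and
#' the origin of voxel (0,0,0); the palette goes to `<path>.json` in the same
#' layout as [write_scene_raw()].
#'
#' @inheritParams write_scene_raw
#' @param path output `.nii` or `.nii.gz` path.
#' @export
write_scene_nifti <- function(scene, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI output; use write_scene_raw() instead")
  sp_mm <- scene$grid$spacing * 1000
  img <- RNifti::asNifti(scene$labels)
  aff <- diag(c(sp_mm, sp_mm, sp_mm, 1))
  aff[1:3, 4] <- scene$grid$origin * 1000
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  meta <- list(
    format = "phasedheat-scene-v1",
    spacing = scene$grid$spacing,
    dims = scene$grid$dims,
    origin = scene$grid$origin,
    palette = lapply(scene$palette, function(m)
      list(name = m$name, sigma = m$sigma, eps_r = m$eps_r,
           rho = m$rho, c = m$c, pec = isTRUE(m$pec)))
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
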