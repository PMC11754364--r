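ph_palette <- function() {
  list(material("air", 0, 1, rho = 1.2, c = 1005),
       material("muscle", 0.5, 75),
       material("fat", 0.05, 11, rho = 900, c = 2430))
}

test_that("world/index maps invert each other with the stated tie-break", {
  g <- voxel_grid(0.01, c(10, 12, 14), origin = c(-0.05, -0.05, -0.05))
  expect_equal(world_to_index(g, g$origin), c(0L, 0L, 0L))
  for (idx in list(c(0, 0, 0), c(3, 5, 7), c(9, 11, 13))) {
    expect_equal(world_to_index(g, index_to_world(g, idx)), as.integer(idx))
  }
  # point exactly between two centers resolves to the lower index
  expect_equal(world_to_index(g, g$origin + c(0.005, 0, 0))[1], 0L)
  expect_error(world_to_index(g, g$origin - 0.01), "outside")
})

test_that("box rasterization labels exactly the voxels whose centers lie inside", {
  g <- voxel_grid(0.01, c(10, 10, 10), origin = c(0, 0, 0))
  scene <- material_grid(g, ph_palette())
  ctr <- c(0.045, 0.045, 0.045)
  scene <- rasterize(scene, prim_box(ctr, c(0.04, 0.04, 0.04)), 1L)
  expect_equal(sum(scene$labels == 1L), 64L)
  # brute-force center-inclusion oracle
  co <- expand.grid(x = 0.01 * (0:9), y = 0.01 * (0:9), z = 0.01 * (0:9))
  inside <- abs(co$x - ctr[1]) <= 0.02 & abs(co$y - ctr[2]) <= 0.02 &
    abs(co$z - ctr[3]) <= 0.02
  expect_equal(sum(scene$labels == 1L), sum(inside))
})

test_that("elliptic cylinder voxel count matches the analytic volume within 1%", {
  h <- 0.0025
  g <- voxel_grid(h, c(150, 102, 468),
                  origin = -h * c(75, 51, 234))
  scene <- material_grid(g, ph_palette())
  scene <- rasterize(scene,
                     prim_elliptic_cylinder_z(c(0, 0, 0), c(0.18, 0.12), 1.15),
                     1L)
  v_analytic <- pi * 0.18 * 0.12 * 1.15
  v_raster <- sum(scene$labels == 1L) * h^3
  expect_lt(abs(v_raster - v_analytic) / v_analytic, 0.01)
})

test_that("rasterized volume error shrinks at least linearly with resolution", {
  vol_err <- function(h) {
    n <- ceiling(c(0.08, 0.06, 0.09) / h) + 2
    g <- voxel_grid(h, 2 * n + 1, origin = -h * n)
    scene <- material_grid(g, ph_palette())
    scene <- rasterize(scene,
                       prim_elliptic_cylinder_z(c(0, 0, 0), c(0.0713, 0.0409), 0.111),
                       1L)
    abs(sum(scene$labels == 1L) * h^3 - pi * 0.0713 * 0.0409 * 0.111)
  }
  e1 <- vol_err(0.005)
  e2 <- vol_err(0.0025)
  expect_lt(e2, e1 / 2 * 1.05)  # halves or better (5% slack on the ratio)
})

test_that("painter's order overwrites and repeated rasterization is idempotent", {
  g <- voxel_grid(0.01, c(21, 21, 21), origin = -0.01 * c(10, 10, 10))
  scene <- material_grid(g, ph_palette())
  scene <- rasterize(scene, prim_cylinder_z(c(0, 0, 0), 0.08, 0.15), 1L)
  once <- rasterize(scene, prim_box(c(0, 0, 0), c(0.05, 0.05, 0.05)), 2L)
  twice <- rasterize(once, prim_box(c(0, 0, 0), c(0.05, 0.05, 0.05)), 2L)
  expect_identical(once$labels, twice$labels)
  expect_true(all(once$labels[once$labels == 2L] == 2L))
  # inner box carved out of the cylinder
  ctr <- world_to_index(g, c(0, 0, 0)) + 1
  expect_equal(once$labels[ctr[1], ctr[2], ctr[3]], 2L)
})

test_that("a primitive with no overlap is a warning no-op", {
  g <- voxel_grid(0.01, c(10, 10, 10), origin = c(0, 0, 0))
  scene <- material_grid(g, ph_palette())
  before <- scene$labels
  expect_warning(scene <- rasterize(scene, prim_box(c(1, 1, 1), c(0.01, 0.01, 0.01)), 1L),
                 "outside")
  expect_identical(scene$labels, before)
})

test_that("oblique cylinder_axis agrees with cylinder_z when axis is +z", {
  g <- voxel_grid(0.01, c(25, 25, 25), origin = -0.01 * c(12, 12, 12))
  s1 <- rasterize(material_grid(g, ph_palette()),
                  prim_cylinder_z(c(0, 0, 0), 0.06, 0.14), 1L)
  s2 <- rasterize(material_grid(g, ph_palette()),
                  prim_cylinder_axis(c(0, 0, 0), 0.06, 0.14, c(0, 0, 2)), 1L)
  expect_identical(s1$labels, s2$labels)
})

test_that("scene serialization round-trips bit-exactly (labels and palette)", {
  g <- voxel_grid(0.0025, c(12, 14, 16), origin = c(-0.01, -0.02, -0.03))
  scene <- material_grid(g, ph_palette())
  scene <- rasterize(scene, prim_cylinder_z(c(0, 0, 0), 0.012, 0.03), 2L)
  path <- tempfile(fileext = ".bin")
  write_scene_raw(scene, path)
  back <- read_scene_raw(path)
  expect_identical(back$labels, scene$labels)
  expect_equal(back$grid$spacing, scene$grid$spacing)
  expect_equal(back$grid$origin, scene$grid$origin)
  for (i in seq_along(scene$palette)) {
    expect_equal(back$palette[[i]]$name, scene$palette[[i]]$name)
    expect_equal(back$palette[[i]]$sigma, scene$palette[[i]]$sigma)
    expect_equal(back$palette[[i]]$eps_r, scene$palette[[i]]$eps_r)
    expect_equal(back$palette[[i]]$rho, scene$palette[[i]]$rho)
  }
})

test_that("label 0 is reserved for air and labels must index the palette", {
  g <- voxel_grid(0.01, c(5, 5, 5), origin = c(0, 0, 0))
  pal_no_air <- list(material("muscle", 0.5, 75))
  expect_error(material_grid(g, pal_no_air), "air")
  scene <- material_grid(g, ph_palette())
  expect_error(rasterize(scene, prim_box(c(0.02, 0.02, 0.02), c(0.02, 0.02, 0.02)), 7L),
               "palette")
})
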