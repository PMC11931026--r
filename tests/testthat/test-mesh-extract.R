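sphere_density <- function(r0 = 0.3, sigma = 100) {
  function(pts) ifelse(rowSums(pts^2) <= r0^2, sigma, 0)
}

test_that("density grids span the box corners and honour the cylinder mask", {
  box <- aabb(c(-0.75, -0.75, -0.55), c(0.75, 0.75, 0.65))
  g <- sample_density_grid(function(p) rep(7, nrow(p)), box, res = 16)
  expect_equal(range(g$xs), c(-0.75, 0.75))
  expect_equal(range(g$zs), c(-0.55, 0.65))
  # constant field: constant inside the cylinder, zero outside
  expect_true(all(g$density[g$mask] == 7))
  expect_true(all(g$density[!g$mask] == 0))
  # every unmasked point satisfies x^2 + y^2 <= r^2
  idx <- which(g$mask, arr.ind = TRUE)
  rr <- g$xs[idx[, 1]]^2 + g$ys[idx[, 2]]^2
  expect_true(all(rr <= 0.75^2 + 1e-12))
})

test_that("the analytic sphere meshes at its true radius", {
  box <- aabb(rep(-0.75, 3), rep(0.75, 3))
  mesh <- extract_mesh(sphere_density(), box, mesh_config(128, 25))
  expect_s3_class(mesh, "triangle_mesh")
  expect_gt(nrow(mesh$vertices), 1000)
  r <- sqrt(rowSums(mesh$vertices^2))
  voxel <- 1.5 / 127
  expect_lt(abs(mean(r) - 0.3), voxel)
  # faces reference valid vertices, no NaN
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))
  expect_false(anyNA(mesh$vertices))
  # all vertices within the box expanded by one voxel
  expect_true(all(abs(mesh$vertices) <= 0.75 + voxel))
})

test_that("refining the grid shrinks the sphere-radius error monotonically", {
  box <- aabb(rep(-0.75, 3), rep(0.75, 3))
  errs <- vapply(c(32, 64, 128), function(res) {
    m <- extract_mesh(sphere_density(), box, mesh_config(res, 25))
    abs(mean(sqrt(rowSums(m$vertices^2))) - 0.3)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("raising the iso-threshold never grows the enclosed volume", {
  # smooth radial density so the level sets nest
  smooth <- function(pts) 100 * exp(-rowSums(pts^2) / (2 * 0.15^2))
  box <- aabb(rep(-0.75, 3), rep(0.75, 3))
  vols <- vapply(c(10, 25, 50), function(thr) {
    m <- extract_mesh(smooth, box, mesh_config(48, thr))
    # enclosed-volume estimate from the mean vertex radius (near-spherical)
    mean(sqrt(rowSums(m$vertices^2)))^3
  }, numeric(1))
  expect_true(all(diff(vols) < 0))
})

test_that("empty fields give empty meshes and error on height", {
  box <- aabb(rep(-1, 3), rep(1, 3))
  expect_warning(mesh <- extract_mesh(function(p) rep(0, nrow(p)), box,
                                      mesh_config(16, 25)),
                 "empty isosurface")
  expect_equal(nrow(mesh$vertices), 0)
  expect_error(mesh_height(mesh), "empty mesh")
})

test_that("mesh height is the z-extent and is translation invariant", {
  # axis-aligned box solid of height 0.5
  boxy <- function(pts) {
    ifelse(abs(pts[, 1]) < 0.2 & abs(pts[, 2]) < 0.2 &
             pts[, 3] > -0.1 & pts[, 3] < 0.4, 100, 0)
  }
  box <- aabb(rep(-0.75, 3), rep(0.75, 3))
  mesh <- extract_mesh(boxy, box, mesh_config(96, 25))
  expect_equal(mesh_height(mesh), 0.5, tolerance = 2 * 1.5 / 95)
  shifted <- mesh
  shifted$vertices[, 3] <- shifted$vertices[, 3] + 0.13
  expect_equal(mesh_height(shifted), mesh_height(mesh))
})

test_that("meshes round-trip to OBJ and PLY files", {
  box <- aabb(rep(-0.75, 3), rep(0.75, 3))
  mesh <- extract_mesh(sphere_density(), box, mesh_config(24, 25))
  dir <- withr::local_tempdir()
  obj <- file.path(dir, "m.obj")
  write_mesh_obj(mesh, obj)
  lines <- readLines(obj)
  expect_equal(sum(startsWith(lines, "v ")), nrow(mesh$vertices))
  expect_equal(sum(startsWith(lines, "f ")), nrow(mesh$faces))
  ply <- file.path(dir, "m.ply")
  write_mesh_ply(mesh, ply, binary = TRUE)
  hdr <- readLines(ply, n = 3, warn = FALSE)
  expect_equal(hdr[2], "format binary_little_endian 1.0")
  plya <- file.path(dir, "ma.ply")
  write_mesh_ply(mesh, plya, binary = FALSE)
  expect_equal(length(grep("^3 ", readLines(plya))), nrow(mesh$faces))
})
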