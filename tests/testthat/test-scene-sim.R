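test_that("plant field is solid inside, empty outside, and deterministic", {
  f <- make_plant_field(seed = 4, n_leaves = 10)
  # trunk axis at mid-trunk height carries the configured solid density
  expect_equal(f$density_fn(c(0, 0, 0.25)), 120)
  expect_equal(f$density_fn(c(10, 0, 0)), 0)
  expect_equal(f$density_fn(c(0, 0, 5)), 0)
  # crown apex is exactly the recorded bound height
  expect_gt(f$density_fn(c(0, 0, f$bound_height - 1e-4)), 0)
  expect_equal(f$density_fn(c(0, 0, f$bound_height + 1e-4)), 0)
  # every solid stays below the bound height (exact z-extent bookkeeping)
  zs <- seq(f$bound_height + 1e-6, f$cylinder[3], length.out = 50)
  grid <- as.matrix(expand.grid(x = seq(-0.45, 0.45, length.out = 41),
                                y = seq(-0.45, 0.45, length.out = 41),
                                z = zs))
  expect_equal(max(f$density_fn(grid)), 0)
  # determinism
  f2 <- make_plant_field(seed = 4, n_leaves = 10)
  expect_identical(f$solids, f2$solids)
  # purity
  p <- matrix(c(0.05, 0.02, 0.4), 1)
  expect_identical(f$density_fn(p), f$density_fn(p))
  expect_identical(f$color_fn(p), f$color_fn(p))
  expect_true(all(f$color_fn(grid) >= 0 & f$color_fn(grid) <= 1))
})

test_that("trajectory cameras sit exactly on two rings aimed at the axis", {
  prior <- default_prior()
  poses <- make_trajectory(prior, 36)
  expect_length(poses, 72)
  ctrs <- t(vapply(poses, pose_center, numeric(3)))
  expect_equal(sqrt(rowSums(ctrs[, 1:2]^2)), rep(prior$r_real, 72),
               tolerance = 1e-12)
  z <- ctrs[, 3]
  expect_equal(as.numeric(tapply(z, attr(poses, "view"), function(v)
    diff(range(v)))), c(0, 0))
  # optical axis passes through x = y = 0: the axis direction projected to
  # xy is antiparallel to the centre's xy position
  for (p in poses[c(1, 20, 40, 70)]) {
    fwd <- p$rotation[, 3]
    ctr <- pose_center(p)
    cr <- ctr[1] * fwd[2] - ctr[2] * fwd[1]  # z-component of cross product
    expect_equal(cr, 0, tolerance = 1e-12)
    expect_lt(sum(fwd[1:2] * ctr[1:2]), 0)
  }
})

test_that("quadrature renderer reproduces trivial scenes", {
  f <- make_plant_field(seed = 1, n_leaves = 0)
  f$solids <- f$solids[0, , drop = FALSE]  # empty field
  intr <- small_intr(16)
  pose <- look_at_pose(c(0.75, 0, 0.35), c(0, 0, 0.4))
  img <- render_ground_truth(f, pose, intr, n_quad = 32,
                             background = c(0.2, 0.5, 0.9))
  expect_equal(dim(img), c(16, 16, 3))
  expect_equal(max(abs(sweep(img, 3, c(0.2, 0.5, 0.9)))), 0)
})

test_that("opaque wall pixels saturate to the wall color", {
  # a very dense huge trunk acts as an opaque constant-color wall
  f <- make_plant_field(seed = 1, n_leaves = 0, trunk_radius = 0.3,
                        trunk_height = 0.79)
  f$solids <- f$solids[1, , drop = FALSE]
  f$solids[1, 20] <- 1e4     # opaque
  f$texture <- c(0, 43)      # no modulation
  intr <- small_intr(16)
  pose <- look_at_pose(c(0.75, 0, 0.4), c(0, 0, 0.4))
  img <- render_ground_truth(f, pose, intr, n_quad = 512)
  centre <- img[8, 8, ]
  expect_equal(centre, c(0.30, 0.20, 0.10), tolerance = 1e-3)
})

test_that("quadrature converges (Cauchy) as the step count doubles", {
  f <- make_plant_field(seed = 3, n_leaves = 6)
  intr <- small_intr(12)
  pose <- look_at_pose(c(0.75, 0.1, 0.45), c(0, 0, 0.4))
  imgs <- lapply(c(32, 64, 128), function(nq)
    render_ground_truth(f, pose, intr, n_quad = nq))
  d1 <- max(abs(imgs[[1]] - imgs[[2]]))
  d2 <- max(abs(imgs[[2]] - imgs[[3]]))
  expect_lt(d2, d1)
})

test_that("constant-density slab quadrature approaches 1 - exp(-sigma*L)", {
  # rendered alpha for a slab of optical depth sigma*L, checked via a huge
  # opaque-free single-solid scene: alpha = 1 - T where T is the residual
  # transmittance against a black background
  for (od in c(0, 0.5, 5)) {
    L <- 0.5
    f <- make_plant_field(seed = 1, n_leaves = 0, trunk_radius = 10,
                          trunk_height = L)
    f$solids <- f$solids[1, , drop = FALSE]
    f$solids[1, 20] <- od / L
    f$texture <- c(0, 1)
    f$cylinder <- c(20, 0, L)
    intr <- camera_intrinsics(1e5, 1e5, 0.5, 0.5, 1, 1)  # single axial pixel
    pose <- camera_pose(cbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1)),
                        c(0, 0, 2), "c2w")  # looking straight down
    img <- render_ground_truth(f, pose, intr, n_quad = 4096,
                               background = c(0, 0, 0), t_far = 4)
    alpha_expected <- 1 - exp(-od)
    col <- f$color_fn(c(0, 0, L / 2))[1, ]
    expect_equal(as.numeric(img[1, 1, ]), alpha_expected * col,
                 tolerance = 2e-3)
  }
})

test_that("degradation applies exposure scaling exactly and blur reduces
           sharpness", {
  cap <- tiny_capture()
  same <- degrade(cap, blur_ids = integer(0), exposure_exps = 0)
  expect_identical(same$frames, cap$frames)

  # unsaturated frame doubles exactly under one stop of exposure
  half <- cap
  half$frames <- lapply(cap$frames, function(f) f / 2)
  doubled <- degrade(half, exposure_exps = 1)
  expect_equal(doubled$frames[[1]], half$frames[[1]] * 2, tolerance = 1e-12)
  halved <- degrade(cap, exposure_exps = -1)
  expect_equal(halved$frames[[2]], cap$frames[[2]] / 2, tolerance = 1e-12)

  blurred <- degrade(cap, blur_ids = 3, blur_sigma = 2)
  expect_lt(laplacian_variance(blurred$frames[[3]]),
            laplacian_variance(cap$frames[[3]]))
  expect_identical(blurred$frames[[1]], cap$frames[[1]])
  expect_equal(blurred$blurred_ids, 3L)
})

test_that("synthetic captures are bit-identical across equal seeds", {
  f1 <- make_plant_field(seed = 9, n_leaves = 5)
  f2 <- make_plant_field(seed = 9, n_leaves = 5)
  intr <- small_intr(16)
  c1 <- simulate_capture(f1, default_prior(), n_per_ring = 3, intr = intr,
                         n_quad = 16)
  c2 <- simulate_capture(f2, default_prior(), n_per_ring = 3, intr = intr,
                         n_quad = 16)
  expect_identical(c1$frames, c2$frames)
})

test_that("captures round-trip to disk through the standard readers", {
  cap <- tiny_capture()
  dir <- withr::local_tempdir()
  write_capture(cap, dir)
  expect_true(file.exists(file.path(dir, "prior.yaml")))
  frames <- read_frames(dir)
  expect_length(frames, length(cap$frames))
  # PNG quantizes to 8 bits
  expect_equal(frames[["lower_0001.png"]], cap$frames[[1]],
               tolerance = 1 / 255)
  model <- read_sfm_model(file.path(dir, "sparse"))
  expect_length(model$poses, length(cap$frames))
  prior <- read_prior(file.path(dir, "prior.yaml"))
  expect_equal(prior$r_real, cap$prior$r_real)
})
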