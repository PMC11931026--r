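test_that("total-least-squares plane fit recovers exact and noisy planes", {
  pts <- cbind(runif(20), runif(20), 0.7)
  pl <- fit_plane(pts)
  expect_equal(pl$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_equal(pl$offset, 0.7, tolerance = 1e-12)

  # plane x + y + z = 1
  set.seed(3)
  u <- runif(30); v <- runif(30)
  pts <- cbind(u, v, 1 - u - v)
  pl <- fit_plane(pts)
  expect_equal(pl$normal, rep(1, 3) / sqrt(3), tolerance = 1e-9)

  # Monte-Carlo: isotropic noise sigma = 1e-3 gives angular error < 1e-2 rad
  for (i in 1:5) {
    noisy <- pts + matrix(rnorm(90, sd = 1e-3), ncol = 3)
    ang <- acos(min(1, abs(sum(fit_plane(noisy)$normal * rep(1, 3) / sqrt(3)))))
    expect_lt(ang, 1e-2)
  }

  expect_error(fit_plane(cbind(1:5, 2 * (1:5), 3 * (1:5))), "collinear")
})

test_that("Rodrigues rotation maps the fitted normal onto z", {
  expect_equal(rotation_from_normal(c(0, 0, 1)), diag(3))
  R <- rotation_from_normal(c(1, 0, 0))
  expect_equal(drop(R %*% c(1, 0, 0)), c(0, 0, 1), tolerance = 1e-12)
  # antiparallel normal is handled
  R <- rotation_from_normal(c(0, 0, -1))
  expect_equal(drop(R %*% c(0, 0, -1)), c(0, 0, 1), tolerance = 1e-12)
  set.seed(4)
  for (i in 1:10) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    R <- rotation_from_normal(n)
    expect_equal(crossprod(R), diag(3), tolerance = 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
    expect_equal(drop(R %*% n), c(0, 0, 1), tolerance = 1e-12)
  }
})

test_that("Kasa circle fit recovers exact circles and circumcircles", {
  ang <- seq(0, 2 * pi, length.out = 25)[-25]
  pts <- cbind(1 + 3 * cos(ang), 2 + 3 * sin(ang))
  cf <- fit_circle_2d(pts)
  expect_equal(cf$center, c(1, 2), tolerance = 1e-9)
  expect_equal(cf$radius, 3, tolerance = 1e-9)

  # three points: compare against the closed-form circumcircle
  set.seed(5)
  for (i in 1:10) {
    p <- matrix(rnorm(6), 3, 2)
    ax <- p[1, 1]; ay <- p[1, 2]; bx <- p[2, 1]; by <- p[2, 2]
    cx <- p[3, 1]; cy <- p[3, 2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-3) next
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    cf <- fit_circle_2d(p)
    expect_equal(cf$center, c(ux, uy), tolerance = 1e-6)
    expect_equal(cf$radius, sqrt((ax - ux)^2 + (ay - uy)^2),
                 tolerance = 1e-6)
    expect_gt(cf$radius, 0)
  }
  expect_error(fit_circle_2d(cbind(1:5, 1:5)), "collinear")
})

test_that("ring splitting separates the two trajectories at mid-height", {
  ang <- seq(0, 2 * pi, length.out = 37)[-37]
  pts <- rbind(cbind(cos(ang), sin(ang), 1), cbind(cos(ang), sin(ang), 2))
  sp <- split_rings(pts)
  expect_equal(sp$z_low, 1)
  expect_equal(sp$z_up, 2)
  expect_equal((sp$z_up + sp$z_low) / 2, 1.5)
  set.seed(6)
  noisy <- pts
  noisy[, 3] <- noisy[, 3] + rnorm(72, sd = 1e-3)
  sp <- split_rings(noisy)
  expect_length(sp$upper, 36)
  expect_length(sp$lower, 36)
  expect_error(split_rings(cbind(ang, ang, 1)), "two rings")
})

test_that("similarity calibration recovers metric geometry from a random
           similarity transform", {
  prior <- default_prior()
  poses <- make_trajectory(prior, 18)
  true_ctrs <- t(vapply(poses, pose_center, numeric(3)))
  true_ctrs[, 3] <- true_ctrs[, 3] - mean(range(true_ctrs[, 3]))
  set.seed(7)
  for (rep in 1:3) {
    Q <- rotation_exp(rnorm(3))
    s <- runif(1, 0.2, 5)
    u <- rnorm(3)
    conv <- if (rep == 2) "w2c" else "c2w"
    pert <- lapply(poses, function(p) {
      pp <- camera_pose(Q %*% p$rotation,
                        s * drop(Q %*% p$translation) + u, "c2w")
      pose_convert(pp, conv)
    })
    cal <- calibrate_poses(pert, prior)
    expect_s3_class(cal$calibration, "similarity_calibration")
    ctrs <- t(vapply(cal$poses, pose_center, numeric(3)))
    # ring radius restored to r_real
    expect_lt(max(abs(sqrt(rowSums(ctrs[, 1:2]^2)) - prior$r_real)), 1e-9)
    # pairwise distances match ground truth (azimuth is gauge)
    expect_lt(max(abs(as.matrix(dist(ctrs)) - as.matrix(dist(true_ctrs)))),
              1e-9)
    # ring heights restored and vertically centred
    expect_equal(cal$calibration$z_up, 0.2, tolerance = 1e-9)
    expect_equal(cal$calibration$z_low, -0.2, tolerance = 1e-9)
  }
})

test_that("calibration of 1 mm noisy rings recovers the radius within 5 mm", {
  prior <- default_prior()
  poses <- make_trajectory(prior, 36)
  set.seed(8)
  Q <- rotation_exp(rnorm(3)); s <- 2.4; u <- c(0.3, -0.8, 1.1)
  pert <- lapply(poses, function(p) {
    camera_pose(Q %*% p$rotation,
                s * (drop(Q %*% p$translation) + rnorm(3, sd = 1e-3)) + u,
                "c2w")
  })
  cal <- calibrate_poses(pert, prior)
  ctrs <- t(vapply(cal$poses, pose_center, numeric(3)))
  r_fit <- fit_circle_2d(ctrs[, 1:2])$radius
  expect_lt(abs(r_fit - prior$r_real), 5e-3)
})

test_that("already-calibrated input is a fixed point up to recentering", {
  prior <- default_prior()
  poses <- make_trajectory(prior, 12)
  cal1 <- calibrate_poses(poses, prior)
  expect_equal(cal1$calibration$k, 1, tolerance = 1e-9)
  expect_equal(cal1$calibration$R_vtr, diag(3), tolerance = 1e-9)
  expect_equal(cal1$calibration$t_s[1:2], c(0, 0), tolerance = 1e-9)
  expect_equal(cal1$calibration$t_s[3], 0.55, tolerance = 1e-9)
  # idempotence: a second calibration changes pairwise distances < 1e-9
  cal2 <- calibrate_poses(cal1$poses, prior)
  d1 <- as.matrix(dist(t(vapply(cal1$poses, pose_center, numeric(3)))))
  d2 <- as.matrix(dist(t(vapply(cal2$poses, pose_center, numeric(3)))))
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("ROI box follows the trajectory prior and contains the cameras", {
  prior <- default_prior()
  cal <- calibrate_poses(make_trajectory(prior, 10), prior)
  box <- compute_roi_aabb(cal$calibration, prior)
  expect_equal(box$min, c(-0.75, -0.75, cal$calibration$z_low - 0.35))
  expect_equal(box$max, c(0.75, 0.75, cal$calibration$z_up + 0.25))
  expect_equal(box$min[1:2], -box$max[1:2])  # symmetric in x and y
  ctrs <- t(vapply(cal$poses, pose_center, numeric(3)))
  expect_true(all(sweep(ctrs, 2, box$min, ">=") - 1e-9 <= 1))
  expect_true(all(ctrs >= matrix(box$min, nrow(ctrs), 3, byrow = TRUE) - 1e-9))
  expect_true(all(ctrs <= matrix(box$max, nrow(ctrs), 3, byrow = TRUE) + 1e-9))
  bad <- cal$calibration
  bad$z_low <- 10  # below-ground corner would sit above the top corner
  expect_error(compute_roi_aabb(bad, prior), "inconsistent")
})

test_that("tidy() exposes the calibration parameters as a tibble", {
  prior <- default_prior()
  cal <- calibrate_poses(make_trajectory(prior, 8), prior)
  td <- tidy(cal$calibration)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "k"], 1, tolerance = 1e-9)
})
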