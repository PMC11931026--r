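test_that("hash grid resolutions follow the geometric progression", {
  cfg <- hash_grid_config()
  expect_equal(cfg$levels, 16)
  expect_equal(cfg$resolutions[1], 16L)
  expect_equal(cfg$resolutions[16], 2048L)
  b <- exp((log(2048) - log(16)) / 15)
  expect_equal(cfg$resolutions, as.integer(floor(16 * b^(0:15) + 1e-9)))
  expect_true(all(diff(cfg$resolutions) > 0))
  expect_error(hash_grid_config(table_size = 1000), "bitwAnd")
})

test_that("hash encoding has dimension L*F, interpolates corners exactly,
           and is continuous", {
  cfg <- hash_grid_config()
  expect_equal(cfg$levels * cfg$features_per_entry, 32)

  small <- hash_grid_config(levels = 3, table_size = 2^12, n_min = 4,
                            n_max = 16)
  set.seed(10)
  total <- small$offsets[length(small$offsets)]
  tab <- matrix(rnorm(2 * total), 2, total)
  # exact corner of the coarsest level (dense indexing: (4+1)^3 <= 2^12)
  corner <- c(2, 3, 1)
  x <- matrix(corner / 4, 1)
  enc <- hash_encode(x, small, tab)
  expect_equal(ncol(enc), 6)
  dense_idx <- corner[1] + 5 * (corner[2] + 5 * corner[3]) + 1
  expect_equal(as.numeric(enc[1, 1:2]), tab[, dense_idx], tolerance = 1e-12)

  # continuity: shrinking perturbations shrink the encoding difference
  x0 <- matrix(c(0.31, 0.57, 0.42), 1)
  d1 <- max(abs(hash_encode(x0 + 1e-3, small, tab) -
                  hash_encode(x0, small, tab)))
  d2 <- max(abs(hash_encode(x0 + 1e-5, small, tab) -
                  hash_encode(x0, small, tab)))
  expect_lt(d2, d1)
  expect_lt(d2, 1e-3)

  # out-of-box points clamp
  expect_equal(hash_encode(matrix(c(-1, 2, 0.5), 1), small, tab),
               hash_encode(matrix(c(0, 1, 0.5), 1), small, tab))
})

test_that("direction encoding is 27-dimensional, bounded and pure", {
  e <- encode_direction(c(0, 0, 1))
  expect_equal(ncol(e), 27)
  expect_identical(e, encode_direction(c(0, 0, 1)))
  # for (0,0,1): sin(2^j*pi*d) = 0 everywhere; cos(pi) = -1 at j = 0 on the
  # z component, +1 at the higher frequencies
  expect_equal(as.numeric(e),
               c(0, 0, 1, 0, 0, 0, 1, 1, -1, rep(c(0, 0, 0, 1, 1, 1), 3)),
               tolerance = 1e-12)
  set.seed(11)
  d <- random_unit(50)
  enc <- encode_direction(d)
  expect_true(all(abs(enc) <= 1 + 1e-12))
  expect_error(encode_direction(c(0, 0, 0)), "zero direction")
  expect_error(encode_direction(c(0, 0, 2)))
})

test_that("density net emits a non-negative density and 15 features", {
  rf <- random_field()
  set.seed(12)
  x <- matrix(runif(3 * 200), ncol = 3)
  enc <- hash_encode(x, rf$fine_cfg, rf$params$f_tab)
  out <- density_net(rf, enc)
  expect_length(out$sigma, 200)
  expect_equal(dim(out$geo), c(200, 15))
  expect_equal(dim(out$geo16), c(200, 16))
  expect_true(all(out$sigma >= 0))
  expect_identical(out, density_net(rf, enc))
  # large random input sweep keeps sigma non-negative
  big <- matrix(rnorm(1e4 * ncol(enc), 0, 3), 1e4)
  expect_true(all(density_net(rf, big)$sigma >= 0))
})

test_that("color net outputs rgb in (0,1) and responds to view direction", {
  rf <- random_field()
  set.seed(13)
  geo <- matrix(rnorm(1e4 * 16), ncol = 16)
  denc <- encode_direction(random_unit(1))
  rgb <- color_net(rf, geo, denc)
  expect_equal(dim(rgb), c(1e4, 3))
  expect_true(all(rgb > 0 & rgb < 1))
  # view dependence: changing the direction with fixed features moves output
  g1 <- geo[1, , drop = FALSE]
  r1 <- color_net(rf, g1, encode_direction(c(0, 0, 1)))
  r2 <- color_net(rf, g1, encode_direction(c(1, 0, 0)))
  expect_gt(max(abs(r1 - r2)), 1e-6)
})

test_that("zeroed parameters give a spatially constant density", {
  rf <- random_field()
  for (b in c("f_tab", "W1", "b1", "W2", "b2")) {
    rf$params[[b]][] <- 0
  }
  set.seed(14)
  pts <- matrix(runif(300, -0.7, 0.7), ncol = 3)
  sig <- query_density(rf, pts)
  expect_equal(sig, rep(log(2), 100), tolerance = 1e-12)  # softplus(0)
})

test_that("parameter accounting is stable and bounded by the table sizes", {
  rf <- random_field()
  counts <- field_param_counts(rf)
  expect_lte(counts[["f_tab"]],
             rf$fine_cfg$levels * rf$fine_cfg$table_size *
               rf$fine_cfg$features_per_entry)
  expect_lte(counts[["c_tab"]],
             rf$coarse_cfg$levels * rf$coarse_cfg$table_size *
               rf$coarse_cfg$features_per_entry)
  expect_identical(counts, field_param_counts(random_field()))
  gl <- glance(rf)
  expect_equal(gl$n_params, sum(counts))
  expect_false(gl$trained)
})

test_that("C++ density queries agree with the R network surface", {
  rf <- random_field()
  set.seed(15)
  pts <- matrix(runif(150, -0.6, 0.6), ncol = 3)
  # R path: normalize to the box, encode, run the density net
  pn <- sweep(sweep(pts, 2, rf$aabb$min), 2, rf$aabb$max - rf$aabb$min, "/")
  pn <- pmin(pmax(pn, 0), 1)
  enc <- hash_encode(pn, rf$fine_cfg, rf$params$f_tab)
  sig_r <- density_net(rf, enc)$sigma
  expect_equal(query_density(rf, pts), sig_r, tolerance = 1e-10)
})
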