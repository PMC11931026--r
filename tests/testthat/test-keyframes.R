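test_that("Laplacian variance matches the hand-computed toy response", {
  # 5x5 black image with a single white centre pixel: the 8-neighborhood
  # Laplacian response is -8 at the centre, 1 at its 8 neighbours, 0
  # elsewhere; mean 0, variance (64 + 8) / 25
  img <- matrix(0, 5, 5)
  img[3, 3] <- 1
  expect_equal(laplacian_variance(img), 72 / 25, tolerance = 1e-12)
})

test_that("Laplacian variance is zero on constants and shift-invariant", {
  expect_equal(laplacian_variance(array(0.37, c(8, 8, 3))), 0)
  set.seed(1)
  img <- array(runif(8 * 8 * 3, 0, 0.5), c(8, 8, 3))
  expect_equal(laplacian_variance(img), laplacian_variance(img + 0.3),
               tolerance = 1e-12)
  expect_gt(laplacian_variance(img), 0)
})

test_that("sharp structure scores higher than its blurred version", {
  chk <- array(0, c(32, 32, 3))
  chk[] <- (outer(0:31 %/% 4, 0:31 %/% 4, "+") %% 2)
  blur <- orbitnerf:::cpp_gaussian_blur(chk, 2)
  expect_gt(laplacian_variance(chk), laplacian_variance(blur))
})

test_that("equidistant downsampling keeps the evenly spaced index rule", {
  expect_equal(equidistant_indices(450, 50),
               as.integer(round(seq(0, 449, length.out = 50)) + 1))
  expect_equal(equidistant_indices(50, 50), 1:50)
  expect_error(equidistant_indices(49, 50), "too few")
  # endpoints always covered
  for (n in c(50, 91, 450)) {
    idx <- equidistant_indices(n, 50)
    expect_equal(idx[1], 1L)
    expect_equal(idx[50], n)
    expect_false(anyDuplicated(idx) > 0)
  }
})

test_that("downsampling a two-view video yields the target count per view", {
  set.seed(2)
  mk <- function(n) replicate(n, array(runif(12), c(2, 2, 3)),
                              simplify = FALSE)
  fs <- equidistant_downsample(list(lower = mk(55), upper = mk(70)),
                               target_per_view = 10)
  expect_equal(unname(per_view_counts(fs)), c(10, 10))
  expect_false(anyNA(fs$meta$sharpness))
  # identity when counts match exactly, order preserved
  fs2 <- equidistant_downsample(list(lower = mk(10)), target_per_view = 10)
  expect_equal(fs2$meta$source_index, 1:10)
})

test_that("blur elimination removes sub-threshold frames and gates quality", {
  # equal sharpness: nothing removed
  fs <- fake_frame_set(rep(5, 20))
  expect_equal(nrow(eliminate_blurry(fs)$meta), 20)

  # 99 sharp frames at 100 and one at 10: 10 < 0.2 * 99.1, removed
  fs <- fake_frame_set(c(rep(100, 99), 10))
  kept <- eliminate_blurry(fs)
  expect_equal(nrow(kept$meta), 99)
  expect_false(100 %in% kept$meta$source_index)

  # permutation invariance: the kept frames are those above threshold,
  # regardless of input order
  sh <- c(rep(100, 30), rep(1, 3))
  set.seed(9)
  for (i in 1:3) {
    perm <- sample(length(sh))
    kept <- eliminate_blurry(fake_frame_set(sh[perm]))
    expect_true(all(kept$meta$sharpness == 100))
    expect_equal(nrow(kept$meta), 30)
  }

  # more than max_removed blurry frames raises the quality gate
  fs <- fake_frame_set(c(rep(100, 89), rep(1, 11)))
  expect_error(eliminate_blurry(fs), class = "orbitnerf_quality_failure")
  expect_error(eliminate_blurry(fs), "re-acquire")
  # exactly max_removed passes
  fs <- fake_frame_set(c(rep(100, 90), rep(1, 10)))
  expect_equal(nrow(eliminate_blurry(fs)$meta), 90)
})

test_that("keyframe selection samples per view, seeded and sorted", {
  fs <- frame_set(replicate(100, array(0.5, c(2, 2, 3)), simplify = FALSE),
                  rep(c("lower", "upper"), each = 50), rep(1:50, 2),
                  rep(1, 100))
  s1 <- select_keyframes(fs, per_view = 45, seed = 11)
  s2 <- select_keyframes(fs, per_view = 45, seed = 11)
  expect_equal(nrow(s1$meta), 90)
  expect_identical(s1$meta, s2$meta)
  expect_equal(unname(per_view_counts(s1)), c(45, 45))
  expect_false(is.unsorted(s1$meta$source_index[s1$meta$view == "lower"]))
  # sample = population when exactly per_view remain
  fs45 <- frame_set(replicate(45, array(0.5, c(2, 2, 3)), simplify = FALSE),
                    rep("lower", 45), 1:45, rep(1, 45))
  expect_equal(select_keyframes(fs45, per_view = 45,
                                seed = 3)$meta$source_index, 1:45)
  expect_error(select_keyframes(fs45, per_view = 46, seed = 1), "need 46")
})

test_that("frame manifest carries filename, view, index and sharpness", {
  fs <- fake_frame_set(c(3, 4), view = "upper")
  man <- frame_manifest(fs)
  expect_equal(man$filename, c("upper_0001.png", "upper_0002.png"))
  expect_equal(man$sharpness, c(3, 4))
})
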