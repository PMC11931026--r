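# ROI-constrained hierarchical ray sampling, volume rendering, exposure
# adjustment, pose refinement and the training loop.

#' Ray / axis-aligned-box intersection (slab method)
#'
#' Computes the parametric entry/exit distances of a ray against a box:
#' `t_min = max((min - o) / d)`, `t_max = min((max - o) / d)` over the three
#' slabs.  The ray hits iff `t_min <= t_max` and `t_max >= 0`.  Because the
#' camera sits inside the ROI box during capture, `t_min` is clamped to 0 on a
#' hit, so the near region always starts at the camera.
#'
#' @param origin,direction numeric 3-vectors; `direction` must be unit length
#'   (zero components are handled by the slab rule).
#' @param box an [aabb()].
#' @param t_b maximum ray length, meters.
#' @return list with `hit` (logical), `t_min` (0 on hit), `t_max`, and `t_b`.
#' @export
ray_aabb_intersect <- function(origin, direction, box, t_b = Inf) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  nd <- sqrt(sum(direction^2))
  stopifnot(abs(nd - 1) < 1e-6)
  t0 <- -Inf
  t1 <- Inf
  for (c in 1:3) {
    if (abs(direction[c]) < 1e-14) {
      if (origin[c] < box$min[c] || origin[c] > box$max[c]) {
        return(list(hit = FALSE, t_min = NA_real_, t_max = NA_real_,
                    t_b = t_b))
      }
    } else {
      a <- (box$min[c] - origin[c]) / direction[c]
      b <- (box$max[c] - origin[c]) / direction[c]
      t0 <- max(t0, min(a, b))
      t1 <- min(t1, max(a, b))
    }
  }
  hit <- t0 <= t1 && t1 >= 0
  if (!hit) {
    return(list(hit = FALSE, t_min = NA_real_, t_max = NA_real_, t_b = t_b))
  }
  list(hit = TRUE, t_min = 0, t_max = t1, t_b = t_b)
}

#' Two-region stratified coarse samples along a ray
#'
#' Places `round(roi_fraction * n_c)` jittered-stratified samples in the ROI
#' region `(0, t_max]` and the remainder in the background region
#' `(t_max, t_b]`; a ray that misses the box gets all `n_c` samples over
#' `(0, t_b]`.  With `jitter = FALSE`, samples sit at the stratum midpoints.
#'
#' @param interval result of [ray_aabb_intersect()].
#' @param n_c number of coarse samples.
#' @param roi_fraction fraction of samples assigned to the ROI region.
#' @param jitter logical; stratified-uniform jitter (default) or midpoints.
#' @return sorted numeric vector of `n_c` distances in `(0, t_b]`.
#' @export
sample_two_regions <- function(interval, n_c, roi_fraction = 0.75,
                               jitter = TRUE) {
  stopifnot(n_c >= 2, roi_fraction > 0, roi_fraction < 1,
            is.finite(interval$t_b))
  strat <- function(n, lo, hi) {
    u <- if (jitter) runif(n) else rep(0.5, n)
    lo + (seq_len(n) - 1 + u) / n * (hi - lo)
  }
  if (!interval$hit) {
    return(strat(n_c, 0, interval$t_b))
  }
  n1 <- round(roi_fraction * n_c)
  n1 <- max(1, min(n_c - 1, n1))
  edge <- min(interval$t_max, interval$t_b)
  sort(c(strat(n1, 0, edge), strat(n_c - n1, edge, interval$t_b)))
}

#' Coarse weights from densities along a ray
#'
#' Computes the volume-rendering weights
#' `w_i = T_i * (1 - exp(-sigma_i * delta_i))` with transmittance
#' `T_i = exp(-sum_(j<i) sigma_j * delta_j)`, and the normalized weights
#' `w_hat = w / sum(w)` that define the piecewise-constant sampling density
#' for the fine pass.  If every weight is zero (empty ray), `w_hat` falls
#' back to uniform and `fallback_uniform` is flagged.
#'
#' @param sigmas non-negative densities at the sample points, 1/m.
#' @param t_values sorted sample distances, meters.
#' @param t_far end of the last interval (defaults to extrapolating the last
#'   spacing).
#' @return list with `t`, `delta`, `transmittance` (T_i), `weights` (w_i),
#'   `normalized` (w_hat), `residual_transmittance`, and `fallback_uniform`.
#' @export
coarse_weights <- function(sigmas, t_values, t_far = NULL) {
  n <- length(t_values)
  stopifnot(length(sigmas) == n, all(sigmas >= 0), !is.unsorted(t_values))
  if (is.null(t_far)) {
    t_far <- if (n > 1) 2 * t_values[n] - t_values[n - 1] else t_values[n] * 2
  }
  delta <- c(diff(t_values), max(0, t_far - t_values[n]))
  od <- sigmas * delta
  Ti <- exp(-c(0, cumsum(od)[-n]))
  w <- Ti * (1 - exp(-od))
  s <- sum(w)
  fallback <- s <= 1e-12
  what <- if (fallback) rep(1 / n, n) else w / s
  list(t = t_values, delta = delta, transmittance = Ti, weights = w,
       normalized = what, residual_transmittance = exp(-sum(od)),
       fallback_uniform = fallback)
}

#' Inverse-transform sampling of fine points
#'
#' Draws `n_f` distances from the piecewise-constant probability density
#' defined by the normalized coarse weights over the bins
#' `[t_i, t_(i+1))` (the last bin ends at `t_far`), then merges and sorts
#' them with the coarse samples.
#'
#' @param batch result of [coarse_weights()].
#' @param n_f number of fine samples.
#' @param seed integer seed.
#' @param t_far end of the last bin (defaults to `t[n] + delta[n]`).
#' @param deterministic if `TRUE`, use the fixed quantiles `(j - 0.5) / n_f`
#'   instead of random draws.
#' @return list with `fine` (the n_f new samples, sorted) and `merged`
#'   (coarse + fine, sorted).
#' @export
inverse_transform_sample <- function(batch, n_f, seed = 1, t_far = NULL,
                                     deterministic = FALSE) {
  what <- batch$normalized
  n <- length(what)
  stopifnot(abs(sum(what) - 1) < 1e-9, all(what >= 0))
  if (is.null(t_far)) t_far <- batch$t[n] + batch$delta[n]
  edges <- c(batch$t, t_far)
  cdf <- cumsum(what)
  cdf[n] <- 1
  u <- if (deterministic) {
    (seq_len(n_f) - 0.5) / n_f
  } else {
    restore <- local_seed(seed)
    on.exit(restore())
    runif(n_f)
  }
  k <- findInterval(u, c(0, cdf), rightmost.closed = TRUE,
                    all.inside = TRUE)
  clo <- c(0, cdf)[k]
  frac <- ifelse(what[k] > 1e-300, (u - clo) / what[k], 0.5)
  frac <- pmin(1, pmax(0, frac))
  fine <- sort(edges[k] + frac * (edges[k + 1] - edges[k]))
  list(fine = fine, merged = sort(c(batch$t, fine)))
}

#' Volume rendering of one ray
#'
#' Standard emission-absorption compositing of per-sample colors with the
#' coarse-weight formula; residual transmittance is composited onto the
#' background color.
#'
#' @param sigmas non-negative densities at the samples.
#' @param colors n x 3 matrix of sample colors in `[0, 1]`.
#' @param t_values sorted sample distances.
#' @param background rgb 3-vector.
#' @param t_far end of the last interval (see [coarse_weights()]).
#' @return list with `color` (rgb 3-vector), `weights`, and
#'   `residual_transmittance`.
#' @export
volume_render <- function(sigmas, colors, t_values,
                          background = c(0, 0, 0), t_far = NULL) {
  colors <- matrix(as.numeric(colors), ncol = 3)
  stopifnot(nrow(colors) == length(sigmas),
            length(sigmas) == length(t_values))
  cw <- coarse_weights(sigmas, t_values, t_far)
  col <- drop(crossprod(cw$weights, colors)) +
    cw$residual_transmittance * background
  list(color = col, weights = cw$weights,
       residual_transmittance = cw$residual_transmittance)
}

#' Exposure adjustment of a synthesized color
#'
#' Scales a rendered color by `S_i = exp(ln(2) * E_i) = 2^E_i`, the learned
#' per-image exposure factor, to match the observed frame before computing
#' the photometric loss.
#'
#' @param rgb color vector/matrix.
#' @param E_i log2 exposure rate.
#' @return scaled color (not clipped).
#' @export
apply_exposure <- function(rgb, E_i) {
  stopifnot(is.finite(E_i))
  rgb * exp(log(2) * E_i)
}

#' Apply a learned pose offset
#'
#' `rotation <- exp([dtheta]_x) %*% rotation`, `translation <- translation +
#' dt`, keeping the result a valid pose.  For a camera-to-world pose this
#' perturbs the camera orientation and shifts the camera centre.
#'
#' @param pose a [camera_pose()].
#' @param dt translation offset, 3-vector (meters).
#' @param dtheta axis-angle rotation offset, 3-vector (radians).
#' @return the offset [camera_pose()].
#' @export
apply_pose_offset <- function(pose, dt, dtheta) {
  camera_pose(rotation_exp(dtheta) %*% pose$rotation,
              pose$translation + dt, pose$convention)
}

#' Train a radiance field on a posed capture
#'
#' Minimizes the mean-squared error between exposure-adjusted rendered colors
#' (both the coarse and the fine pass) and the observed pixels over random
#' ray minibatches, plus L2 regularizers on the exposure rates and the pose
#' offsets, by Adam.  Exposure rates and pose offsets are updated by
#' backpropagation alongside the hash tables and perceptron weights.  Sample
#' placement along each ray is treated as non-differentiable.
#'
#' @param field a [radiance_field()].
#' @param frames list of H x W x 3 arrays (the training images).
#' @param poses list of calibrated [camera_pose()]s, one per frame.
#' @param intr a [camera_intrinsics()] (ideal pinhole).
#' @param n_iter number of gradient steps.
#' @param batch rays per step.
#' @param lr_hash,lr_mlp,lr_exposure,lr_pose Adam learning rates.
#' @param optimize_exposure,optimize_pose enable the per-image parameters.
#' @param seed integer seed driving ray selection and jitter.
#' @return the trained `radiance_field` (with `$log`, a tibble of iteration /
#'   loss pairs).
#' @export
train_radiance_field <- function(field, frames, poses, intr, n_iter = 2000,
                                 batch = 256, lr_hash = 1e-2, lr_mlp = 1e-3,
                                 lr_exposure = 1e-2, lr_pose = 1e-3,
                                 optimize_exposure = TRUE,
                                 optimize_pose = FALSE, seed = 1) {
  stopifnot(inherits(field, "radiance_field"), length(frames) >= 2,
            length(frames) == length(poses),
            length(frames) == field$n_images)
  cap <- pack_capture(frames, poses, intr)
  res <- cpp_train(field$params, field_cfg_list(field), cap$images, cap$R,
                   cap$centers, cap$intr, as.integer(n_iter),
                   as.integer(batch), as.integer(seed), lr_hash, lr_mlp,
                   lr_exposure, lr_pose, optimize_exposure, optimize_pose,
                   25L)
  field$params <- res$params
  field$log <- tibble::tibble(iteration = res$log_iter, loss = res$log_loss)
  field
}

# stack frames/poses for the C++ core
pack_capture <- function(frames, poses, intr) {
  h <- dim(frames[[1]])[1]
  w <- dim(frames[[1]])[2]
  n <- length(frames)
  images <- array(0, c(h, w, 3, n))
  R <- array(0, c(3, 3, n))
  centers <- matrix(0, 3, n)
  for (i in seq_len(n)) {
    stopifnot(all(dim(frames[[i]]) == c(h, w, 3)))
    images[, , , i] <- frames[[i]]
    p <- pose_convert(poses[[i]], "c2w")
    R[, , i] <- p$rotation
    centers[, i] <- p$translation
  }
  list(images = images, R = R, centers = centers,
       intr = c(intr$fx, intr$fy, intr$cx, intr$cy))
}

#' Photometric loss and analytic gradients for a fixed ray set
#'
#' Computes the training objective on the given pixels and its analytic
#' gradients with respect to the per-image exposure rates and pose offsets
#' (sample placement held fixed).  Used for gradient verification.
#'
#' @inheritParams train_radiance_field
#' @param img_id,rows,cols parallel integer vectors selecting the rays
#'   (1-based).
#' @param jitter logical; `FALSE` gives deterministic sample placement.
#' @param seed seed for jittered placement.
#' @return list with `loss`, `gE`, `gdT`, `gdTh`.
#' @export
field_loss_grads <- function(field, frames, poses, intr, img_id, rows, cols,
                             jitter = FALSE, seed = 1) {
  cap <- pack_capture(frames, poses, intr)
  cpp_loss_grads(field$params, field_cfg_list(field), cap$images, cap$R,
                 cap$centers, cap$intr, as.integer(img_id), as.integer(rows),
                 as.integer(cols), jitter, as.integer(seed))
}

#' Render a full view from a trained field
#'
#' Renders every pixel of a view at canonical exposure (`E = 0`) using the
#' hierarchical ROI sampler; deterministic (midpoint strata and fixed fine
#' quantiles) unless `jitter = TRUE`.
#'
#' @param field a trained [radiance_field()].
#' @param pose a [camera_pose()].
#' @param intr a [camera_intrinsics()].
#' @param h,w output size (defaults from `intr`).
#' @param jitter logical; random sample jitter.
#' @param seed seed used when `jitter = TRUE`.
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_view <- function(field, pose, intr, h = intr$height, w = intr$width,
                        jitter = FALSE, seed = 1) {
  stopifnot(inherits(field, "radiance_field"))
  px <- expand.grid(row = seq_len(h), col = seq_len(w))
  rays <- pixel_rays(pose, intr, px$row, px$col)
  out <- matrix(0, nrow(px), 3)
  chunk <- 1024L
  cfg <- field_cfg_list(field)
  for (s in seq(1, nrow(px), by = chunk)) {
    e <- min(nrow(px), s + chunk - 1)
    out[s:e, ] <- cpp_render_rays(field$params, cfg,
                                  rays$origins[s:e, , drop = FALSE],
                                  rays$directions[s:e, , drop = FALSE],
                                  jitter, as.integer(seed + s))
  }
  img <- array(0, c(h, w, 3))
  img[cbind(px$row, px$col, 1)] <- out[, 1]
  img[cbind(px$row, px$col, 2)] <- out[, 2]
  img[cbind(px$row, px$col, 3)] <- out[, 3]
  img
}

#' Training-loss curve
#' @param field a trained [radiance_field()].
#' @return a ggplot object of loss vs iteration (log y scale).
#' @export
plot_training_curve <- function(field) {
  stopifnot(!is.null(field$log))
  ggplot2::ggplot(field$log,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "iteration", y = "training loss")
}
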