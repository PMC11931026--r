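# The radiance-field representation: multi-resolution hash encoding feeding a
# shallow density perceptron, a direction-conditioned color perceptron, and
# per-training-image exposure and pose-offset parameters.

#' Multi-resolution hash grid configuration
#'
#' Per-level resolutions follow the geometric progression
#' `N_l = floor(N_min * b^l)` with `b = exp((log(N_max) - log(N_min)) /
#' (L - 1))`, so `N_0 = N_min` and `N_(L-1) = N_max`.  Levels whose dense
#' corner grid fits in the table are indexed directly; finer levels use the
#' spatial hash (xor of coordinates times large primes, modulo the table
#' size).  The full-scale default divides the finest level into 2048 voxels
#' per axis while leaving the encoding output dimension at `L * F`.
#'
#' @param levels number of resolution levels L (default 16).
#' @param table_size hash-table entries per level T (a power of two,
#'   default `2^19`).
#' @param features_per_entry feature dimensions per entry F (default 2).
#' @param n_min,n_max coarsest and finest grid resolution (defaults 16, 2048).
#' @return An object of class `hash_grid_config` with the per-level
#'   `resolutions` and entry `offsets` precomputed.
#' @export
hash_grid_config <- function(levels = 16, table_size = 2^19,
                             features_per_entry = 2, n_min = 16,
                             n_max = 2048) {
  stopifnot(levels >= 1, features_per_entry >= 1, n_min >= 1, n_max >= n_min,
            bitwAnd(table_size, table_size - 1) == 0)
  if (levels == 1) {
    res <- n_min
  } else {
    b <- exp((log(n_max) - log(n_min)) / (levels - 1))
    res <- floor(n_min * b^(0:(levels - 1)) + 1e-9)
  }
  entries <- pmin((res + 1)^3, table_size)
  structure(list(levels = levels, table_size = table_size,
                 features_per_entry = features_per_entry,
                 n_min = n_min, n_max = n_max,
                 resolutions = as.integer(res),
                 offsets = c(0, cumsum(entries))),
            class = "hash_grid_config")
}

#' @export
print.hash_grid_config <- function(x, ...) {
  cat(sprintf(paste0("<hash_grid_config> L=%d T=%d F=%d N_min=%d N_max=%d ",
                     "(%g total entries)\n"),
              x$levels, x$table_size, x$features_per_entry, x$n_min, x$n_max,
              x$offsets[length(x$offsets)]))
  invisible(x)
}

#' Hash-encode normalized positions
#'
#' Trilinearly interpolates the `F`-dimensional features at the 8 surrounding
#' grid corners of every level and concatenates over levels, giving a
#' `levels * features_per_entry`-dimensional positional feature.  Points
#' outside `[0, 1]^3` are clamped.
#'
#' @param x n x 3 matrix (or length-3 vector) of ROI-normalized positions.
#' @param cfg a [hash_grid_config()].
#' @param tables feature table, `features_per_entry` x total-entries matrix
#'   (see [radiance_field()]).
#' @return n x (levels * features_per_entry) feature matrix.
#' @export
hash_encode <- function(x, cfg, tables) {
  stopifnot(inherits(cfg, "hash_grid_config"))
  x <- matrix(as.numeric(x), ncol = 3)
  stopifnot(ncol(tables) == cfg$offsets[length(cfg$offsets)],
            nrow(tables) == cfg$features_per_entry)
  cpp_hash_encode(tables, cfg$resolutions, cfg$offsets, x)
}

#' Frequency encoding of a viewing direction
#'
#' `[d, sin(2^j * pi * d), cos(2^j * pi * d)]` for `j = 0..3` applied
#' componentwise: 3 raw + 24 frequency components = 27 dimensions.
#'
#' @param d unit 3-vector, or n x 3 matrix of unit rows.
#' @return n x 27 matrix (a vector input gives a 1 x 27 matrix).
#' @export
encode_direction <- function(d) {
  d <- matrix(as.numeric(d), ncol = 3)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-9)) stop("zero direction vector", call. = FALSE)
  stopifnot(all(abs(nrm - 1) < 1e-6))
  out <- matrix(0, nrow(d), 27)
  out[, 1:3] <- d
  for (j in 0:3) {
    f <- 2^j * pi
    out[, 3 + 6 * j + 1:3] <- sin(f * d)
    out[, 3 + 6 * j + 4:6] <- cos(f * d)
  }
  out
}

relu_mat <- function(x) {
  x[x < 0] <- 0
  x
}
softplus_vec <- function(x) ifelse(x > 30, x, log1p(exp(x)))
elu_mat <- function(x) ifelse(x > 0, x, expm1(x))
sigmoid_mat <- function(x) 1 / (1 + exp(-x))

#' Initialize a radiance field
#'
#' Allocates the trainable state: fine and coarse hash tables (the coarse
#' stage is a smaller grid with its own density/color head used only to place
#' the fine samples), the density perceptron (one hidden layer; outputs a raw
#' density plus a 15-dimensional geometric feature), the color perceptron
#' (two hidden layers on the 16-dimensional geometric feature -- raw density
#' concatenated with the 15 features -- and the 27-dimensional direction
#' encoding; terminal sigmoid), per-image exposure rates `E_i` (log2 units)
#' and per-image pose offsets (translation + axis-angle rotation).
#'
#' @param aabb the ROI [aabb()] the field is normalized to.
#' @param n_images number of training images (exposure/pose slots).
#' @param fine_cfg,coarse_cfg [hash_grid_config()]s for the two stages.
#' @param hidden_density,hidden_color hidden-layer widths (default 64).
#' @param background background color composited behind residual
#'   transmittance.
#' @param seed seed for weight initialization.
#' @return An object of class `radiance_field`.
#' @export
radiance_field <- function(aabb, n_images,
                           fine_cfg = hash_grid_config(),
                           coarse_cfg = hash_grid_config(levels = 8,
                                                         table_size = 2^14,
                                                         n_max = 512),
                           hidden_density = 64, hidden_color = 64,
                           background = c(0.40, 0.42, 0.45), seed = 1) {
  stopifnot(inherits(aabb, "aabb"), n_images >= 1)
  restore <- local_seed(seed)
  on.exit(restore())
  he <- function(nout, nin) {
    matrix(rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
  }
  tab <- function(cfg) {
    n <- cfg$offsets[length(cfg$offsets)]
    matrix(runif(cfg$features_per_entry * n, -1e-4, 1e-4),
           cfg$features_per_entry, n)
  }
  in_f <- fine_cfg$levels * fine_cfg$features_per_entry
  in_c <- coarse_cfg$levels * coarse_cfg$features_per_entry
  params <- list(
    f_tab = tab(fine_cfg), f_res = fine_cfg$resolutions,
    f_off = fine_cfg$offsets,
    W1 = he(hidden_density, in_f), b1 = numeric(hidden_density),
    W2 = he(16, hidden_density), b2 = numeric(16),
    V1 = he(hidden_color, 16 + 27), c1 = numeric(hidden_color),
    V2 = he(hidden_color, hidden_color), c2 = numeric(hidden_color),
    V3 = he(3, hidden_color), c3 = numeric(3),
    c_tab = tab(coarse_cfg), c_res = coarse_cfg$resolutions,
    c_off = coarse_cfg$offsets,
    U1 = he(hidden_density, in_c), u1 = numeric(hidden_density),
    U2 = he(4, hidden_density), u2 = numeric(4),
    E = numeric(n_images),
    dT = matrix(0, 3, n_images), dTh = matrix(0, 3, n_images))
  structure(list(params = params, aabb = aabb, fine_cfg = fine_cfg,
                 coarse_cfg = coarse_cfg, background = background,
                 n_images = n_images, n_c = 64, n_f = 128, roi_frac = 0.75,
                 t_b = 2 * aabb_diagonal(aabb),
                 lambda_E = 1e-4, lambda_p = 1e-4,
                 log = NULL),
            class = "radiance_field")
}

#' @export
print.radiance_field <- function(x, ...) {
  cat(sprintf(paste0("<radiance_field> fine L=%d N_max=%d, coarse L=%d ",
                     "N_max=%d, %d images, %s\n"),
              x$fine_cfg$levels, x$fine_cfg$n_max, x$coarse_cfg$levels,
              x$coarse_cfg$n_max, x$n_images,
              if (is.null(x$log)) "untrained" else "trained"))
  invisible(x)
}

#' Number of trainable parameters of a radiance field
#' @param field a [radiance_field()].
#' @return named numeric vector of per-block parameter counts.
#' @export
field_param_counts <- function(field) {
  p <- field$params
  blocks <- c("f_tab", "W1", "b1", "W2", "b2", "V1", "c1", "V2", "c2", "V3",
              "c3", "c_tab", "U1", "u1", "U2", "u2", "E", "dT", "dTh")
  vapply(blocks, function(b) length(p[[b]]), numeric(1))
}

# config list handed to the C++ core
field_cfg_list <- function(field) {
  list(aabb_min = field$aabb$min, aabb_max = field$aabb$max,
       bg = field$background, n_c = as.integer(field$n_c),
       n_f = as.integer(field$n_f), roi_frac = field$roi_frac,
       t_b = field$t_b, lambda_E = field$lambda_E, lambda_p = field$lambda_p)
}

#' Density-network forward pass
#'
#' One hidden ReLU layer on the hash features; the first output passes
#' through a softplus to give the non-negative volume density, the remaining
#' 15 (ELU-activated) are the geometric feature vector.
#'
#' @param field a [radiance_field()].
#' @param x_enc n x (L*F) matrix of hash features (from [hash_encode()]).
#' @return list with `sigma` (length n, >= 0), `geo` (n x 15 features) and
#'   `geo16` (n x 16: raw density value plus the 15 features), the color-net
#'   input.
#' @export
density_net <- function(field, x_enc) {
  p <- field$params
  x_enc <- matrix(as.numeric(x_enc), ncol = ncol(p$W1))
  h <- relu_mat(tcrossprod(x_enc, p$W1) + rep(p$b1, each = nrow(x_enc)))
  y <- tcrossprod(h, p$W2) + rep(p$b2, each = nrow(x_enc))
  list(sigma = softplus_vec(y[, 1]),
       geo = elu_mat(y[, -1, drop = FALSE]),
       geo16 = cbind(y[, 1], elu_mat(y[, -1, drop = FALSE])))
}

#' Color-network forward pass
#'
#' Two hidden ReLU layers on the concatenated 16-dimensional geometric
#' feature and 27-dimensional direction encoding, terminal sigmoid.
#'
#' @param field a [radiance_field()].
#' @param geo16 n x 16 matrix (from [density_net()]).
#' @param d_enc n x 27 matrix (from [encode_direction()]), or one row
#'   recycled.
#' @return n x 3 rgb matrix with entries in `(0, 1)`.
#' @export
color_net <- function(field, geo16, d_enc) {
  p <- field$params
  geo16 <- matrix(as.numeric(geo16), ncol = 16)
  d_enc <- matrix(as.numeric(d_enc), ncol = 27)
  if (nrow(d_enc) == 1 && nrow(geo16) > 1) {
    d_enc <- d_enc[rep(1, nrow(geo16)), , drop = FALSE]
  }
  z <- cbind(geo16, d_enc)
  h1 <- relu_mat(tcrossprod(z, p$V1) + rep(p$c1, each = nrow(z)))
  h2 <- relu_mat(tcrossprod(h1, p$V2) + rep(p$c2, each = nrow(z)))
  sigmoid_mat(tcrossprod(h2, p$V3) + rep(p$c3, each = nrow(z)))
}

#' Query the trained density field at world positions
#' @param field a [radiance_field()].
#' @param points n x 3 matrix of world coordinates, meters.
#' @return length-n vector of densities (1/m).
#' @export
query_density <- function(field, points) {
  points <- matrix(as.numeric(points), ncol = 3)
  as.numeric(cpp_query_density(field$params, field_cfg_list(field), points))
}

#' @rdname query_density
#' @param dirs n x 3 matrix of unit viewing directions (default: straight
#'   down).
#' @return `query_color`: n x 3 rgb matrix.
#' @export
query_color <- function(field, points, dirs = NULL) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (is.null(dirs)) {
    dirs <- matrix(rep(c(0, 0, -1), each = nrow(points)), ncol = 3)
  }
  cpp_query_color(field$params, field_cfg_list(field), points, dirs)
}

#' @rdname radiance_field
#' @param x a `radiance_field`.
#' @param ... unused.
#' @export
glance.radiance_field <- function(x, ...) {
  tibble::tibble(
    n_params = sum(field_param_counts(x)),
    n_images = x$n_images,
    trained = !is.null(x$log),
    final_loss = if (is.null(x$log)) NA_real_ else x$log$loss[nrow(x$log)])
}
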