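# Deterministic synthetic plant scenes: an analytic piecewise-constant
# density/color field (trunk cylinder + ellipsoidal leaves), two-ring orbital
# camera trajectories, a quadrature reference renderer, and controlled
# exposure/blur degradation.  Every downstream stage of the pipeline can be
# exercised against these scenes with exact ground truth.

#' Analytic plant-like density/color field
#'
#' Builds a piecewise-constant volumetric field consisting of a vertical trunk
#' cylinder plus `n_leaves` randomly placed and oriented ellipsoidal "leaves"
#' with distinct green tones, topped by a crown ellipsoid whose apex sits
#' exactly at `bound_height`.  A deterministic sinusoidal color modulation
#' adds leaf-scale texture.  Density is identically zero outside a declared
#' bounding cylinder.  All randomness is driven by `seed`.
#'
#' @param seed integer seed.
#' @param n_leaves number of leaf ellipsoids (>= 0) in addition to the crown.
#' @param bound_height exact z-extent of the solid region, meters
#'   (default 0.8).
#' @param trunk_height,trunk_radius trunk cylinder size, meters.
#' @param solid_density density inside leaves, 1/m (trunk is 1.2x denser).
#' @param clutter if `TRUE`, adds a few faint blobs outside the plant region
#'   (and enlarges the declared bounding cylinder) to emulate background
#'   structure.
#' @return An object of class `plant_field` with elements `density_fn(points)`
#'   (n x 3 matrix -> densities, 1/m), `color_fn(points, dirs = NULL)`
#'   (-> n x 3 rgb in `[0,1]`), `bound_height`, and the solid parameters.
#' @export
make_plant_field <- function(seed = 1, n_leaves = 12, bound_height = 0.8,
                             trunk_height = 0.55, trunk_radius = 0.025,
                             solid_density = 100, clutter = FALSE) {
  stopifnot(n_leaves >= 0, bound_height > 0.2, trunk_height < bound_height)
  restore <- local_seed(seed)
  on.exit(restore())

  solid <- function(type, center, size, rot = diag(3), col, dens) {
    c(type, center, size, as.numeric(t(rot)), col, dens)
  }
  rows <- list(solid(0, c(0, 0, 0), c(trunk_radius, 0, trunk_height),
                     col = c(0.30, 0.20, 0.10), dens = 1.2 * solid_density))
  # crown: apex exactly at bound_height
  # solid colors stay below half scale even after texture modulation, so a
  # one-stop exposure push (x2) cannot saturate unblurred pixels
  crown_c <- 0.06
  rows[[2]] <- solid(1, c(0, 0, bound_height - crown_c),
                     c(0.10, 0.10, crown_c),
                     col = c(0.10, 0.35, 0.12), dens = solid_density)
  if (n_leaves > 0) {
    golden <- pi * (3 - sqrt(5))
    for (i in seq_len(n_leaves)) {
      ang <- i * golden + runif(1, -0.2, 0.2)
      rad <- runif(1, 0.06, 0.21)
      zc <- runif(1, 0.28, 0.70)
      ax <- c(0.10, 0.065, 0.022) * runif(3, 0.8, 1.2)
      rot <- rotation_exp(rnorm(3) * runif(1, 0, 1.2))
      col <- c(runif(1, 0.05, 0.13), runif(1, 0.26, 0.37),
               runif(1, 0.05, 0.13))
      # exact z half-extent of the rotated ellipsoid
      hz <- sqrt(sum((ax * rot[3, ])^2))
      zc <- min(zc, bound_height - 0.02 - hz)
      zc <- max(zc, hz + 0.02)
      rows[[length(rows) + 1]] <-
        solid(1, c(rad * cos(ang), rad * sin(ang), zc), ax, rot, col,
              solid_density)
    }
  }
  cyl <- c(0.45, 0, bound_height + 0.1)
  if (clutter) {
    for (i in 1:3) {
      ang <- runif(1, 0, 2 * pi)
      rows[[length(rows) + 1]] <-
        solid(1, c(1.3 * cos(ang), 1.3 * sin(ang), runif(1, 0.2, 0.7)),
              c(0.12, 0.12, 0.12), diag(3),
              col = c(0.35, 0.35, 0.30), dens = 6)
    }
    cyl <- c(2.0, 0, bound_height + 0.1)
  }
  solids <- do.call(rbind, rows)
  tex <- c(0.35, 43)

  density_fn <- function(points) {
    points <- matrix(as.numeric(points), ncol = 3)
    as.numeric(cpp_field_density(solids, cyl, points))
  }
  color_fn <- function(points, dirs = NULL) {
    points <- matrix(as.numeric(points), ncol = 3)
    cpp_field_color(solids, cyl, tex, points)
  }
  structure(list(density_fn = density_fn, color_fn = color_fn,
                 bound_height = bound_height, solids = solids,
                 cylinder = cyl, texture = tex, seed = seed,
                 n_leaves = n_leaves),
            class = "plant_field")
}

#' @export
print.plant_field <- function(x, ...) {
  cat(sprintf("<plant_field> %d solids, bound_height = %g m (seed %d)\n",
              nrow(x$solids), x$bound_height, x$seed))
  invisible(x)
}

#' Two-ring orbital camera trajectory
#'
#' Places `n_per_ring` cameras on each of two horizontal circles of radius
#' `prior$r_real` at heights `z_lower` and `z_upper`; every optical axis
#' passes through the vertical axis x = y = 0 (aimed at `(0, 0, target_z)`).
#' The upper ring is staggered by half an angular step.
#'
#' @param prior a [trajectory_prior()].
#' @param n_per_ring cameras per ring (>= 3).
#' @param z_lower,z_upper ring heights, meters; defaults put the lower camera
#'   `h1` above the ground (ground at z = 0) and the upper one 0.4 m higher.
#' @param target_z height of the aim point on the axis.
#' @return list of `2 * n_per_ring` [camera_pose()] ("c2w"), lower ring first,
#'   with a `view` attribute of ring labels (`"lower"`/`"upper"`).
#' @export
make_trajectory <- function(prior, n_per_ring, z_lower = prior$h1,
                            z_upper = z_lower + 0.4,
                            target_z = (z_lower + z_upper) / 2) {
  stopifnot(inherits(prior, "trajectory_prior"), n_per_ring >= 3)
  poses <- list()
  view <- character()
  for (ring in c("lower", "upper")) {
    z <- if (ring == "lower") z_lower else z_upper
    offs <- if (ring == "lower") 0 else pi / n_per_ring
    for (j in seq_len(n_per_ring)) {
      ang <- 2 * pi * (j - 1) / n_per_ring + offs
      ctr <- c(prior$r_real * cos(ang), prior$r_real * sin(ang), z)
      poses[[length(poses) + 1]] <- look_at_pose(ctr, c(0, 0, target_z))
      view <- c(view, ring)
    }
  }
  attr(poses, "view") <- view
  poses
}

#' Quadrature reference rendering of an analytic field
#'
#' Renders one view by fixed-step midpoint quadrature of the volume-rendering
#' integral over `[0, t_far]`, composited onto a constant background.  This is
#' the ground-truth oracle: it never touches the trained model.
#'
#' @param field a [make_plant_field()] field.
#' @param pose a [camera_pose()].
#' @param intr a [camera_intrinsics()].
#' @param h,w output size in pixels (defaults from `intr`).
#' @param n_quad number of quadrature steps (>= 8).
#' @param background rgb background color.
#' @param t_far integration range, meters (default: safely past the scene).
#' @return H x W x 3 array in `[0, 1]`.
#' @export
render_ground_truth <- function(field, pose, intr, h = intr$height,
                                w = intr$width, n_quad = 128,
                                background = c(0.40, 0.42, 0.45),
                                t_far = NULL) {
  stopifnot(inherits(field, "plant_field"), inherits(pose, "camera_pose"),
            n_quad >= 8)
  p <- pose_convert(pose, "c2w")
  if (abs(det(p$rotation)) < 1e-6) stop("degenerate pose", call. = FALSE)
  if (is.null(t_far)) {
    t_far <- sqrt(sum(p$translation^2)) +
      sqrt(field$cylinder[1]^2 + max(abs(field$cylinder[2:3]))^2) + 0.2
  }
  cpp_render_gt(field$solids, field$cylinder, field$texture, background,
                p$rotation, p$translation, intr$fx, intr$fy, intr$cx, intr$cy,
                as.integer(h), as.integer(w), as.integer(n_quad), t_far)
}

#' Synthetic orbital capture
#'
#' Renders ground-truth frames for a full two-ring trajectory around an
#' analytic plant field, bundling frames, true poses, intrinsics, trajectory
#' prior and degradation bookkeeping into one object consumed by the rest of
#' the pipeline exactly like a real capture.
#'
#' @inheritParams render_ground_truth
#' @param prior a [trajectory_prior()].
#' @param n_per_ring cameras per ring.
#' @param intr a [camera_intrinsics()]; default is a 64 x 64 pinhole.
#' @param n_quad quadrature steps per ray.
#' @return An object of class `synthetic_capture`: `frames` (list of arrays),
#'   `views` (ring label per frame), `true_poses`, `intrinsics`, `prior`,
#'   `background`, `field`, `true_exposures` (log2 units, all 0), and
#'   `blurred_ids` (empty).
#' @export
simulate_capture <- function(field, prior = trajectory_prior(0.75, 0.35, 0.25),
                             n_per_ring = 20,
                             intr = camera_intrinsics(48, 48, 32, 32, 64, 64),
                             n_quad = 96, background = c(0.40, 0.42, 0.45)) {
  poses <- make_trajectory(prior, n_per_ring,
                           target_z = field$bound_height / 2)
  frames <- lapply(poses, function(p) {
    render_ground_truth(field, p, intr, n_quad = n_quad,
                        background = background)
  })
  structure(list(frames = frames, views = attr(poses, "view"),
                 true_poses = poses, intrinsics = intr, prior = prior,
                 background = background, field = field,
                 true_exposures = rep(0, length(frames)),
                 blurred_ids = integer(0)),
            class = "synthetic_capture")
}

#' @export
print.synthetic_capture <- function(x, ...) {
  cat(sprintf("<synthetic_capture> %d frames (%dx%d), r_real=%g m\n",
              length(x$frames), x$intrinsics$height, x$intrinsics$width,
              x$prior$r_real))
  invisible(x)
}

#' Degrade a synthetic capture with exposure scaling and blur
#'
#' Frame `i` is multiplied by `2^exposure_exps[i]` and clipped to `[0, 1]`
#' (the inverse of the exposure model learned during reconstruction); frames
#' listed in `blur_ids` are then convolved with a Gaussian kernel of standard
#' deviation `blur_sigma` pixels (replicate borders); optionally the result is
#' quantized to 8 bits.  The operation is deterministic.
#'
#' @param capture a [simulate_capture()] object.
#' @param blur_ids integer indices of frames to blur.
#' @param exposure_exps numeric vector of per-frame log2 exposure exponents
#'   (length 1 or `length(capture$frames)`).
#' @param blur_sigma Gaussian standard deviation, pixels.
#' @param seed integer (kept for interface symmetry; the degradation itself
#'   is deterministic).
#' @param quantize if `TRUE`, round pixel values to 8-bit levels.
#' @return the degraded `synthetic_capture` with `true_exposures` and
#'   `blurred_ids` recorded.
#' @export
degrade <- function(capture, blur_ids = integer(0), exposure_exps = 0,
                    blur_sigma = 2, seed = 1, quantize = FALSE) {
  stopifnot(inherits(capture, "synthetic_capture"),
            all(is.finite(exposure_exps)))
  n <- length(capture$frames)
  exposure_exps <- rep_len(exposure_exps, n)
  blur_ids <- as.integer(blur_ids)
  stopifnot(all(blur_ids >= 1), all(blur_ids <= n))
  out <- capture
  for (i in seq_len(n)) {
    f <- capture$frames[[i]] * 2^exposure_exps[i]
    f[f > 1] <- 1
    f[f < 0] <- 0
    if (i %in% blur_ids) {
      f <- cpp_gaussian_blur(f, blur_sigma)
    }
    if (quantize) {
      f <- round(f * 255) / 255
    }
    out$frames[[i]] <- f
  }
  out$true_exposures <- exposure_exps
  out$blurred_ids <- sort(unique(blur_ids))
  out
}

#' Write a synthetic capture to disk in standard formats
#'
#' Writes PNG frames, a COLMAP-style text camera model (`cameras.txt`,
#' `images.txt`) and a YAML trajectory-prior file, so synthetic captures are
#' consumed through the same readers as real data.
#'
#' @param capture a [simulate_capture()] object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_capture <- function(capture, dir) {
  stopifnot(inherits(capture, "synthetic_capture"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  within_view <- stats::ave(seq_along(capture$views), capture$views,
                            FUN = seq_along)
  names <- sprintf("%s_%04d.png", capture$views, within_view)
  for (i in seq_along(capture$frames)) {
    png::writePNG(capture$frames[[i]], file.path(dir, names[i]))
  }
  write_sfm_model(file.path(dir, "sparse"), capture$intrinsics,
                  capture$true_poses, names)
  yaml::write_yaml(list(r_real = capture$prior$r_real,
                        h1 = capture$prior$h1, h2 = capture$prior$h2),
                   file.path(dir, "prior.yaml"))
  invisible(dir)
}
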