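# Global similarity calibration of structure-from-motion camera poses using
# the known circular imaging trajectory as a metric prior.
#
# SfM recovers poses in an arbitrary ("virtual") frame: orientation, scale and
# origin are free.  The capture rig constrains all three: the two camera rings
# are horizontal circles of known radius, so the fitted trajectory plane fixes
# the world z-axis, the fitted circle radius fixes the metric scale, and the
# circle centre plus the mid-height of the two rings fix the origin.  The
# azimuth about z is the one remaining gauge freedom and is left unfixed (the
# plant is axially centred, so it does not affect measurements).

#' Trajectory prior of the orbital capture rig
#'
#' @param r_real radius of the camera rings, meters.
#' @param h1 height of the lower camera above the ground, meters.
#' @param h2 distance from the upper camera to the top of the bracket, meters.
#' @return An object of class `trajectory_prior`.
#' @export
trajectory_prior <- function(r_real, h1, h2) {
  stopifnot(r_real > 0, h1 > 0, h2 > 0)
  structure(list(r_real = r_real, h1 = h1, h2 = h2),
            class = "trajectory_prior")
}

#' @export
print.trajectory_prior <- function(x, ...) {
  cat(sprintf("<trajectory_prior> r_real=%g m, h1=%g m, h2=%g m\n",
              x$r_real, x$h1, x$h2))
  invisible(x)
}

#' Total-least-squares plane fit
#'
#' Fits a plane to 3D points by minimizing orthogonal distances (smallest
#' eigenvector of the centered covariance).  The normal sign is chosen with a
#' non-negative z-component.
#'
#' @param points n x 3 matrix of points, n >= 3, not collinear.
#' @return list with `normal` (unit 3-vector) and `offset` such that points on
#'   the plane satisfy `sum(normal * x) == offset`.
#' @export
fit_plane <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  ctr <- colMeans(points)
  X <- sweep(points, 2, ctr)
  e <- eigen(crossprod(X), symmetric = TRUE)
  # degenerate (collinear) point sets have two near-zero eigenvalues
  if (e$values[2] <= max(e$values[1], 1) * 1e-12) {
    stop("points are collinear or coincident; plane fit is degenerate",
         call. = FALSE)
  }
  n <- e$vectors[, 3]
  if (n[3] < 0 || (n[3] == 0 && (n[1] < 0 || (n[1] == 0 && n[2] < 0)))) {
    n <- -n
  }
  list(normal = n, offset = sum(n * ctr))
}

#' Rotation aligning a unit normal with the world z-axis
#'
#' Rodrigues rotation about `axis = n x (0,0,1)` by `angle = acos(n . z)`, so
#' that `rotation_from_normal(n) %*% n == c(0, 0, 1)`.  The antiparallel case
#' (`n` close to `(0,0,-1)`, where the Rodrigues axis is undefined) rotates by
#' pi about the x-axis.
#'
#' @param n unit 3-vector.
#' @return 3x3 rotation matrix.
#' @export
rotation_from_normal <- function(n) {
  stopifnot(length(n) == 3)
  nn <- sqrt(sum(n^2))
  if (abs(nn - 1) > 1e-6) stop("`n` must be a unit vector", call. = FALSE)
  n <- n / nn
  cz <- n[3]
  axis <- c(n[2], -n[1], 0)           # n x (0,0,1)
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    if (cz > 0) return(diag(3))
    return(rotation_exp(c(pi, 0, 0))) # antiparallel: any axis in xy works
  }
  rotation_exp(axis / s * acos(max(-1, min(1, cz))))
}

#' Algebraic least-squares circle fit (Kasa)
#'
#' Fits `(x - x_c)^2 + (y - y_c)^2 = r^2` by linear least squares.
#'
#' @param points n x 2 matrix, n >= 3, not collinear.
#' @return list with `center` (2-vector) and `radius`.
#' @export
fit_circle_2d <- function(points) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2)
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  x <- points[, 1]; y <- points[, 2]
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b, tol = 1e-12),
                  error = function(e) stop("collinear points; circle fit is degenerate",
                                           call. = FALSE))
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0) {
    stop("degenerate circle fit (non-positive radius)", call. = FALSE)
  }
  list(center = c(sol[1], sol[2]), radius = sqrt(r2))
}

#' Split camera positions into the upper and lower rings
#'
#' Assumes the positions are already orientation-calibrated (trajectory plane
#' perpendicular to z) and splits at the midpoint of the z range.
#'
#' @param positions n x 3 matrix of camera centres.
#' @return list with integer index vectors `upper` and `lower`, and the mean
#'   ring heights `z_up` and `z_low`.
#' @export
split_rings <- function(positions) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3)
  z <- positions[, 3]
  zr <- range(z)
  if (diff(zr) < 1e-9 * max(1, abs(zr[2]))) {
    stop("all camera heights are equal: need two rings to split", call. = FALSE)
  }
  mid <- mean(zr)
  upper <- which(z > mid)
  lower <- which(z <= mid)
  if (length(upper) == 0 || length(lower) == 0) {
    stop("ring split failed: one group is empty", call. = FALSE)
  }
  list(upper = upper, lower = lower,
       z_up = mean(z[upper]), z_low = mean(z[lower]))
}

#' Calibrate SfM poses to metric world coordinates
#'
#' Applies the trajectory-prior similarity calibration: (1) fit a plane to the
#' camera centres and rotate its normal onto z; (2) fit a circle to the
#' rotated centres in xy and scale by `k = r_real / r_virtual`; (3) recentre
#' so the circle centre is on the z-axis and the mid-height of the two rings
#' is z = 0.  One global rotation, scale and translation are applied to every
#' pose.
#'
#' @param poses list of [camera_pose()] (any convention), at least 6, spanning
#'   two rings.
#' @param prior a [trajectory_prior()].
#' @return list with `poses` (calibrated, same conventions as input) and
#'   `calibration`, an object of class `similarity_calibration` with fields
#'   `R_vtr`, `k`, `t_s`, `z_up`, `z_low`, `r_virtual`.
#' @export
calibrate_poses <- function(poses, prior) {
  stopifnot(is.list(poses), length(poses) >= 6,
            inherits(prior, "trajectory_prior"))
  centers <- t(vapply(poses, pose_center, numeric(3)))

  pl <- fit_plane(centers)
  R_vtr <- rotation_from_normal(pl$normal)
  c1 <- centers %*% t(R_vtr)

  circ <- fit_circle_2d(c1[, 1:2])
  k <- prior$r_real / circ$radius
  c2 <- k * c1

  rings <- split_rings(c2)
  z_c <- (rings$z_up + rings$z_low) / 2
  t_s <- c(k * circ$center[1], k * circ$center[2], z_c)

  cal <- structure(list(R_vtr = R_vtr, k = k, t_s = t_s,
                        z_up = rings$z_up - z_c, z_low = rings$z_low - z_c,
                        r_virtual = circ$radius),
                   class = "similarity_calibration")

  new_poses <- lapply(poses, function(p) {
    if (p$convention == "c2w") {
      camera_pose(R_vtr %*% p$rotation,
                  k * drop(R_vtr %*% p$translation) - t_s, "c2w")
    } else {
      Rn <- p$rotation %*% t(R_vtr)
      camera_pose(Rn, k * p$translation + drop(Rn %*% t_s), "w2c")
    }
  })
  list(poses = new_poses, calibration = cal)
}

#' @export
print.similarity_calibration <- function(x, ...) {
  cat(sprintf(paste0("<similarity_calibration> k=%.6g r_virtual=%.6g\n",
                     "  t_s = [%s]   z_up=%.4g z_low=%.4g\n"),
              x$k, x$r_virtual, paste(signif(x$t_s, 6), collapse = ", "),
              x$z_up, x$z_low))
  invisible(x)
}

#' @rdname calibrate_poses
#' @param x a `similarity_calibration`.
#' @param ... unused.
#' @export
tidy.similarity_calibration <- function(x, ...) {
  tibble::tibble(
    term = c("k", "r_virtual", "t_s_x", "t_s_y", "t_s_z", "z_up", "z_low"),
    estimate = c(x$k, x$r_virtual, x$t_s, x$z_up, x$z_low))
}

#' Region-of-interest box from the calibrated trajectory
#'
#' The plant stands on the ground between the rings' footprint: the ROI box
#' spans `[-r_real, r_real]` in x and y, and `[z_low - h1, z_up + h2]` in z,
#' where `z_low`/`z_up` are the calibrated ring heights and `h1`/`h2` the rig
#' height offsets of the prior.
#'
#' @param cal a `similarity_calibration` from [calibrate_poses()].
#' @param prior a [trajectory_prior()].
#' @return an [aabb()].
#' @export
compute_roi_aabb <- function(cal, prior) {
  stopifnot(inherits(cal, "similarity_calibration"),
            inherits(prior, "trajectory_prior"))
  zmin <- cal$z_low - prior$h1
  zmax <- cal$z_up + prior$h2
  if (zmin >= zmax) {
    stop("inconsistent prior: z_low - h1 >= z_up + h2", call. = FALSE)
  }
  aabb(c(-prior$r_real, -prior$r_real, zmin),
       c(prior$r_real, prior$r_real, zmax))
}
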