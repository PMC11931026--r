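# Rotations, camera poses, intrinsics and axis-aligned boxes.
#
# World convention throughout the package: z-up, metric meters, origin at the
# plant centre after trajectory calibration.  Camera convention: x right,
# y down, z forward (optical axis), as used by COLMAP-style models.

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @param v numeric 3-vector.
#' @return 3x3 matrix `[v]_x` with `skew3(v) %*% w == cross(v, w)`.
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Rodrigues axis-angle exponential map
#'
#' Converts an axis-angle vector to a rotation matrix,
#' `R = exp([theta]_x)`.  The inverse is [rotation_log()].
#'
#' @param theta numeric 3-vector; direction is the rotation axis, norm the
#'   rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
#' @examples
#' rotation_exp(c(0, 0, pi / 2))  # quarter turn about z
rotation_exp <- function(theta) {
  stopifnot(is.numeric(theta), length(theta) == 3, all(is.finite(theta)))
  ang <- sqrt(sum(theta^2))
  if (ang < 1e-12) {
    K <- skew3(theta)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  k <- theta / ang
  K <- skew3(k)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Axis-angle logarithm of a rotation matrix
#'
#' @param R 3x3 rotation matrix with rotation angle strictly below pi.
#' @return numeric 3-vector `theta` with `rotation_exp(theta) == R`.
#' @export
rotation_log <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3, 3)))
  cos_ang <- (sum(diag(R)) - 1) / 2
  cos_ang <- max(-1, min(1, cos_ang))
  ang <- acos(cos_ang)
  if (ang < 1e-12) {
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(ang))
  ang * axis
}

is_rotation <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    max(abs(crossprod(R) - diag(3))) < tol && det(R) > 0
}

#' Camera pose
#'
#' A rigid camera pose storing a rotation and a translation together with the
#' convention they are expressed in: `"c2w"` (camera-to-world: `rotation` maps
#' camera-frame directions to world directions and `translation` is the camera
#' centre) or `"w2c"` (world-to-camera, the structure-from-motion convention:
#' a world point `X` maps to `R %*% X + t` in the camera frame).
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation numeric 3-vector (meters).
#' @param convention `"c2w"` or `"w2c"`.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation, translation, convention = c("c2w", "w2c")) {
  convention <- match.arg(convention)
  if (!is_rotation(rotation)) {
    stop("`rotation` must be orthonormal with determinant +1", call. = FALSE)
  }
  stopifnot(is.numeric(translation), length(translation) == 3,
            all(is.finite(translation)))
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 convention = convention),
            class = "camera_pose")
}

#' @export
print.camera_pose <- function(x, ...) {
  cat("<camera_pose> (", x$convention, ") centre = [",
      paste(signif(pose_center(x), 5), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

#' Camera centre of a pose in world coordinates
#' @param pose a [camera_pose()].
#' @return numeric 3-vector.
#' @export
pose_center <- function(pose) {
  if (pose$convention == "c2w") pose$translation
  else -drop(crossprod(pose$rotation, pose$translation))
}

#' Convert a pose between conventions
#' @param pose a [camera_pose()].
#' @param convention target convention, `"c2w"` or `"w2c"`.
#' @return a [camera_pose()] in the requested convention.
#' @export
pose_convert <- function(pose, convention = c("c2w", "w2c")) {
  convention <- match.arg(convention)
  if (pose$convention == convention) return(pose)
  # both directions are the same inversion
  camera_pose(t(pose$rotation),
              -drop(crossprod(pose$rotation, pose$translation)),
              convention)
}

#' Look-at camera pose
#'
#' Builds a camera-to-world pose for a camera at `center` whose optical axis
#' points at `target`, with image y pointing downwards in world z (z-up world).
#'
#' @param center,target numeric 3-vectors, meters.
#' @param up world up direction, default `c(0, 0, 1)`.
#' @return a [camera_pose()] with convention `"c2w"`.
#' @export
look_at_pose <- function(center, target, up = c(0, 0, 1)) {
  fwd <- target - center
  nf <- sqrt(sum(fwd^2))
  if (nf < 1e-12) stop("`center` and `target` coincide", call. = FALSE)
  fwd <- fwd / nf
  right <- c(fwd[2] * up[3] - fwd[3] * up[2],
             fwd[3] * up[1] - fwd[1] * up[3],
             fwd[1] * up[2] - fwd[2] * up[1])
  nr <- sqrt(sum(right^2))
  if (nr < 1e-12) stop("view direction parallel to `up`", call. = FALSE)
  right <- right / nr
  down <- c(fwd[2] * right[3] - fwd[3] * right[2],
            fwd[3] * right[1] - fwd[1] * right[3],
            fwd[1] * right[2] - fwd[2] * right[1])
  camera_pose(unname(cbind(right, down, fwd)), center, "c2w")
}

#' Pinhole camera intrinsics with radial/tangential distortion
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param width,height image size in pixels.
#' @param skew axis skew in pixels (default 0).
#' @param k1,k2,k3 radial distortion coefficients.
#' @param p1,p2 tangential distortion coefficients.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, width, height, skew = 0,
                              k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  stopifnot(fx > 0, fy > 0, width >= 1, height >= 1)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 width = as.integer(width), height = as.integer(height),
                 skew = skew, k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> %dx%d fx=%.4g fy=%.4g cx=%.4g cy=%.4g\n",
              x$width, x$height, x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

has_distortion <- function(intr) {
  any(abs(c(intr$k1, intr$k2, intr$k3, intr$p1, intr$p2)) > 0)
}

#' Axis-aligned bounding box
#'
#' The region of interest containing the target plant is represented as an
#' axis-aligned box (AABB) given by its minimum and maximum corners.
#'
#' @param min_corner,max_corner numeric 3-vectors, meters, with
#'   `min_corner < max_corner` componentwise.
#' @return An object of class `aabb`.
#' @export
aabb <- function(min_corner, max_corner) {
  stopifnot(length(min_corner) == 3, length(max_corner) == 3,
            all(is.finite(min_corner)), all(is.finite(max_corner)))
  if (!all(min_corner < max_corner)) {
    stop("`min_corner` must be strictly below `max_corner` componentwise",
         call. = FALSE)
  }
  structure(list(min = as.numeric(min_corner), max = as.numeric(max_corner)),
            class = "aabb")
}

#' @export
print.aabb <- function(x, ...) {
  cat("<aabb> min = [", paste(signif(x$min, 5), collapse = ", "),
      "], max = [", paste(signif(x$max, 5), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

aabb_diagonal <- function(box) sqrt(sum((box$max - box$min)^2))

#' Camera rays through pixel centres
#'
#' Generates world-space rays for the given pixel coordinates (1-based row and
#' column of the pixel; the ray passes through the pixel centre).  Directions
#' are unit length.
#'
#' @param pose a [camera_pose()].
#' @param intr a [camera_intrinsics()] (assumed undistorted / ideal pinhole).
#' @param rows,cols integer vectors of equal length, 1-based pixel indices.
#' @return list with `origins` (n x 3) and `directions` (n x 3) matrices.
#' @export
pixel_rays <- function(pose, intr, rows, cols) {
  stopifnot(length(rows) == length(cols))
  p <- pose_convert(pose, "c2w")
  # pixel centre (col - 0.5, row - 0.5) in a coordinate system where the
  # upper-left image corner is (0, 0)
  xs <- (cols - 0.5 - intr$cx) / intr$fx
  ys <- (rows - 0.5 - intr$cy) / intr$fy
  d_cam <- cbind(xs, ys, 1)
  d_cam <- d_cam / sqrt(rowSums(d_cam^2))
  d_world <- d_cam %*% t(p$rotation)
  list(origins = matrix(p$translation, nrow = length(rows), ncol = 3,
                        byrow = TRUE),
       directions = d_world)
}
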