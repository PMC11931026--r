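# Format adapters: COLMAP-style text camera models, PNG frames, YAML priors
# and configs, and undistortion at ingest.

rotation_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q / sqrt(sum(q^2))
}

quat_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Write a COLMAP-style text camera model
#'
#' Emits `cameras.txt` (one OPENCV or PINHOLE camera) and `images.txt`
#' (world-to-camera quaternion + translation per image).
#'
#' @param dir model directory (created if missing).
#' @param intr a [camera_intrinsics()].
#' @param poses list of [camera_pose()]s.
#' @param image_names character vector of image file names.
#' @return `dir`, invisibly.
#' @export
write_sfm_model <- function(dir, intr, poses, image_names) {
  stopifnot(length(poses) == length(image_names))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (has_distortion(intr)) {
    cam <- sprintf("1 OPENCV %d %d %.10g %.10g %.10g %.10g %.10g %.10g %.10g %.10g",
                   intr$width, intr$height, intr$fx, intr$fy, intr$cx,
                   intr$cy, intr$k1, intr$k2, intr$p1, intr$p2)
  } else {
    cam <- sprintf("1 PINHOLE %d %d %.10g %.10g %.10g %.10g",
                   intr$width, intr$height, intr$fx, intr$fy, intr$cx,
                   intr$cy)
  }
  writeLines(c("# Camera list with one line of data per camera:",
               "#   CAMERA_ID, MODEL, WIDTH, HEIGHT, PARAMS[]", cam),
             file.path(dir, "cameras.txt"))
  lines <- c("# Image list with two lines of data per image:",
             "#   IMAGE_ID, QW, QX, QY, QZ, TX, TY, TZ, CAMERA_ID, NAME",
             "#   POINTS2D[] as (X, Y, POINT3D_ID)")
  for (i in seq_along(poses)) {
    p <- pose_convert(poses[[i]], "w2c")
    q <- rotation_to_quat(p$rotation)
    lines <- c(lines,
               sprintf("%d %.10g %.10g %.10g %.10g %.10g %.10g %.10g 1 %s",
                       i, q[1], q[2], q[3], q[4], p$translation[1],
                       p$translation[2], p$translation[3], image_names[i]),
               "")
  }
  writeLines(lines, file.path(dir, "images.txt"))
  invisible(dir)
}

#' Read a COLMAP-style text camera model
#'
#' Parses `cameras.txt` (PINHOLE or OPENCV camera models) and `images.txt`
#' into intrinsics and world-to-camera poses.
#'
#' @param dir model directory containing `cameras.txt` and `images.txt`.
#' @return list with `intrinsics`, `poses` (list of "w2c" [camera_pose()]s,
#'   ordered by image id), and `image_names`.
#' @export
read_sfm_model <- function(dir) {
  cam_path <- file.path(dir, "cameras.txt")
  img_path <- file.path(dir, "images.txt")
  if (!file.exists(cam_path)) stop("missing cameras.txt in ", dir, call. = FALSE)
  if (!file.exists(img_path)) stop("missing images.txt in ", dir, call. = FALSE)
  cl <- grep("^\\s*(#|$)", readLines(cam_path), invert = TRUE, value = TRUE)
  if (length(cl) < 1) stop("no camera entries in cameras.txt", call. = FALSE)
  tok <- strsplit(trimws(cl[1]), "\\s+")[[1]]
  model <- tok[2]
  w <- as.integer(tok[3]); h <- as.integer(tok[4])
  par <- as.numeric(tok[-(1:4)])
  intr <- switch(model,
    PINHOLE = camera_intrinsics(par[1], par[2], par[3], par[4], w, h),
    OPENCV = camera_intrinsics(par[1], par[2], par[3], par[4], w, h,
                               k1 = par[5], k2 = par[6], p1 = par[7],
                               p2 = par[8]),
    stop("unsupported camera model: ", model, call. = FALSE))
  il <- grep("^\\s*(#|$)", readLines(img_path), invert = TRUE, value = TRUE)
  # image entries occupy two lines; the 2D-point line may be empty (dropped
  # by the blank filter) or populated -- detect pose lines by field count
  pose_lines <- il[vapply(strsplit(trimws(il), "\\s+"),
                          function(t) length(t) == 10 &&
                            !anyNA(suppressWarnings(as.numeric(t[2:8]))),
                          logical(1))]
  if (length(pose_lines) == 0) stop("no image entries in images.txt", call. = FALSE)
  ids <- integer(); poses <- list(); nms <- character()
  for (ln in pose_lines) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    v <- as.numeric(t[2:8])
    ids <- c(ids, as.integer(t[1]))
    poses[[length(poses) + 1]] <-
      camera_pose(quat_to_rotation(v[1:4]), v[5:7], "w2c")
    nms <- c(nms, t[10])
  }
  o <- order(ids)
  list(intrinsics = intr, poses = poses[o], image_names = nms[o])
}

#' Read a trajectory-prior YAML file
#' @param path YAML file with fields `r_real`, `h1`, `h2`.
#' @return a [trajectory_prior()].
#' @export
read_prior <- function(path) {
  y <- yaml::read_yaml(path)
  stopifnot(all(c("r_real", "h1", "h2") %in% names(y)))
  trajectory_prior(y$r_real, y$h1, y$h2)
}

#' Read an image directory as frames
#' @param dir directory of PNG frames.
#' @param pattern file-name pattern (default `"\\.png$"`).
#' @return named list of H x W x 3 arrays, sorted by file name.
#' @export
read_frames <- function(dir, pattern = "\\.png$") {
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0) stop("no frames found in ", dir, call. = FALSE)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  names(frames) <- basename(files)
  frames
}

#' Undistort an image to an ideal pinhole view
#'
#' Applies the radial (`k1, k2, k3`) and tangential (`p1, p2`) distortion
#' model once at ingest: each output pixel looks up the distorted source
#' location by forward-mapping its ideal normalized coordinates, with
#' bilinear resampling.  Downstream modules then assume an ideal pinhole.
#'
#' @param image H x W x 3 array.
#' @param intr a [camera_intrinsics()].
#' @return undistorted H x W x 3 array (identical input when all distortion
#'   coefficients are zero).
#' @export
undistort_image <- function(image, intr) {
  if (!has_distortion(intr)) return(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  grid <- expand.grid(row = seq_len(h), col = seq_len(w))
  x <- (grid$col - 0.5 - intr$cx) / intr$fx
  y <- (grid$row - 0.5 - intr$cy) / intr$fy
  r2 <- x^2 + y^2
  rad <- 1 + intr$k1 * r2 + intr$k2 * r2^2 + intr$k3 * r2^3
  xd <- x * rad + 2 * intr$p1 * x * y + intr$p2 * (r2 + 2 * x^2)
  yd <- y * rad + intr$p1 * (r2 + 2 * y^2) + 2 * intr$p2 * x * y
  sc <- xd * intr$fx + intr$cx + 0.5
  sr <- yd * intr$fy + intr$cy + 0.5
  c0 <- pmin(pmax(floor(sc), 1), w - 1); r0 <- pmin(pmax(floor(sr), 1), h - 1)
  fc <- pmin(pmax(sc - c0, 0), 1); fr <- pmin(pmax(sr - r0, 0), 1)
  out <- array(0, dim(image))
  for (ch in 1:3) {
    m <- image[, , ch]
    v <- (1 - fr) * (1 - fc) * m[cbind(r0, c0)] +
      (1 - fr) * fc * m[cbind(r0, c0 + 1)] +
      fr * (1 - fc) * m[cbind(r0 + 1, c0)] +
      fr * fc * m[cbind(r0 + 1, c0 + 1)]
    out[, , ch][cbind(grid$row, grid$col)] <- v
  }
  out
}
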