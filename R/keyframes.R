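# Keyframe extraction from two-view orbital video: equidistant downsampling,
# Laplacian-variance blur rejection with a quality gate, and seeded random
# subselection down to the target image count.

#' Convert an RGB image to grayscale (ITU-R BT.601 luma)
#' @param image H x W x 3 array in `[0, 1]`, or an H x W matrix (returned
#'   unchanged).
#' @return H x W numeric matrix.
#' @export
rgb_to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
}

pad_replicate <- function(m) {
  m <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m[, 1, drop = FALSE], m, m[, ncol(m), drop = FALSE])
}

#' Laplacian-variance sharpness score
#'
#' Converts the image to grayscale, convolves it with the 8-neighborhood
#' Laplacian kernel `[[1,1,1],[1,-8,1],[1,1,1]]` (replicate border padding)
#' and returns the variance of the response,
#' `Var(L) = (1/N) * sum((L_i - mu)^2)`.  Larger values mean sharper images;
#' a constant image scores exactly 0.
#'
#' @param image H x W x 3 array or H x W matrix, values in `[0, 1]`.
#' @return non-negative scalar.
#' @export
laplacian_variance <- function(image) {
  g <- rgb_to_gray(image)
  if (length(g) == 0) stop("empty image", call. = FALSE)
  h <- nrow(g); w <- ncol(g)
  p <- pad_replicate(g)
  L <- p[1:h, 1:w] + p[1:h, 2:(w + 1)] + p[1:h, 3:(w + 2)] +
    p[2:(h + 1), 1:w] - 8 * g + p[2:(h + 1), 3:(w + 2)] +
    p[3:(h + 2), 1:w] + p[3:(h + 2), 2:(w + 1)] + p[3:(h + 2), 3:(w + 2)]
  mu <- mean(L)
  mean((L - mu)^2)
}

#' Frame set
#'
#' A collection of video frames with per-frame metadata.  `frames` is a list
#' of H x W x 3 arrays; `meta` is a tibble with columns `view` (factor-like
#' character, e.g. `"upper"`/`"lower"`), `source_index` (position in the
#' originating video) and `sharpness` (Laplacian variance, `NA` until scored).
#'
#' @param frames list of H x W x 3 arrays in `[0, 1]`.
#' @param view character vector of view ids, one per frame.
#' @param source_index integer vector, one per frame.
#' @param sharpness optional numeric vector of precomputed scores.
#' @return An object of class `frame_set`.
#' @export
frame_set <- function(frames, view, source_index, sharpness = NULL) {
  n <- length(frames)
  stopifnot(length(view) == n, length(source_index) == n)
  if (is.null(sharpness)) sharpness <- rep(NA_real_, n)
  stopifnot(length(sharpness) == n)
  structure(list(frames = frames,
                 meta = tibble::tibble(view = as.character(view),
                                       source_index = as.integer(source_index),
                                       sharpness = as.numeric(sharpness))),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  counts <- per_view_counts(x)
  cat("<frame_set> ", nrow(x$meta), " frames (",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Frames per view
#' @param fs a [frame_set()].
#' @return named integer vector of per-view frame counts.
#' @export
per_view_counts <- function(fs) {
  tab <- table(fs$meta$view)
  stats::setNames(as.integer(tab), names(tab))
}

subset_frame_set <- function(fs, idx) {
  frame_set(fs$frames[idx], fs$meta$view[idx], fs$meta$source_index[idx],
            fs$meta$sharpness[idx])
}

#' Evenly spaced downsampling indices
#'
#' `round(seq(0, n - 1, length.out = target)) + 1`: an endpoint-covering,
#' maximal-gap arithmetic-like progression from the first to the last frame.
#'
#' @param n number of available frames.
#' @param target number of frames to keep.
#' @return integer vector of `target` distinct 1-based indices.
#' @export
equidistant_indices <- function(n, target) {
  stopifnot(target >= 1)
  if (n < target) {
    stop(sprintf("cannot select %d frames from %d: too few frames", target, n),
         call. = FALSE)
  }
  idx <- round(seq(0, n - 1, length.out = target)) + 1L
  if (anyDuplicated(idx)) {
    stop("downsampling produced duplicate indices", call. = FALSE)
  }
  as.integer(idx)
}

#' Equidistant downsampling of multi-view video
#'
#' Keeps `target_per_view` evenly spaced frames from each view of the orbital
#' capture (default 50 per view, i.e. 100 frames for the two-ring rig),
#' reducing redundancy between neighbouring frames before blur scoring.
#'
#' @param video_frames_per_view named list mapping a view id to a list of
#'   H x W x 3 frame arrays, in video order.
#' @param target_per_view frames retained per view (default 50).
#' @return a [frame_set()] with sharpness scores computed.
#' @export
equidistant_downsample <- function(video_frames_per_view, target_per_view = 50) {
  stopifnot(is.list(video_frames_per_view),
            !is.null(names(video_frames_per_view)))
  frames <- list(); view <- character(); src <- integer()
  for (v in names(video_frames_per_view)) {
    fv <- video_frames_per_view[[v]]
    idx <- equidistant_indices(length(fv), target_per_view)
    frames <- c(frames, fv[idx])
    view <- c(view, rep(v, length(idx)))
    src <- c(src, idx)
  }
  sharp <- vapply(frames, laplacian_variance, numeric(1))
  frame_set(frames, view, src, sharp)
}

#' Eliminate blurry frames with a quality gate
#'
#' Removes every frame whose sharpness is below `rel_threshold` times the mean
#' sharpness of all frames (both views jointly, single pass).  If more than
#' `max_removed` frames fall below the threshold the whole capture is judged
#' not up to standard and an error of class `orbitnerf_quality_failure` is
#' raised, instructing re-acquisition.
#'
#' @param fs a [frame_set()] with sharpness scores.
#' @param rel_threshold fraction of the mean sharpness below which a frame is
#'   considered blurry (default 0.2).
#' @param max_removed maximum tolerated number of removed frames (default 10).
#' @return the filtered [frame_set()].
#' @export
eliminate_blurry <- function(fs, rel_threshold = 0.2, max_removed = 10) {
  stopifnot(inherits(fs, "frame_set"))
  s <- fs$meta$sharpness
  if (anyNA(s)) stop("sharpness scores missing", call. = FALSE)
  thr <- rel_threshold * mean(s)
  keep <- s >= thr
  if (!any(keep)) stop("all frames are blurry: degenerate capture", call. = FALSE)
  removed <- sum(!keep)
  if (removed > max_removed) {
    stop(structure(class = c("orbitnerf_quality_failure", "error", "condition"),
                   list(message = sprintf(
                     paste0("%d frames below %.0f%% of mean sharpness ",
                            "(max allowed %d): data quality not up to ",
                            "standard, please re-acquire the video"),
                     removed, 100 * rel_threshold, max_removed),
                     call = sys.call(-1))))
  }
  subset_frame_set(fs, which(keep))
}

#' Random keyframe subselection
#'
#' Samples `per_view` frames per view uniformly without replacement with a
#' fixed seed, then sorts by (view, source index).
#'
#' @param fs a [frame_set()].
#' @param per_view frames to keep per view (default 45).
#' @param seed integer seed for the sampling.
#' @return a [frame_set()] with `per_view` frames per view.
#' @export
select_keyframes <- function(fs, per_view = 45, seed = 1) {
  stopifnot(inherits(fs, "frame_set"))
  views <- sort(unique(fs$meta$view))
  keep <- integer()
  rng <- local_seed(seed)
  for (v in views) {
    idx <- which(fs$meta$view == v)
    if (length(idx) < per_view) {
      stop(sprintf("view '%s' has %d frames, need %d", v, length(idx), per_view),
           call. = FALSE)
    }
    keep <- c(keep, sample(idx, per_view))
  }
  rng()
  keep <- keep[order(fs$meta$view[keep], fs$meta$source_index[keep])]
  subset_frame_set(fs, keep)
}

# Scoped RNG: sets the seed, returns a restorer for the previous RNG state.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Full keyframe-extraction pipeline
#'
#' Runs equidistant downsampling (default 50 frames per view), blur
#' elimination with the quality gate, and random subselection (default 45 per
#' view, 90 keyframes for the two-view rig).
#'
#' @inheritParams equidistant_downsample
#' @inheritParams eliminate_blurry
#' @inheritParams select_keyframes
#' @return a [frame_set()] of keyframes.
#' @export
extract_keyframes <- function(video_frames_per_view, target_per_view = 50,
                              rel_threshold = 0.2, max_removed = 10,
                              per_view = 45, seed = 1) {
  fs <- equidistant_downsample(video_frames_per_view, target_per_view)
  fs <- eliminate_blurry(fs, rel_threshold, max_removed)
  select_keyframes(fs, per_view, seed)
}

#' Frame manifest
#' @param fs a [frame_set()].
#' @return tibble with one row per frame: `filename`, `view`, `source_index`,
#'   `sharpness`.
#' @export
frame_manifest <- function(fs) {
  tibble::tibble(
    filename = sprintf("%s_%04d.png", fs$meta$view, fs$meta$source_index),
    view = fs$meta$view,
    source_index = fs$meta$source_index,
    sharpness = fs$meta$sharpness)
}
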