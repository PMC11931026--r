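# Image-quality metrics (MSE / PSNR) and phenotype-accuracy summaries
# (MAE, R^2) for validation runs.

#' Mean squared error between two images
#'
#' `(1/(M*N)) * sum((a - b)^2)`, averaged over color channels.
#'
#' @param a,b images (arrays or matrices) of identical shape.
#' @return non-negative scalar.
#' @export
img_mse <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("image shape mismatch", call. = FALSE)
  mean((a - b)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(max_i^2 / MSE)` in decibels.  Identical images give
#' `+Inf`.
#'
#' @param a,b images of identical shape.
#' @param max_i peak signal value: 1 for float pipelines (default), 255 after
#'   8-bit export.
#' @return PSNR in dB.
#' @export
img_psnr <- function(a, b, max_i = 1) {
  m <- img_mse(a, b)
  if (m == 0) return(Inf)
  10 * log10(max_i^2 / m)
}

#' Phenotype accuracy: mean absolute error and coefficient of determination
#'
#' `MAE = mean(|estimated - truth|)`;
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` the total sum of squares of the
#' true values.
#'
#' @param estimated,truth numeric vectors of equal length >= 2.
#' @return An object of class `phenotype_stats`: list with `mae`, `r_squared`
#'   and `n`.
#' @export
phenotype_stats <- function(estimated, truth) {
  stopifnot(length(estimated) == length(truth), length(truth) >= 2)
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot <= 0) {
    stop("zero variance in `truth`: R^2 undefined", call. = FALSE)
  }
  structure(list(mae = mean(abs(estimated - truth)),
                 r_squared = 1 - sum((estimated - truth)^2) / ss_tot,
                 n = length(truth),
                 estimated = estimated, truth = truth),
            class = "phenotype_stats")
}

#' @export
print.phenotype_stats <- function(x, ...) {
  cat(sprintf("<phenotype_stats> n=%d  MAE=%.4g  R^2=%.4f\n",
              x$n, x$mae, x$r_squared))
  invisible(x)
}

#' @rdname phenotype_stats
#' @param x a `phenotype_stats`.
#' @param ... unused.
#' @export
glance.phenotype_stats <- function(x, ...) {
  tibble::tibble(mae = x$mae, r_squared = x$r_squared, n = x$n)
}

#' @rdname phenotype_stats
#' @export
tidy.phenotype_stats <- function(x, ...) {
  tibble::tibble(truth = x$truth, estimated = x$estimated,
                 error = x$estimated - x$truth)
}

#' @rdname phenotype_stats
#' @param object a `phenotype_stats`.
#' @export
autoplot.phenotype_stats <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$truth, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "measured", y = "estimated",
                  subtitle = sprintf("MAE = %.4g, R² = %.4f",
                                     object$mae, object$r_squared))
}

#' Evaluate rendered views against reference frames
#'
#' Renders each requested view from the trained field and reports per-view
#' MSE and PSNR plus the aggregate mean PSNR.
#'
#' @param field a trained [radiance_field()].
#' @param frames list of reference H x W x 3 arrays.
#' @param poses list of [camera_pose()]s matching `frames`.
#' @param intr a [camera_intrinsics()].
#' @param ids indices of the views to evaluate (default: all).
#' @param max_i peak signal value (see [img_psnr()]).
#' @return An object of class `metric_report`: a tibble with columns `id`,
#'   `mse`, `psnr`, plus attributes `mean_psnr` and `max_i`.
#' @export
evaluate_views <- function(field, frames, poses, intr, ids = NULL,
                           max_i = 1) {
  if (is.null(ids)) ids <- seq_along(frames)
  rows <- lapply(ids, function(i) {
    img <- render_view(field, poses[[i]], intr,
                       h = dim(frames[[i]])[1], w = dim(frames[[i]])[2])
    tibble::tibble(id = i, mse = img_mse(img, frames[[i]]),
                   psnr = img_psnr(img, frames[[i]], max_i))
  })
  out <- do.call(rbind, rows)
  attr(out, "mean_psnr") <- mean(out$psnr)
  attr(out, "max_i") <- max_i
  class(out) <- c("metric_report", class(out))
  out
}
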