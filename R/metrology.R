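#' Circular region of interest
#'
#' @param x_cm,y_cm Center in image coordinates (cm, origin at the
#'   rotation axis).
#' @param radius_cm ROI radius (cm), `> 0`.
#' @return An object of class `roi_circle`.
#' @export
roi_circle <- function(x_cm, y_cm, radius_cm) {
  if (radius_cm <= 0) abort("`radius_cm` must be positive")
  structure(list(x_cm = x_cm, y_cm = y_cm, radius_cm = radius_cm),
            class = "roi_circle")
}

.roi_mask <- function(image, roi) {
  stopifnot(inherits(roi, "roi_circle"))
  g <- nrow(image)
  px_cm <- attr(image, "pixel_size_mm") / 10
  half <- g * px_cm / 2
  if (abs(roi$x_cm) + roi$radius_cm > half ||
      abs(roi$y_cm) + roi$radius_cm > half) {
    abort("ROI extends outside the image")
  }
  ctr <- .pixel_centers_cm(g, px_cm)
  X <- matrix(ctr, g, g)
  Y <- matrix(ctr, g, g, byrow = TRUE)
  (X - roi$x_cm)^2 + (Y - roi$y_cm)^2 <= roi$radius_cm^2
}

#' Extract ROI pixel values
#'
#' @param image A `recon_image`.
#' @param roi A [roi_circle()], fully inside the image.
#' @return Numeric vector of pixel values.
#' @export
roi_pixels <- function(image, roi) {
  unclass(image)[.roi_mask(image, roi)]
}

#' ROI noise
#'
#' Noise is the sample standard deviation of pixel intensities within the
#' region — conventionally measured in a water background ROI.
#'
#' @inheritParams roi_pixels
#' @param min_voxels Minimum ROI size (default 25).
#' @return Standard deviation in image units (HU for calibrated images).
#' @export
roi_noise <- function(image, roi, min_voxels = 25) {
  v <- roi_pixels(image, roi)
  if (length(v) < min_voxels) {
    abort(sprintf("ROI holds %d voxels; need at least %d",
                  length(v), min_voxels))
  }
  stats::sd(v)
}

#' ROI contrast
#'
#' Contrast of an insert against the background:
#' \eqn{C = \mu_{insert} - \mu_{background}}, the difference of ROI mean
#' values.  Identical ROIs give exactly zero; partially overlapping ROIs
#' are rejected.
#'
#' @param image A `recon_image`.
#' @param insert_roi,background_roi [roi_circle()] regions.
#' @return Contrast in image units.
#' @export
roi_contrast <- function(image, insert_roi, background_roi) {
  mi <- .roi_mask(image, insert_roi)
  mb <- .roi_mask(image, background_roi)
  if (any(mi & mb) && !identical(mi, mb)) {
    abort("insert and background ROIs overlap")
  }
  mean(unclass(image)[mi]) - mean(unclass(image)[mb])
}

#' Per-voxel multi-bin feature vectors from matched ROIs
#'
#' Stacks the values of the same spatial ROI across several per-bin
#' images into an n_voxels x n_bins matrix — the sample unit for the
#' Hotelling observer.
#'
#' @param images List of `recon_image`s on a common grid (e.g. low- and
#'   high-bin reconstructions).
#' @param roi A [roi_circle()].
#' @return Numeric matrix, one column per image (named after the list).
#' @export
roi_vectors <- function(images, roi) {
  stopifnot(is.list(images), length(images) >= 1)
  cols <- lapply(images, roi_pixels, roi = roi)
  n <- lengths(cols)
  if (length(unique(n)) != 1L) abort("images do not share a common grid")
  m <- do.call(cbind, cols)
  colnames(m) <- names(images)
  m
}

.class_stats <- function(X, name) {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) < 2L) {
    abort(sprintf("class %s needs at least 2 sample vectors", name))
  }
  list(mean = colMeans(X), cov = stats::cov(X), n = nrow(X), X = X)
}

#' Hotelling observer template
#'
#' The optimal linear discriminant for two Gaussian classes with a common
#' covariance: \eqn{w = S^{-1}(\bar{x}_A - \bar{x}_B)} where
#' \eqn{S = (\Sigma_A + \Sigma_B)/2} is the pooled (equally weighted)
#' sample covariance, stabilized by a small ridge
#' \eqn{S + r \, tr(S)/d \, I}.  A covariance that is degenerate even
#' after the ridge raises an error rather than returning zeros.
#'
#' @param A,B Numeric matrices of per-voxel feature vectors (rows =
#'   voxels, columns = energy bins), equal column count.
#' @param ridge Ridge fraction (default 1e-6).
#' @return Numeric weight vector of length `ncol(A)`.
#' @export
hotelling_template <- function(A, B, ridge = 1e-6) {
  sa <- .class_stats(A, "A"); sb <- .class_stats(B, "B")
  if (length(sa$mean) != length(sb$mean)) {
    abort("A and B must have the same number of bins")
  }
  d <- length(sa$mean)
  S <- (sa$cov + sb$cov) / 2
  Sr <- S + ridge * sum(diag(S)) / d * diag(d)
  drop(solve(Sr, sa$mean - sb$mean))
}

#' Separability index of two materials
#'
#' Applies the Hotelling template to every voxel vector of both classes,
#' \eqn{\lambda_i = w \cdot x_i}, and standardizes the difference of the
#' two \eqn{\lambda} distributions:
#' \deqn{s' = \frac{\bar\lambda_A - \bar\lambda_B}
#'   {\sqrt{\tfrac{1}{2}(\sigma^2_{\lambda A} + \sigma^2_{\lambda B})}}}
#' The index is reported as a magnitude (`s_prime`), with the sign of the
#' raw difference retained in `sign`.
#'
#' @inheritParams hotelling_template
#' @return An object of class `separability_result` with the template,
#'   per-class \eqn{\bar\lambda} and \eqn{\sigma^2_\lambda}, `s_prime`,
#'   and `sign`.
#' @examples
#' set.seed(1)
#' A <- matrix(rnorm(2000), ncol = 2)
#' B <- matrix(rnorm(2000, mean = 1), ncol = 2)
#' separability_index(A, B)$s_prime
#' @export
separability_index <- function(A, B, ridge = 1e-6) {
  w <- hotelling_template(A, B, ridge)
  if (!is.matrix(A)) A <- as.matrix(A)
  if (!is.matrix(B)) B <- as.matrix(B)
  lA <- drop(A %*% w); lB <- drop(B %*% w)
  num <- mean(lA) - mean(lB)
  den <- sqrt(0.5 * (stats::var(lA) + stats::var(lB)))
  s <- num / den
  structure(list(template_w = w,
                 lambda_mean_A = mean(lA), lambda_mean_B = mean(lB),
                 lambda_var_A = stats::var(lA), lambda_var_B = stats::var(lB),
                 s_prime = abs(s), sign = sign(s),
                 n_A = nrow(A), n_B = nrow(B), ridge = ridge),
            class = "separability_result")
}

#' @export
print.separability_result <- function(x, ...) {
  cat(sprintf("<separability_result> s' = %.3f (sign %+d, n = %d/%d)\n",
              x$s_prime, x$sign, x$n_A, x$n_B))
  invisible(x)
}
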