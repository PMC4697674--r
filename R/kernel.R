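#' Kernel configuration
#'
#' Bandwidth of the Gaussian radial basis function (GRBF) kernel.  In
#' `"auto_from_data"` mode (the default) sigma is estimated from the image by
#' [estimate_sigma()]; in `"fixed"` mode a user value (for example the
#' sigma = 150 convention used in earlier kernelized FCM work on 8-bit MR
#' slices) is used as is.
#'
#' @param mode `"auto_from_data"` or `"fixed"`.
#' @param sigma positive kernel width in intensity units; required when
#'   `mode = "fixed"`.
#' @return object of class `kernel_config`.
#' @export
kernel_config <- function(mode = c("auto_from_data", "fixed"), sigma = NULL) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("fixed mode requires sigma > 0", call. = FALSE)
  } else if (!is.null(sigma)) {
    stop("sigma is estimated from data in auto_from_data mode", call. = FALSE)
  }
  structure(list(mode = mode, sigma = sigma), class = "kernel_config")
}

#' Data-driven kernel width
#'
#' Estimates the GRBF bandwidth from the dispersion of pixel-to-mean
#' distances: with `d_i = |x_i - xbar|` (xbar the global mean grayscale over
#' the foreground) and `dbar` their average, `sigma = sqrt(sum (d_i - dbar)^2
#' / (N - 1))`.  Scaling the image by a > 0 scales sigma by a, which is what
#' makes the kernelized distance invariant to affine intensity rescaling.
#'
#' @param img `gray_image` or numeric array.
#' @return positive scalar.
#' @export
estimate_sigma <- function(img) {
  img <- as_gray_image(img)
  x <- img$pixels[img$mask]
  if (length(x) < 2L)
    stop("sigma estimation needs at least 2 foreground pixels", call. = FALSE)
  d <- abs(x - mean(x))
  sigma <- stats::sd(d)
  if (!is.finite(sigma) || sigma == 0)
    stop("degenerate input: all grayscales identical; use kernel_config(\"fixed\", sigma = ...)",
         call. = FALSE)
  sigma
}

# Resolve a kernel_config against an image: returns the sigma actually used.
.resolve_sigma <- function(cfg, img) {
  if (cfg$mode == "fixed") cfg$sigma else estimate_sigma(img)
}

#' GRBF kernel
#'
#' `K(x, v) = exp(-(x - v)^2 / (2 sigma^2))`, symmetric, equal to 1 at zero
#' distance and decaying monotonically.  Vectorized over `x` and `v`.
#'
#' @param x,v grayscales (recycled against each other).
#' @param sigma positive kernel width, or a `kernel_config` in fixed mode.
#' @return values in (0, 1].
#' @export
grbf <- function(x, v, sigma) {
  if (inherits(sigma, "kernel_config")) {
    if (sigma$mode != "fixed")
      stop("auto_from_data kernel_config must be resolved against an image first",
           call. = FALSE)
    sigma <- sigma$sigma
  }
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  exp(-(x - v)^2 / (2 * sigma^2))
}

#' Kernel-induced distance
#'
#' The squared distance between feature-space images of two grayscales under
#' the GRBF kernel collapses to `2 (1 - K(x, v))`: zero iff `x == v`, bounded
#' above by 2.
#'
#' @inheritParams grbf
#' @return values in \[0, 2).
#' @export
kernel_distance <- function(x, v, sigma) {
  2 * (1 - grbf(x, v, sigma))
}
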