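#' Grayscale image container
#'
#' Wraps a 2-D matrix (or 3-D array) of non-negative grayscales together with
#' an optional foreground mask and optional voxel spacing.  All clustering,
#' regularization and kernel-width estimation operate on the foreground only;
#' background pixels still act as neighbors in window operations so that the
#' window cardinality is constant across the image.
#'
#' @param pixels numeric matrix or 3-D array of grayscales; must be finite.
#'   Negative values are allowed only if they arise from user preprocessing
#'   (a warning is emitted by downstream operations that assume
#'   non-negativity).
#' @param mask optional logical array of the same shape; `TRUE` marks
#'   foreground.  Defaults to all-foreground.
#' @param spacing optional numeric vector of per-axis physical sizes.  Carried
#'   through to outputs, never used by the algorithm.
#' @param normalize if `TRUE`, linearly rescale foreground grayscales to
#'   \[0, 1\].  The algorithm is invariant to affine rescaling when the kernel
#'   width is estimated from the data, so this is cosmetic.
#'
#' @return An object of class `gray_image` with elements `pixels`, `mask`
#'   and `spacing`.
#' @export
#' @examples
#' img <- gray_image(matrix(c(0, 0, 0, 0, 9, 0, 0, 0, 0), 3, 3))
#' local_mean(img, neighborhood_spec(3))
gray_image <- function(pixels, mask = NULL, spacing = NULL, normalize = FALSE) {
  if (is.data.frame(pixels)) pixels <- as.matrix(pixels)
  if (!is.numeric(pixels)) stop("pixels must be numeric", call. = FALSE)
  if (is.null(dim(pixels))) stop("pixels must be a matrix or array", call. = FALSE)
  nd <- length(dim(pixels))
  if (nd < 2L || nd > 3L) stop("pixels must be 2-D or 3-D", call. = FALSE)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("pixels contains NA/NaN/Inf", call. = FALSE)
  if (is.null(mask)) {
    mask <- array(TRUE, dim(pixels))
  } else {
    if (!identical(dim(mask), dim(pixels)))
      stop("mask shape must match pixels", call. = FALSE)
    mask <- array(as.logical(mask), dim(pixels))
    if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  }
  if (!any(mask)) stop("mask has no foreground pixel", call. = FALSE)
  if (normalize) {
    fg <- pixels[mask]
    rng <- range(fg)
    if (rng[2] > rng[1]) pixels <- (pixels - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(pixels = pixels, mask = mask, spacing = spacing),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  d <- dim(x$pixels)
  fg <- x$pixels[x$mask]
  cat(sprintf("<gray_image %s, %d foreground px, range [%.4g, %.4g]>\n",
              paste(d, collapse = "x"), sum(x$mask), min(fg), max(fg)))
  invisible(x)
}

as_gray_image <- function(x) {
  if (inherits(x, "gray_image")) x else gray_image(x)
}

#' Neighborhood specification
#'
#' Defines the square (2-D) or cubic (3-D) local window used by all
#' neighborhood operations.  Image borders are handled by replicate
#' (nearest-edge) padding so the window cardinality `N_R = window_edge^ndim`
#' is the same at every pixel.
#'
#' @param window_edge odd integer >= 3, edge length of the window in pixels.
#'   Default 3 (a 3x3 window), the recommended size: larger windows smooth
#'   more aggressively and erode thin structures such as the CSF ribbon.
#' @param boundary_policy only `"replicate"` is supported.
#' @return An object of class `neighborhood_spec`.
#' @export
neighborhood_spec <- function(window_edge = 3L, boundary_policy = "replicate") {
  window_edge <- as.integer(window_edge)
  if (length(window_edge) != 1L || is.na(window_edge) ||
      window_edge < 3L || window_edge %% 2L == 0L)
    stop("window_edge must be an odd integer >= 3", call. = FALSE)
  boundary_policy <- match.arg(boundary_policy, "replicate")
  structure(list(window_edge = window_edge, boundary_policy = boundary_policy),
            class = "neighborhood_spec")
}

# Clamped (replicate-padded) index sequence for one axis.
.clamp_idx <- function(n, offset) pmin(pmax(seq_len(n) + offset, 1L), n)

#' Neighbor stack of an image
#'
#' Returns an `N x N_R` matrix whose row i lists the grayscales in the window
#' centered at pixel i (replicate padding at borders).  Offsets are ordered
#' lexicographically, so the center pixel sits in column `(N_R + 1) / 2`.
#' This is the workhorse behind the local filters and the regularizer.
#'
#' @param img `gray_image` or numeric array.
#' @param spec `neighborhood_spec`.
#' @return numeric matrix with `prod(dim)` rows and `window_edge^ndim` columns.
#' @keywords internal
neighbor_stack <- function(img, spec = neighborhood_spec()) {
  x <- if (inherits(img, "gray_image")) img$pixels else img
  d <- dim(x)
  w <- spec$window_edge
  if (any(w > d))
    stop("window_edge (", w, ") exceeds image extent along some axis",
         call. = FALSE)
  half <- (w - 1L) %/% 2L
  offs <- seq.int(-half, half)
  nd <- length(d)
  n_r <- w^nd
  out <- matrix(0, length(x), n_r)
  col <- 0L
  if (nd == 2L) {
    for (oj in offs) {
      jj <- .clamp_idx(d[2L], oj)
      for (oi in offs) {
        col <- col + 1L
        out[, col] <- x[.clamp_idx(d[1L], oi), jj]
      }
    }
  } else {
    for (ok in offs) {
      kk <- .clamp_idx(d[3L], ok)
      for (oj in offs) {
        jj <- .clamp_idx(d[2L], oj)
        for (oi in offs) {
          col <- col + 1L
          out[, col] <- x[.clamp_idx(d[1L], oi), jj, kk]
        }
      }
    }
  }
  out
}

.center_col <- function(n_r) (n_r + 1L) %/% 2L

#' Local mean filter
#'
#' Arithmetic mean of the window centered at each pixel (the center pixel is
#' included), replicate padding at borders.  Feeds the first ARKFCM variant.
#'
#' @inheritParams neighbor_stack
#' @return numeric array, same shape as the input image.
#' @export
local_mean <- function(img, spec = neighborhood_spec()) {
  img <- as_gray_image(img)
  st <- neighbor_stack(img, spec)
  array(rowMeans(st), dim(img$pixels))
}

#' Local median filter
#'
#' Window median at each pixel (center included), replicate padding.  Feeds
#' the second ARKFCM variant; the median is more robust than the mean against
#' impulse (salt-and-pepper) noise.
#'
#' @inheritParams neighbor_stack
#' @return numeric array, same shape as the input image.
#' @export
local_median <- function(img, spec = neighborhood_spec()) {
  img <- as_gray_image(img)
  st <- neighbor_stack(img, spec)
  n_r <- ncol(st)
  # odd-edge square/cubic windows in even dimension give odd N_R in 2-D/3-D
  if (n_r %% 2L == 1L) {
    k <- (n_r + 1L) %/% 2L
    med <- apply(st, 1L, function(r) sort.int(r, partial = k)[k])
  } else {
    med <- apply(st, 1L, stats::median)
  }
  array(med, dim(img$pixels))
}
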