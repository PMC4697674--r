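#' Phantom specification
#'
#' Describes a synthetic piecewise-constant multi-tissue test image with
#' ground truth, emulating the validation regime used for brain MR
#' segmentation benchmarks: distinct tissue grayscales corrupted by noise
#' and a smooth multiplicative intensity nonuniformity (bias) field.
#'
#' Noise and bias levels follow the simulated-brain-database conventions:
#' "p percent noise" means a noise standard deviation of p percent of the
#' brightest tissue mean, and a "p percent" intensity nonuniformity means a
#' multiplicative field spanning `1 - p/2` to `1 + p/2` percent of nominal
#' (so `bias_field = 0.2` gives a field in \[0.9, 1.1\], the standard 20
#' percent regime).
#'
#' @param shape image dimensions, default `c(128, 128)`.
#' @param n_classes number of tissue classes (>= 2).
#' @param class_means per-class grayscale means, pairwise distinct.  The
#'   default `c(48, 106, 154)` mimics CSF/GM/WM contrast on a T1-weighted
#'   slice; ground-truth label j carries mean `class_means[j]`.
#' @param geometry `"slice_like"` (brain-like nested blobs with a thin CSF
#'   ribbon and a background mask; 3 classes only), `"concentric"`
#'   (area-balanced concentric rings, no background) or `"voronoi"`
#'   (random nearest-seed cells, no background).
#' @param noise_model `"none"`, `"gaussian"`, `"salt_pepper"` or `"rician"`.
#' @param noise_level percentage of the brightest class mean (e.g. 7 for the
#'   7 percent regime).
#' @param bias_field amplitude of the multiplicative nonuniformity as a
#'   fraction (0.2 for a 20 percent bias field, i.e. a field in
#'   \[0.9, 1.1\]); 0 disables it.
#' @param seed integer seed; regeneration with the same spec is
#'   bit-identical.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128L, 128L), n_classes = 3L,
                         class_means = c(48, 106, 154),
                         geometry = c("slice_like", "concentric", "voronoi"),
                         noise_model = c("none", "gaussian", "salt_pepper",
                                         "rician"),
                         noise_level = 0, bias_field = 0, seed = 1L) {
  geometry <- match.arg(geometry)
  noise_model <- match.arg(noise_model)
  shape <- as.integer(shape)
  n_classes <- as.integer(n_classes)
  if (length(shape) < 2L || any(shape < 8L))
    stop("shape must give at least an 8x8 image", call. = FALSE)
  if (n_classes < 2L) stop("n_classes must be >= 2", call. = FALSE)
  if (length(class_means) != n_classes)
    stop("class_means must have one value per class", call. = FALSE)
  if (anyDuplicated(class_means))
    stop("class_means must be pairwise distinct", call. = FALSE)
  if (geometry == "slice_like" && n_classes != 3L)
    stop("slice_like geometry models exactly 3 tissue classes", call. = FALSE)
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  if (bias_field < 0) stop("bias_field must be >= 0", call. = FALSE)
  structure(list(shape = shape, n_classes = n_classes,
                 class_means = as.numeric(class_means), geometry = geometry,
                 noise_model = noise_model, noise_level = noise_level,
                 bias_field = bias_field, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Evaluate RNG-dependent code under a fixed seed without disturbing the
# caller's RNG stream.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Label geometries ----------------------------------------------------------

.geom_concentric <- function(shape, n_classes) {
  ci <- (shape[1] + 1) / 2
  cj <- (shape[2] + 1) / 2
  r <- sqrt(outer((seq_len(shape[1]) - ci)^2, (seq_len(shape[2]) - cj)^2, "+"))
  br <- stats::quantile(r, probs = seq(0, 1, length.out = n_classes + 1))
  lab <- matrix(as.integer(cut(r, breaks = br, include.lowest = TRUE)), shape[1])
  lab
}

.geom_voronoi <- function(shape, n_classes) {
  si <- stats::runif(n_classes, 1, shape[1])
  sj <- stats::runif(n_classes, 1, shape[2])
  ii <- matrix(seq_len(shape[1]), shape[1], shape[2])
  jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  best <- matrix(Inf, shape[1], shape[2])
  lab <- matrix(1L, shape[1], shape[2])
  for (k in seq_len(n_classes)) {
    d2 <- (ii - si[k])^2 + (jj - sj[k])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- k
  }
  lab
}

# Brain-like slice: WM core inside a GM cortex, separated by a thin CSF
# ribbon, plus a central CSF ventricle; everything outside the outer blob is
# background (label 0).  Class 1 = CSF, 2 = GM, 3 = WM so that labels follow
# ascending T1 contrast.  Boundaries are sinusoidally modulated so the
# structures are blob-like rather than circular.  CSF is proportioned as in
# an axial slice: the ventricular blob carries most of the CSF area while
# the ~2-3 px interface ribbon keeps the thin-structure regime present.
.geom_slice_like <- function(shape) {
  ci <- (shape[1] + 1) / 2
  cj <- (shape[2] + 1) / 2
  ii <- matrix(seq_len(shape[1]), shape[1], shape[2]) - ci
  jj <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE) - cj
  r <- sqrt(ii^2 + jj^2)
  th <- atan2(jj, ii)
  p <- stats::runif(3, 0, 2 * pi)
  r0 <- 0.42 * min(shape)
  outer_r <- r0 * (1 + 0.12 * sin(3 * th + p[1]) + 0.07 * sin(5 * th + p[2]))
  rn <- r / outer_r
  vent <- 0.32 * (1 + 0.25 * sin(2 * th + p[3]))
  ribbon_in <- 0.62
  # ~2-3 px ribbon on realistically sized images; relative width on tiny
  # ones so every tissue band keeps at least a few pixels
  ribbon_w <- min(2.6 / r0, 0.12)
  lab <- matrix(0L, shape[1], shape[2])
  lab[rn <= 1] <- 2L                                  # GM cortex
  lab[rn <= ribbon_in + ribbon_w] <- 1L               # CSF ribbon
  lab[rn <= ribbon_in] <- 3L                          # WM core
  lab[rn <= vent] <- 1L                               # CSF ventricle
  lab
}

# Corruption ----------------------------------------------------------------

#' Corrupt an image with noise
#'
#' Applies one of the supported noise models to an arbitrary grayscale
#' image.  `gaussian`: additive zero-mean noise with standard deviation
#' `noise_level` percent of `reference`.  `salt_pepper`: a fraction
#' `noise_level` percent of pixels is set to the global minimum or maximum
#' grayscale (half each, in expectation).  `rician`: the magnitude-image MR
#' noise model `sqrt((x + n1)^2 + n2^2)` with independent zero-mean Gaussians
#' `n1`, `n2` of standard deviation `noise_level` percent of `reference`;
#' its output is non-negative by construction.
#'
#' @param img `gray_image` or numeric array.
#' @param noise_model `"none"`, `"gaussian"`, `"salt_pepper"` or `"rician"`.
#' @param noise_level percentage (see [phantom_spec()] for the convention).
#' @param seed integer seed; same seed, same output.
#' @param reference intensity the percentage refers to; defaults to the
#'   maximum grayscale of the image (for phantoms, the brightest class mean
#'   is passed instead).
#' @return `gray_image` with the same mask and spacing.
#' @export
corrupt_image <- function(img, noise_model, noise_level, seed = 1L,
                          reference = NULL) {
  img <- as_gray_image(img)
  noise_model <- match.arg(noise_model,
                           c("none", "gaussian", "salt_pepper", "rician"))
  if (noise_level < 0) stop("noise_level must be >= 0", call. = FALSE)
  x <- img$pixels
  if (noise_model == "none" || noise_level == 0)
    return(img)
  if (is.null(reference)) reference <- max(x)
  s <- noise_level / 100 * reference
  out <- .with_seed(seed, {
    switch(noise_model,
      gaussian = x + array(stats::rnorm(length(x), sd = s), dim(x)),
      salt_pepper = {
        n_hit <- round(noise_level / 100 * length(x))
        idx <- sample.int(length(x), n_hit)
        y <- x
        lohi <- sample(c(min(x), max(x)), n_hit, replace = TRUE)
        y[idx] <- lohi
        y
      },
      rician = {
        n1 <- array(stats::rnorm(length(x), sd = s), dim(x))
        n2 <- array(stats::rnorm(length(x), sd = s), dim(x))
        sqrt((x + n1)^2 + n2^2)
      })
  })
  out[out < 0] <- 0
  gray_image(out, mask = img$mask, spacing = img$spacing)
}

# Smooth multiplicative bias surface in [-1, 1]: a randomly oriented,
# randomly phased cosine ramp across the field of view.
.bias_surface <- function(shape) {
  xx <- matrix(seq(-1, 1, length.out = shape[1]), shape[1], shape[2])
  yy <- matrix(seq(-1, 1, length.out = shape[2]), shape[1], shape[2],
               byrow = TRUE)
  a <- stats::runif(2, 0.5, 1.2)
  ph <- stats::runif(1, 0, 2 * pi)
  cos(pi / 2 * (a[1] * xx + a[2] * yy) + ph)
}

#' Generate a synthetic phantom
#'
#' Builds the piecewise-constant tissue image described by a
#' [phantom_spec()], applies the bias field (if any), then the noise model
#' (if any), and clamps negatives to zero.  Generation is fully determined
#' by the spec (including its seed).
#'
#' @param spec `phantom_spec`.
#' @return object of class `phantom`: list with `image` (`gray_image`),
#'   `truth` (integer label array, 0 = background), and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64), noise_model =
#'   "gaussian", noise_level = 7, bias_field = 0.2, seed = 42))
#' range(ph$image$pixels)
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  out <- .with_seed(spec$seed, {
    truth <- switch(spec$geometry,
      concentric = .geom_concentric(spec$shape, spec$n_classes),
      voronoi    = .geom_voronoi(spec$shape, spec$n_classes),
      slice_like = .geom_slice_like(spec$shape))
    counts <- tabulate(truth, nbins = spec$n_classes)
    if (any(counts == 0L))
      stop("degenerate phantom: some class received no pixel", call. = FALSE)
    px <- array(0, dim(truth))
    fg <- truth > 0L
    px[fg] <- spec$class_means[truth[fg]]
    if (spec$bias_field > 0)
      px <- px * (1 + spec$bias_field / 2 * .bias_surface(spec$shape))
    list(truth = truth, px = px)
  })
  img <- gray_image(pmax(out$px, 0), mask = out$truth > 0L)
  img <- corrupt_image(img, spec$noise_model, spec$noise_level,
                       # decorrelate the noise stream from the geometry
                       seed = spec$seed + 1L,
                       reference = max(spec$class_means))
  structure(list(image = img, truth = list(labels = out$truth,
                                           class_ids = seq_len(spec$n_classes),
                                           background_id = 0L),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom %s, %d classes, geometry=%s, noise=%s %.3g%%, bias=%.3g>\n",
              paste(x$spec$shape, collapse = "x"), x$spec$n_classes,
              x$spec$geometry, x$spec$noise_model, x$spec$noise_level,
              x$spec$bias_field))
  invisible(x)
}
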