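#' Clustering configuration
#'
#' @param n_clusters number of tissue classes c (>= 2); for T1-weighted brain
#'   slices typically 3 (CSF, GM, WM) or 4 when background is clustered too.
#' @param m fuzzifier (> 1); 2 is the standard default.
#' @param epsilon convergence threshold on the maximum absolute change of any
#'   membership value between iterations; default 0.001.
#' @param max_iter iteration cap (inclusive); default 100.
#' @param variant which smoothing input drives the regularized term:
#'   `"average"` (local mean filter), `"median"` (local median filter),
#'   `"weighted"` (the devised weighted image) or `"none"` (phi forced to 0,
#'   which reduces the method to kernelized FCM).
#' @param seed integer seed used by randomized initialization (and only
#'   there); the default initialization is deterministic.
#' @param init `"equal_interval"` (default) places initial centers at evenly
#'   spaced positions across the foreground grayscale range — deterministic,
#'   and robust to unbalanced class sizes; `"percentile_centers"` places them
#'   at evenly spaced quantiles instead (deterministic, but on images whose
#'   smallest tissue class occupies well under `1/c` of the foreground the
#'   lowest center starts inside the wrong intensity mode, which the
#'   short-ranged GRBF weighting cannot correct); `"random_membership"` draws
#'   each initial membership row uniformly from the simplex (seeded).
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(n_clusters = 3L, m = 2, epsilon = 0.001,
                           max_iter = 100L,
                           variant = c("average", "median", "weighted", "none"),
                           seed = 1L,
                           init = c("equal_interval", "percentile_centers",
                                    "random_membership")) {
  n_clusters <- as.integer(n_clusters)
  if (is.na(n_clusters) || n_clusters < 2L)
    stop("n_clusters must be an integer >= 2", call. = FALSE)
  if (!is.finite(m) || m <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("epsilon must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("max_iter must be a positive integer", call. = FALSE)
  structure(list(n_clusters = n_clusters, m = m, epsilon = epsilon,
                 max_iter = max_iter, variant = match.arg(variant),
                 seed = as.integer(seed), init = match.arg(init)),
            class = "cluster_config")
}

#' Regularized kernel clustering objective
#'
#' `J = 2 sum_ij u_ij^m (1 - K(x_i, v_j)) + sum_ij phi_i u_ij^m
#' (1 - K(xbar_i, v_j))` over foreground pixels: a kernelized within-cluster
#' dissimilarity plus a phi-weighted term that pulls each pixel's membership
#' toward that of its smoothed grayscale.
#'
#' @param x foreground grayscales (vector).
#' @param xb smoothed grayscales, same length (the variant's mean/median/
#'   weighted image values).
#' @param phi regularization weights, same length.
#' @param u membership matrix, `length(x)` rows, one column per cluster.
#' @param v cluster centers.
#' @param m fuzzifier.
#' @param sigma GRBF kernel width.
#' @return non-negative scalar.
#' @export
arkfcm_objective <- function(x, xb, phi, u, v, m, sigma) {
  um <- u^m
  k1 <- exp(-outer(x, v, "-")^2 / (2 * sigma^2))
  k2 <- exp(-outer(xb, v, "-")^2 / (2 * sigma^2))
  2 * sum(um * (1 - k1)) + sum(phi * um * (1 - k2))
}

#' Membership update
#'
#' One alternate-optimization membership step: with dissimilarity
#' `D_ij = (1 - K(x_i, v_j)) + phi_i (1 - K(xbar_i, v_j))`, memberships are
#' `u_ij = D_ij^(-1/(m-1)) / sum_k D_ik^(-1/(m-1))`.  A pixel whose
#' dissimilarity to one or more centers is exactly zero gets a crisp
#' membership split equally among those centers (the standard singularity
#' convention).
#'
#' @inheritParams arkfcm_objective
#' @return membership matrix with rows summing to 1.
#' @export
update_memberships <- function(x, xb, phi, v, m, sigma) {
  k1 <- exp(-outer(x, v, "-")^2 / (2 * sigma^2))
  k2 <- exp(-outer(xb, v, "-")^2 / (2 * sigma^2))
  d <- (1 - k1) + phi * (1 - k2)
  zero_rows <- which(rowSums(d == 0) > 0L)
  pw <- d^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  if (length(zero_rows)) {
    for (i in zero_rows) {
      z <- d[i, ] == 0
      u[i, ] <- ifelse(z, 1 / sum(z), 0)
    }
  }
  u
}

#' Center update
#'
#' One fixed-point center step: `v_j = sum_i u_ij^m (K(x_i, v_j) x_i +
#' phi_i K(xbar_i, v_j) xbar_i) / sum_i u_ij^m (K(x_i, v_j) + phi_i
#' K(xbar_i, v_j))`, with the kernels evaluated at the previous iterate's
#' centers.  Each new center is a convex combination of grayscales and
#' smoothed grayscales, hence stays inside the data range.  A cluster whose
#' denominator underflows to zero (empty cluster) is re-seeded at the
#' grayscale of the pixel that is least committed to any cluster, with a
#' warning.
#'
#' @inheritParams arkfcm_objective
#' @param v previous centers (used inside the kernels).
#' @return updated center vector.
#' @export
update_centers <- function(x, xb, phi, u, v, m, sigma) {
  um <- u^m
  k1 <- exp(-outer(x, v, "-")^2 / (2 * sigma^2))
  k2 <- exp(-outer(xb, v, "-")^2 / (2 * sigma^2))
  num <- colSums(um * (k1 * x + phi * k2 * xb))
  den <- colSums(um * (k1 + phi * k2))
  bad <- !is.finite(num / den) | den == 0
  v_new <- num / den
  if (any(bad)) {
    warning("empty cluster re-seeded at least-committed pixel")
    reseed_at <- which.min(apply(u, 1L, max))
    v_new[bad] <- x[reseed_at]
  }
  v_new
}

# Shared alternate-optimization loop.  `center_fn(u, v)` and
# `member_fn(v)` close over the data; `objective_fn(u, v)` evaluates J.
.alternate_optimize <- function(x, cfg, center_fn, member_fn, objective_fn) {
  c_ <- cfg$n_clusters
  probs <- (2 * seq_len(c_) - 1) / (2 * c_)
  v <- if (cfg$init == "percentile_centers") {
    stats::quantile(x, probs = probs, names = FALSE, type = 7)
  } else {
    min(x) + probs * (max(x) - min(x))
  }
  if (cfg$init == "random_membership") {
    if (exists(".Random.seed", envir = globalenv())) {
      old_seed <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
    }
    set.seed(cfg$seed)
    g <- matrix(stats::rexp(length(x) * c_), length(x), c_)
    u <- g / rowSums(g)
  } else {
    u <- member_fn(v)
  }
  trace <- numeric(0)
  converged <- FALSE
  n_iter <- 0L
  delta_trace <- numeric(0)
  for (t in seq_len(cfg$max_iter)) {
    v <- center_fn(u, v)
    u_new <- member_fn(v)
    delta <- max(abs(u_new - u))
    u <- u_new
    n_iter <- t
    trace <- c(trace, objective_fn(u, v))
    delta_trace <- c(delta_trace, delta)
    if (delta < cfg$epsilon) {
      converged <- TRUE
      break
    }
  }
  list(u = u, v = v, objective_trace = trace, delta_trace = delta_trace,
       n_iter = n_iter, converged = converged)
}

# Package raw optimizer output into a segmentation_result: sort centers
# ascending, renumber labels accordingly, restore image shape.
.finalize_result <- function(opt, img, cfg, sigma, extras = list()) {
  ord <- order(opt$v)
  v <- opt$v[ord]
  u <- opt$u[, ord, drop = FALSE]
  labels_fg <- max.col(u, ties.method = "first")
  labels <- array(0L, dim(img$pixels))
  labels[img$mask] <- labels_fg
  structure(c(list(labels = labels,
                   partition = list(memberships = u, centers = v),
                   objective_trace = opt$objective_trace,
                   delta_trace = opt$delta_trace,
                   n_iter = opt$n_iter,
                   converged = opt$converged,
                   sigma = sigma,
                   config = cfg,
                   mask = img$mask,
                   spacing = img$spacing),
              extras),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result: %d clusters, variant=%s, %d iter (%s), sigma=%.4g>\n",
    x$config$n_clusters, x$config$variant %||% "fcm", x$n_iter,
    if (x$converged) "converged" else "cap reached", x$sigma))
  cat("centers:", paste(sprintf("%.4g", x$partition$centers), collapse = ", "),
      "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptively regularized kernel fuzzy C-means segmentation
#'
#' Segments a grayscale image into `n_clusters` fuzzy classes.  The
#' regularization field phi is computed once up front from the local
#' variation coefficient; the smoothing input is the local mean
#' (variant `"average"`), local median (`"median"`) or the devised weighted
#' image (`"weighted"`); with variant `"none"` phi is forced to zero and the
#' method reduces to kernelized FCM.  Centers and memberships are then
#' alternately updated until the largest membership change drops below
#' `epsilon` or the iteration cap is hit.  Output labels are renumbered so
#' that 1 is the darkest center and `n_clusters` the brightest (for
#' T1-weighted brain images with 3 clusters: CSF, GM, WM); background /
#' masked pixels are labeled 0.
#'
#' @param img `gray_image` (or numeric matrix/array).
#' @param cfg `cluster_config`.
#' @param spec `neighborhood_spec` for all window operations.
#' @param kernel_cfg `kernel_config`; by default the GRBF width is estimated
#'   from the original foreground grayscales.
#' @return object of class `segmentation_result`: integer `labels` array
#'   (0 = background), `partition` (memberships and ascending centers),
#'   `objective_trace`, `n_iter`, `converged`, the `sigma` used, and the
#'   phi field under `regularizer` (`NULL` for variant `"none"`).
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48), seed = 7))
#' seg <- arkfcm_segment(ph$image, cluster_config(3, variant = "weighted"))
#' table(seg$labels[seg$labels > 0], ph$truth$labels[seg$labels > 0])
arkfcm_segment <- function(img, cfg = cluster_config(),
                           spec = neighborhood_spec(),
                           kernel_cfg = kernel_config()) {
  img <- as_gray_image(img)
  n_fg <- sum(img$mask)
  if (cfg$n_clusters >= n_fg)
    stop("n_clusters must be smaller than the number of foreground pixels",
         call. = FALSE)
  sigma <- .resolve_sigma(kernel_cfg, img)
  x <- img$pixels[img$mask]
  if (cfg$variant == "none") {
    reg <- NULL
    phi <- numeric(n_fg)
    xb <- x
  } else {
    reg <- compute_phi(img, spec)
    phi <- reg$phi[img$mask]
    smooth <- switch(cfg$variant,
      average  = local_mean(img, spec),
      median   = local_median(img, spec),
      weighted = weighted_image(img, reg, spec)$values)
    xb <- smooth[img$mask]
  }
  m <- cfg$m
  opt <- .alternate_optimize(
    x, cfg,
    center_fn = function(u, v) update_centers(x, xb, phi, u, v, m, sigma),
    member_fn = function(v) update_memberships(x, xb, phi, v, m, sigma),
    objective_fn = function(u, v) arkfcm_objective(x, xb, phi, u, v, m, sigma))
  .finalize_result(opt, img, cfg, sigma,
                   extras = list(regularizer = reg, smooth_values = xb))
}

#' Baseline fuzzy C-means segmentation
#'
#' Plain FCM on the foreground grayscales with squared Euclidean distance,
#' the same initialization and stopping conventions as [arkfcm_segment()].
#' Serves as the unregularized baseline: accurate on clean images, sensitive
#' to noise.
#'
#' @inheritParams arkfcm_segment
#' @return object of class `segmentation_result` (`sigma` is `NA`).
#' @export
fcm_segment <- function(img, cfg = cluster_config()) {
  img <- as_gray_image(img)
  n_fg <- sum(img$mask)
  if (cfg$n_clusters >= n_fg)
    stop("n_clusters must be smaller than the number of foreground pixels",
         call. = FALSE)
  x <- img$pixels[img$mask]
  m <- cfg$m
  member_fn <- function(v) {
    d2 <- outer(x, v, "-")^2
    zero_rows <- which(rowSums(d2 == 0) > 0L)
    pw <- d2^(-1 / (m - 1))
    u <- pw / rowSums(pw)
    if (length(zero_rows)) {
      for (i in zero_rows) {
        z <- d2[i, ] == 0
        u[i, ] <- ifelse(z, 1 / sum(z), 0)
      }
    }
    u
  }
  center_fn <- function(u, v) {
    um <- u^m
    den <- colSums(um)
    v_new <- colSums(um * x) / den
    bad <- !is.finite(v_new)
    if (any(bad)) {
      warning("empty cluster re-seeded at least-committed pixel")
      v_new[bad] <- x[which.min(apply(u, 1L, max))]
    }
    v_new
  }
  objective_fn <- function(u, v) sum(u^m * outer(x, v, "-")^2)
  opt <- .alternate_optimize(x, cfg, center_fn, member_fn, objective_fn)
  .finalize_result(opt, img, cfg, NA_real_)
}
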