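#' Local variation coefficient (LVC)
#'
#' Window variance of the grayscales normalized by the squared window mean:
#' `LVC_i = sum_{k in N_i} (x_k - xbar_i)^2 / (N_R * xbar_i^2)`, a scale-free
#' measure of local heterogeneity.  In noisy windows the LVC is large; in
#' homogeneous tissue it is near zero.  Where the window mean is zero the LVC
#' is defined as 0 — for non-negative images a zero mean forces a zero-variance
#' window, so nothing is lost.  If the image contains negative grayscales
#' (possible after user preprocessing) the squared mean is clamped below by a
#' tiny epsilon and a warning is emitted.
#'
#' @param img `gray_image` or numeric array.
#' @param spec `neighborhood_spec`.
#' @return non-negative numeric array, same shape as the image.
#' @export
compute_lvc <- function(img, spec = neighborhood_spec()) {
  img <- as_gray_image(img)
  st <- neighbor_stack(img, spec)
  n_r <- ncol(st)
  mu <- rowMeans(st)
  ss <- rowSums((st - mu)^2)
  denom <- n_r * mu^2
  if (any(img$pixels < 0)) {
    warning("image contains negative grayscales; clamping squared window mean")
    denom <- pmax(denom, .Machine$double.eps)
    lvc <- ss / denom
  } else {
    lvc <- ifelse(mu == 0, 0, ss / pmax(denom, .Machine$double.xmin))
  }
  array(lvc, dim(img$pixels))
}

#' Adaptive regularization field phi
#'
#' Derives the per-pixel regularization weight that replaces the fixed
#' neighbor-influence parameter of spatially constrained FCM variants.
#' The LVC values of the neighbors (center excluded) are summed and
#' exponentiated, `zeta_i = exp(sum_{k in N_i, k != i} LVC_k)`, then
#' normalized over the full window, `omega_i = zeta_i / sum_{k in N_i}
#' zeta_k`, which is a softmax over the window's exponent sums.  The final
#' weight compares each pixel with its local arithmetic mean:
#' `phi_i = 2 + omega_i` where the pixel is brighter than its window mean,
#' `2 - omega_i` where darker, and `0` where equal (there the clustering
#' reduces locally to plain FCM behavior).  The base constant 2 balances
#' convergence rate against detail preservation.
#'
#' The exponent sums are unbounded, so omega is evaluated in shifted
#' (stabilized softmax) form: the window maximum exponent is subtracted
#' before exponentiation.  This leaves omega mathematically unchanged and
#' makes overflow impossible.
#'
#' @param img `gray_image` or numeric array.
#' @param spec `neighborhood_spec`.
#' @param lvc optional precomputed LVC field (from [compute_lvc()] with the
#'   same spec); computed on the fly when missing.
#' @return An object of class `regularizer_field`: list with arrays `lvc`,
#'   `omega`, `phi`, and `base_constant = 2`.
#' @export
compute_phi <- function(img, spec = neighborhood_spec(), lvc = NULL) {
  img <- as_gray_image(img)
  d <- dim(img$pixels)
  if (is.null(lvc)) {
    lvc <- compute_lvc(img, spec)
  } else if (!identical(dim(lvc), d)) {
    stop("lvc shape must match image", call. = FALSE)
  }
  lvc_st <- neighbor_stack(lvc, spec)
  n_r <- ncol(lvc_st)
  cc <- .center_col(n_r)
  # exponent of zeta: neighbor LVC sum, center excluded
  s <- rowSums(lvc_st) - lvc_st[, cc]
  s_arr <- array(s, d)
  s_st <- neighbor_stack(s_arr, spec)
  s_max <- do.call(pmax, as.data.frame(s_st))
  omega <- exp(s - s_max) / rowSums(exp(s_st - s_max))
  mu <- rowMeans(neighbor_stack(img, spec))
  x <- as.vector(img$pixels)
  phi <- numeric(length(x))
  phi[mu < x] <- 2 + omega[mu < x]
  phi[mu > x] <- 2 - omega[mu > x]
  structure(list(lvc = lvc,
                 omega = array(omega, d),
                 phi = array(phi, d),
                 base_constant = 2),
            class = "regularizer_field")
}

#' @export
print.regularizer_field <- function(x, ...) {
  cat(sprintf("<regularizer_field %s, phi in [%.4g, %.4g], max omega %.4g>\n",
              paste(dim(x$phi), collapse = "x"),
              min(x$phi), max(x$phi), max(x$omega)))
  invisible(x)
}

#' Weighted image
#'
#' The devised smoothing input of the ARKFCM_w variant: a convex blend of
#' each pixel with the mean of its neighbors (center excluded), with mixing
#' weight driven by the global maximum of phi over the foreground:
#' `xi_i = (x_i + (1 + max phi) / (N_R - 1) * sum_{r in N_i, r != i} x_r)
#' / (2 + max phi)`.  The coefficients of the center grayscale and of the
#' neighbor mean sum to one, so the output never leaves the input range.
#'
#' @param img `gray_image` or numeric array.
#' @param reg `regularizer_field` computed on `img` with the same `spec`;
#'   computed on the fly when missing.
#' @param spec `neighborhood_spec`.
#' @return list with `values` (numeric array, same shape) and `phi_max`.
#' @export
weighted_image <- function(img, reg = NULL, spec = neighborhood_spec()) {
  img <- as_gray_image(img)
  if (is.null(reg)) reg <- compute_phi(img, spec)
  if (!identical(dim(reg$phi), dim(img$pixels)))
    stop("regularizer field shape must match image", call. = FALSE)
  phi_max <- max(reg$phi[img$mask])
  st <- neighbor_stack(img, spec)
  n_r <- ncol(st)
  cc <- .center_col(n_r)
  x <- st[, cc]
  neigh_sum <- rowSums(st) - x
  values <- (x + (1 + phi_max) / (n_r - 1) * neigh_sum) / (2 + phi_max)
  list(values = array(values, dim(img$pixels)), phi_max = phi_max)
}
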