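#' Jaccard similarity of one class
#'
#' Intersection over union of the pixel sets carrying `class_id` in the
#' predicted and ground-truth label maps.  If both sets are empty the score
#' is 1 (nothing to segment, nothing segmented); if exactly one is empty it
#' is 0.
#'
#' @param pred,truth integer label arrays of identical shape.
#' @param class_id label value to evaluate.
#' @return scalar in \[0, 1\].
#' @export
jaccard <- function(pred, truth, class_id) {
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth shapes differ", call. = FALSE)
  a <- pred == class_id
  b <- truth == class_id
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0L) return(1)
  inter / uni
}

#' Per-class and average Jaccard similarity
#'
#' @inheritParams jaccard
#' @param class_ids labels to evaluate; defaults to the sorted nonzero labels
#'   present in `truth`.
#' @return named numeric vector of per-class scores plus `"average"`
#'   (unweighted mean).
#' @export
jaccard_scores <- function(pred, truth, class_ids = NULL) {
  if (is.null(class_ids))
    class_ids <- sort(unique(truth[truth != 0]))
  js <- vapply(class_ids, function(k) jaccard(pred, truth, k), numeric(1))
  names(js) <- as.character(class_ids)
  c(js, average = mean(js))
}

#' Entropy-based segmentation quality measure
#'
#' Ground-truth-free quality score: the expected within-region grayscale
#' entropy plus the region-layout entropy,
#' `E = sum_j (S_j / S_I) H(R_j) - sum_j (S_j / S_I) log(S_j / S_I)`,
#' where `H(R_j) = -sum_m (L_j(m) / S_j) log(L_j(m) / S_j)` is the entropy of
#' the grayscale histogram of region j, `S_j` its area and `S_I` the total
#' evaluated area.  Lower is better: homogeneous regions shrink the first
#' term while an uninformative layout (one giant region) inflates nothing
#' because the layout term is capped at `log c`.  Background (label
#' `background_id`) is excluded, matching practice on pathological slices
#' where tumor and background are not scored.
#'
#' @param img `gray_image` or numeric array of grayscales.
#' @param labels integer label array, same shape.
#' @param background_id label excluded from evaluation (default 0).
#' @param base logarithm base; natural log by default.  Rankings are
#'   unaffected as long as comparisons share a base.
#' @param n_bins histogram bins for non-integer images (default 256 over the
#'   evaluated range); integer-valued images use exact intensity bins.
#' @return non-negative scalar.
#' @export
entropy_E <- function(img, labels, background_id = 0L, base = exp(1),
                      n_bins = 256L) {
  x <- if (inherits(img, "gray_image")) img$pixels else img
  if (!identical(dim(x), dim(labels)))
    stop("image and labels shapes differ", call. = FALSE)
  keep <- labels != background_id
  if (!any(keep)) stop("all evaluated regions are empty", call. = FALSE)
  vals <- x[keep]
  regs <- labels[keep]
  integerish <- all(vals == round(vals))
  if (!integerish) {
    rng <- range(vals)
    if (rng[2] > rng[1]) {
      vals <- pmin(floor((vals - rng[1]) / (rng[2] - rng[1]) * n_bins),
                   n_bins - 1L)
    } else {
      vals <- rep(0L, length(vals))
    }
  }
  s_i <- length(regs)
  region_ids <- sort(unique(regs))
  expected_region_entropy <- 0
  layout_entropy <- 0
  for (j in region_ids) {
    in_j <- regs == j
    s_j <- sum(in_j)
    p_j <- s_j / s_i
    counts <- table(vals[in_j])
    pm <- as.numeric(counts) / s_j
    h_j <- -sum(pm * log(pm, base = base))
    expected_region_entropy <- expected_region_entropy + p_j * h_j
    layout_entropy <- layout_entropy - p_j * log(p_j, base = base)
  }
  expected_region_entropy + layout_entropy
}
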