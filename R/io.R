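#' Read a grayscale image from disk
#'
#' Supported formats: NIfTI (`.nii`, `.nii.gz`; affine and header preserved
#' for round-tripping), PNG and TIFF (8/16-bit grayscale; multi-channel
#' input is averaged to grayscale).  An optional mask file (nonzero =
#' foreground) of the same shape may be supplied.
#'
#' @param path image file.
#' @param mask_path optional mask file.
#' @param normalize passed to [gray_image()].
#' @return `gray_image`; for NIfTI input the source header is attached as
#'   attribute `"nifti_ref"` so label maps can be written back into the same
#'   geometry.
#' @export
read_gray_image <- function(path, mask_path = NULL, normalize = FALSE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  px <- .read_pixels(path)
  msk <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path))
      stop("mask file not found: ", mask_path, call. = FALSE)
    msk <- .read_pixels(mask_path)$pixels != 0
  }
  img <- gray_image(px$pixels, mask = msk, normalize = normalize)
  attr(img, "nifti_ref") <- px$nifti_ref
  img
}

.read_pixels <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  switch(ext,
    nii = {
      vol <- RNifti::readNifti(path)
      arr <- drop(as.array(vol))
      if (length(dim(arr)) < 2L) arr <- matrix(arr, nrow = length(arr))
      list(pixels = arr, nifti_ref = vol)
    },
    png = {
      arr <- png::readPNG(path)
      if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
      list(pixels = arr, nifti_ref = NULL)
    },
    tif = ,
    tiff = {
      arr <- tiff::readTIFF(path)
      if (length(dim(arr)) == 3L) arr <- apply(arr, c(1, 2), mean)
      list(pixels = arr, nifti_ref = NULL)
    },
    stop("unsupported image format: .", ext, call. = FALSE))
}

#' Write a label map (or scalar field) to disk
#'
#' NIfTI output reuses the geometry of `reference` when available; PNG
#' output scales values to the 8-bit range (labels `0..c` map to evenly
#' spaced gray levels).
#'
#' @param values integer or numeric array.
#' @param path output file (`.nii`, `.nii.gz` or `.png`).
#' @param reference optional object carrying a `"nifti_ref"` attribute (as
#'   returned by [read_gray_image()]).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(values, path, reference = NULL) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (tolower(tools::file_ext(path)) == "gz") ext <- "nii"
  if (ext == "nii") {
    ref <- attr(reference, "nifti_ref")
    if (!is.null(ref)) {
      RNifti::writeNifti(RNifti::asNifti(values, reference = ref), path)
    } else {
      RNifti::writeNifti(RNifti::asNifti(array(as.numeric(values),
                                               dim(values))), path)
    }
  } else if (ext == "png") {
    v <- as.numeric(values)
    hi <- max(v)
    scaled <- if (hi > 0) v / hi else v
    png::writePNG(array(scaled, dim(values)), path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Write a JSON run report
#'
#' Records everything needed to audit a segmentation run: the configuration,
#' the kernel width actually used, iteration count, convergence flag, final
#' centers, and the per-iteration objective values and membership changes
#' (so that the monotone decrease of the objective can be checked post hoc).
#'
#' @param seg `segmentation_result`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(seg, path) {
  cfg <- seg$config
  report <- list(
    variant = cfg$variant %||% "fcm",
    n_clusters = cfg$n_clusters,
    fuzzifier = cfg$m,
    epsilon = cfg$epsilon,
    max_iter = cfg$max_iter,
    init = cfg$init,
    seed = cfg$seed,
    sigma = if (is.na(seg$sigma)) NULL else seg$sigma,
    n_iter = seg$n_iter,
    converged = seg$converged,
    centers = seg$partition$centers,
    objective_trace = seg$objective_trace,
    max_membership_change = seg$delta_trace)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
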