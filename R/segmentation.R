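# Stain-positive extraction and conversion of ring-shaped vessel-wall stain
# into filled vessel masks.

#' Binary stain mask
#'
#' Lightweight container for a segmented slice: a logical pixel matrix plus
#' the pixel size, stain tag and slice index it came from.
#'
#' @param pixels Logical matrix.
#' @param pixel_size Pixel size in um (> 0).
#' @param stain `"vessel_stain"` or `"epithelium_stain"`.
#' @param slice_index 0-based slice index.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size = 1,
                        stain = c("vessel_stain", "epithelium_stain"),
                        slice_index = 0L) {
  stain <- match.arg(stain)
  stopifnot(is.matrix(pixels))
  stop_if_not_scalar_number(pixel_size, "pixel_size", 0, strict_min = TRUE)
  structure(list(pixels = pixels > 0.5 & !is.na(pixels),
                 pixel_size = pixel_size, stain = stain,
                 slice_index = as.integer(slice_index)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %d x %d px (%g um/px), %s, slice %d, %d positive\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$stain,
              x$slice_index, sum(x$pixels)))
  invisible(x)
}

mask_pixels <- function(m) if (inherits(m, "binary_mask")) m$pixels else m > 0.5

with_mask_pixels <- function(m, px) {
  if (inherits(m, "binary_mask")) { m$pixels <- px; m } else px
}

#' Extract stain-positive pixels
#'
#' Global thresholding of a single-channel intensity image: pixels with
#' intensity at or above the threshold are positive.  With
#' `method = "automatic"` the threshold is chosen by Otsu's criterion on the
#' image histogram; a constant image yields an empty mask with a warning
#' rather than an error.
#'
#' @param image Numeric matrix of finite intensities.
#' @param method `"automatic"` (Otsu) or `"fixed"` (requires `threshold`).
#' @param threshold Threshold for the fixed method.
#' @param pixel_size,stain,slice_index Metadata forwarded to [binary_mask()].
#' @return A [binary_mask].
#' @export
segment_positive <- function(image, method = c("automatic", "fixed"),
                             threshold = NULL, pixel_size = 1,
                             stain = "vessel_stain", slice_index = 0L) {
  method <- match.arg(method)
  stopifnot(is.matrix(image))
  if (!all(is.finite(image))) stop("image must be finite", call. = FALSE)
  if (method == "fixed") {
    if (is.null(threshold))
      stop("fixed-threshold segmentation requires `threshold`", call. = FALSE)
    px <- image >= threshold
  } else {
    rng <- range(image)
    if (diff(rng) == 0) {
      warning("constant image: automatic threshold undefined, returning empty mask")
      px <- matrix(FALSE, nrow(image), ncol(image))
    } else {
      xn <- (image - rng[1]) / diff(rng)
      th <- EBImage::otsu(xn, range = c(0, 1))
      px <- xn >= th
    }
  }
  binary_mask(px, pixel_size = pixel_size, stain = stain,
              slice_index = slice_index)
}

#' Fill vessel lumens inside ring-shaped wall masks
#'
#' Converts the ring-shaped wall stain into filled vessel masks: the inner
#' area enclosed by a stained wall is counted as vessel.  A morphological
#' closing (disc of radius `closing_radius`) is applied first so that walls
#' broken by gaps of up to twice the radius are rescued before hole filling;
#' with `closing_radius = 0` the operation is pure hole filling.  All holes
#' not connected to the image border are filled.  The output always contains
#' the input.
#'
#' @param wall_mask A [binary_mask] or logical matrix of wall-positive pixels.
#' @param closing_radius Disc radius in px (>= 0; default 2).
#' @return Same container type as the input, with lumens filled.
#' @export
fill_vessel_lumens <- function(wall_mask, closing_radius = 2) {
  stop_if_not_scalar_number(closing_radius, "closing_radius", 0)
  m <- mask_pixels(wall_mask)
  if (!any(m)) return(with_mask_pixels(wall_mask, m))
  cl <- m
  if (closing_radius > 0) {
    k <- EBImage::makeBrush(2 * as.integer(closing_radius) + 1L, "disc")
    cl <- as.matrix(EBImage::closing(m * 1, k)) > 0.5
  }
  filled <- as.matrix(EBImage::fillHull(cl * 1)) > 0.5
  with_mask_pixels(wall_mask, filled | m)
}

#' Segment the epithelium stain
#'
#' Positive segmentation of an epithelium-stained slice, removal of
#' connected components smaller than `min_object_area`, and filling of holes
#' enclosed within epithelial bands.  With `min_object_area = 0` this is
#' [segment_positive()] followed by hole filling.
#'
#' @param image Numeric matrix of finite intensities.
#' @param min_object_area Minimum component area in px^2 to keep.
#' @param method,threshold Passed to [segment_positive()].
#' @param fill_holes Fill enclosed holes (default TRUE).
#' @param pixel_size,slice_index Metadata forwarded to [binary_mask()].
#' @return A [binary_mask] tagged `"epithelium_stain"`.
#' @export
segment_epithelium <- function(image, min_object_area = 0,
                               method = c("automatic", "fixed"),
                               threshold = NULL, fill_holes = TRUE,
                               pixel_size = 1, slice_index = 0L) {
  mask <- segment_positive(image, method = method, threshold = threshold,
                           pixel_size = pixel_size,
                           stain = "epithelium_stain",
                           slice_index = slice_index)
  px <- mask$pixels
  if (min_object_area > 0 && any(px)) {
    comp <- label_components_3d(as.vector(px), c(dim(px), 1L))
    comp <- matrix(comp, nrow(px), ncol(px))
    keep <- which(tabulate(comp[comp > 0L]) >= min_object_area)
    px <- matrix(comp %in% keep & comp > 0L, nrow(px), ncol(px))
  }
  if (fill_holes && any(px))
    px <- as.matrix(EBImage::fillHull(px * 1)) > 0.5
  mask$pixels <- px
  mask
}

#' Per-slice component report
#'
#' Counts 2D connected components and their areas for a list of masks, the
#' standard QC table written next to segmentation output.
#'
#' @param masks List of [binary_mask] objects (or logical matrices).
#' @return Data frame with `slice_index`, `stain`, `n_components`,
#'   `total_area_px`, `total_area_um2`.
#' @export
mask_report <- function(masks) {
  rows <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    px <- mask_pixels(m)
    comp <- label_components_3d(as.vector(px), c(dim(px), 1L))
    ps <- if (inherits(m, "binary_mask")) m$pixel_size else 1
    data.frame(
      slice_index = if (inherits(m, "binary_mask")) m$slice_index else i - 1L,
      stain = if (inherits(m, "binary_mask")) m$stain else NA_character_,
      n_components = max(comp),
      total_area_px = sum(px),
      total_area_um2 = sum(px) * ps^2)
  })
  do.call(rbind, rows)
}
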