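# On-disk formats: multi-page TIFF stacks with JSON sidecar manifests, CSV
# tables for transforms, depths, area records and ground truth.  Nothing is
# inferred from file names; the sidecar records axis order and um scales.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

read_json_file <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Write / read a section series
#'
#' A series is stored as `slices.tif` (multi-page 32-bit float TIFF, one
#' page per slice in order) plus `manifest.json` holding the pixel size,
#' slice thickness, stain schedule, orientation, and each slice's stain and
#' true/estimated rigid transform.  The round trip is lossless up to float
#' precision; a manifest whose stain schedule contradicts its stated period
#' and offset is rejected.
#'
#' @param series A `section_series`.
#' @param dir Directory to write into (created if needed).
#' @return `write_section_series()` the directory path, invisibly;
#'   `read_section_series()` the reconstructed `section_series`.
#' @export
write_section_series <- function(series, dir) {
  stopifnot(inherits(series, "section_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pages <- lapply(series$slices, `[[`, "image")
  suppressWarnings(tiff::writeTIFF(pages, file.path(dir, "slices.tif"),
                                   bits.per.sample = 32L))
  manifest <- list(
    format = "vasc3d_section_series", version = 1L,
    pixel_size_um = series$pixel_size,
    slice_thickness_um = series$slice_thickness,
    epithelium_stain_period = series$epithelium_stain_period,
    stain_period_offset = series$stain_period_offset,
    orientation = series$orientation,
    slices = lapply(series$slices, function(s)
      list(index = s$index, stain = s$stain,
           dx = s$true_transform$dx, dy = s$true_transform$dy,
           theta = s$true_transform$theta)))
  write_json_file(manifest, file.path(dir, "manifest.json"))
  invisible(dir)
}

#' @rdname write_section_series
#' @export
read_section_series <- function(dir) {
  man <- read_json_file(file.path(dir, "manifest.json"))
  pages <- tiff::readTIFF(file.path(dir, "slices.tif"), all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  info <- man$slices
  if (length(pages) != nrow(info))
    stop(sprintf("slice count mismatch: %d pages but %d manifest entries",
                 length(pages), nrow(info)), call. = FALSE)
  shapes <- vapply(pages, function(p) paste(dim(p)[1:2], collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("slice images have inconsistent shapes", call. = FALSE)
  period <- man$epithelium_stain_period
  offset <- man$stain_period_offset
  expected <- ifelse(info$index %% period == offset,
                     "epithelium_stain", "vessel_stain")
  if (!all(info$stain == expected))
    stop("manifest stain schedule is inconsistent with its period/offset",
         call. = FALSE)
  if (!all(info$index == seq_len(nrow(info)) - 1L))
    stop("slice indices must be consecutive from 0", call. = FALSE)
  slices <- lapply(seq_along(pages), function(k) {
    img <- pages[[k]]
    if (length(dim(img)) > 2) img <- img[, , 1]
    list(index = info$index[k], stain = info$stain[k], image = img,
         true_transform = rigid_transform(info$dx[k], info$dy[k],
                                          info$theta[k]),
         pixel_size = man$pixel_size_um)
  })
  structure(list(slices = slices, pixel_size = man$pixel_size_um,
                 slice_thickness = man$slice_thickness_um,
                 epithelium_stain_period = period,
                 stain_period_offset = offset,
                 orientation = man$orientation),
            class = "section_series")
}

#' Write phantom ground truth
#'
#' Components as CSV (`id, x_um, y_um, z_um, true_depth_um, n_voxels`) and
#' the surface-height map as a 32-bit float TIFF in units of mm (scale
#' recorded in the sidecar).
#'
#' @param truth A `phantom_truth`.
#' @param dir Output directory.
#' @return The directory, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  comps <- truth$vessel_components
  names(comps) <- c("id", "x_um", "y_um", "z_um", "true_depth_um", "n_voxels")
  utils::write.csv(comps, file.path(dir, "components.csv"), row.names = FALSE)
  utils::write.csv(truth$crypt_orifices, file.path(dir, "crypt_orifices.csv"),
                   row.names = FALSE)
  suppressWarnings(tiff::writeTIFF(truth$surface_height / 1000,
                                   file.path(dir, "surface_height.tif"),
                                   bits.per.sample = 32L))
  write_json_file(list(surface_height_scale_um = 1000),
                  file.path(dir, "truth.json"))
  invisible(dir)
}

#' Write / read a transform chain as CSV
#'
#' Columns `slice_index` (0-based), `dx`, `dy`, `theta` (absolute transforms
#' into the anchor frame), plus an `anchor` column flagging the anchor slice.
#'
#' @param chain A `transform_chain`.
#' @param path CSV path.
#' @return `write_transform_chain()` the path, invisibly;
#'   `read_transform_chain()` the `transform_chain`.
#' @export
write_transform_chain <- function(chain, path) {
  stopifnot(inherits(chain, "transform_chain"))
  df <- data.frame(
    slice_index = seq_len(chain$n) - 1L,
    dx = vapply(chain$absolute, `[[`, numeric(1), "dx"),
    dy = vapply(chain$absolute, `[[`, numeric(1), "dy"),
    theta = vapply(chain$absolute, `[[`, numeric(1), "theta"),
    anchor = seq_len(chain$n) == chain$anchor)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transform_chain
#' @export
read_transform_chain <- function(path) {
  df <- utils::read.csv(path)
  structure(list(
    absolute = lapply(seq_len(nrow(df)), function(k)
      rigid_transform(df$dx[k], df$dy[k], df$theta[k])),
    anchor = which(df$anchor)[1], n = nrow(df)),
    class = "transform_chain")
}

#' Write / read a labelled volume
#'
#' Each channel as a multi-page TIFF (pages along the depth axis) plus
#' `volume.json` (voxel size, orientation, axis order).
#'
#' @param volume A `labeled_volume`.
#' @param dir Directory.
#' @return `write_volume()` the directory, invisibly; `read_volume()` the
#'   `labeled_volume`.
#' @export
write_volume <- function(volume, dir) {
  stopifnot(inherits(volume, "labeled_volume"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("vessel", "epithelium")) {
    pages <- lapply(seq_len(dim(volume[[ch]])[3]),
                    function(k) volume[[ch]][, , k] * 1)
    tiff::writeTIFF(pages, file.path(dir, paste0(ch, ".tif")),
                    bits.per.sample = 8L)
  }
  write_json_file(list(format = "vasc3d_volume", version = 1L,
                       voxel_size_um = volume$voxel_size,
                       orientation = volume$orientation,
                       depth_axis = volume$depth_axis,
                       axis_order = "x,y,depth"),
                  file.path(dir, "volume.json"))
  invisible(dir)
}

#' @rdname write_volume
#' @export
read_volume <- function(dir) {
  man <- read_json_file(file.path(dir, "volume.json"))
  read_ch <- function(name) {
    pages <- tiff::readTIFF(file.path(dir, paste0(name, ".tif")), all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(FALSE, c(dim(pages[[1]])[1:2], length(pages)))
    for (k in seq_along(pages)) {
      p <- pages[[k]]
      if (length(dim(p)) > 2) p <- p[, , 1]
      arr[, , k] <- p > 0.5
    }
    arr
  }
  structure(list(vessel = read_ch("vessel"), epithelium = read_ch("epithelium"),
                 voxel_size = man$voxel_size_um,
                 orientation = man$orientation,
                 depth_axis = man$depth_axis),
            class = "labeled_volume")
}

#' Write a projection or BLI image
#'
#' Single-page TIFF; binary projections as 0/1, counts normalised by the
#' recorded maximum, intensity images as-is.
#'
#' @param image A `projection`, or a numeric matrix in `[0, 1]`.
#' @param path TIFF path.
#' @return The path, invisibly.
#' @export
write_image <- function(image, path) {
  img <- if (inherits(image, "projection")) {
    if (image$kind == "binary") image$image * 1
    else image$image / max(1, max(image$image))
  } else image
  suppressWarnings(tiff::writeTIFF(clamp01(img), path, bits.per.sample = 16L))
  invisible(path)
}

#' Write / read per-area records
#'
#' @param records Data frame from [area_records()].
#' @param path CSV path.
#' @return `write_area_records()` the path invisibly;
#'   `read_visibility_labels()` a data frame of `area_id, visible` for
#'   [label_visibility()].
#' @export
write_area_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_area_records
#' @export
read_visibility_labels <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("area_id", "visible") %in% names(df)))
    stop("visibility labels CSV needs columns `area_id` and `visible`",
         call. = FALSE)
  df[, c("area_id", "visible")]
}

#' Write the analysis summary as JSON
#'
#' @param summary A `visibility_summary`.
#' @param test An `mwu_result`.
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(summary, test, path) {
  write_json_file(list(
    visibility = unclass(summary),
    mann_whitney = unclass(test)), path)
  invisible(path)
}
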