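# The validation analysis: divide a matched ROI into areas, measure each
# area's nearest-vessel depth, label per-area visibility (manual CSV or the
# virtual-BLI render), compare visible vs invisible depths, and estimate the
# visibility boundary, with an optional correction for small lateral gaps
# between the endoscopic and histological frames.

#' Divide an ROI into analysis areas
#'
#' Splits a rectangular (or line-like) ROI into `n_areas` equal cells along
#' its long axis, the unit of the per-area visibility assessment (the
#' reference protocol used a 0.86 mm line divided into 50 areas, i.e.
#' 17.2 um cells).
#'
#' @param roi Numeric length-4 `c(x0, y0, x1, y1)` in um, `x1 > x0`,
#'   `y1 >= y0`.
#' @param n_areas Number of cells (>= 2).
#' @param pixel_size Optional pixel size in um; when given, rejects an ROI
#'   narrower than `n_areas` pixels.
#' @return An `analysis_grid`: data frame `cells` (`area_id, x0, x1, y0,
#'   y1`), the `roi`, `n_areas` and the `long_axis` (`"x"` or `"y"`).
#' @export
divide_roi <- function(roi, n_areas, pixel_size = NULL) {
  stopifnot(is.numeric(roi), length(roi) == 4)
  n_areas <- as.integer(n_areas)
  if (n_areas < 2L) stop("n_areas must be >= 2", call. = FALSE)
  lx <- roi[3] - roi[1]; ly <- roi[4] - roi[2]
  if (lx < 0 || ly < 0) stop("roi must have x1 >= x0 and y1 >= y0", call. = FALSE)
  long_axis <- if (lx >= ly) "x" else "y"
  len <- max(lx, ly)
  if (len <= 0) stop("roi has zero extent", call. = FALSE)
  if (!is.null(pixel_size) && len / n_areas < pixel_size)
    stop(sprintf("roi long axis (%g um) is narrower than n_areas = %d pixels",
                 len, n_areas), call. = FALSE)
  bk <- seq(0, len, length.out = n_areas + 1L)
  cells <- if (long_axis == "x")
    data.frame(area_id = seq_len(n_areas),
               x0 = roi[1] + bk[-length(bk)], x1 = roi[1] + bk[-1],
               y0 = roi[2], y1 = roi[4])
  else
    data.frame(area_id = seq_len(n_areas),
               x0 = roi[1], x1 = roi[3],
               y0 = roi[2] + bk[-length(bk)], y1 = roi[2] + bk[-1])
  structure(list(cells = cells, roi = roi, n_areas = n_areas,
                 long_axis = long_axis),
            class = "analysis_grid")
}

#' @export
print.analysis_grid <- function(x, ...) {
  cat(sprintf("analysis_grid: %d cells of %.2f um along %s, roi [%g, %g] x [%g, %g] um\n",
              x$n_areas,
              (if (x$long_axis == "x") x$roi[3] - x$roi[1] else x$roi[4] - x$roi[2]) /
                x$n_areas,
              x$long_axis, x$roi[1], x$roi[3], x$roi[2], x$roi[4]))
  invisible(x)
}

# Columns (top-view pixel centres, um) occupied by each vessel component.
component_footprints <- function(field) {
  d <- dim(field$component_labels)
  idx <- which(field$component_labels > 0L)
  if (!length(idx))
    return(data.frame(id = integer(), x = numeric(), y = numeric()))
  ij <- index3_to_ij(idx, d)
  key <- paste(field$component_labels[idx], ij[, 1], ij[, 2])
  keep <- !duplicated(key)
  data.frame(id = field$component_labels[idx][keep],
             x = (ij[keep, 1] - 0.5) * field$voxel_size[1],
             y = (ij[keep, 2] - 0.5) * field$voxel_size[2])
}

#' Nearest-vessel depth per analysis area
#'
#' For every cell, the minimum lumen-centre depth over all vessel components
#' whose top-view footprint intersects the cell, restricted to components no
#' deeper than `max_depth` (vasculature was measured up to 400 um in depth).
#' Cells with no such component are censored (`NA`).
#'
#' @param grid An `analysis_grid`.
#' @param field A `depth_field`.
#' @param max_depth Measurement bound in um (default 400).
#' @return Numeric vector of depths (um), `NA` = censored, ordered by
#'   `area_id`.
#' @export
nearest_vessel_depth <- function(grid, field, max_depth = 400) {
  stopifnot(inherits(grid, "analysis_grid"), inherits(field, "depth_field"))
  fp <- component_footprints(field)
  depths <- field$components$depth[match(fp$id, field$components$id)]
  ok <- !is.na(depths) & depths <= max_depth
  fp <- fp[ok, , drop = FALSE]; depths <- depths[ok]
  vapply(seq_len(grid$n_areas), function(q) {
    cell <- grid$cells[q, ]
    sel <- fp$x >= cell$x0 & fp$x <= cell$x1 &
      fp$y >= cell$y0 & fp$y <= cell$y1
    if (!any(sel)) return(NA_real_)
    min(depths[sel])
  }, numeric(1))
}

#' Label per-area visibility
#'
#' Manual path: a data frame (or CSV-derived) of `area_id, visible` flags is
#' read verbatim (the endoscopist's call per area); the count must match the
#' grid.  Virtual path: a rendered BLI image is thresholded per cell — a
#' cell is visible when the mean contrast (1 - intensity) over its
#' vessel-contributing pixels reaches `contrast_threshold`.
#'
#' @param grid An `analysis_grid`.
#' @param source Either a data frame with columns `area_id` and `visible`
#'   (0/1 or logical), or a numeric BLI image matrix from
#'   [render_virtual_bli()].
#' @param pixel_size Pixel size of the BLI image (um); defaults to its
#'   `pixel_size` attribute.
#' @param contrast_threshold Minimum mean vessel contrast for visibility.
#' @return Logical vector ordered by `area_id`, with attribute
#'   `visibility_source` (`"manual_label"` or `"virtual_bli"`).
#' @export
label_visibility <- function(grid, source, pixel_size = NULL,
                             contrast_threshold = 0.02) {
  stopifnot(inherits(grid, "analysis_grid"))
  if (is.data.frame(source)) {
    if (!all(c("area_id", "visible") %in% names(source)))
      stop("manual labels need columns `area_id` and `visible`", call. = FALSE)
    if (nrow(source) != grid$n_areas)
      stop(sprintf("label count (%d) does not match n_areas (%d)",
                   nrow(source), grid$n_areas), call. = FALSE)
    v <- as.logical(source$visible[order(source$area_id)])
    return(structure(v, visibility_source = "manual_label"))
  }
  stopifnot(is.matrix(source))
  ps <- pixel_size %||% attr(source, "pixel_size")
  if (is.null(ps)) stop("pixel_size required for a BLI image", call. = FALSE)
  ps <- rep(as.numeric(ps), length.out = 2)
  contrast <- 1 - source
  xcent <- (seq_len(nrow(source)) - 0.5) * ps[1]
  ycent <- (seq_len(ncol(source)) - 0.5) * ps[2]
  v <- vapply(seq_len(grid$n_areas), function(q) {
    cell <- grid$cells[q, ]
    ii <- which(xcent >= cell$x0 & xcent <= cell$x1)
    jj <- which(ycent >= cell$y0 & ycent <= cell$y1)
    if (!length(ii) || !length(jj)) return(FALSE)
    cc <- contrast[ii, jj]
    pos <- cc > 1e-9
    any(pos) && mean(cc[pos]) >= contrast_threshold
  }, logical(1))
  structure(v, visibility_source = "virtual_bli")
}

#' Assemble per-area records
#'
#' @param grid An `analysis_grid`.
#' @param nearest_depth Depths from [nearest_vessel_depth()] (`NA` =
#'   censored).
#' @param visible Flags from [label_visibility()].
#' @return Data frame of `area_record`s: `area_id, nearest_depth, censored,
#'   visible, visibility_source, corrected, excluded`.
#' @export
area_records <- function(grid, nearest_depth, visible) {
  stopifnot(inherits(grid, "analysis_grid"),
            length(nearest_depth) == grid$n_areas,
            length(visible) == grid$n_areas)
  data.frame(area_id = grid$cells$area_id,
             nearest_depth = as.numeric(nearest_depth),
             censored = is.na(nearest_depth),
             visible = as.logical(visible),
             visibility_source =
               attr(visible, "visibility_source") %||% "manual_label",
             corrected = FALSE, excluded = FALSE)
}

# Threshold maximising concordance of `visible <=> depth <= t`; used as the
# fallback boundary when visible and invisible depths overlap, and as the
# default discordance threshold for the gap correction.
crossing_threshold <- function(depth, visible) {
  ds <- sort(unique(depth))
  cands <- if (length(ds) > 1) (head(ds, -1) + tail(ds, -1)) / 2
  else ds
  cands <- c(ds[1] - 1e-6, cands, ds[length(ds)] + 1e-6)
  score <- vapply(cands, function(t)
    sum(visible & depth <= t) + sum(!visible & depth > t), numeric(1))
  stats::median(cands[score == max(score)])
}

#' Correct small lateral gaps between the endoscopic and histological frames
#'
#' When the en-face image is overlaid on the section there can be a
#' horizontal gap of a few micrometres, which produces discordant areas: an
#' area called visible whose nearest in-cell vessel is deep, or one called
#' invisible whose nearest vessel is shallow.  For each discordant area this
#' step searches for a vessel component within `lateral_tolerance` um of the
#' cell boundary whose depth resolves the discordance; if found, the area's
#' depth is re-assigned to that component (flagged `corrected`), otherwise
#' the area is flagged `excluded`.  With `lateral_tolerance = 0` records are
#' returned unchanged.  Off by default in the pipeline and never applied
#' silently.
#'
#' @param records Data frame from [area_records()].
#' @param grid The `analysis_grid` the records were measured on.
#' @param field The `depth_field`.
#' @param lateral_tolerance Search tolerance in um (default 0 = no-op).
#' @param threshold Depth (um) separating "shallow" from "deep"; defaults to
#'   the concordance-maximising crossing of the uncorrected records.
#' @param max_depth Measurement bound in um.
#' @return The records with `nearest_depth`, `corrected` and `excluded`
#'   updated; attributes `n_corrected`, `n_excluded`, `threshold`.
#' @export
reconcile_gaps <- function(records, grid, field, lateral_tolerance = 0,
                           threshold = NULL, max_depth = 400) {
  stopifnot(is.data.frame(records), inherits(grid, "analysis_grid"),
            inherits(field, "depth_field"))
  if (lateral_tolerance <= 0) {
    attr(records, "n_corrected") <- 0L
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  use <- !records$censored
  if (is.null(threshold))
    threshold <- crossing_threshold(records$nearest_depth[use],
                                    records$visible[use])
  fp <- component_footprints(field)
  depths <- field$components$depth[match(fp$id, field$components$id)]
  ok <- !is.na(depths) & depths <= max_depth
  fp <- fp[ok, , drop = FALSE]; depths <- depths[ok]
  n_corrected <- 0L; n_excluded <- 0L
  for (q in which(use)) {
    d0 <- records$nearest_depth[q]
    vis <- records$visible[q]
    discordant <- (vis && d0 > threshold) || (!vis && d0 <= threshold)
    if (!discordant) next
    cell <- grid$cells[records$area_id[q] == grid$cells$area_id, ]
    # lateral distance from each component's footprint to the cell rectangle
    ddx <- pmax(cell$x0 - fp$x, fp$x - cell$x1, 0)
    ddy <- pmax(cell$y0 - fp$y, fp$y - cell$y1, 0)
    lat <- sqrt(ddx^2 + ddy^2)
    near <- lat > 0 & lat <= lateral_tolerance
    resolves <- if (vis) depths <= threshold else depths > threshold
    cand <- which(near & resolves)
    if (length(cand)) {
      pick <- cand[which.min(lat[cand])]
      records$nearest_depth[q] <- depths[pick]
      records$corrected[q] <- TRUE
      n_corrected <- n_corrected + 1L
    } else {
      records$excluded[q] <- TRUE
      n_excluded <- n_excluded + 1L
    }
  }
  attr(records, "n_corrected") <- n_corrected
  attr(records, "n_excluded") <- n_excluded
  attr(records, "threshold") <- threshold
  records
}

#' Summarise visible versus invisible vessel depths
#'
#' Medians and (min, max) ranges per group over non-censored, non-excluded
#' records, and the visibility-boundary estimate: the midpoint between the
#' maximum visible depth and the minimum invisible depth when those are
#' ordered (the reasoning that put the boundary near 80 um); when the groups
#' overlap, the concordance-maximising crossing of the empirical visibility
#' fraction is reported with a warning.
#'
#' @param records Data frame from [area_records()] (optionally gap-corrected).
#' @return A `visibility_summary`: `median_visible`, `median_invisible`,
#'   `range_visible`, `range_invisible`, `boundary_estimate`, `n_visible`,
#'   `n_invisible`, `n_censored`, `n_corrected`, `n_excluded`,
#'   `boundary_method`.
#' @export
summarize_visibility <- function(records) {
  stopifnot(is.data.frame(records))
  use <- !records$censored & !records$excluded
  vis <- records$nearest_depth[use & records$visible]
  inv <- records$nearest_depth[use & !records$visible]
  if (!length(vis)) stop("no visible areas with a measurable vessel", call. = FALSE)
  if (!length(inv)) stop("no invisible areas with a measurable vessel", call. = FALSE)
  maxv <- max(vis); mini <- min(inv)
  if (maxv <= mini) {
    boundary <- (maxv + mini) / 2
    method <- "midpoint"
  } else {
    warning("visible and invisible depth ranges overlap; ",
            "boundary estimated from the visibility-fraction crossing")
    boundary <- crossing_threshold(c(vis, inv),
                                   rep(c(TRUE, FALSE), c(length(vis), length(inv))))
    method <- "crossing"
  }
  structure(list(
    median_visible = stats::median(vis),
    median_invisible = stats::median(inv),
    range_visible = range(vis),
    range_invisible = range(inv),
    boundary_estimate = boundary,
    boundary_method = method,
    n_visible = length(vis), n_invisible = length(inv),
    n_censored = sum(records$censored),
    n_corrected = sum(records$corrected),
    n_excluded = sum(records$excluded)),
    class = "visibility_summary")
}

#' @export
print.visibility_summary <- function(x, ...) {
  cat(sprintf("visible:   median %.1f um (%.1f-%.1f um), n = %d\n",
              x$median_visible, x$range_visible[1], x$range_visible[2],
              x$n_visible))
  cat(sprintf("invisible: median %.1f um (%.1f-%.1f um), n = %d\n",
              x$median_invisible, x$range_invisible[1], x$range_invisible[2],
              x$n_invisible))
  cat(sprintf("visibility boundary ~ %.1f um (%s)", x$boundary_estimate,
              x$boundary_method))
  if (x$n_censored + x$n_excluded + x$n_corrected > 0)
    cat(sprintf("; %d censored, %d corrected, %d excluded",
                x$n_censored, x$n_corrected, x$n_excluded))
  cat("\n")
  invisible(x)
}

#' Run the full visibility analysis on a depth field
#'
#' Measures per-area nearest-vessel depths, applies the visibility labels,
#' optionally reconciles lateral gaps, summarises both groups and runs the
#' Mann-Whitney U test on visible versus invisible depths.
#'
#' @param field A `depth_field`.
#' @param grid An `analysis_grid`.
#' @param visible Labels from [label_visibility()].
#' @param max_depth Measurement bound in um.
#' @param reconcile Apply [reconcile_gaps()] (default FALSE).
#' @param lateral_tolerance,threshold Passed to [reconcile_gaps()].
#' @return A `visibility_analysis`: list with `records`, `summary`, `test`.
#' @export
analyze_visibility <- function(field, grid, visible, max_depth = 400,
                               reconcile = FALSE, lateral_tolerance = 0,
                               threshold = NULL) {
  depths <- nearest_vessel_depth(grid, field, max_depth)
  records <- area_records(grid, depths, visible)
  if (reconcile)
    records <- reconcile_gaps(records, grid, field,
                              lateral_tolerance = lateral_tolerance,
                              threshold = threshold, max_depth = max_depth)
  summary <- summarize_visibility(records)
  use <- !records$censored & !records$excluded
  test <- mann_whitney_u(records$nearest_depth[use & records$visible],
                         records$nearest_depth[use & !records$visible])
  structure(list(records = records, summary = summary, test = test),
            class = "visibility_analysis")
}

#' @export
print.visibility_analysis <- function(x, ...) {
  print(x$summary)
  print(x$test)
  invisible(x)
}
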