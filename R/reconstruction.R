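# Stacking aligned masks into an anisotropic labelled volume, extracting the
# mucosal surface, per-vessel depth measurement, depth-windowed projections
# and cross-sections.

#' Stack an aligned section series into a labelled volume
#'
#' Segments each slice (unless masks are supplied), aligns all masks into
#' the anchor frame with the transform chain, pairs every slice position
#' with its nearest same-stain slice (epithelium masks are propagated
#' between the periodically stained slices by nearest-slice copy), and
#' stacks the result into a two-channel anisotropic volume.  The depth axis
#' is always the third array axis: for vertical sections the in-slice
#' vertical axis, for horizontal sections the stack axis.
#'
#' @param series A `section_series`.
#' @param chain A `transform_chain` from [register_series()] (identity
#'   transforms are used if `NULL`).
#' @param vessel_masks,epithelium_masks Optional pre-computed lists of
#'   [binary_mask] (one per slice of that stain, in slice order).  When
#'   `NULL`, vessel slices are segmented with a fixed threshold and lumens
#'   filled with [fill_vessel_lumens()]; epithelium slices with
#'   [segment_epithelium()].
#' @param threshold Fixed segmentation threshold.
#' @param closing_radius Broken-wall rescue radius for vessel masks.
#' @param min_object_area Small-object removal for epithelium masks.
#' @return A `labeled_volume`: logical arrays `epithelium` and `vessel`,
#'   `voxel_size` (um), `orientation`, `depth_axis = 3`.
#' @export
stack_series <- function(series, chain = NULL, vessel_masks = NULL,
                         epithelium_masks = NULL, threshold = 0.5,
                         closing_radius = 2, min_object_area = 0) {
  stopifnot(inherits(series, "section_series"))
  n <- length(series$slices)
  stains <- vapply(series$slices, `[[`, character(1), "stain")
  dims2 <- dim(series$slices[[1]]$image)
  if (!is.null(chain) && chain$n != n)
    stop("transform chain length does not match the series", call. = FALSE)

  get_mask <- function(k) {
    s <- series$slices[[k]]
    if (!all(dim(s$image) == dims2))
      stop("slice images have inconsistent shapes", call. = FALSE)
    if (s$stain == "vessel_stain") {
      if (!is.null(vessel_masks)) {
        m <- vessel_masks[[sum(stains[seq_len(k)] == "vessel_stain")]]
        mask_pixels(m)
      } else {
        m <- segment_positive(s$image, "fixed", threshold,
                              pixel_size = s$pixel_size,
                              stain = "vessel_stain", slice_index = s$index)
        mask_pixels(fill_vessel_lumens(m, closing_radius))
      }
    } else {
      if (!is.null(epithelium_masks)) {
        m <- epithelium_masks[[sum(stains[seq_len(k)] == "epithelium_stain")]]
        mask_pixels(m)
      } else {
        mask_pixels(segment_epithelium(s$image, min_object_area,
                                       method = "fixed",
                                       threshold = threshold,
                                       pixel_size = s$pixel_size,
                                       slice_index = s$index))
      }
    }
  }

  aligned <- vector("list", n)
  for (k in seq_len(n)) {
    m <- get_mask(k)
    if (!is.null(chain) && !is_identity_transform(chain$absolute[[k]]))
      m <- apply_transform(m, chain$absolute[[k]], "nearest",
                           background = FALSE)
    aligned[[k]] <- m
  }

  # nearest same-stain propagation so both channels exist at every position
  nearest_of <- function(idx) {
    vapply(seq_len(n), function(k) idx[which.min(abs(idx - k))], integer(1))
  }
  vi <- which(stains == "vessel_stain")
  ei <- which(stains == "epithelium_stain")
  if (!length(vi)) stop("series contains no vessel-stained slices", call. = FALSE)
  if (!length(ei)) stop("series contains no epithelium-stained slices", call. = FALSE)
  vsrc <- nearest_of(vi)
  esrc <- nearest_of(ei)

  vertical <- series$orientation == "vertical_section"
  ps <- series$pixel_size; th <- series$slice_thickness
  if (vertical) {
    dims <- c(dims2[1], n, dims2[2])
    voxel <- c(ps, th, ps)
  } else {
    dims <- c(dims2[1], dims2[2], n)
    voxel <- c(ps, ps, th)
  }
  vessel <- array(FALSE, dims)
  epithelium <- array(FALSE, dims)
  for (k in seq_len(n)) {
    if (vertical) {
      vessel[, k, ] <- aligned[[vsrc[k]]]
      epithelium[, k, ] <- aligned[[esrc[k]]]
    } else {
      vessel[, , k] <- aligned[[vsrc[k]]]
      epithelium[, , k] <- aligned[[esrc[k]]]
    }
  }
  structure(list(epithelium = epithelium, vessel = vessel,
                 voxel_size = voxel, orientation = series$orientation,
                 depth_axis = 3L),
            class = "labeled_volume")
}

#' Convert a phantom tissue volume to a labelled two-channel volume
#'
#' Direct conversion of ground-truth labels into the reconstruction
#' container (vessel = wall or lumen; epithelium), bypassing sectioning,
#' segmentation and registration.  Used for controlled experiments where the
#' imaging chain is not under study.
#'
#' @param volume A `tissue_volume`.
#' @return A `labeled_volume`.
#' @export
as_labeled_volume <- function(volume) {
  stopifnot(inherits(volume, "tissue_volume"))
  structure(list(
    epithelium = volume$labels == .labels[["epithelium"]],
    vessel = volume$labels == .labels[["vessel_wall"]] |
      volume$labels == .labels[["vessel_lumen"]],
    voxel_size = volume$voxel_size, orientation = volume$orientation,
    depth_axis = 3L),
    class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  d <- dim(x$vessel)
  cat(sprintf(paste0("labeled_volume: %d x %d x %d voxels at %g x %g x %g um ",
                     "(%s)\n  vessel voxels: %d, epithelium voxels: %d\n"),
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3], x$orientation, sum(x$vessel),
              sum(x$epithelium)))
  invisible(x)
}

#' Extract the mucosal surface
#'
#' For every column along the depth axis, the surface is the position of the
#' first foreground voxel (epithelium or vessel) from the luminal side,
#' converted to um (the top face of that voxel), followed by median
#' smoothing (separable running median of the given window, which removes
#' narrow crypt-orifice dips).  Columns with no tissue are marked invalid.
#'
#' @param volume A `labeled_volume`.
#' @param smoothing_window Median window in px (odd; `<= 1` disables).
#' @return A `surface_map`: `height` matrix (um, `NA` where invalid) and
#'   logical `valid` footprint.
#' @export
extract_surface <- function(volume, smoothing_window = 25) {
  stopifnot(inherits(volume, "labeled_volume"))
  fg <- volume$epithelium | volume$vessel
  if (!any(fg)) stop("volume contains no tissue", call. = FALSE)
  d <- dim(fg)
  m <- matrix(fg, d[1] * d[2], d[3])
  first <- rep(NA_integer_, nrow(m))
  remaining <- seq_len(nrow(m))
  for (k in seq_len(d[3])) {
    hit <- m[remaining, k]
    if (any(hit)) {
      first[remaining[hit]] <- k
      remaining <- remaining[!hit]
    }
    if (!length(remaining)) break
  }
  height <- matrix((first - 1L) * volume$voxel_size[3], d[1], d[2])
  valid <- !is.na(height)
  height <- median_smooth_2d(height, smoothing_window)
  structure(list(height = height, valid = valid,
                 voxel_size = volume$voxel_size),
            class = "surface_map")
}

#' @export
print.surface_map <- function(x, ...) {
  cat(sprintf("surface_map: %d x %d columns, %d valid, height %.1f-%.1f um\n",
              nrow(x$height), ncol(x$height), sum(x$valid),
              min(x$height, na.rm = TRUE), max(x$height, na.rm = TRUE)))
  invisible(x)
}

#' Compute per-voxel and per-component vessel depths
#'
#' Depth below the mucosal surface for every vessel voxel, and the
#' lumen-centre depth of every 3D 26-connected vessel component (depth at
#' the component centroid, anisotropy respected; the nearest defined voxel
#' is used when the centroid column is invalid).  `mode = "axis"` measures
#' along the depth axis (voxel depth-coordinate minus the surface height in
#' its column, how a pathologist reads a vertical section); `"euclidean"`
#' measures distance to the nearest surface point (anisotropic chamfer
#' propagation seeded at the surface).  The two agree exactly on a flat
#' surface.
#'
#' @param volume A `labeled_volume`.
#' @param surface A `surface_map` from [extract_surface()].
#' @param mode `"axis"` (default) or `"euclidean"`.
#' @return A `depth_field`: `depth` (3D array, um, `NA` off vessels),
#'   `component_labels` (3D integer array), `components` data frame
#'   (`id, x, y, z, depth, n_voxels`), `mode`, `n_excluded` (vessel voxels
#'   in invalid columns), `voxel_size`.
#' @export
compute_depth_field <- function(volume, surface, mode = c("axis", "euclidean")) {
  stopifnot(inherits(volume, "labeled_volume"),
            inherits(surface, "surface_map"))
  mode <- match.arg(mode)
  d <- dim(volume$vessel)
  vz <- volume$voxel_size[3]
  depth <- array(NA_real_, d)
  n_excluded <- 0L

  if (mode == "axis") {
    idx <- which(volume$vessel)
    if (length(idx)) {
      ij <- index3_to_ij(idx, d)
      kk <- index3_to_k(idx, d)
      h <- surface$height[cbind(ij[, 1], ij[, 2])]
      val <- !is.na(h)
      n_excluded <- sum(!val)
      depth[idx[val]] <- pmax((kk[val] - 0.5) * vz - h[val], 0)
    }
  } else {
    # chamfer propagation from sub-voxel surface seeds
    init <- array(Inf, d)
    hh <- surface$height
    ok <- which(!is.na(hh))
    if (length(ok)) {
      ij <- cbind((ok - 1L) %% d[1] + 1L, (ok - 1L) %/% d[1] + 1L)
      k0 <- pmin(floor(hh[ok] / vz) + 1L, d[3])
      init[cbind(ij, k0)] <- pmin(init[cbind(ij, k0)],
                                  pmax((k0 - 0.5) * vz - hh[ok], 0))
    }
    cd <- chamfer_distance_3d(as.vector(init), d, volume$voxel_size)
    cd <- array(cd, d)
    depth[volume$vessel] <- cd[volume$vessel]
    bad <- volume$vessel & !is.finite(depth)
    n_excluded <- sum(bad, na.rm = TRUE)
    depth[bad] <- NA_real_
  }

  comp <- label_components_3d(as.vector(volume$vessel), d)
  comps <- depth_component_table(comp, depth, surface, volume$voxel_size, mode)
  structure(list(depth = depth, component_labels = comp, components = comps,
                 mode = mode, n_excluded = n_excluded,
                 voxel_size = volume$voxel_size),
            class = "depth_field")
}

depth_component_table <- function(comp, depth, surface, voxel_size, mode) {
  idx <- which(comp > 0L)
  if (!length(idx))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), depth = numeric(), n_voxels = integer()))
  d <- dim(comp)
  cl <- comp[idx]
  ij <- index3_to_ij(idx, d)
  kk <- index3_to_k(idx, d)
  xs <- (ij[, 1] - 0.5) * voxel_size[1]
  ys <- (ij[, 2] - 0.5) * voxel_size[2]
  zs <- (kk - 0.5) * voxel_size[3]
  sums <- rowsum(cbind(xs, ys, zs), cl)
  ids <- sort(unique(cl))
  cnt <- tabulate(cl, nbins = max(cl))[ids]
  cen <- sums / cnt
  i_n <- pmin(pmax(round(cen[, 1] / voxel_size[1] + 0.5), 1L), d[1])
  j_n <- pmin(pmax(round(cen[, 2] / voxel_size[2] + 0.5), 1L), d[2])
  cdep <- numeric(length(ids))
  for (q in seq_along(ids)) {
    h <- surface$height[i_n[q], j_n[q]]
    if (mode == "axis" && !is.na(h)) {
      cdep[q] <- max(cen[q, 3] - h, 0)
    } else {
      # nearest defined voxel of the component to its centroid
      sel <- cl == ids[q]
      dv <- depth[idx[sel]]
      dd <- (xs[sel] - cen[q, 1])^2 + (ys[sel] - cen[q, 2])^2 +
        (zs[sel] - cen[q, 3])^2
      dd[is.na(dv)] <- Inf
      cdep[q] <- if (all(is.infinite(dd))) NA_real_ else dv[which.min(dd)]
    }
  }
  data.frame(id = ids, x = cen[, 1], y = cen[, 2], z = cen[, 3],
             depth = cdep, n_voxels = cnt)
}

#' @export
print.depth_field <- function(x, ...) {
  cat(sprintf(paste0("depth_field (%s mode): %d components, depths ",
                     "%.1f-%.1f um, %d voxels excluded\n"), x$mode,
              nrow(x$components),
              if (nrow(x$components)) min(x$components$depth, na.rm = TRUE) else NA,
              if (nrow(x$components)) max(x$components$depth, na.rm = TRUE) else NA,
              x$n_excluded))
  invisible(x)
}

#' Depth-windowed top-view projection
#'
#' En-face projection of all vessel voxels no deeper than `window` um below
#' the mucosal surface — the thin-slice microvasculature images
#' (conventionally rendered at 50, 100 and 150 um).  Projections nest:
#' a smaller window is always a pixelwise subset of a larger one.
#'
#' @param field A `depth_field`.
#' @param window Depth window in um (> 0).
#' @param kind `"binary"` (any vessel voxel in the column) or `"count"`
#'   (number of such voxels per column).
#' @return A `projection`: `image` matrix over the two lateral axes,
#'   `window`, `kind`, `pixel_size`.
#' @export
depth_window_projection <- function(field, window, kind = c("binary", "count")) {
  stopifnot(inherits(field, "depth_field"))
  kind <- match.arg(kind)
  stop_if_not_scalar_number(window, "window", 0, strict_min = TRUE)
  d <- dim(field$depth)
  m <- matrix(!is.na(field$depth) & field$depth <= window, d[1] * d[2], d[3])
  cnt <- matrix(rowSums(m), d[1], d[2])
  img <- if (kind == "binary") cnt > 0L else cnt
  structure(list(image = img, window = window, kind = kind,
                 pixel_size = field$voxel_size[1:2]),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("projection: %s, window %g um, %d positive px\n",
              x$kind, x$window, sum(x$image > 0)))
  invisible(x)
}

#' Cross-sectional view along a top-view polyline
#'
#' Samples the volume along a polyline drawn in top-view coordinates and
#' returns a depth-by-arc-length image of both channels (0 = background,
#' 1 = epithelium, 2 = vessel; vessel over epithelium).  With
#' `thickness > 1` px the section is the union over perpendicular offsets.
#'
#' @param volume A `labeled_volume`.
#' @param line Two-column matrix of polyline vertices (um, lateral axes).
#' @param thickness Section thickness in px (odd union of offsets).
#' @return Integer matrix, rows = depth voxels, columns = arc-length samples;
#'   attributes `arc_step` (um) and `depth_step` (um).
#' @export
cross_section <- function(volume, line, thickness = 1) {
  stopifnot(inherits(volume, "labeled_volume"), is.matrix(line),
            ncol(line) == 2, nrow(line) >= 2)
  seg <- diff(line)
  seglen <- sqrt(rowSums(seg^2))
  if (sum(seglen) <= 0) stop("degenerate (zero-length) line", call. = FALSE)
  d <- dim(volume$vessel)
  step <- min(volume$voxel_size[1:2])
  pts <- NULL; nrm <- NULL
  for (s in seq_len(nrow(seg))) {
    if (seglen[s] == 0) next
    nst <- max(2L, ceiling(seglen[s] / step) + 1L)
    tt <- seq(0, 1, length.out = nst)
    if (s > 1) tt <- tt[-1]
    p <- cbind(line[s, 1] + tt * seg[s, 1], line[s, 2] + tt * seg[s, 2])
    u <- seg[s, ] / seglen[s]
    pts <- rbind(pts, p)
    nrm <- rbind(nrm, matrix(c(-u[2], u[1]), nrow(p), 2, byrow = TRUE))
  }
  offs <- (seq_len(max(1L, as.integer(thickness))) -
             (as.integer(thickness) + 1) / 2) * step
  out <- matrix(0L, d[3], nrow(pts))
  for (o in offs) {
    q <- pts + o * nrm
    i <- round(q[, 1] / volume$voxel_size[1] + 0.5)
    j <- round(q[, 2] / volume$voxel_size[2] + 0.5)
    ok <- i >= 1 & i <= d[1] & j >= 1 & j <= d[2]
    for (s in which(ok)) {
      ep <- volume$epithelium[i[s], j[s], ]
      ve <- volume$vessel[i[s], j[s], ]
      col <- pmax(out[, s], ifelse(ve, 2L, ifelse(ep, 1L, 0L)))
      out[, s] <- col
    }
  }
  structure(out, arc_step = step, depth_step = volume$voxel_size[3])
}
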