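# Synthetic colonic-mucosa phantom: labelled 3D volume, virtual sectioning
# into stained serial slices, and a virtual magnifying-BLI top view.

#' Build a synthetic mucosa volume with ground truth
#'
#' Generates a labelled 3D tissue volume (background / epithelium / stroma /
#' vessel wall / vessel lumen / extravasation) together with exact ground
#' truth: the generative surface-height map, every 3D vessel component's
#' lumen-centre position and true depth below the mucosal surface, and the
#' crypt orifice positions.  Deterministic given `spec$rng_seed`.
#'
#' Normal tissue places capillary rings around a regular hexagonal crypt
#' lattice (the honeycomb pattern of normal mucosa seen en face); adenoma and
#' carcinoma perturb crypt positions and radii by `crypt_distortion` and
#' scale vessel calibres up; carcinoma additionally seeds extravasated
#' erythrocyte blobs.  Vessels are tube primitives transverse to the slicing
#' plane, so every 2D vessel cross-section is a closed ring whose lumen is
#' enclosed by wall (the wall thickness is required to exceed the in-plane
#' voxel diagonal).
#'
#' @param spec A [phantom_spec].
#' @return A list with elements `volume` (a `tissue_volume`: `labels` 3D
#'   integer array, `voxel_size`, `orientation`) and `truth` (a
#'   `phantom_truth`: `surface_height` um map, `vessel_components` data frame
#'   with `id, x, y, z, true_depth, n_voxels`, `crypt_orifices`, and the 3D
#'   `component_labels` array).
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  with_seed(spec$rng_seed, build_phantom_impl(spec))
}

build_phantom_impl <- function(spec) {
  nx <- spec$volume_extent[1]; ny <- spec$volume_extent[2]
  nz <- spec$volume_extent[3]
  vx <- spec$voxel_size[1]; vy <- spec$voxel_size[2]; vz <- spec$voxel_size[3]
  xc <- (seq_len(nx) - 0.5) * vx
  yc <- (seq_len(ny) - 0.5) * vy
  zc <- (seq_len(nz) - 0.5) * vz
  Zext <- nz * vz

  # generative mucosal surface height (um), varying along x when undulated
  hvec <- spec$surface_height +
    spec$surface_amplitude * sin(2 * pi * xc / spec$surface_period)
  hmat <- matrix(hvec, nx, ny)

  # tissue footprint: a glass margin surrounds the block inside each slice
  # frame (lateral in-slice axes; for vertical sections also below the block)
  fm <- spec$footprint_margin
  vertical <- spec$orientation == "vertical_section"
  fp_x <- xc >= fm & xc <= nx * vx - fm
  fp_y <- if (vertical) rep(TRUE, ny) else (yc >= fm & yc <= ny * vy - fm)
  fp <- outer(fp_x, fp_y, "&")
  z_bottom <- if (vertical) Zext - fm else Zext

  labels <- array(.labels[["background"]], dim = c(nx, ny, nz))
  lin <- spec$epithelium_lining
  for (k in seq_len(nz)) {
    if (zc[k] >= z_bottom) break
    below <- hmat < zc[k] & fp
    labels[, , k][below] <- .labels[["stroma"]]
    lining <- below & zc[k] <= hmat + lin
    labels[, , k][lining] <- .labels[["epithelium"]]
  }

  # crypt gland lattice (hexagonal), perturbed for neoplastic classes
  crypts <- place_crypts(spec, nx * vx, ny * vy, vertical)
  r_lumen <- pmax(crypts$radius - spec$crypt_wall_thickness, 2)
  for (ci in seq_len(nrow(crypts))) {
    cx <- crypts$x[ci]; cy <- crypts$y[ci]
    r_c <- crypts$radius[ci]; r_l <- r_lumen[ci]
    bbx <- which(abs(xc - cx) <= r_c + vx)
    bby <- which(abs(yc - cy) <= r_c + vy)
    if (!length(bbx) || !length(bby)) next
    rho <- sqrt(outer((xc[bbx] - cx)^2, (yc[bby] - cy)^2, "+"))
    hloc <- hmat[bbx, bby, drop = FALSE]
    h0 <- spec$surface_height +
      spec$surface_amplitude * sin(2 * pi * cx / spec$surface_period)
    bottom <- h0 + spec$crypt_depth_fraction * (Zext - h0)
    wall <- rho <= r_c & rho > r_l
    lum <- rho <= r_l
    for (k in seq_len(nz)) {
      if (zc[k] <= min(hloc)) next
      inz <- zc[k] > hloc
      if (zc[k] <= bottom) {
        sl <- labels[bbx, bby, k]
        sl[wall & inz] <- .labels[["epithelium"]]
        sl[lum & inz] <- .labels[["background"]]  # open crypt lumen
        labels[bbx, bby, k] <- sl
      } else if (zc[k] <= bottom + spec$crypt_wall_thickness) {
        sl <- labels[bbx, bby, k]
        sl[(wall | lum) & inz] <- .labels[["epithelium"]]  # gland base
        labels[bbx, bby, k] <- sl
      } else break
    }
  }

  labels <- draw_vessels(labels, spec, crypts, xc, yc, zc, hmat)

  if (spec$extravasation_count > 0L)
    labels <- draw_extravasation(labels, spec, xc, yc, zc, hmat)

  # ground truth from the realized labels: 3D 26-connected vessel components
  vm <- labels == .labels[["vessel_wall"]] | labels == .labels[["vessel_lumen"]]
  comp <- label_components_3d(as.vector(vm), dim(labels))
  comps <- component_table(comp, labels, spec$voxel_size, hmat)

  volume <- structure(list(labels = labels, voxel_size = spec$voxel_size,
                           orientation = spec$orientation),
                      class = "tissue_volume")
  orifices <- data.frame(x = crypts$x, y = crypts$y, radius = r_lumen)
  truth <- structure(list(surface_height = hmat,
                          vessel_components = comps,
                          crypt_orifices = orifices,
                          component_labels = comp),
                     class = "phantom_truth")
  list(volume = volume, truth = truth)
}

# Hexagonal crypt lattice within the footprint; degenerate pitches give 0 or
# 1 crypt.  Errors only when the footprint cannot hold a single crypt.
place_crypts <- function(spec, Xext, Yext, vertical) {
  r0 <- spec$crypt_radius
  fm <- spec$footprint_margin
  # crypts (and the capillary rings around them) must stay inside the block
  ring_reach <- r0 + 10 + spec$vessel_radius_mean +
    spec$vessel_wall_thickness + 4
  mx <- fm + ring_reach
  my <- (if (vertical) 0 else fm) + ring_reach
  pitch <- spec$crypt_pitch
  safe_seq <- function(from, to, by)
    if (to < from) numeric(0) else seq(from, to, by = by)
  ys <- safe_seq(my, Yext - my, pitch * sqrt(3) / 2)
  centers <- NULL
  if (length(ys)) {
    for (ri in seq_along(ys)) {
      off <- if (ri %% 2L == 0L) pitch / 2 else 0
      xs <- safe_seq(mx + off, Xext - mx, pitch)
      if (length(xs))
        centers <- rbind(centers, cbind(x = xs, y = ys[ri]))
    }
  }
  if (is.null(centers)) {
    # the controlled parallel layout carries no glands unless a lattice fits
    if (spec$vessel_layout == "parallel")
      return(data.frame(x = numeric(), y = numeric(), radius = numeric()))
    # honeycomb: fall back to a single central crypt when one fits in the
    # slice plane (clipping along the stack axis is harmless)
    fits <- if (vertical) Xext - 2 * fm >= 2 * r0
    else Xext - 2 * fm >= 2 * r0 && Yext - 2 * fm >= 2 * r0
    if (fits) {
      centers <- cbind(x = Xext / 2, y = Yext / 2)
    } else {
      stop(sprintf(paste0("volume footprint %.0f x %.0f um is too small to ",
                          "hold a single crypt of radius %.0f um"),
                   Xext, Yext, r0), call. = FALSE)
    }
  }
  d <- spec$crypt_distortion
  n <- nrow(centers)
  jx <- d * 0.25 * pitch * stats::runif(n, -1, 1)
  jy <- d * 0.25 * pitch * stats::runif(n, -1, 1)
  radius <- r0 * (1 + d * stats::runif(n, -0.4, 0.4))
  data.frame(x = pmin(pmax(centers[, "x"] + jx, mx), Xext - mx),
             y = pmin(pmax(centers[, "y"] + jy, my), Yext - my),
             radius = radius)
}

draw_vessels <- function(labels, spec, crypts, xc, yc, zc, hmat) {
  wl <- .labels[["vessel_wall"]]; lu <- .labels[["vessel_lumen"]]
  w <- spec$vessel_wall_thickness
  vscale <- 1 + 0.8 * spec$crypt_distortion
  lo <- spec$vessel_depth_range[1]; hi <- spec$vessel_depth_range[2]
  nx <- length(xc); ny <- length(yc); nz <- length(zc)

  draw_torus <- function(labels, cx, cy, z0, R, r) {
    bbx <- which(abs(xc - cx) <= R + r + w + 2 * spec$voxel_size[1])
    bby <- which(abs(yc - cy) <= R + r + w + 2 * spec$voxel_size[2])
    bbz <- which(abs(zc - z0) <= r + w + 2 * spec$voxel_size[3])
    if (!length(bbx) || !length(bby) || !length(bbz)) return(labels)
    rho <- sqrt(outer((xc[bbx] - cx)^2, (yc[bby] - cy)^2, "+"))
    for (k in bbz) {
      f <- sqrt((rho - R)^2 + (zc[k] - z0)^2)
      sl <- labels[bbx, bby, k]
      sl[f >= r & f < r + w & sl != lu] <- wl
      sl[f < r] <- lu
      labels[bbx, bby, k] <- sl
    }
    labels
  }

  if (spec$vessel_layout == "honeycomb") {
    V <- spec$vessels_per_crypt
    for (ci in seq_len(nrow(crypts))) {
      h0 <- spec$surface_height +
        spec$surface_amplitude * sin(2 * pi * crypts$x[ci] / spec$surface_period)
      for (v in seq_len(V)) {
        # pericryptal rings widen slightly with depth, as the plexus does;
        # stratified depths keep rings of one crypt well separated
        R <- crypts$radius[ci] + 10 + (v - 1) * 6
        d <- lo + (v - 1) / V * (hi - lo) + stats::runif(1) * (hi - lo) / V
        r <- max(1.2, stats::rnorm(1, spec$vessel_radius_mean * vscale,
                                   spec$vessel_radius_sd))
        labels <- draw_torus(labels, crypts$x[ci], crypts$y[ci], h0 + d, R, r)
      }
    }
  } else if (spec$orientation == "vertical_section") {
    # straight tubes along the stack axis (y), one lateral position each
    marg <- spec$footprint_margin + spec$vessel_radius_mean + w +
      2 * spec$voxel_size[1]
    xs <- seq(spec$vessel_spacing / 2, nx * spec$voxel_size[1],
              by = spec$vessel_spacing)
    xs <- xs[xs >= marg & xs <= nx * spec$voxel_size[1] - marg]
    for (x0 in xs) {
      d <- stats::runif(1, lo, hi)
      r <- max(1.2, stats::rnorm(1, spec$vessel_radius_mean * vscale,
                                 spec$vessel_radius_sd))
      h0 <- spec$surface_height +
        spec$surface_amplitude * sin(2 * pi * x0 / spec$surface_period)
      z0 <- h0 + d
      bbx <- which(abs(xc - x0) <= r + w + 2 * spec$voxel_size[1])
      bbz <- which(abs(zc - z0) <= r + w + 2 * spec$voxel_size[3])
      if (!length(bbx) || !length(bbz)) next
      f <- sqrt(outer((xc[bbx] - x0)^2, (zc[bbz] - z0)^2, "+"))
      wall2 <- f >= r & f < r + w
      lum2 <- f < r
      sub <- labels[bbx, , bbz, drop = FALSE]
      wall_a <- aperm(array(wall2, c(length(bbx), length(bbz), ny)), c(1, 3, 2))
      lum_a <- aperm(array(lum2, c(length(bbx), length(bbz), ny)), c(1, 3, 2))
      sub[wall_a & sub != lu] <- wl
      sub[lum_a] <- lu
      labels[bbx, , bbz] <- sub
    }
  } else {
    # horizontal sectioning: vertical tube segments along the depth axis
    marg <- spec$footprint_margin + spec$vessel_radius_mean + w +
      2 * spec$voxel_size[1]
    xs <- seq(spec$vessel_spacing / 2, nx * spec$voxel_size[1],
              by = spec$vessel_spacing)
    xs <- xs[xs >= marg & xs <= nx * spec$voxel_size[1] - marg]
    ys <- seq(spec$vessel_spacing / 2, ny * spec$voxel_size[2],
              by = spec$vessel_spacing)
    ys <- ys[ys >= marg & ys <= ny * spec$voxel_size[2] - marg]
    grid <- expand.grid(x = xs, y = ys)
    for (gi in seq_len(nrow(grid))) {
      d <- stats::runif(1, lo, hi)
      r <- max(1.2, stats::rnorm(1, spec$vessel_radius_mean * vscale,
                                 spec$vessel_radius_sd))
      x0 <- grid$x[gi]; y0 <- grid$y[gi]
      h0 <- spec$surface_height +
        spec$surface_amplitude * sin(2 * pi * x0 / spec$surface_period)
      zlo <- max(h0 + d - spec$vessel_segment_length / 2, h0 + 2)
      zhi <- min(h0 + d + spec$vessel_segment_length / 2,
                 nz * spec$voxel_size[3] - 2)
      if (zhi <= zlo) next
      bbx <- which(abs(xc - x0) <= r + w + 2 * spec$voxel_size[1])
      bby <- which(abs(yc - y0) <= r + w + 2 * spec$voxel_size[2])
      bbz <- which(zc >= zlo - (r + w) & zc <= zhi + (r + w))
      if (!length(bbx) || !length(bby) || !length(bbz)) next
      rho <- sqrt(outer((xc[bbx] - x0)^2, (yc[bby] - y0)^2, "+"))
      for (k in bbz) {
        # distance to the capped axial segment
        dz <- max(0, zlo - zc[k], zc[k] - zhi)
        f <- sqrt(rho^2 + dz^2)
        sl <- labels[bbx, bby, k]
        sl[f >= r & f < r + w & sl != lu] <- wl
        sl[f < r] <- lu
        labels[bbx, bby, k] <- sl
      }
    }
  }
  labels
}

draw_extravasation <- function(labels, spec, xc, yc, zc, hmat) {
  ex <- .labels[["extravasation"]]; st <- .labels[["stroma"]]
  nx <- length(xc); ny <- length(yc)
  Xext <- nx * spec$voxel_size[1]; Yext <- ny * spec$voxel_size[2]
  rx <- 20; ry <- 20; rz <- 12
  for (b in seq_len(spec$extravasation_count)) {
    x0 <- stats::runif(1, 0.2 * Xext, 0.8 * Xext)
    y0 <- stats::runif(1, 0.2 * Yext, 0.8 * Yext)
    d <- stats::runif(1, 30, 150)
    z0 <- spec$surface_height + d
    bbx <- which(abs(xc - x0) <= rx); bby <- which(abs(yc - y0) <= ry)
    bbz <- which(abs(zc - z0) <= rz)
    if (!length(bbx) || !length(bby) || !length(bbz)) next
    q <- outer((xc[bbx] - x0)^2 / rx^2, (yc[bby] - y0)^2 / ry^2, "+")
    for (k in bbz) {
      f <- q + (zc[k] - z0)^2 / rz^2
      sl <- labels[bbx, bby, k]
      sl[f <= 1 & sl == st] <- ex
      labels[bbx, bby, k] <- sl
    }
  }
  labels
}

# Per-component centroids (um, lumen voxels preferred) and depths below the
# generative surface.
component_table <- function(comp, labels, voxel_size, hmat) {
  idx <- which(comp > 0L)
  if (!length(idx))
    return(data.frame(id = integer(), x = numeric(), y = numeric(),
                      z = numeric(), true_depth = numeric(),
                      n_voxels = integer()))
  dims <- dim(comp)
  cl <- comp[idx]
  ij <- index3_to_ij(idx, dims)
  kk <- index3_to_k(idx, dims)
  xs <- (ij[, 1] - 0.5) * voxel_size[1]
  ys <- (ij[, 2] - 0.5) * voxel_size[2]
  zs <- (kk - 0.5) * voxel_size[3]
  is_lumen <- labels[idx] == .labels[["vessel_lumen"]]
  n_lumen <- tabulate(cl[is_lumen], nbins = max(cl))
  use <- is_lumen | n_lumen[cl] == 0L   # fall back to all voxels if no lumen
  g <- cl[use]
  sums <- rowsum(cbind(xs, ys, zs)[use, , drop = FALSE], g)
  cnt <- tabulate(g, nbins = max(cl))[sort(unique(g))]
  ids <- sort(unique(g))
  cen <- sums / cnt
  i_n <- pmin(pmax(round(cen[, 1] / voxel_size[1] + 0.5), 1L), dims[1])
  j_n <- pmin(pmax(round(cen[, 2] / voxel_size[2] + 0.5), 1L), dims[2])
  depth <- pmax(cen[, 3] - hmat[cbind(i_n, j_n)], 0)
  data.frame(id = ids, x = cen[, 1], y = cen[, 2], z = cen[, 3],
             true_depth = depth,
             n_voxels = tabulate(cl, nbins = max(cl))[ids])
}

#' @export
print.tissue_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("tissue_volume: %d x %d x %d voxels (%g x %g x %g um), %s\n",
              d[1], d[2], d[3], d[1] * x$voxel_size[1], d[2] * x$voxel_size[2],
              d[3] * x$voxel_size[3], x$orientation))
  tb <- table(factor(x$labels, levels = .labels, labels = names(.labels)))
  print(tb)
  invisible(x)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d vessel components (depths %.1f-%.1f um), %d crypts\n",
              nrow(x$vessel_components),
              if (nrow(x$vessel_components)) min(x$vessel_components$true_depth) else NA,
              if (nrow(x$vessel_components)) max(x$vessel_components$true_depth) else NA,
              nrow(x$crypt_orifices)))
  invisible(x)
}

#' Section a phantom volume into a stained serial-slice series
#'
#' Virtually cuts the labelled volume into `spec$n_slices` consecutive
#' sections of `spec$slice_thickness` um along the sectioning axis.  Slices
#' whose 0-based index satisfies `index %% epithelium_stain_period ==
#' stain_period_offset` render the epithelium as bright; all other slices
#' render the vessel *wall* as bright and the lumen as background (the
#' ring-shaped appearance of an endothelium stain).  A fraction of 2D vessel
#' rings get an arc of wall erased (`broken_wall_fraction`), each slice is
#' perturbed by a rigid jitter drawn within the spec bounds (the true
#' transform is recorded), and additive Gaussian noise is applied.
#'
#' @param volume A `tissue_volume` from [build_phantom()].
#' @param spec The [phantom_spec] used to build it.
#' @return A `section_series`: ordered slices with fields `index` (0-based),
#'   `stain`, `image` (in `[0, 1]`), `true_transform`, `pixel_size`.
#' @export
section_volume <- function(volume, spec) {
  stopifnot(inherits(volume, "tissue_volume"), inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  axis <- if (spec$orientation == "vertical_section") 2L else 3L
  if (spec$n_slices > dim(volume$labels)[axis])
    stop("volume extent along the sectioning axis is smaller than n_slices",
         call. = FALSE)
  pixel_size <- spec$voxel_size[setdiff(1:3, axis)][1]
  with_seed(spec$rng_seed + 1L, {
    slices <- vector("list", spec$n_slices)
    for (k in seq_len(spec$n_slices)) {
      plane <- if (axis == 2L) volume$labels[, k, ] else volume$labels[, , k]
      idx0 <- k - 1L
      is_epi <- (idx0 %% spec$epithelium_stain_period) ==
        spec$stain_period_offset
      stain <- if (is_epi) "epithelium_stain" else "vessel_stain"
      img <- if (is_epi) (plane == .labels[["epithelium"]]) * 1
      else (plane == .labels[["vessel_wall"]]) * 1
      if (!is_epi && spec$broken_wall_fraction > 0)
        img <- break_walls(img, spec$broken_wall_fraction,
                           spec$broken_wall_gap)
      # unstained tissue renders at the counterstain level
      img <- pmax(img, (plane != .labels[["background"]]) *
                    spec$tissue_background)
      tr <- rigid_transform(
        dx = stats::runif(1, -spec$jitter_max_translation,
                          spec$jitter_max_translation),
        dy = stats::runif(1, -spec$jitter_max_translation,
                          spec$jitter_max_translation),
        theta = stats::runif(1, -spec$jitter_max_rotation,
                             spec$jitter_max_rotation))
      obs <- apply_transform(img, tr, "linear")
      if (spec$noise_sd > 0)
        obs <- obs + matrix(stats::rnorm(length(obs), 0, spec$noise_sd),
                            nrow(obs))
      slices[[k]] <- list(index = idx0, stain = stain,
                          image = clamp01(obs), true_transform = tr,
                          pixel_size = pixel_size)
    }
    structure(list(slices = slices, pixel_size = pixel_size,
                   slice_thickness = spec$slice_thickness,
                   epithelium_stain_period = spec$epithelium_stain_period,
                   stain_period_offset = spec$stain_period_offset,
                   orientation = spec$orientation),
              class = "section_series")
  })
}

# Erase an arc of wall from a random subset of 2D wall components.
break_walls <- function(img, fraction, gap) {
  wall <- img > 0.5
  comp <- label_components_3d(as.vector(wall), c(dim(wall), 1L))
  comp <- matrix(comp, nrow(wall), ncol(wall))
  ncomp <- max(comp)
  if (ncomp == 0L) return(img)
  sel <- which(stats::runif(ncomp) < fraction)
  for (id in sel) {
    pix <- which(comp == id, arr.ind = TRUE)
    p <- pix[sample.int(nrow(pix), 1L), ]
    dd <- sqrt((pix[, 1] - p[1])^2 + (pix[, 2] - p[2])^2)
    hit <- pix[dd <= gap / 2, , drop = FALSE]
    img[hit] <- 0
  }
  img
}

#' @export
print.section_series <- function(x, ...) {
  n <- length(x$slices)
  ne <- sum(vapply(x$slices, function(s) s$stain == "epithelium_stain", TRUE))
  d <- dim(x$slices[[1]]$image)
  cat(sprintf(paste0("section_series: %d slices (%d epithelium / %d vessel), ",
                     "%d x %d px at %g um/px, thickness %g um, %s\n"),
              n, ne, n - ne, d[1], d[2], x$pixel_size, x$slice_thickness,
              x$orientation))
  invisible(x)
}

#' Render a virtual magnifying-BLI top view
#'
#' Produces an en-face intensity image emulating how superficial microvessels
#' appear on magnifying blue-laser imaging: each vessel component darkens its
#' top-view footprint in proportion to `exp(-true_depth / visibility_scale)`,
#' and contributes nothing beyond `hard_cutoff` (the empirical visibility
#' boundary of roughly 80 um; vessels at 120-180 um are invisible).
#' Extravasated-erythrocyte regions render as diffuse dark patches; crypt
#' orifices can optionally be rendered as faint rings.  The model is
#' phenomenological (driven by haemoglobin absorption of ~410 nm light), not
#' an optical light-transport simulation.
#'
#' @param volume A `tissue_volume`.
#' @param truth The matching `phantom_truth`.
#' @param visibility_scale Exponential contrast decay scale in um (> 0).
#' @param hard_cutoff Depth in um beyond which a vessel contributes nothing.
#' @param render_orifices Render crypt orifices as faint rings (default off).
#' @param orifice_contrast Contrast of the optional orifice rings.
#' @param extravasation_contrast Peak contrast scale of extravasation blobs.
#' @param extravasation_blur Gaussian blur sigma (px) for extravasation.
#' @return A numeric matrix in `[0, 1]` over the two lateral axes (1 =
#'   bright mucosa), with attributes `pixel_size`, `visibility_scale`,
#'   `hard_cutoff`.
#' @export
render_virtual_bli <- function(volume, truth, visibility_scale = 40,
                               hard_cutoff = 80, render_orifices = FALSE,
                               orifice_contrast = 0.15,
                               extravasation_contrast = 0.5,
                               extravasation_blur = 3) {
  stopifnot(inherits(volume, "tissue_volume"), inherits(truth, "phantom_truth"))
  stop_if_not_scalar_number(visibility_scale, "visibility_scale", 0,
                            strict_min = TRUE)
  stop_if_not_scalar_number(hard_cutoff, "hard_cutoff", 0, strict_min = TRUE)
  dims <- dim(volume$labels)
  comp <- truth$component_labels
  comps <- truth$vessel_components
  weight <- numeric(if (nrow(comps)) max(comps$id) else 0L)
  if (nrow(comps)) {
    vis <- comps$true_depth <= hard_cutoff
    weight[comps$id[vis]] <- exp(-comps$true_depth[vis] / visibility_scale)
  }
  contrast <- matrix(0, dims[1], dims[2])
  lut <- c(0, weight)
  for (k in seq_len(dims[3])) {
    wk <- matrix(lut[comp[, , k] + 1L], dims[1], dims[2])
    contrast <- pmax(contrast, wk)
  }

  ev <- volume$labels == .labels[["extravasation"]]
  if (any(ev)) {
    ecomp <- label_components_3d(as.vector(ev), dims)
    etab <- component_table(ecomp, volume$labels, volume$voxel_size,
                            truth$surface_height)
    ew <- numeric(if (nrow(etab)) max(etab$id) else 0L)
    evis <- etab$true_depth <= hard_cutoff
    ew[etab$id[evis]] <- extravasation_contrast *
      exp(-etab$true_depth[evis] / visibility_scale)
    elut <- c(0, ew)
    E <- matrix(0, dims[1], dims[2])
    for (k in seq_len(dims[3]))
      E <- pmax(E, matrix(elut[ecomp[, , k] + 1L], dims[1], dims[2]))
    if (extravasation_blur > 0)
      E <- as.matrix(EBImage::gblur(E, sigma = extravasation_blur))
    contrast <- pmax(contrast, E)
  }

  if (render_orifices && nrow(truth$crypt_orifices)) {
    xc <- (seq_len(dims[1]) - 0.5) * volume$voxel_size[1]
    yc <- (seq_len(dims[2]) - 0.5) * volume$voxel_size[2]
    for (ci in seq_len(nrow(truth$crypt_orifices))) {
      o <- truth$crypt_orifices[ci, ]
      rho <- sqrt(outer((xc - o$x)^2, (yc - o$y)^2, "+"))
      ring <- abs(rho - o$radius) <= volume$voxel_size[1]
      contrast[ring] <- pmax(contrast[ring], orifice_contrast)
    }
  }

  structure(1 - clamp01(contrast),
            pixel_size = volume$voxel_size[1:2],
            visibility_scale = visibility_scale, hard_cutoff = hard_cutoff)
}
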