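# Rigid slice-to-slice registration: consecutive slices are aligned in
# consideration of continuity, then pairwise transforms are propagated
# outward from an anchor slice into a common frame.

#' Estimate the rigid transform between two slices
#'
#' Finds the rigid transform `t` maximising the spatial cross-correlation of
#' `apply_transform(moving, t)` with `fixed`.  Translation is found at the
#' correlation peak (FFT cross-correlation of the mean-subtracted images)
#' with optional sub-pixel refinement by parabolic interpolation; rotation,
#' when enabled, is a coarse grid search over
#' `[-max_rotation, +max_rotation]`.  Deterministic.  Empty or constant
#' input returns the identity with a warning.
#'
#' @param fixed,moving Numeric matrices of equal dimensions (images, masks,
#'   or feature images such as capped distance transforms).
#' @param max_rotation Rotation search bound in degrees (0 = translation
#'   only, the default).
#' @param rotation_step Grid step of the rotation search in degrees.
#' @param search_radius Maximum translation magnitude considered, in px.
#' @param subpixel Refine the translation peak by parabolic interpolation.
#' @return A [rigid_transform] mapping `moving` onto `fixed`.
#' @export
estimate_pairwise <- function(fixed, moving, max_rotation = 0,
                              rotation_step = 0.5, search_radius = 20,
                              subpixel = TRUE) {
  stopifnot(is.matrix(fixed), is.matrix(moving),
            all(dim(fixed) == dim(moving)))
  if (diff(range(fixed)) == 0 || diff(range(moving)) == 0) {
    warning("empty or constant image: returning identity transform")
    return(rigid_transform())
  }
  thetas <- if (max_rotation > 0)
    unique(c(0, seq(-max_rotation, max_rotation, by = rotation_step))) else 0
  thetas <- sort(thetas)
  best <- NULL
  scores <- numeric(length(thetas))
  fits <- vector("list", length(thetas))
  for (q in seq_along(thetas)) {
    mv <- if (thetas[q] != 0)
      apply_transform(moving, rigid_transform(theta = thetas[q]), "linear")
    else moving
    fits[[q]] <- correlate_translation(fixed, mv, search_radius, subpixel)
    scores[q] <- fits[[q]]$score
  }
  qb <- which.max(scores)
  theta <- thetas[qb]
  # parabolic refinement of the rotation on the score profile
  if (length(thetas) > 2 && qb > 1 && qb < length(thetas)) {
    den <- scores[qb - 1] - 2 * scores[qb] + scores[qb + 1]
    if (den < 0)
      theta <- theta + 0.5 * (scores[qb - 1] - scores[qb + 1]) / den *
        (thetas[qb + 1] - thetas[qb])
  }
  rigid_transform(dx = fits[[qb]]$dx, dy = fits[[qb]]$dy, theta = theta)
}

# FFT cross-correlation translation estimate.  Returns the shift (dx, dy)
# such that moving translated by (dx, dy) best overlays fixed.  Sub-pixel
# refinement evaluates the cross-correlation on an upsampled local grid
# around the integer peak by matrix-multiply DFT (local frequency-domain
# upsampling), then a parabolic vertex fit on the fine grid.
correlate_translation <- function(fixed, moving, search_radius, subpixel,
                                  upsample = 20L) {
  n1 <- nrow(fixed); n2 <- ncol(fixed)
  pad <- ceiling(search_radius) + 1L
  P1 <- n1 + 2L * pad; P2 <- n2 + 2L * pad
  f <- matrix(0, P1, P2); m <- matrix(0, P1, P2)
  f[seq_len(n1), seq_len(n2)] <- fixed - mean(fixed)
  m[seq_len(n1), seq_len(n2)] <- moving - mean(moving)
  FF <- stats::fft(f) * Conj(stats::fft(m))
  cc <- Re(stats::fft(FF, inverse = TRUE)) / (P1 * P2)
  # admissible circular shifts
  s1 <- c(0:(P1 - 1)); s1 <- ifelse(s1 > P1 / 2, s1 - P1, s1)
  s2 <- c(0:(P2 - 1)); s2 <- ifelse(s2 > P2 / 2, s2 - P2, s2)
  ok1 <- abs(s1) <= search_radius; ok2 <- abs(s2) <= search_radius
  sub <- cc[ok1, ok2, drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  i0 <- which(ok1)[pk[1]]; j0 <- which(ok2)[pk[2]]
  dx <- s1[i0]; dy <- s2[j0]
  score <- cc[i0, j0]
  if (subpixel) {
    fu <- s1; fv <- s2   # signed DFT frequencies
    av <- dx + seq(-1, 1, by = 1 / upsample)
    bv <- dy + seq(-1, 1, by = 1 / upsample)
    ka <- exp(2i * pi * outer(fu, av) / P1)
    kb <- exp(2i * pi * outer(fv, bv) / P2)
    ccu <- Re(crossprod(ka, FF %*% kb)) / (P1 * P2)
    pku <- which(ccu == max(ccu), arr.ind = TRUE)[1, ]
    dx <- av[pku[1]]; dy <- bv[pku[2]]
    score <- max(ccu)
    # parabolic vertex on the fine grid
    if (pku[1] > 1 && pku[1] < length(av)) {
      cm <- ccu[pku[1] - 1, pku[2]]; c0 <- ccu[pku[1], pku[2]]
      cp <- ccu[pku[1] + 1, pku[2]]
      den <- cm - 2 * c0 + cp
      if (den < 0) dx <- dx + 0.5 * (cm - cp) / den / upsample
    }
    if (pku[2] > 1 && pku[2] < length(bv)) {
      cm <- ccu[pku[1], pku[2] - 1]; c0 <- ccu[pku[1], pku[2]]
      cp <- ccu[pku[1], pku[2] + 1]
      den <- cm - 2 * c0 + cp
      if (den < 0) dy <- dy + 0.5 * (cm - cp) / den / upsample
    }
  }
  list(dx = dx, dy = dy, score = score)
}

# Sub-pixel position of the tissue surface in a vertical-section slice.
# A hard step edge resampled bilinearly has exactly one transition sample
# whose value encodes the sub-pixel edge position: for a step of height A
# shifted by fraction f, the transition sample equals A * (1 - f).  Per
# column, the first sample above the noise floor is taken as the transition,
# the next sample as the local plateau A (which may be the stain level or
# the tissue-contour level, so the estimate is stain-invariant), and the
# edge position follows in closed form.  The median over columns is robust
# to crypt orifices, glass margins and noise.
surface_row_position <- function(img, threshold, noise_floor = 0.06) {
  n1 <- nrow(img); n2 <- ncol(img)
  pos <- rep(NA_real_, n1)
  for (i in seq_len(n1)) {
    p <- img[i, ]
    k <- which(p >= noise_floor)
    if (length(k) < 2L) next
    k1 <- k[1L]
    if (k1 >= n2 - 1L) next
    A <- p[k1 + 1L]
    if (A < threshold) next       # no tissue plateau below (glass margin)
    f <- 1 - min(max(p[k1] / A, 0), 1)
    pos[i] <- k1 + f
  }
  if (all(is.na(pos))) return(NA_real_)
  stats::median(pos, na.rm = TRUE)
}

#' Propagate pairwise transforms into a chain of absolute transforms
#'
#' Given transforms `pairwise[[k]]` aligning slice `k + 1` onto slice `k`,
#' composes them outward from the anchor slice so that every slice maps into
#' the anchor's frame; the anchor maps to the identity.
#'
#' @param pairwise List of `n - 1` [rigid_transform]s.
#' @param anchor Anchor slice (1-based; default the middle slice).
#' @return A `transform_chain`: list with `absolute` (length-n list of
#'   transforms), `anchor`, `n`.
#' @export
propagate <- function(pairwise, anchor = NULL) {
  n <- length(pairwise) + 1L
  anchor <- as.integer(anchor %||% ((n + 1L) %/% 2L))
  if (anchor < 1L || anchor > n)
    stop(sprintf("anchor %d out of range 1..%d", anchor, n), call. = FALSE)
  absolute <- vector("list", n)
  absolute[[anchor]] <- rigid_transform()
  if (anchor < n)
    for (k in seq(anchor + 1L, n))
      absolute[[k]] <- compose_transforms(absolute[[k - 1L]], pairwise[[k - 1L]])
  if (anchor > 1L)
    for (k in seq(anchor - 1L, 1L))
      absolute[[k]] <- compose_transforms(absolute[[k + 1L]],
                                          invert_transform(pairwise[[k]]))
  structure(list(absolute = absolute, anchor = anchor, n = n),
            class = "transform_chain")
}

#' @export
print.transform_chain <- function(x, ...) {
  dxs <- vapply(x$absolute, `[[`, numeric(1), "dx")
  dys <- vapply(x$absolute, `[[`, numeric(1), "dy")
  cat(sprintf(paste0("transform_chain: %d slices, anchor %d, |translation| ",
                     "range %.2f-%.2f px\n"), x$n, x$anchor,
              min(sqrt(dxs^2 + dys^2)), max(sqrt(dxs^2 + dys^2))))
  invisible(x)
}

#' Register a section series into a common frame
#'
#' Stain-aware sequential registration.  A backbone chain is built over the
#' slices of the majority stain (the vessel stain under the usual
#' every-third-slice epithelium schedule), registering each backbone slice
#' to its predecessor on the raw intensity image — same-stain neighbours
#' share their structures, and intensity correlation localises to a few
#' hundredths of a pixel.  Each remaining slice is then attached to its
#' nearest backbone neighbour by a single cross-stain link computed on a
#' stain-invariant tissue feature (intensity saturated at the tissue-contour
#' level, so the specimen silhouette, mucosal surface and crypt lumens carry
#' the correlation while stain-specific structures are suppressed).
#' Cross-stain links are less precise but terminal: their errors do not
#' propagate along the chain.
#'
#' Sequential chaining accumulates per-pair error as a random walk, so a
#' second, anchored pass follows (`refine = TRUE`): every slice, already
#' coarsely placed by the chain, is re-registered directly against the
#' anchor slice on the stain-invariant tissue feature and its residual
#' correction applied.  Residual errors are then independent per slice and
#' the chain accumulates no drift.  Finally everything is expressed
#' relative to the anchor slice.
#'
#' @param series A `section_series`.
#' @param feature Backbone feature: `"intensity"` (default), `"mask"`
#'   (binary tissue mask), or `"mask_distance"` (capped distance transform;
#'   larger capture range, less precise localisation).
#' @param threshold Tissue-contour intensity level used by the mask features
#'   and the cross-stain saturation (default 0.1).
#' @param feature_cap Distance cap in px for the `"mask_distance"` feature.
#' @param max_rotation,rotation_step,search_radius,subpixel Passed to
#'   [estimate_pairwise()].
#' @param anchor Anchor slice (1-based; default middle).
#' @param refine Run the anchored refinement pass (default TRUE).
#' @param refine_radius Residual search radius of the refinement pass, px.
#' @return A `transform_chain` of absolute transforms into the anchor frame.
#' @export
register_series <- function(series, feature = c("mask", "intensity",
                                                "mask_distance"),
                            threshold = 0.1, feature_cap = 15,
                            max_rotation = 0, rotation_step = 0.5,
                            search_radius = 20, subpixel = TRUE,
                            anchor = NULL, refine = TRUE,
                            refine_radius = 8) {
  stopifnot(inherits(series, "section_series"))
  feature <- match.arg(feature)
  n <- length(series$slices)
  stains <- vapply(series$slices, `[[`, character(1), "stain")
  backbone_feat <- function(s) {
    if (feature == "intensity") return(s$image)
    m <- s$image >= threshold
    if (feature == "mask") return(m * 1)
    if (!any(m)) return(matrix(0, nrow(s$image), ncol(s$image)))
    d <- as.matrix(EBImage::distmap((!m) * 1))
    pmax(feature_cap - d, 0) / feature_cap
  }
  # stain-invariant tissue feature for cross-stain links and refinement;
  # the refinement variant supersamples 2x before thresholding, which
  # halves the edge-quantisation noise of the binary mask
  tissue_feat <- function(img) (img >= threshold) * 1
  tissue_feat_2x <- function(img) {
    up <- as.matrix(EBImage::resize(img, w = 2L * nrow(img),
                                    h = 2L * ncol(img)))
    (up >= threshold) * 1
  }

  majority <- names(which.max(table(stains)))
  bb <- which(stains == majority)
  if (length(bb) < 1L) bb <- seq_len(n)
  anchor <- as.integer(anchor %||% ((n + 1L) %/% 2L))
  if (anchor < 1L || anchor > n)
    stop(sprintf("anchor %d out of range 1..%d", anchor, n), call. = FALSE)

  est <- function(fi, mi, ffun) {
    estimate_pairwise(ffun(series$slices[[fi]]), ffun(series$slices[[mi]]),
                      max_rotation = max_rotation,
                      rotation_step = rotation_step,
                      search_radius = search_radius, subpixel = subpixel)
  }

  absolute <- vector("list", n)
  # backbone chain, anchored at the backbone slice nearest the anchor
  ba <- which.min(abs(bb - anchor))
  absolute[[bb[ba]]] <- rigid_transform()
  bfeats <- lapply(series$slices[bb], backbone_feat)
  if (ba < length(bb))
    for (q in seq(ba + 1L, length(bb))) {
      t <- estimate_pairwise(bfeats[[q - 1L]], bfeats[[q]],
                             max_rotation = max_rotation,
                             rotation_step = rotation_step,
                             search_radius = search_radius,
                             subpixel = subpixel)
      absolute[[bb[q]]] <- compose_transforms(absolute[[bb[q - 1L]]], t)
    }
  if (ba > 1L)
    for (q in seq(ba - 1L, 1L)) {
      t <- estimate_pairwise(bfeats[[q]], bfeats[[q + 1L]],
                             max_rotation = max_rotation,
                             rotation_step = rotation_step,
                             search_radius = search_radius,
                             subpixel = subpixel)
      absolute[[bb[q]]] <- compose_transforms(absolute[[bb[q + 1L]]],
                                              invert_transform(t))
    }
  # terminal cross-stain links for the remaining slices
  for (k in setdiff(seq_len(n), bb)) {
    b <- bb[which.min(abs(bb - k))]
    t <- est(b, k, function(s) tissue_feat(s$image))
    absolute[[k]] <- compose_transforms(absolute[[b]], t)
  }
  # anchored refinement: register each coarsely placed slice directly to
  # the anchor; residual errors no longer accumulate along the chain.  For
  # vertical sections the depth coordinate is additionally locked to the
  # mucosal surface line (sub-pixel median of per-column first crossings),
  # which is the stable depth reference when gland cross-sections come and
  # go between distant slices.
  if (refine) {
    vertical <- identical(series$orientation, "vertical_section")
    anchor_img <- apply_transform(series$slices[[anchor]]$image,
                                  absolute[[anchor]], "linear")
    ref <- tissue_feat_2x(anchor_img)
    ref_surf <- if (vertical)
      surface_row_position(anchor_img, threshold) else NA_real_
    for (k in seq_len(n)) {
      warped <- apply_transform(series$slices[[k]]$image, absolute[[k]],
                                "linear")
      r <- estimate_pairwise(ref, tissue_feat_2x(warped),
                             max_rotation = max_rotation,
                             rotation_step = rotation_step,
                             search_radius = 2 * refine_radius,
                             subpixel = subpixel)
      dy <- r$dy / 2
      if (vertical && is.finite(ref_surf)) {
        cur <- surface_row_position(warped, threshold)
        if (is.finite(cur) && abs(ref_surf - cur) <= refine_radius)
          dy <- ref_surf - cur
      }
      absolute[[k]] <- compose_transforms(
        rigid_transform(r$dx / 2, dy, r$theta), absolute[[k]])
    }
  }
  # express everything relative to the requested anchor slice
  inv_a <- invert_transform(absolute[[anchor]])
  absolute <- lapply(absolute, function(t) compose_transforms(inv_a, t))
  structure(list(absolute = absolute, anchor = anchor, n = n),
            class = "transform_chain")
}

#' Pair each slice with its nearest epithelium-stained slice
#'
#' Implements the superimposition of adjacent epithelium and vessel images:
#' every slice is paired with the epithelium-stained slice of nearest index,
#' ties resolved toward the lower index.
#'
#' @param series A `section_series` (or a character vector of per-slice
#'   stains).
#' @return Integer vector: for each slice, the 1-based position of its
#'   paired epithelium slice.
#' @export
assign_epithelium <- function(series) {
  stains <- if (inherits(series, "section_series"))
    vapply(series$slices, `[[`, character(1), "stain") else series
  epi <- which(stains == "epithelium_stain")
  if (!length(epi))
    stop("series contains no epithelium-stained slices", call. = FALSE)
  vapply(seq_along(stains), function(k) epi[which.min(abs(epi - k))],
         integer(1))
}
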