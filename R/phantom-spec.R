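#' Phantom specification
#'
#' Parameters of the synthetic colonic-mucosa phantom.  The defaults encode
#' the study conditions the pipeline is designed for: 100 consecutive
#' sections of 3 um thickness, the epithelium stain applied every third
#' slice, ring-shaped vessel-wall staining with unstained lumens, a
#' honeycomb capillary arrangement around a regular crypt lattice for normal
#' mucosa, and crypt/vessel distortion for neoplastic classes.
#'
#' All lengths are in micrometres unless stated otherwise.  The depth axis is
#' always the third axis of the generated volume; `orientation` controls how
#' the block is sectioned: `"vertical_section"` cuts perpendicular to the
#' mucosal surface (the surface lies inside each slice and the stack axis is
#' lateral), `"horizontal_section"` cuts parallel to it (depth accumulates
#' across the stack).
#'
#' @param tissue_class `"normal"`, `"adenoma"` or `"carcinoma"`.  Neoplastic
#'   classes perturb crypt positions/radii by `crypt_distortion` and scale
#'   vessel radii up; `"carcinoma"` additionally places extravasated
#'   erythrocyte blobs.
#' @param orientation Sectioning axis semantics (see Details).
#' @param volume_extent Integer triple, volume size in voxels `(x, y, z)`
#'   with z the depth axis.  Defaults are derived from `n_slices` and the
#'   orientation.
#' @param voxel_size Numeric triple, um per voxel.  The voxel size along the
#'   sectioning axis must equal `slice_thickness` and the two in-plane voxel
#'   sizes must be equal (square pixels).
#' @param n_slices Number of serial sections (default 100).
#' @param slice_thickness Section thickness in um (default 3).
#' @param epithelium_stain_period Every `period`-th slice carries the
#'   epithelium stain (default 3); all other slices carry the vessel stain.
#' @param stain_period_offset Index (0-based) of the first epithelium-stained
#'   slice within each period.
#' @param crypt_pitch Centre-to-centre crypt spacing of the hexagonal lattice.
#'   A pitch larger than the footprint yields 0 or 1 crypt (degenerate but
#'   valid).
#' @param crypt_radius Outer crypt gland radius.
#' @param crypt_wall_thickness Radial thickness of the epithelial gland wall.
#' @param crypt_depth_fraction Fraction of the sub-surface depth extent the
#'   crypts span.
#' @param crypt_distortion Distortion in `[0, 1]` applied to crypt positions
#'   and radii; `NULL` uses the class default (0 / 0.35 / 0.6).
#' @param vessel_layout `"honeycomb"` places capillary rings around each
#'   crypt (tori in the surface plane, the normal-mucosa pattern);
#'   `"parallel"` places straight tubes parallel to the sectioning axis on a
#'   regular lateral grid, each at its own depth (useful for controlled
#'   depth-recovery experiments).
#' @param vessels_per_crypt Number of rings per crypt in the honeycomb
#'   layout, placed at stratified random depths within `vessel_depth_range`.
#' @param vessel_spacing Lateral spacing of the parallel layout.
#' @param vessel_segment_length Axial length of parallel-layout tubes for
#'   horizontal sectioning (vertical sections use full-width tubes).
#' @param vessel_radius_mean,vessel_radius_sd Lumen radius distribution.
#' @param vessel_wall_thickness Vessel wall thickness.  Must exceed the
#'   in-plane voxel diagonal so that every 2D cross-section is a closed ring.
#' @param vessel_depth_range Length-2 range of lumen-centre depths below the
#'   mucosal surface.  Collapse it to a point to place all vessels at one
#'   depth.
#' @param broken_wall_fraction Fraction of 2D vessel-wall cross-sections with
#'   an erased wall arc (models incompletely stained walls).
#' @param broken_wall_gap Arc-gap size in pixels for broken walls.
#' @param jitter_max_translation Per-slice rigid jitter bound in pixels.
#' @param jitter_max_rotation Per-slice rotation jitter bound in degrees.
#' @param noise_sd Additive Gaussian stain-noise SD (intensity units; images
#'   are clipped to `[0, 1]`).
#' @param tissue_background Intensity of unstained tissue in rendered slices
#'   (the counterstained tissue contour visible on any slide photograph;
#'   stain-positive pixels render at 1).  Registration keys on the tissue
#'   contour, segmentation on the stain level.
#' @param surface_height Mean depth-axis position of the mucosal surface.
#'   `NULL` chooses 24 um for vertical sections (a glass margin above the
#'   surface large enough that slice jitter never clips the surface at the
#'   frame edge) and 6 um for horizontal sections.
#' @param surface_amplitude,surface_period Amplitude/period of an optional
#'   sinusoidal surface undulation (amplitude 0 gives a flat surface).
#' @param epithelium_lining Thickness of the surface epithelial lining.
#' @param footprint_margin Background (glass) margin around the tissue block
#'   inside each slice frame, in um.  A slide photograph contains the whole
#'   section with empty glass around it; the moving specimen silhouette is
#'   the dominant cue for slice-to-slice alignment.  Applied to the in-slice
#'   lateral axes and, for vertical sections, below the block.
#' @param extravasation_count Number of extravasated-erythrocyte blobs;
#'   `NULL` uses the class default (0 / 0 / 2).
#' @param rng_seed Integer seed; all phantom randomness flows from it.
#' @return An object of class `phantom_spec` (a validated parameter list).
#' @export
phantom_spec <- function(tissue_class = c("normal", "adenoma", "carcinoma"),
                         orientation = c("vertical_section", "horizontal_section"),
                         volume_extent = NULL,
                         voxel_size = NULL,
                         n_slices = 100L,
                         slice_thickness = 3,
                         epithelium_stain_period = 3L,
                         stain_period_offset = 0L,
                         crypt_pitch = 80,
                         crypt_radius = 18,
                         crypt_wall_thickness = 8,
                         crypt_depth_fraction = 0.85,
                         crypt_distortion = NULL,
                         vessel_layout = c("honeycomb", "parallel"),
                         vessels_per_crypt = 2L,
                         vessel_spacing = 14,
                         vessel_segment_length = 60,
                         vessel_radius_mean = 4,
                         vessel_radius_sd = 0.8,
                         vessel_wall_thickness = 4,
                         vessel_depth_range = c(20, 260),
                         broken_wall_fraction = 0.1,
                         broken_wall_gap = 3,
                         jitter_max_translation = 3,
                         jitter_max_rotation = 0,
                         noise_sd = 0.02,
                         tissue_background = 0.15,
                         surface_height = NULL,
                         surface_amplitude = 0,
                         surface_period = 256,
                         epithelium_lining = 6,
                         footprint_margin = 40,
                         extravasation_count = NULL,
                         rng_seed = 1L) {
  tissue_class <- match.arg(tissue_class)
  orientation <- match.arg(orientation)
  vessel_layout <- match.arg(vessel_layout)
  n_slices <- as.integer(n_slices)
  epithelium_stain_period <- as.integer(epithelium_stain_period)
  stain_period_offset <- as.integer(stain_period_offset)

  if (is.null(voxel_size))
    voxel_size <- if (orientation == "vertical_section")
      c(2, slice_thickness, 2) else c(2, 2, slice_thickness)
  if (is.null(volume_extent)) {
    stack_n <- n_slices
    volume_extent <- if (orientation == "vertical_section")
      c(256L, stack_n, 175L) else c(256L, 192L, stack_n)
  }
  volume_extent <- as.integer(volume_extent)
  # in vertical sections the glass margin above the surface must absorb the
  # jitter, or jittered slices lose their surface at the frame edge
  if (is.null(surface_height))
    surface_height <- if (orientation == "vertical_section") 24 else 6

  if (is.null(crypt_distortion))
    crypt_distortion <- switch(tissue_class, normal = 0, adenoma = 0.35,
                               carcinoma = 0.6)
  if (is.null(extravasation_count))
    extravasation_count <- if (tissue_class == "carcinoma") 2L else 0L

  spec <- structure(list(
    tissue_class = tissue_class, orientation = orientation,
    volume_extent = volume_extent, voxel_size = as.numeric(voxel_size),
    n_slices = n_slices, slice_thickness = slice_thickness,
    epithelium_stain_period = epithelium_stain_period,
    stain_period_offset = stain_period_offset,
    crypt_pitch = crypt_pitch, crypt_radius = crypt_radius,
    crypt_wall_thickness = crypt_wall_thickness,
    crypt_depth_fraction = crypt_depth_fraction,
    crypt_distortion = crypt_distortion,
    vessel_layout = vessel_layout,
    vessels_per_crypt = as.integer(vessels_per_crypt),
    vessel_spacing = vessel_spacing,
    vessel_segment_length = vessel_segment_length,
    vessel_radius_mean = vessel_radius_mean,
    vessel_radius_sd = vessel_radius_sd,
    vessel_wall_thickness = vessel_wall_thickness,
    vessel_depth_range = as.numeric(vessel_depth_range),
    broken_wall_fraction = broken_wall_fraction,
    broken_wall_gap = broken_wall_gap,
    jitter_max_translation = jitter_max_translation,
    jitter_max_rotation = jitter_max_rotation,
    noise_sd = noise_sd,
    tissue_background = tissue_background,
    surface_height = surface_height,
    surface_amplitude = surface_amplitude,
    surface_period = surface_period,
    epithelium_lining = epithelium_lining,
    footprint_margin = footprint_margin,
    extravasation_count = as.integer(extravasation_count),
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

#' Validate a phantom specification
#'
#' Checks the invariants of a [phantom_spec]: positive lengths, a stain
#' period of at least 1, `broken_wall_fraction` in `[0, 1]`, and that the
#' sectioned span `n_slices * slice_thickness` fits inside the volume along
#' the sectioning axis.
#'
#' @param spec A `phantom_spec`.
#' @return `spec`, invisibly; errors describe the offending field.
#' @export
validate_phantom_spec <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with(spec, {
    if (length(volume_extent) != 3L || any(volume_extent < 1L))
      stop("volume_extent must be 3 positive integers", call. = FALSE)
    if (length(voxel_size) != 3L || any(voxel_size <= 0))
      stop("voxel_size must be 3 positive lengths (um)", call. = FALSE)
    for (f in c("slice_thickness", "crypt_pitch", "crypt_radius",
                "crypt_wall_thickness", "vessel_radius_mean",
                "vessel_wall_thickness", "vessel_spacing"))
      if (get(f) <= 0) stop(sprintf("`%s` must be > 0", f), call. = FALSE)
    if (n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
    if (epithelium_stain_period < 1L)
      stop("epithelium_stain_period must be >= 1", call. = FALSE)
    if (broken_wall_fraction < 0 || broken_wall_fraction > 1)
      stop("broken_wall_fraction must lie in [0, 1]", call. = FALSE)
    if (crypt_distortion < 0 || crypt_distortion > 1)
      stop("crypt_distortion must lie in [0, 1]", call. = FALSE)
    if (footprint_margin < 0)
      stop("footprint_margin must be >= 0", call. = FALSE)
    if (length(vessel_depth_range) != 2L ||
        vessel_depth_range[2] < vessel_depth_range[1] ||
        vessel_depth_range[1] < 0)
      stop("vessel_depth_range must be an increasing non-negative pair",
           call. = FALSE)
    axis <- if (orientation == "vertical_section") 2L else 3L
    span <- volume_extent[axis] * voxel_size[axis]
    if (n_slices * slice_thickness > span + 1e-9)
      stop(sprintf(paste0("n_slices * slice_thickness = %g um exceeds the ",
                          "volume extent along the sectioning axis (%g um)"),
                   n_slices * slice_thickness, span), call. = FALSE)
    if (abs(voxel_size[axis] - slice_thickness) > 1e-9)
      stop("voxel size along the sectioning axis must equal slice_thickness",
           call. = FALSE)
    plane <- setdiff(1:3, axis)
    if (abs(voxel_size[plane[1]] - voxel_size[plane[2]]) > 1e-9)
      stop("in-plane voxel sizes must be equal (square slice pixels)",
           call. = FALSE)
  })
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %s tissue, %s\n", x$tissue_class, x$orientation))
  cat(sprintf("  volume %d x %d x %d voxels at %g x %g x %g um\n",
              x$volume_extent[1], x$volume_extent[2], x$volume_extent[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  %d slices of %g um, epithelium stain every %d (offset %d)\n",
              x$n_slices, x$slice_thickness, x$epithelium_stain_period,
              x$stain_period_offset))
  cat(sprintf("  vessel layout %s, depth range %g-%g um, seed %d\n",
              x$vessel_layout, x$vessel_depth_range[1],
              x$vessel_depth_range[2], x$rng_seed))
  invisible(x)
}
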