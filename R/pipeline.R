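# One configuration drives the whole pipeline; every stage parameter is
# validated against its module's preconditions before any stage runs, and a
# manifest with per-file hashes is written at the end of a run.

default_config <- function() {
  list(
    phantom = list(),              # phantom_spec() arguments
    input = list(series_dir = NULL, labels_csv = NULL),
    segmentation = list(method = "fixed", threshold = 0.5,
                        closing_radius = 2, min_object_area = 0),
    registration = list(feature = "mask", threshold = 0.1,
                        feature_cap = 15, max_rotation = 0,
                        rotation_step = 0.5, search_radius = 20,
                        anchor = NULL),
    reconstruction = list(smoothing_window = 25, depth_mode = "axis"),
    projection = list(windows = c(50, 100, 150), kind = "binary"),
    bli = list(visibility_scale = 40, hard_cutoff = 80,
               render_orifices = FALSE),
    analysis = list(n_areas = 50, max_depth = 400, roi = NULL,
                    contrast_threshold = 0.02, reconcile = FALSE,
                    lateral_tolerance = 0),
    rng_seed = 1L,
    output_dir = NULL)
}

merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stop(sprintf("unknown configuration key `%s`", full), call. = FALSE)
    if (is.list(base[[key]]) && !key %in% c("phantom", "input") &&
        is.list(user[[key]])) {
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Build and validate a run configuration
#'
#' Merges user settings over the pipeline defaults.  Unknown keys are
#' rejected with the offending key named; stage parameters are validated
#' against their module's preconditions (for example a negative
#' `segmentation.closing_radius` is rejected here, before any stage runs).
#'
#' @param ... Named top-level sections (e.g. `phantom = list(...)`,
#'   `segmentation = list(threshold = 0.4)`), or a single unnamed list of
#'   them.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  user <- list(...)
  if (length(user) == 1L && is.null(names(user)) && is.list(user[[1]]))
    user <- user[[1]]
  cfg <- merge_config(default_config(), user)
  validate_run_config(cfg)
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with the same structure as [run_config()].
#' @return A validated `run_config` list.
#' @export
load_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

validate_run_config <- function(cfg) {
  if (cfg$segmentation$closing_radius < 0)
    stop("segmentation.closing_radius must be >= 0", call. = FALSE)
  if (cfg$segmentation$min_object_area < 0)
    stop("segmentation.min_object_area must be >= 0", call. = FALSE)
  if (!cfg$segmentation$method %in% c("fixed", "automatic"))
    stop("segmentation.method must be \"fixed\" or \"automatic\"", call. = FALSE)
  if (cfg$registration$search_radius <= 0)
    stop("registration.search_radius must be > 0", call. = FALSE)
  if (cfg$registration$max_rotation < 0)
    stop("registration.max_rotation must be >= 0", call. = FALSE)
  if (!cfg$reconstruction$depth_mode %in% c("axis", "euclidean"))
    stop("reconstruction.depth_mode must be \"axis\" or \"euclidean\"",
         call. = FALSE)
  if (any(cfg$projection$windows <= 0))
    stop("projection.windows must be > 0", call. = FALSE)
  if (cfg$bli$visibility_scale <= 0)
    stop("bli.visibility_scale must be > 0", call. = FALSE)
  if (cfg$bli$hard_cutoff <= 0)
    stop("bli.hard_cutoff must be > 0", call. = FALSE)
  if (cfg$analysis$n_areas < 2)
    stop("analysis.n_areas must be >= 2", call. = FALSE)
  if (cfg$analysis$max_depth <= 0)
    stop("analysis.max_depth must be > 0", call. = FALSE)
  if (cfg$analysis$lateral_tolerance < 0)
    stop("analysis.lateral_tolerance must be >= 0", call. = FALSE)
  # phantom arguments are validated by phantom_spec() itself
  do.call(phantom_spec, c(cfg$phantom, list(rng_seed = cfg$rng_seed)))
  invisible(cfg)
}

#' Run the reconstruction-and-analysis pipeline
#'
#' Runs simulate -> segment -> register -> reconstruct -> project -> analyze
#' on a synthetic phantom (the default), or segment -> analyze on a section
#' series read from `input.series_dir` with manual visibility labels from
#' `input.labels_csv`.  All randomness flows from `config$rng_seed`; a rerun
#' with the same configuration and seed reproduces identical output hashes.
#' When `output_dir` is set, every stage product is written there along with
#' `manifest.json` (configuration echo, software version, seed, timestamps
#' and per-file MD5 hashes).
#'
#' @param config A `run_config` (or arguments for one).
#' @param output_dir Output directory; overrides `config$output_dir`.
#'   `NULL` keeps everything in memory.
#' @param quiet Suppress stage progress messages.
#' @return Invisibly, a list with the stage products: `spec`, `truth`,
#'   `series`, `chain`, `volume`, `surface`, `field`, `projections`, `bli`,
#'   `grid`, `analysis`, and `output_dir`.
#' @export
run_pipeline <- function(config = run_config(), output_dir = NULL,
                         quiet = FALSE) {
  cfg <- validate_run_config(config)
  out <- output_dir %||% cfg$output_dir
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tic <- Sys.time()
    r <- force(expr)
    say("[%s] %.1f s", name, as.numeric(difftime(Sys.time(), tic, "secs")))
    r
  }

  from_phantom <- is.null(cfg$input$series_dir)
  spec <- NULL; truth <- NULL; phantom <- NULL
  if (from_phantom) {
    spec <- do.call(phantom_spec, c(cfg$phantom, list(rng_seed = cfg$rng_seed)))
    phantom <- stage("simulate", build_phantom(spec))
    truth <- phantom$truth
    series <- stage("section", section_volume(phantom$volume, spec))
  } else {
    series <- stage("read", read_section_series(cfg$input$series_dir))
  }

  chain <- stage("register", register_series(
    series, feature = cfg$registration$feature,
    threshold = cfg$registration$threshold,
    feature_cap = cfg$registration$feature_cap,
    max_rotation = cfg$registration$max_rotation,
    rotation_step = cfg$registration$rotation_step,
    search_radius = cfg$registration$search_radius,
    anchor = cfg$registration$anchor))

  volume <- stage("stack", stack_series(
    series, chain, threshold = cfg$segmentation$threshold,
    closing_radius = cfg$segmentation$closing_radius,
    min_object_area = cfg$segmentation$min_object_area))

  surface <- stage("surface", extract_surface(
    volume, cfg$reconstruction$smoothing_window))
  field <- stage("depth", compute_depth_field(
    volume, surface, cfg$reconstruction$depth_mode))

  projections <- stage("project", lapply(cfg$projection$windows, function(w)
    depth_window_projection(field, w, cfg$projection$kind)))
  names(projections) <- paste0("window_", cfg$projection$windows)

  # analysis ROI: a band across the footprint middle unless configured
  d <- dim(volume$vessel)
  ext <- d[1:2] * volume$voxel_size[1:2]
  roi <- cfg$analysis$roi %||% c(0, ext[2] / 3, ext[1], ext[2] * 2 / 3)
  grid <- divide_roi(roi, cfg$analysis$n_areas)

  bli <- NULL
  if (from_phantom) {
    bli <- stage("render", render_virtual_bli(
      phantom$volume, truth, visibility_scale = cfg$bli$visibility_scale,
      hard_cutoff = cfg$bli$hard_cutoff,
      render_orifices = cfg$bli$render_orifices))
    visible <- label_visibility(grid, bli,
                                contrast_threshold = cfg$analysis$contrast_threshold)
  } else {
    if (is.null(cfg$input$labels_csv))
      stop("input.labels_csv is required when analysing user data", call. = FALSE)
    visible <- label_visibility(grid, read_visibility_labels(cfg$input$labels_csv))
  }

  analysis <- stage("analyze", analyze_visibility(
    field, grid, visible, max_depth = cfg$analysis$max_depth,
    reconcile = cfg$analysis$reconcile,
    lateral_tolerance = cfg$analysis$lateral_tolerance))

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    if (from_phantom) {
      write_section_series(series, file.path(out, "series"))
      write_ground_truth(truth, file.path(out, "truth"))
      write_image(bli, file.path(out, "virtual_bli.tif"))
    }
    write_transform_chain(chain, file.path(out, "transforms.csv"))
    write_volume(volume, file.path(out, "volume"))
    suppressWarnings(tiff::writeTIFF(
      ifelse(is.na(surface$height), 0, surface$height) / 1000,
      file.path(out, "surface_height.tif"), bits.per.sample = 32L))
    comps <- analysis_components_table(field)
    utils::write.csv(comps, file.path(out, "component_depths.csv"),
                     row.names = FALSE)
    for (nm in names(projections))
      write_image(projections[[nm]], file.path(out, paste0(nm, "_um.tif")))
    write_area_records(analysis$records, file.path(out, "area_records.csv"))
    write_summary_json(analysis$summary, analysis$test,
                       file.path(out, "summary.json"))
    plot_depth_by_area(analysis$records,
                       file.path(out, "depth_by_area.png"))
    write_run_manifest(cfg, out, t0)
  }

  say("pipeline done in %.1f s",
      as.numeric(difftime(Sys.time(), t0, "secs")))
  invisible(list(spec = spec, truth = truth, series = series, chain = chain,
                 volume = volume, surface = surface, field = field,
                 projections = projections, bli = bli, grid = grid,
                 analysis = analysis, output_dir = out))
}

analysis_components_table <- function(field) {
  comps <- field$components
  names(comps) <- c("id", "x_um", "y_um", "z_um", "depth_um", "n_voxels")
  comps
}

plot_depth_by_area <- function(records, path) {
  grDevices::png(path, width = 900, height = 450)
  on.exit(grDevices::dev.off())
  use <- !records$censored
  graphics::plot(records$area_id[use], records$nearest_depth[use],
                 col = ifelse(records$visible[use], "brown", "steelblue"),
                 pch = ifelse(records$excluded[use], 4, 19),
                 xlab = "area", ylab = "nearest vessel depth (um)",
                 main = "per-area nearest-vessel depth (brown = visible on BLI)",
                 ylim = rev(range(records$nearest_depth[use], na.rm = TRUE)))
  graphics::grid()
  invisible(path)
}

write_run_manifest <- function(cfg, out, t0) {
  files <- list.files(out, recursive = TRUE, full.names = FALSE)
  files <- setdiff(files, "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out, files)))
  names(hashes) <- files
  write_json_file(list(
    package = "vasc3d",
    version = as.character(utils::packageVersion("vasc3d")),
    rng_seed = cfg$rng_seed,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    files = hashes), file.path(out, "manifest.json"))
  invisible(out)
}
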