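test_that("phantom specification enforces its invariants", {
  expect_error(phantom_spec(broken_wall_fraction = 1.5), "broken_wall_fraction")
  expect_error(phantom_spec(epithelium_stain_period = 0), "epithelium_stain_period")
  expect_error(phantom_spec(vessel_depth_range = c(100, 50)), "vessel_depth_range")
  expect_error(phantom_spec(n_slices = 120, volume_extent = c(64, 100, 175)),
               "exceeds the volume extent")
  # too small to hold a single crypt
  expect_error(build_phantom(phantom_spec(n_slices = 4,
                                          volume_extent = c(20, 4, 175))),
               "too small to hold a single crypt")
})

test_that("phantom generation is deterministic given the seed", {
  spec <- phantom_spec(n_slices = 6, volume_extent = c(96, 6, 175),
                       rng_seed = 17)
  a <- build_phantom(spec); b <- build_phantom(spec)
  expect_identical(a$volume$labels, b$volume$labels)
  expect_identical(a$truth$vessel_components, b$truth$vessel_components)
  sa <- section_volume(a$volume, spec); sb <- section_volume(b$volume, spec)
  expect_identical(lapply(sa$slices, `[[`, "image"),
                   lapply(sb$slices, `[[`, "image"))
  ra <- render_virtual_bli(a$volume, a$truth)
  rb <- render_virtual_bli(b$volume, b$truth)
  expect_identical(as.vector(ra), as.vector(rb))
})

test_that("a collapsed depth range places every vessel at that depth", {
  ph <- parallel_phantom(n_slices = 8, nx = 150, nz = 175,
                         depth_range = c(100, 100), seed = 2)
  expect_gt(nrow(ph$truth$vessel_components), 2)
  expect_equal(ph$truth$vessel_components$true_depth,
               rep(100, nrow(ph$truth$vessel_components)), tolerance = 1e-6)
})

test_that("a crypt pitch larger than the footprint degrades to one crypt", {
  spec <- phantom_spec(n_slices = 8, volume_extent = c(160, 8, 175),
                       crypt_pitch = 5000, rng_seed = 1)
  ph <- build_phantom(spec)
  expect_equal(nrow(ph$truth$crypt_orifices), 1L)
})

test_that("lumen volume matches the analytic cylinder volume", {
  ph <- parallel_phantom(n_slices = 20, nx = 300, nz = 175, spacing = 24,
                         depth_range = c(30, 120), seed = 6,
                         vessel_radius_mean = 5, vessel_radius_sd = 0)
  n_t <- nrow(ph$truth$vessel_components)
  lum <- sum(ph$volume$labels == tissue_labels()[["vessel_lumen"]]) *
    prod(ph$spec$voxel_size)
  analytic <- n_t * pi * 5^2 * (20 * 3)   # sum of pi r^2 l over tubes
  expect_lt(abs(lum / analytic - 1), 0.10)
})

test_that("the sectioned series realises the stain schedule and jitter bookkeeping", {
  fx <- clean_honeycomb()
  series <- fx$series
  expect_length(series$slices, fx$spec$n_slices)
  # consecutive indices from 0, epithelium stain exactly on the period
  idx <- vapply(series$slices, `[[`, integer(1), "index")
  expect_identical(idx, seq_len(fx$spec$n_slices) - 1L)
  stains <- vapply(series$slices, `[[`, character(1), "stain")
  expect_identical(stains == "epithelium_stain",
                   idx %% fx$spec$epithelium_stain_period ==
                     fx$spec$stain_period_offset)
  # all images share a shape; series spans n_slices * thickness
  shp <- unique(lapply(series$slices, function(s) dim(s$image)))
  expect_length(shp, 1L)
  expect_equal(fx$spec$n_slices * fx$spec$slice_thickness,
               fx$spec$volume_extent[2] * fx$spec$voxel_size[2])
  # zero jitter bounds record identity transforms
  for (s in series$slices)
    expect_equal(c(s$true_transform$dx, s$true_transform$dy,
                   s$true_transform$theta), c(0, 0, 0))
})

test_that("unbroken vessel walls are closed rings (flood-fill oracle)", {
  fx <- clean_honeycomb()
  lum_code <- tissue_labels()[["vessel_lumen"]]
  wall_code <- tissue_labels()[["vessel_wall"]]
  checked <- 0L
  for (k in seq_along(fx$series$slices)) {
    s <- fx$series$slices[[k]]
    if (s$stain != "vessel_stain") next
    plane <- fx$volume$labels[, k, ]
    if (!any(plane == wall_code)) next
    enc <- enclosed_background(s$image >= 0.5)
    # the enclosed holes of the wall stain are exactly the lumen voxels
    expect_identical(enc, plane == lum_code)
    checked <- checked + 1L
  }
  expect_gt(checked, 4L)
})

test_that("broken-wall rescue matches the closing-then-flood-fill oracle", {
  spec <- phantom_spec(n_slices = 9, volume_extent = c(128, 9, 175),
                       broken_wall_fraction = 1, broken_wall_gap = 3,
                       jitter_max_translation = 0, noise_sd = 0, rng_seed = 5)
  ph <- build_phantom(spec)
  series <- section_volume(ph$volume, spec)
  lum_code <- tissue_labels()[["vessel_lumen"]]
  lum_total <- 0L; lum_rescued <- 0L
  for (k in seq_along(series$slices)) {
    s <- series$slices[[k]]
    if (s$stain != "vessel_stain") next
    plane <- ph$volume$labels[, k, ]
    if (!any(plane == lum_code)) next
    wall <- s$image >= 0.5
    filled <- fill_vessel_lumens(wall, closing_radius = 2)
    # exact agreement with the independent oracle
    closed <- as.matrix(EBImage::closing(wall * 1,
                                         EBImage::makeBrush(5, "disc"))) > 0.5
    oracle <- closed | enclosed_background(closed) | wall
    expect_identical(unname(filled), unname(oracle))
    expect_true(all(filled[wall]))               # output contains input
    lum_total <- lum_total + sum(plane == lum_code)
    lum_rescued <- lum_rescued + sum(filled[plane == lum_code])
  }
  # with every wall broken by a small arc, most lumens are still recovered
  expect_gt(lum_rescued / lum_total, 0.5)
})

test_that("the virtual BLI render follows the exponential depth-contrast law", {
  # hand-built volume: three tubes at depths 30, 60 and 150 um
  dims <- c(30L, 10L, 60L)
  labels <- array(tissue_labels()[["stroma"]], dims)
  comp <- array(0L, dims)
  place <- function(labels, comp, i, k, id) {
    labels[i, , k] <- tissue_labels()[["vessel_lumen"]]
    comp[i, , k] <- id
    list(labels, comp)
  }
  r <- place(labels, comp, 5L, 10L, 1L);  labels <- r[[1]]; comp <- r[[2]]
  r <- place(labels, comp, 15L, 20L, 2L); labels <- r[[1]]; comp <- r[[2]]
  r <- place(labels, comp, 25L, 50L, 3L); labels <- r[[1]]; comp <- r[[2]]
  volume <- structure(list(labels = labels, voxel_size = c(2, 3, 3),
                           orientation = "vertical_section"),
                      class = "tissue_volume")
  truth <- structure(list(
    surface_height = matrix(0, dims[1], dims[2]),
    vessel_components = data.frame(id = 1:3, x = c(9, 29, 49), y = 15,
                                   z = c(28.5, 58.5, 148.5),
                                   true_depth = c(30, 60, 150),
                                   n_voxels = 10L),
    crypt_orifices = data.frame(x = numeric(), y = numeric(),
                                radius = numeric()),
    component_labels = comp), class = "phantom_truth")

  img <- render_virtual_bli(volume, truth, visibility_scale = 40,
                            hard_cutoff = 80)
  c1 <- 1 - img[5, 1]; c2 <- 1 - img[15, 1]; c3 <- 1 - img[25, 1]
  expect_equal(c1, exp(-30 / 40), tolerance = 1e-12)
  expect_equal(c1 / c2, exp(30 / 40), tolerance = 1e-9)
  expect_equal(c3, 0)   # beyond the cutoff: invisible

  # a vessel at depth 0 darkens maximally
  truth$vessel_components$true_depth[1] <- 0
  img0 <- render_virtual_bli(volume, truth, visibility_scale = 40,
                             hard_cutoff = 80)
  expect_equal(1 - img0[5, 1], 1)

  expect_error(render_virtual_bli(volume, truth, visibility_scale = 0),
               "visibility_scale")
})
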