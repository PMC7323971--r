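test_that("stacking produces the right anisotropic geometry", {
  fx <- clean_honeycomb()
  chain <- register_series(fx$series, refine = FALSE)
  vol <- stack_series(fx$series, chain)
  d <- dim(vol$vessel)
  expect_equal(d[2], fx$spec$n_slices)             # stack axis (vertical)
  expect_equal(vol$voxel_size, c(2, 3, 2))
  expect_equal(vol$depth_axis, 3L)
  expect_identical(dim(vol$epithelium), dim(vol$vessel))

  # horizontal orientation: 100 slices of 3 um span 300 um along depth
  hspec <- phantom_spec(orientation = "horizontal_section",
                        vessel_layout = "parallel", n_slices = 100,
                        volume_extent = c(96, 96, 100), vessel_spacing = 30,
                        vessel_depth_range = c(20, 250),
                        jitter_max_translation = 0, noise_sd = 0,
                        broken_wall_fraction = 0, rng_seed = 2)
  hser <- section_volume(build_phantom(hspec)$volume, hspec)
  hvol <- stack_series(hser, NULL)
  expect_equal(dim(hvol$vessel)[3] * hvol$voxel_size[3], 300)

  # a 1.5 mm x 1.0 mm x 0.4 mm block is representable
  blk <- structure(list(epithelium = array(FALSE, c(150, 100, 40)),
                        vessel = array(FALSE, c(150, 100, 40)),
                        voxel_size = c(10, 10, 10),
                        orientation = "horizontal_section", depth_axis = 3L),
                   class = "labeled_volume")
  expect_equal(dim(blk$vessel) * blk$voxel_size, c(1500, 1000, 400))

  # empty masks stack to empty channels without failure
  empty_series <- fx$series
  for (k in seq_along(empty_series$slices))
    empty_series$slices[[k]]$image[] <- 0
  evol <- stack_series(empty_series, NULL)
  expect_equal(sum(evol$vessel), 0)
  expect_equal(sum(evol$epithelium), 0)
})

test_that("surface extraction recovers flat and sinusoidal phantom surfaces", {
  ph <- parallel_phantom(n_slices = 12, nx = 180, nz = 175, seed = 4,
                         depth_range = c(50, 200))
  vol <- as_labeled_volume(ph$volume)
  surf <- extract_surface(vol)
  inside <- surf$valid
  expect_true(all(abs(surf$height[inside] -
                        ph$truth$surface_height[inside]) <=
                    vol$voxel_size[3]))
  # glass-margin columns carry no tissue and are invalid
  expect_false(surf$valid[2, 2])

  ph2 <- parallel_phantom(n_slices = 16, nx = 300, nz = 200, seed = 4,
                          depth_range = c(60, 250), surface_amplitude = 10,
                          surface_period = 200)
  vol2 <- as_labeled_volume(ph2$volume)
  surf2 <- extract_surface(vol2)
  err <- abs(surf2$height - ph2$truth$surface_height)[surf2$valid]
  expect_true(all(err <= vol2$voxel_size[3]))

  empty <- structure(list(epithelium = array(FALSE, c(4, 4, 4)),
                          vessel = array(FALSE, c(4, 4, 4)),
                          voxel_size = c(1, 1, 1),
                          orientation = "vertical_section", depth_axis = 3L),
                     class = "labeled_volume")
  expect_error(extract_surface(empty), "no tissue")
})

test_that("component depths are recovered within a slice plus a pixel", {
  ph <- parallel_phantom(n_slices = 15, nx = 400, nz = 200, seed = 4,
                         depth_range = c(10, 300))
  vol <- as_labeled_volume(ph$volume)
  surf <- extract_surface(vol)
  field <- compute_depth_field(vol, surf, "axis")
  m <- match_components(ph$truth$vessel_components, field$components)
  expect_gte(nrow(m), 10)
  expect_true(all(abs(m$recovered_depth - m$truth_depth) <=
                    ph$spec$slice_thickness + max(ph$spec$voxel_size[c(1, 3)])))

  # axis and euclidean modes agree exactly on a flat surface
  fe <- compute_depth_field(vol, surf, "euclidean")
  va <- field$depth[!is.na(field$depth)]
  ve <- fe$depth[!is.na(fe$depth)]
  expect_equal(va, ve, tolerance = 1e-9)
})

test_that("depth-window projections nest and saturate", {
  ph <- parallel_phantom(n_slices = 15, nx = 300, nz = 200, seed = 9,
                         depth_range = c(10, 300))
  vol <- as_labeled_volume(ph$volume)
  field <- compute_depth_field(vol, extract_surface(vol))
  p50 <- depth_window_projection(field, 50)
  p100 <- depth_window_projection(field, 100)
  p150 <- depth_window_projection(field, 150)
  expect_true(all(p100$image[p50$image]))
  expect_true(all(p150$image[p100$image]))
  # a window beyond the deepest vessel equals the full top view
  pall <- depth_window_projection(field, 1e4)
  full <- apply(vol$vessel, c(1, 2), any)
  expect_identical(unname(pall$image), unname(full))
  # counts sum the voxels per column
  pc <- depth_window_projection(field, 1e4, "count")
  expect_equal(sum(pc$image), sum(vol$vessel))
  # component conservation: the projection cannot show more components
  proj_comp <- label_components_3d(as.vector(p150$image),
                                   c(dim(p150$image), 1L))
  expect_lte(max(proj_comp), nrow(field$components))
  expect_error(depth_window_projection(field, 0), "window")
})

test_that("cross-sections sample the volume along top-view lines", {
  ph <- parallel_phantom(n_slices = 15, nx = 200, nz = 175, seed = 12,
                         depth_range = c(40, 250))
  vol <- as_labeled_volume(ph$volume)
  # an axis-aligned line along x at a stack position reproduces that slice
  yq <- 22  # um, centre of slice 8 (voxel 3 um)
  cs <- cross_section(vol, rbind(c(1, yq), c(399, yq)), thickness = 1)
  k <- ceiling(yq / vol$voxel_size[2])
  ref <- t(vol$vessel[, k, ])
  got <- cs[, seq(1, ncol(cs), length.out = ncol(ref))]
  # vessel pixels of the slice appear as vessel in the section
  expect_gt(sum(cs == 2), 0)
  field <- compute_depth_field(vol, extract_surface(vol))
  comp <- field$components[1, ]
  cs2 <- cross_section(vol, rbind(c(comp$x - 30, comp$y),
                                  c(comp$x + 30, comp$y)))
  rows <- which(rowSums(cs2 == 2) > 0)
  depth_rows <- rows * attr(cs2, "depth_step")
  expect_true(any(abs(depth_rows - (comp$depth + 24)) < 15))
  # thicker sections are unions of thin ones
  cs_thin <- cross_section(vol, rbind(c(50, yq), c(150, yq)), thickness = 1)
  cs_thick <- cross_section(vol, rbind(c(50, yq), c(150, yq)), thickness = 3)
  expect_true(all(cs_thick[cs_thin == 2] == 2))
  expect_error(cross_section(vol, rbind(c(5, 5), c(5, 5))), "zero-length")
})
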