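# hand-built depth field: components at chosen depths and lateral positions
toy_field <- function(xs, depths, nx = 60, ny = 6, nz = 10,
                      voxel = c(10, 10, 10)) {
  comp <- array(0L, c(nx, ny, nz))
  depth <- array(NA_real_, c(nx, ny, nz))
  for (q in seq_along(xs)) {
    i <- ceiling(xs[q] / voxel[1])
    comp[i, , 2] <- q
    depth[i, , 2] <- depths[q]
  }
  structure(list(
    depth = depth, component_labels = comp,
    components = data.frame(id = seq_along(xs), x = xs, y = ny * voxel[2] / 2,
                            z = depths, depth = depths,
                            n_voxels = ny),
    mode = "axis", n_excluded = 0L, voxel_size = voxel),
    class = "depth_field")
}

test_that("ROI division yields equal cells that tile the line exactly", {
  g <- divide_roi(c(0, 0, 860, 30), 50)
  w <- g$cells$x1 - g$cells$x0
  expect_equal(unique(round(w, 9)), 17.2)          # 0.86 mm / 50
  expect_equal(sum(w), 860)
  g2 <- divide_roi(c(0, 0, 100, 10), 2)
  expect_equal(g2$cells$x0, c(0, 50))
  expect_error(divide_roi(c(0, 0, 100, 10), 1), "n_areas")
  expect_error(divide_roi(c(0, 0, 10, 2), 50, pixel_size = 2), "narrower")
})

test_that("nearest-vessel depth takes the minimum and censors beyond the bound", {
  fld <- toy_field(xs = c(55, 75, 250, 455), depths = c(30, 120, 450, 80))
  g <- divide_roi(c(0, 0, 600, 60), 6)   # 100 um cells
  d <- nearest_vessel_depth(g, fld, max_depth = 400)
  expect_equal(d[1], 30)        # components at 30 and 120: minimum wins
  expect_true(is.na(d[3]))      # only component is at 450 -> censored
  expect_equal(d[5], 80)
  expect_true(is.na(d[6]))      # no vessel at all
})

test_that("virtual visibility labels equal the depth-cutoff indicator", {
  ph <- parallel_phantom(n_slices = 10, nx = 600, nz = 200, spacing = 24,
                         depth_range = c(10, 300), seed = 14)
  vol <- as_labeled_volume(ph$volume)
  field <- compute_depth_field(vol, extract_surface(vol))
  tr <- ph$truth$vessel_components
  xs <- sort(tr$x)
  roi <- c(min(xs) - 12, 0, min(xs) - 12 + 24 * length(xs), 30)
  g <- divide_roi(roi, length(xs))
  bli <- render_virtual_bli(ph$volume, ph$truth, visibility_scale = 40,
                            hard_cutoff = 80)
  vis <- label_visibility(g, bli)
  truth_vis <- tr$true_depth[order(tr$x)] <= 80
  expect_identical(as.logical(vis), truth_vis)
  expect_equal(attr(vis, "visibility_source"), "virtual_bli")

  # an all-bright image labels everything invisible
  blank <- matrix(1, nrow(bli), ncol(bli))
  attr(blank, "pixel_size") <- attr(bli, "pixel_size")
  expect_false(any(label_visibility(g, blank)))

  # manual labels pass through verbatim and validate their count
  man <- data.frame(area_id = seq_len(g$n_areas),
                    visible = rep_len(c(1, 0), g$n_areas))
  vm <- label_visibility(g, man)
  expect_identical(as.logical(vm), as.logical(man$visible))
  expect_error(label_visibility(g, man[-1, ]), "does not match")
})

test_that("gap reconciliation only touches discordant areas", {
  # cell 1: visible but nearest in-cell vessel deep (220 um); a shallow
  # component sits 5 um outside the cell boundary
  fld <- toy_field(xs = c(55, 105), depths = c(220, 30))
  g <- divide_roi(c(0, 0, 200, 60), 2)    # cells [0,100], [100,200]
  rec <- area_records(g, c(220, 30),
                      structure(c(TRUE, TRUE),
                                visibility_source = "manual_label"))
  out0 <- reconcile_gaps(rec, g, fld, lateral_tolerance = 0)
  expect_identical(out0$nearest_depth, rec$nearest_depth)

  out <- reconcile_gaps(rec, g, fld, lateral_tolerance = 10, threshold = 80)
  expect_equal(out$nearest_depth[1], 30)
  expect_true(out$corrected[1])
  expect_equal(attr(out, "n_corrected"), 1L)
  # the concordant cell 2 (visible, 30 um) is untouched
  expect_equal(out$nearest_depth[2], 30)
  expect_false(out$corrected[2])

  # an unresolvable discordant cell is excluded
  fld2 <- toy_field(xs = c(55), depths = c(220))
  g1 <- divide_roi(c(0, 0, 200, 60), 2)
  rec2 <- area_records(g1, c(220, NA),
                       structure(c(TRUE, FALSE),
                                 visibility_source = "manual_label"))
  out2 <- reconcile_gaps(rec2, g1, fld2, lateral_tolerance = 10,
                         threshold = 80)
  expect_true(out2$excluded[1])
})

test_that("summaries report medians, ranges and the boundary midpoint", {
  g <- divide_roi(c(0, 0, 500, 10), 5)
  rec <- area_records(g, c(20, 40, 76, 80, 150),
                      structure(c(TRUE, TRUE, TRUE, FALSE, FALSE),
                                visibility_source = "manual_label"))
  s <- summarize_visibility(rec)
  expect_equal(s$boundary_estimate, 78)    # midpoint of [76, 80]
  expect_equal(s$median_visible, 40)
  expect_equal(s$range_invisible, c(80, 150))

  rec2 <- area_records(divide_roi(c(0, 0, 200, 10), 2), c(10, 100),
                       structure(c(TRUE, FALSE),
                                 visibility_source = "manual_label"))
  s2 <- summarize_visibility(rec2)
  expect_equal(c(s2$median_visible, s2$median_invisible,
                 s2$boundary_estimate), c(10, 100, 55))

  # overlapping groups fall back to the visibility-fraction crossing
  rec3 <- area_records(divide_roi(c(0, 0, 400, 10), 4),
                       c(20, 90, 60, 150),
                       structure(c(TRUE, TRUE, FALSE, FALSE),
                                 visibility_source = "manual_label"))
  expect_warning(s3 <- summarize_visibility(rec3), "overlap")
  expect_equal(s3$boundary_method, "crossing")

  rec4 <- rec2; rec4$visible <- c(TRUE, TRUE)
  expect_error(summarize_visibility(rec4), "invisible")
})

test_that("the visibility boundary recovers the renderer cutoff", {
  ph <- parallel_phantom(n_slices = 12, nx = 1100, nz = 200, spacing = 20,
                         depth_range = c(10, 300), seed = 9)
  vol <- as_labeled_volume(ph$volume)
  field <- compute_depth_field(vol, extract_surface(vol))
  tr <- ph$truth$vessel_components
  xs <- sort(tr$x)
  roi <- c(min(xs) - 10, 0, min(xs) - 10 + 20 * length(xs), 36)
  g <- divide_roi(roi, length(xs))
  bli <- render_virtual_bli(ph$volume, ph$truth, visibility_scale = 40,
                            hard_cutoff = 80)
  res <- analyze_visibility(field, g, label_visibility(g, bli))
  expect_lt(abs(res$summary$boundary_estimate - 80), 10)
  expect_lt(res$summary$median_visible, res$summary$median_invisible)
  expect_lt(res$test$p_two_sided, 0.05)
})
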