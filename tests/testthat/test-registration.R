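test_that("pairwise estimation recovers constructed shifts and rotations", {
  fx <- clean_honeycomb()
  img <- fx$series$slices[[2]]$image

  t0 <- estimate_pairwise(img, img)
  expect_equal(c(t0$dx, t0$dy, t0$theta), c(0, 0, 0), tolerance = 0.05)

  sh <- apply_transform(img, rigid_transform(3, -2), "nearest")
  t1 <- estimate_pairwise(img, sh, search_radius = 10)
  expect_equal(c(t1$dx, t1$dy), c(-3, 2), tolerance = 0.05)

  rot <- apply_transform(img, rigid_transform(theta = 2), "linear")
  t2 <- estimate_pairwise(img, rot, max_rotation = 4, rotation_step = 0.5,
                          search_radius = 10)
  expect_lt(abs(t2$theta - (-2)), 0.5)

  expect_warning(t3 <- estimate_pairwise(matrix(0, 10, 10), matrix(0, 10, 10)),
                 "constant")
  expect_equal(c(t3$dx, t3$dy, t3$theta), c(0, 0, 0))
})

test_that("transform propagation composes outward from the anchor", {
  id <- rigid_transform()
  chain <- propagate(list(id, id, id), anchor = 2)
  for (t in chain$absolute)
    expect_equal(c(t$dx, t$dy, t$theta), c(0, 0, 0))

  # pure translations accumulate as running sums
  pw <- list(rigid_transform(1, 0), rigid_transform(2, -1),
             rigid_transform(-0.5, 3))
  chain <- propagate(pw, anchor = 1)
  expect_equal(c(chain$absolute[[2]]$dx, chain$absolute[[2]]$dy), c(1, 0))
  expect_equal(c(chain$absolute[[3]]$dx, chain$absolute[[3]]$dy), c(3, -1))
  expect_equal(c(chain$absolute[[4]]$dx, chain$absolute[[4]]$dy), c(2.5, 2))

  # middle anchor of three slices: single pairwise terms, one inverted
  pw2 <- list(rigid_transform(2, 1), rigid_transform(-1, 4))
  ch2 <- propagate(pw2, anchor = 2)
  expect_equal(c(ch2$absolute[[1]]$dx, ch2$absolute[[1]]$dy), c(-2, -1))
  expect_equal(c(ch2$absolute[[3]]$dx, ch2$absolute[[3]]$dy), c(-1, 4))

  expect_error(propagate(pw, anchor = 9), "out of range")
})

test_that("epithelium pairing follows the nearest-index rule with low-index ties", {
  stains <- rep("vessel_stain", 7)
  stains[c(1, 4, 7)] <- "epithelium_stain"   # 0-based indices 0, 3, 6
  p <- assign_epithelium(stains)
  expect_equal(p[2], 1)   # slice index 1 pairs with 0
  expect_equal(p[3], 4)   # slice index 2 pairs with 3 (|2-3| < |2-0|)
  # equidistant between epithelium slices -> lower index wins
  stains2 <- rep("vessel_stain", 6)
  stains2[c(4, 6)] <- "epithelium_stain"
  expect_equal(assign_epithelium(stains2)[5], 4)
  # a single epithelium slice captures everything
  stains3 <- c("epithelium_stain", rep("vessel_stain", 4))
  expect_true(all(assign_epithelium(stains3) == 1))
  expect_error(assign_epithelium(rep("vessel_stain", 3)), "no epithelium")
})

test_that("jittered phantom series are recovered within fractions of a pixel", {
  spec <- phantom_spec(tissue_class = "normal", n_slices = 40,
                       volume_extent = c(192, 40, 175),
                       jitter_max_translation = 3, noise_sd = 0.02,
                       broken_wall_fraction = 0.1, rng_seed = 23)
  ph <- build_phantom(spec)
  series <- section_volume(ph$volume, spec)
  chain <- register_series(series)
  err <- chain_truth_error(series, chain)
  expect_lt(sqrt(mean(err^2)), 0.5)
})

test_that("re-estimating transforms on the aligned series yields near-identity", {
  spec <- phantom_spec(tissue_class = "normal", n_slices = 15,
                       volume_extent = c(160, 15, 175),
                       jitter_max_translation = 3, noise_sd = 0.02,
                       broken_wall_fraction = 0.1, rng_seed = 31)
  ph <- build_phantom(spec)
  series <- section_volume(ph$volume, spec)
  chain <- register_series(series)
  aligned <- lapply(seq_along(series$slices), function(k)
    apply_transform(series$slices[[k]]$image, chain$absolute[[k]], "linear"))
  feats <- lapply(aligned, function(img) (img >= 0.1) * 1)
  for (k in seq_len(length(feats) - 1)) {
    t <- estimate_pairwise(feats[[k]], feats[[k + 1]], search_radius = 6)
    expect_lt(abs(t$dx), 0.5)
    expect_lt(abs(t$dy), 0.5)
  }
})
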