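test_that("fixed-threshold segmentation and degenerate inputs behave", {
  z <- matrix(0, 10, 10)
  expect_equal(sum(segment_positive(z, "fixed", 0.5)$pixels), 0)
  expect_warning(m <- segment_positive(z, "automatic"), "constant image")
  expect_equal(sum(m$pixels), 0)
  expect_error(segment_positive(z, "fixed"), "threshold")
  expect_error(segment_positive(matrix(c(1, NA), 2, 2)), "finite")
})

test_that("automatic threshold separates a bimodal image like a brute-force sweep", {
  set.seed(11)
  lo <- rnorm(600, 0.2, 0.04)
  hi <- rnorm(400, 0.8, 0.04)
  img <- matrix(sample(c(lo, hi)), 25, 40)
  # oracle: exhaustive sweep maximising between-class variance
  cand <- sort(unique(as.vector(img)))
  bcv <- vapply(cand[-length(cand)], function(t) {
    w1 <- mean(img <= t); w2 <- 1 - w1
    if (w1 == 0 || w2 == 0) return(0)
    w1 * w2 * (mean(img[img <= t]) - mean(img[img > t]))^2
  }, numeric(1))
  t_oracle <- cand[which.max(bcv)]
  auto <- segment_positive(img, "automatic")
  fixed <- segment_positive(img, "fixed", (0.2 + 0.8) / 2)
  expect_identical(auto$pixels, fixed$pixels)
  expect_identical(auto$pixels, img > t_oracle)
})

test_that("lumen filling fills closed rings and respects the closing radius", {
  ring <- function(gap_px = 0) {
    m <- matrix(FALSE, 41, 41)
    rr <- sqrt((row(m) - 21)^2 + (col(m) - 21)^2)
    m[rr >= 9 & rr < 12] <- TRUE
    if (gap_px > 0) {
      dd <- sqrt((row(m) - 21)^2 + (col(m) - 31.5)^2)
      m[m & dd <= gap_px / 2] <- FALSE
    }
    m
  }
  # perfect ring fills to a disk
  filled <- fill_vessel_lumens(ring(), closing_radius = 0)
  expect_true(all(filled[sqrt((row(filled) - 21)^2 + (col(filled) - 21)^2) < 9]))

  # a gap within twice the closing radius is rescued; a larger one is not
  inner <- sqrt((row(ring()) - 21)^2 + (col(ring()) - 21)^2) < 7
  f_small <- fill_vessel_lumens(ring(gap_px = 3), closing_radius = 2)
  f_big <- fill_vessel_lumens(ring(gap_px = 6), closing_radius = 2)
  expect_true(all(f_small[inner]))
  expect_false(any(f_big[inner]))

  # equivalence with the flood-fill-from-border oracle after explicit closing
  for (g in c(0, 3, 6)) {
    m <- ring(gap_px = g)
    got <- fill_vessel_lumens(m, closing_radius = 2)
    closed <- as.matrix(EBImage::closing(m * 1,
                                         EBImage::makeBrush(5, "disc"))) > 0.5
    oracle <- closed | enclosed_background(closed) | m
    expect_identical(got, oracle)
  }

  # empty mask stays empty; negative radius rejected
  e <- matrix(FALSE, 5, 5)
  expect_identical(fill_vessel_lumens(e, 2), e)
  expect_error(fill_vessel_lumens(e, -1), "closing_radius")
})

test_that("lumen filling is monotone and idempotent on random ring fields", {
  set.seed(7)
  for (rep in 1:5) {
    m <- matrix(FALSE, 60, 60)
    for (v in 1:4) {
      ci <- sample(12:48, 1); cj <- sample(12:48, 1); r0 <- sample(4:8, 1)
      rr <- sqrt((row(m) - ci)^2 + (col(m) - cj)^2)
      m[rr >= r0 & rr < r0 + 2] <- TRUE
    }
    f1 <- fill_vessel_lumens(m, closing_radius = 2)
    f2 <- fill_vessel_lumens(f1, closing_radius = 2)
    expect_true(all(f1[m]))        # output contains input
    expect_identical(f1, f2)       # idempotent
  }
})

test_that("filled vessel masks equal the phantom wall-and-lumen labels pixel-exactly", {
  fx <- clean_honeycomb()
  wall <- tissue_labels()[["vessel_wall"]]
  lum <- tissue_labels()[["vessel_lumen"]]
  for (k in seq_along(fx$series$slices)) {
    s <- fx$series$slices[[k]]
    if (s$stain != "vessel_stain") next
    plane <- fx$volume$labels[, k, ]
    got <- fill_vessel_lumens(segment_positive(s$image, "fixed", 0.5),
                              closing_radius = 0)
    expect_identical(got$pixels, plane == wall | plane == lum)
  }
})

test_that("epithelium segmentation matches the phantom labels and removes speckle", {
  fx <- clean_honeycomb()
  epi <- tissue_labels()[["epithelium"]]
  for (k in seq_along(fx$series$slices)) {
    s <- fx$series$slices[[k]]
    if (s$stain != "epithelium_stain") next
    plane <- fx$volume$labels[, k, ]
    got <- segment_epithelium(s$image, min_object_area = 0,
                              method = "fixed", threshold = 0.5)
    expect_identical(got$pixels, plane == epi)
  }

  # speckle noise only, below the area threshold -> empty
  set.seed(3)
  sp <- matrix(0, 50, 50)
  sp[cbind(sample(50, 12), sample(50, 12))] <- 1
  expect_equal(sum(segment_epithelium(sp, min_object_area = 5,
                                      method = "fixed",
                                      threshold = 0.5)$pixels), 0)

  # min_object_area = 0 equals positive segmentation plus hole filling
  img <- fx$series$slices[[1]]$image
  a <- segment_epithelium(img, 0, method = "fixed", threshold = 0.5)
  b <- segment_positive(img, "fixed", 0.5)
  b$pixels <- as.matrix(EBImage::fillHull(b$pixels * 1)) > 0.5
  expect_identical(a$pixels, b$pixels)
})
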