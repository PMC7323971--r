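# Shared fixtures: all synthetic, built in code, cached per test run.

# small clean honeycomb phantom (no jitter/noise/broken walls): the
# segmentation oracle setting
clean_honeycomb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(tissue_class = "normal", n_slices = 12,
                           volume_extent = c(128L, 12L, 175L),
                           broken_wall_fraction = 0,
                           jitter_max_translation = 0, noise_sd = 0,
                           rng_seed = 3L)
      ph <- build_phantom(spec)
      cache <<- list(spec = spec, volume = ph$volume, truth = ph$truth,
                     series = section_volume(ph$volume, spec))
    }
    cache
  }
})

# parallel-tube phantom with one tube per lateral position at a known depth
parallel_phantom <- function(n_slices = 15L, nx = 250L, nz = 200L,
                             spacing = 24, depth_range = c(10, 300),
                             seed = 4L, ...) {
  spec <- phantom_spec(vessel_layout = "parallel", n_slices = n_slices,
                       volume_extent = c(nx, n_slices, nz),
                       vessel_spacing = spacing,
                       vessel_depth_range = depth_range,
                       jitter_max_translation = 0, noise_sd = 0,
                       broken_wall_fraction = 0, rng_seed = seed, ...)
  c(list(spec = spec), build_phantom(spec))
}

# independent flood-fill oracle: enclosed background pixels of a binary
# mask (4-connected background not reachable from the border)
enclosed_background <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  reach <- matrix(FALSE, n1, n2)
  queue <- which(!mask & (row(mask) %in% c(1L, n1) | col(mask) %in% c(1L, n2)))
  reach[queue] <- TRUE
  while (length(queue)) {
    i <- (queue - 1L) %% n1 + 1L
    j <- (queue - 1L) %/% n1 + 1L
    nb <- c(queue[i > 1L] - 1L, queue[i < n1] + 1L,
            queue[j > 1L] - n1, queue[j < n2] + n1)
    nb <- unique(nb[!mask[nb] & !reach[nb]])
    reach[nb] <- TRUE
    queue <- nb
  }
  !mask & !reach
}

# per-slice chain recovery error against the recorded true jitter
chain_truth_error <- function(series, chain) {
  tru <- t(vapply(series$slices,
                  function(s) c(s$true_transform$dx, s$true_transform$dy),
                  numeric(2)))
  rec <- t(vapply(chain$absolute, function(t) c(t$dx, t$dy), numeric(2)))
  rec + sweep(tru, 2, tru[chain$anchor, ])
}

# match recovered components to ground-truth tubes by lateral position
match_components <- function(truth, comps, max_dist = 8) {
  dmat <- outer(comps$x, truth$x, "-")
  off <- stats::median(dmat[abs(dmat) < 10])
  m <- vapply(truth$x, function(x) which.min(abs(comps$x - off - x)),
              integer(1))
  ok <- abs(comps$x[m] - off - truth$x) < max_dist
  data.frame(truth_depth = truth$true_depth[ok],
             recovered_depth = comps$depth[m[ok]])
}
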