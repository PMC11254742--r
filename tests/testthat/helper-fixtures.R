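# Shared fixtures: small synthetic acquisitions built in code at test time.

tiny_spec <- function(n_sequences = 3L, tile_size = 128L)
  acquisition_spec(n_sequences = n_sequences, tile_size = tile_size)

tiny_config <- function(n_sequences = 3L, tile_size = 128L, n_beads = 120L,
                        seed = 7L, ...)
  simulation_config(acquisition = tiny_spec(n_sequences, tile_size),
                    n_beads = n_beads, seed = seed, ...)

# a single-tile acquisition spec for segmentation tests (small motion so the
# margin stays thin and the tiny field still fits the requested beads)
one_tile_config <- function(tile_size = 160L, n_beads = 45L, seed = 3L,
                            jitter_sigma = 0.5, ...)
  simulation_config(
    acquisition = acquisition_spec(n_sequences = 2L, n_tiles_x = 1L,
                                   n_tiles_y = 1L, tile_size = tile_size),
    n_beads = n_beads, shift_range = 2, theta_range = 0.5,
    jitter_sigma = jitter_sigma, tile_jitter = 0L, seed = seed, ...)

# min-separated points over a rectangle (independent of the package sampler)
rect_layout <- function(n, W, H, min_sep = 10, seed = 5L) {
  set.seed(seed)
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 20000L) {
    tries <- tries + 1L
    p <- c(runif(1, 4, W - 4), runif(1, 4, H - 4))
    if (nrow(pts) == 0L || min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= min_sep)
      pts <- rbind(pts, p)
  }
  pts
}

# brightfield tile + ground-truth local positions of round 1
one_tile_fixture <- function(config = one_tile_config()) {
  acq <- generate_acquisition(config)
  img <- acq$stacks[[1]]$images[[1]][["brightfield"]]
  pos <- truth_positions_round(acq$truth, 1L)
  list(acq = acq, img = img, pos = pos, config = config)
}

# true tile offsets of a round, re-anchored at tile 1 (the mosaic convention)
true_layout_offsets <- function(truth, round) {
  to <- truth$tile_offsets[[round]]
  sweep(to, 2, to[1, ])
}

expect_offsets_equal <- function(layout, truth, round) {
  expect_equal(unname(as.matrix(layout$offsets[, c("dx", "dy")])),
               unname(true_layout_offsets(truth, round)))
}
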