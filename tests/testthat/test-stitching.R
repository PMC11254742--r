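# Helper: a global bead field cropped into tiles at known integer offsets.
cropped_tiles <- function(offsets, ts = 128L, n = 150L, seed = 5L) {
  W <- max(offsets[, 1]) + ts; H <- max(offsets[, 2]) + ts
  pts <- rect_layout(n, W, H, min_sep = 10, seed = seed)
  tiles <- lapply(seq_len(nrow(offsets)), function(k)
    puckcall:::paint_discs(c(ts, ts),
                           cbind(pts[, 1] - offsets[k, 1],
                                 pts[, 2] - offsets[k, 2]),
                           3, warn_clip = FALSE))
  list(tiles = tiles, pts = pts)
}

test_that("pairwise offsets recover exact crops, verified against brute force", {
  ov <- 13L; ts <- 128L
  fx <- cropped_tiles(cbind(c(0, ts - ov), c(0, 0)), ts = ts, n = 60L)
  po <- pairwise_offset(fx$tiles[[1]], fx$tiles[[2]], ov)
  expect_equal(c(po$dx, po$dy), c(ts - ov, 0))
  expect_equal(po$cost, 0)

  # shifted by nominal + 3: brute-force evaluation of every window shift
  fx2 <- cropped_tiles(cbind(c(0, ts - ov + 3), c(0, -2)), ts = ts, n = 60L, seed = 8)
  po2 <- pairwise_offset(fx2$tiles[[1]], fx2$tiles[[2]], ov)
  expect_equal(c(po2$dx, po2$dy), c(ts - ov + 3, -2))
  brute <- expand.grid(dx = (ts - ov - 15):(ts - ov + 15), dy = -15:15)
  brute$cost <- mapply(function(dx, dy)
    puckcall:::strip_cost(fx2$tiles[[1]], fx2$tiles[[2]], dx, dy,
                          lambda = puckcall:::content_prior()),
    brute$dx, brute$dy)
  k <- which.min(brute$cost)
  expect_equal(c(brute$dx[k], brute$dy[k]), c(po2$dx, po2$dy))

  # two independent random masks: cost positive, argmin still defined
  set.seed(1)
  a <- matrix(rbinom(128 * 128, 1, 0.02), 128)
  b <- matrix(rbinom(128 * 128, 1, 0.02), 128)
  po3 <- pairwise_offset(a, b, ov)
  expect_gt(po3$cost, 0)
  expect_true(is.finite(po3$dx) && is.finite(po3$dy))
})

test_that("recovered layouts equal ground truth exactly on integer-shift mosaics", {
  spec <- tiny_spec(n_sequences = 1L)
  nom <- nominal_layout(spec)$offsets
  set.seed(3)
  true_off <- cbind(nom$dx + sample(-3:3, 9, TRUE), nom$dy + sample(-3:3, 9, TRUE))
  true_off[1, ] <- c(0L, 0L)
  fx <- cropped_tiles(true_off, ts = spec$tile_size, n = 220L)
  lay0 <- init_layout(fx$tiles, spec)
  lay <- global_refine(fx$tiles, lay0)
  expect_equal(unname(as.matrix(lay$offsets[, c("dx", "dy")])), unname(true_off))

  # total cost never increases across refinement, and at the optimum the
  # refinement is a fixed point (idempotence)
  expect_lte(attr(lay, "cost"), puckcall:::layout_cost(fx$tiles, lay0))
  lay2 <- global_refine(fx$tiles, lay)
  expect_equal(lay2$offsets, lay$offsets)

  # perturbing one tile away from truth is repaired
  pert <- lay
  pert$offsets$dx[5] <- pert$offsets$dx[5] + 2L
  pert$offsets$dy[5] <- pert$offsets$dy[5] - 2L
  fixed <- global_refine(fx$tiles, pert)
  expect_equal(unname(as.matrix(fixed$offsets[, c("dx", "dy")])), unname(true_off))
})

test_that("mosaic composition handles union, difference and single tiles", {
  spec <- tiny_spec(n_sequences = 1L)
  nom <- nominal_layout(spec)
  fx <- cropped_tiles(as.matrix(nom$offsets[, c("dx", "dy")]),
                      ts = spec$tile_size, n = 200L)
  uni <- compose_mosaic(fx$tiles, nom, mode = "union")
  dif <- compose_mosaic(fx$tiles, nom, mode = "difference")
  # perfectly consistent overlaps leave the difference image empty
  expect_equal(sum(dif), 0)
  expect_equal(dim(uni), nom$mosaic_shape)

  # single tile mosaic equals the tile
  one <- stitch_layout(data.frame(tile = 1L, row = 0L, col = 0L, dx = 0L, dy = 0L),
                       c(spec$tile_size, spec$tile_size))
  expect_equal(compose_mosaic(fx$tiles[1], one, "union"), fx$tiles[[1]])

  # union mosaic bead count ~ ground truth after centroid extraction
  cent <- extract_centroids(uni, segmenter_config())
  dd <- dedupe_beads(cent, 3)
  expect_equal(nrow(dd), nrow(fx$pts), tolerance = 0.02)
})

test_that("overlap-zone duplicates collapse to single beads", {
  b <- bead_set(c(10, 10.8, 40), c(10, 10.4, 40))
  dd <- dedupe_beads(b, 3)
  expect_equal(nrow(dd), 2L)
  expect_false(any(duplicated(dd$id)))
})

test_that("stitch_round recovers the true stage layout from rendered images", {
  cfg <- tiny_config(n_sequences = 1L, n_beads = 150L, seed = 17L)
  acq <- generate_acquisition(cfg)
  sr <- stitch_round(acq$stacks[[1]], cfg$acquisition)
  expect_offsets_equal(sr$layout, acq$truth, 1L)
  # every ground-truth bead appears exactly once in the mosaic bead set
  gt <- truth_positions_round(acq$truth, 1L)
  m <- match_points(gt, bead_xy(sr$beads), threshold = 3)
  expect_gte(nrow(m$pairs) / nrow(gt), 0.99)
})
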