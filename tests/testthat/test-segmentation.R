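# local copy of the shift helper so the oracle stays independent
mat_shift_test <- function(m, dy, dx) {
  out <- matrix(0, nrow(m), ncol(m))
  ys <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
  xs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

test_that("centroids of rendered discs match a brute-force pixel mean", {
  cfg <- segmenter_config()
  # single filled disc centred at (25, 25)
  m <- matrix(0, 50, 50)
  g <- expand.grid(x = 0:49, y = 0:49)
  inside <- (g$x - 25)^2 + (g$y - 25)^2 <= 5^2
  m[cbind(g$y + 1L, g$x + 1L)[inside, ]] <- 1
  b <- extract_centroids(m, cfg)
  expect_equal(nrow(b), 1L)
  # brute-force oracle: mean of the disc pixel coordinates
  expect_equal(b$x, mean(g$x[inside]), tolerance = 0.5)
  expect_equal(b$y, mean(g$y[inside]), tolerance = 0.5)

  # two discs separated by background -> two centroids
  m2 <- m + mat_shift_test(m, 0L, 20L)
  b2 <- extract_centroids(pmin(m2, 1), cfg)
  expect_equal(nrow(b2), 2L)

  # empty raster -> empty set
  expect_equal(nrow(extract_centroids(matrix(0, 30, 30), cfg)), 0L)
})

test_that("render_mask paints discs whose pixel count matches an exhaustive scan", {
  b <- bead_set(20, 15)
  m <- render_mask(b, 3, c(40, 40))
  g <- expand.grid(x = 0:39, y = 0:39)
  n_oracle <- sum((g$x - 20)^2 + (g$y - 15)^2 <= 9)
  expect_equal(sum(m), n_oracle)
  # empty bead set -> all-zero raster
  expect_equal(sum(render_mask(bead_set(), 3, c(20, 20))), 0)
  # clipping warns
  expect_warning(render_mask(bead_set(1, 1), 3, c(20, 20)), "clipped")
})

test_that("mask -> centroids -> mask is idempotent on isolated beads", {
  set.seed(11)
  for (rep in 1:3) {
    xy <- puckcall:::sample_positions_disc(20, c(50, 50), 40, 12)
    m1 <- render_mask(bead_set(xy[, 1], xy[, 2]), 3, c(100, 100))
    b <- extract_centroids(m1, segmenter_config())
    m2 <- render_mask(b, 3, c(100, 100))
    expect_equal(m1, m2)
  }
})

test_that("the classical detector recovers all beads on a noise-free tile", {
  fx <- one_tile_fixture(one_tile_config(noise_sigma = 0, gain_range = c(1, 1)))
  b <- oracle_segment(fx$img, segmenter_config())
  m <- match_points(bead_xy(b), fx$pos, threshold = 2)
  expect_equal(nrow(m$pairs), nrow(fx$pos))
  expect_equal(nrow(b), nrow(fx$pos))
  # localisation error <= 1 px RMS
  expect_lt(sqrt(mean(m$pairs$dist^2)), 1)
  # blank image -> empty set
  expect_equal(nrow(oracle_segment(matrix(0, 60, 60))), 0L)
})

test_that("detection is equivariant to integer shifts for interior beads", {
  fx <- one_tile_fixture()
  b0 <- oracle_segment(fx$img, segmenter_config())
  dx <- 7L; dy <- -4L
  shifted <- mat_shift_test(fx$img, dy, dx)
  b1 <- oracle_segment(shifted, segmenter_config())
  interior <- b0[b0$x > 20 & b0$x < 130 & b0$y > 20 & b0$y < 130, ]
  moved <- cbind(interior$x + dx, interior$y + dy)
  m <- match_points(moved, bead_xy(b1), threshold = 1)
  expect_equal(nrow(m$pairs), nrow(interior))
})

test_that("the segmentation network trains, beats the blank baseline and finds beads", {
  fx <- one_tile_fixture(one_tile_config(tile_size = 140L, n_beads = 35L))
  labels <- segmentation_labels(fx$pos, fx$config$bead_radius, dim(fx$img))
  cfg <- segmenter_config(epochs = 28L, n_patches = 32L, seed = 2L)
  model <- train_segmenter(fx$img, labels, cfg)

  # validation BCE must beat predicting the all-background rate everywhere
  q <- mean(labels)
  baseline <- -(q * log(q) + (1 - q) * log(1 - q))
  expect_lt(tail(model$history$val_loss, 1), baseline)

  # training loss trend is non-increasing after 5-epoch smoothing
  tr <- model$history$train_loss
  smooth <- stats::filter(tr, rep(1 / 5, 5), sides = 1)
  smooth <- smooth[!is.na(smooth)]
  expect_true(all(diff(smooth) <= 1e-3))

  # training is repeatable per seed
  model2 <- train_segmenter(fx$img, labels, cfg)
  expect_identical(model$par, model2$par)

  # >= 95% of true centres recovered on the training tile
  prob <- segment_tile(fx$img, model)
  expect_equal(dim(prob), dim(fx$img))
  cent <- extract_centroids(prob, cfg)
  m <- match_points(bead_xy(cent), fx$pos, threshold = 3)
  expect_gte(nrow(m$pairs) / nrow(fx$pos), 0.95)

  # agreement with the classical detector (mutual matches within 3 px)
  orc <- oracle_segment(fx$img, cfg)
  agree <- match_points(bead_xy(orc), bead_xy(cent), threshold = 3)
  expect_gte(nrow(agree$pairs) / max(nrow(orc), nrow(cent)), 0.9)

  # all-zero input stays below the binarisation threshold everywhere
  blank <- segment_tile(matrix(0, 140, 140), model)
  expect_lt(max(blank), cfg$prob_threshold)

  # too-small input errors
  expect_error(segment_tile(matrix(0, 20, 20), model), "patch_size")
})

test_that("degenerate label sets are rejected", {
  img <- matrix(0.1, 60, 60)
  expect_error(train_segmenter(img, matrix(0, 60, 60), segmenter_config()),
               "no positive")
})
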