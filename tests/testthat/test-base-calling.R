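test_that("identity crosstalk with no noise is called perfectly", {
  cfg <- simulation_config(crosstalk = diag(4), noise_sigma = 0)
  smp <- simulate_intensity_samples(400, cfg, seed = 2L)
  model <- train_base_caller(smp$samples, smp$labels,
                             base_caller_config(epochs = 60L), n_train = 360L)
  expect_equal(model$test_accuracy, 1)
  # one-hot input on channel k maps to channel_to_base(k)
  for (k in 1:4) {
    v <- numeric(4); v[k] <- 1
    call <- call_base(v, model)
    expect_equal(call$base, unname(model$config$channel_to_base[k]))
  }
})

test_that("the trained caller matches or beats exact unmixing under crosstalk", {
  cfg <- simulation_config()   # default crosstalk (0.7 diagonal) + noise
  smp <- simulate_intensity_samples(1200, cfg, seed = 5L)
  model <- train_base_caller(smp$samples, smp$labels,
                             base_caller_config(seed = 5L), n_train = 1080L)
  baseline <- unmix_argmax_accuracy(smp$samples, smp$labels, cfg)
  expect_gte(model$test_accuracy, baseline - 0.01)
  # deterministic given the seed
  model2 <- train_base_caller(smp$samples, smp$labels,
                              base_caller_config(seed = 5L), n_train = 1080L)
  expect_identical(model$test_accuracy, model2$test_accuracy)
  # the two code paths agree: call_base on the test samples reproduces
  # the reported held-out accuracy
  set.seed(puckcall:::sub_seed(5L, "caller-split"))
  idx <- sample.int(1200)
  te <- idx[-seq_len(1080)]
  calls <- call_base(smp$samples[te, ], model)
  expect_equal(mean(calls$base == smp$labels[te]), model$test_accuracy)
})

test_that("calling is invariant to global gain and flags degenerate input", {
  cfg <- simulation_config()
  smp <- simulate_intensity_samples(800, cfg, seed = 9L)
  model <- train_base_caller(smp$samples, smp$labels,
                             base_caller_config(seed = 9L), n_train = 720L)
  x <- smp$samples[1:200, ]
  base0 <- call_base(x, model)$base
  for (g in c(0.8, 1.2)) {
    baseg <- call_base(x * g, model)$base
    expect_lte(mean(baseg != base0), 0.02)
  }
  # all-equal input: deterministic tie-break, low confidence
  tie1 <- call_base(rep(0.5, 4), model)
  tie2 <- call_base(rep(0.5, 4), model)
  expect_identical(tie1$base, tie2$base)
  expect_error(call_base(c(0.1, NA, 0.2, 0.3), model), "finite")
  expect_error(train_base_caller(smp$samples[1:10, ], rep("A", 10),
                                 base_caller_config()), "single class")
})

test_that("extracted intensity vectors match the closed-form disc mean", {
  cfg <- one_tile_config(noise_sigma = 0, gain_range = c(1, 1),
                         crosstalk = diag(4), n_beads = 12L, tile_size = 128L)
  acq <- generate_acquisition(cfg)
  pos <- truth_positions_round(acq$truth, 1L)
  gid <- attr(pos, "gt_id")
  st <- acq$stacks[[1]]
  interior <- which(pos[, 1] > 15 & pos[, 1] < 112 & pos[, 2] > 15 & pos[, 2] < 112)
  sigma <- cfg$bead_radius / 2
  for (i in interior[seq_len(min(4, length(interior)))]) {
    base <- acq$truth$barcodes[gid[i], 1]
    chan <- cfg$base_to_channel[[base]]
    amp <- acq$truth$brightness[gid[i]]
    # closed-form expectation: amplitude x disc mean of the Gaussian profile,
    # evaluated on the pixel grid, minus the annulus-median tail
    cx <- round(pos[i, 1]); cy <- round(pos[i, 2])
    g <- expand.grid(dx = -8:8, dy = -8:8)
    d2 <- ((cx + g$dx) - pos[i, 1])^2 + ((cy + g$dy) - pos[i, 2])^2
    prof <- exp(-d2 / (2 * sigma^2))   # disc and annulus lie inside 3 sigma
    disc <- g$dx^2 + g$dy^2 <= 9
    ann <- g$dx^2 + g$dy^2 >= 25 & g$dx^2 + g$dy^2 <= 64
    expected <- amp * (mean(prof[disc]) - median(prof[ann]))
    got <- puckcall:::disc_mean(st$images[[1]][[chan]], pos[i, 1], pos[i, 2], 3)
    expect_equal(got, expected, tolerance = 0.02)
  }
})

test_that("barcodes assemble with N at missing rounds and exact completeness", {
  tracks <- data.frame(bead_id = 1:2, x = c(1, 2), y = c(3, 4),
                       match_r1 = c(1L, 1L), match_r2 = c(2L, NA),
                       match_r3 = c(3L, NA))
  class(tracks) <- c("track_table", "data.frame")
  intens <- array(NA_real_, c(2, 3, 4))
  intens[1, , ] <- matrix(c(1, 0, 0, 0), 3, 4, byrow = TRUE)
  intens[2, 1, ] <- c(0, 1, 0, 0)
  cfg <- simulation_config(crosstalk = diag(4), noise_sigma = 0)
  smp <- simulate_intensity_samples(400, cfg, seed = 2L)
  model <- train_base_caller(smp$samples, smp$labels,
                             base_caller_config(epochs = 60L), n_train = 360L)
  bc <- assemble_barcodes(tracks, intens, model)
  expect_equal(bc$barcode[1], "AAA")
  expect_equal(substr(bc$barcode[2], 2, 3), "NN")
  expect_equal(bc$completeness, c(1, 1 / 3))
})

test_that("washed-out rounds yield missing intensities, never zeros", {
  cfg <- tiny_config(n_sequences = 2L, n_beads = 60L, washout_prob = 0.3,
                     appear_rate = 0, seed = 77L)
  run <- run_pipeline(cfg)
  tracks <- run$tracks
  missing <- is.na(tracks$match_r2)
  skip_if(!any(missing), "no washout at this seed")
  expect_true(all(substr(run$barcodes$barcode[missing], 2, 2) == "N"))
})
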