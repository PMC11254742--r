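test_that("bead layouts respect the separation constraint and the seed", {
  cfg <- tiny_config(n_beads = 80L)
  p1 <- sample_bead_layout(cfg)
  expect_equal(nrow(p1), 80L)
  expect_gte(min(dist(p1)), cfg$min_separation)
  # deterministic given the seed
  expect_identical(p1, sample_bead_layout(cfg))
  # empty request
  expect_equal(nrow(sample_bead_layout(cfg, n = 0L)), 0L)
  # infeasible density errors with advice
  dense <- tiny_config(n_beads = 120L, min_separation = 60)
  expect_error(sample_bead_layout(dense), "density")
})

test_that("washout is permanent and presence flags stay monotone", {
  cfg <- tiny_config(n_sequences = 8L, washout_prob = 0.15, seed = 21L)
  truth <- sample_truth(cfg)
  for (i in seq_len(nrow(truth$present))) {
    pr <- truth$present[i, truth$first_round[i]:ncol(truth$present)]
    expect_true(all(diff(as.integer(pr)) <= 0L))   # never comes back
  }
})

test_that("higher washout probability removes more beads in expectation", {
  count_last <- function(w) {
    mean(vapply(1:4, function(s) {
      cfg <- tiny_config(n_sequences = 6L, washout_prob = w, n_beads = 100L,
                         seed = 30L + s)
      sum(sample_truth(cfg)$present[, 6])
    }, numeric(1)))
  }
  expect_gt(count_last(0.0), count_last(0.05))
  expect_gt(count_last(0.05), count_last(0.25))
})

test_that("rendering puts a pure one-hot signal in the dye channel", {
  cfg <- one_tile_config(noise_sigma = 0, crosstalk = diag(4),
                         gain_range = c(1, 1))
  acq <- generate_acquisition(cfg)
  st <- acq$stacks[[1]]
  pos <- truth_positions_round(acq$truth, 1L)
  gid <- attr(pos, "gt_id")
  interior <- which(pos[, 1] > 10 & pos[, 1] < 150 & pos[, 2] > 10 & pos[, 2] < 150)
  for (i in interior[1:10]) {
    base <- acq$truth$barcodes[gid[i], 1]
    chan <- cfg$base_to_channel[[base]]
    px <- round(pos[i, 1]) + 1L; py <- round(pos[i, 2]) + 1L
    vals <- vapply(c("475", "555", "575", "635"), function(ch)
      st$images[[1]][[ch]][py, px], numeric(1))
    expect_gt(vals[[chan]], 0.3)
    expect_equal(unname(sum(vals > 1e-9)), 1L)   # only the dye channel is lit
  }
})

test_that("a bead in the overlap strip appears in both tiles consistently", {
  cfg <- noise_free_config(tiny_config(n_beads = 60L, seed = 13L))
  acq <- generate_acquisition(cfg)
  st <- acq$stacks[[1]]
  lay <- nominal_layout(cfg$acquisition)
  pos <- truth_positions_round(acq$truth, 1L)
  step <- lay$offsets$dx[2]
  ts <- cfg$acquisition$tile_size
  in_strip <- which(pos[, 1] > step + 2 & pos[, 1] < ts - 2 &
                    pos[, 2] > 2 & pos[, 2] < ts - 2)
  skip_if(length(in_strip) == 0, "no bead fell in the strip for this seed")
  i <- in_strip[1]
  v1 <- st$images[[1]][["brightfield"]][round(pos[i, 2]) + 1L, round(pos[i, 1]) + 1L]
  l2 <- local_coords(2L, pos[i, ], lay)
  v2 <- st$images[[2]][["brightfield"]][round(l2[2]) + 1L, round(l2[1]) + 1L]
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("washed-out beads are absent from every tile of that round", {
  cfg <- tiny_config(n_sequences = 5L, washout_prob = 0.2, noise_sigma = 0,
                     seed = 9L)
  acq <- generate_acquisition(cfg)
  truth <- acq$truth
  gone <- which(truth$first_round == 1L & !truth$present[, 5])
  skip_if(length(gone) == 0, "no washout at this seed")
  pos <- truth_positions_round(truth, 5L, present_only = FALSE)
  st <- acq$stacks[[5]]
  for (i in gone[seq_len(min(5, length(gone)))]) {
    for (k in seq_along(st$images)) {
      o <- truth$tile_offsets[[5]][k, ]
      lx <- round(pos[i, 1] - o[["dx"]]); ly <- round(pos[i, 2] - o[["dy"]])
      if (lx < 1 || ly < 1 || lx > cfg$acquisition$tile_size - 2 ||
          ly > cfg$acquisition$tile_size - 2) next
      expect_lt(st$images[[k]][["brightfield"]][ly + 1L, lx + 1L], 0.05)
    }
  }
})

test_that("one tile stack is produced per requested round, reproducibly", {
  cfg <- one_tile_config(tile_size = 128L, n_beads = 15L)
  cfg$acquisition$n_sequences <- 4L
  acq <- generate_acquisition(cfg)
  expect_length(acq$stacks, 4L)
  expect_equal(vapply(acq$stacks, `[[`, integer(1), "sequence_index"), 1:4)
  # byte-identical rasters on a second run
  acq2 <- generate_acquisition(cfg)
  expect_identical(acq$stacks[[3]]$images[[1]], acq2$stacks[[3]]$images[[1]])
})

test_that("zero washout and appearance keeps every bead in every round", {
  cfg <- tiny_config(washout_prob = 0, appear_rate = 0, n_beads = 40L)
  truth <- sample_truth(cfg)
  expect_true(all(truth$present))
  expect_true(all(truth$first_round == 1L))
})

test_that("acquisitions round-trip through TIFF + manifest", {
  cfg <- one_tile_config(tile_size = 96L, n_beads = 6L, jitter_sigma = 0)
  acq <- generate_acquisition(cfg)
  d <- file.path(tempdir(), "acq_rt")
  write_acquisition(acq, d)
  expect_true(file.exists(file.path(d, "ground_truth.tsv")))
  stacks <- read_acquisition(file.path(d, "manifest.csv"))
  expect_length(stacks, 2L)
  expect_equal(stacks[[1]]$images[[1]][["brightfield"]],
               acq$stacks[[1]]$images[[1]][["brightfield"]], tolerance = 1e-4)
  unlink(d, recursive = TRUE)
})
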