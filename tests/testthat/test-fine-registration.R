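test_that("beads partition into disjoint patches with the half-open rule", {
  b <- bead_set(c(0, 127.9, 128, 300), c(0, 10, 0, 200))
  p <- partition_beads(b, 128L)
  expect_equal(p$px, c(0, 0, 1, 2))
  expect_equal(p$py, c(0, 0, 0, 1))
  # counts over patches sum to the bead count
  expect_equal(sum(table(paste(p$px, p$py))), nrow(b))
})

test_that("patch shifts are recovered exactly, matching exhaustive search", {
  set.seed(6)
  ref <- cbind(runif(15, 0, 100), runif(15, 0, 100))
  mov <- cbind(ref[, 1] - 3, ref[, 2] + 2)   # ref = mov + (3, -2)
  cfg <- fine_reg_config()
  res <- optimal_patch_shift(ref, mov, cfg)
  expect_equal(res$shift, c(3, -2))
  expect_equal(res$objective, 0)
  # exhaustive-shift oracle over the same grid
  objective_at <- function(s) {
    d <- sqrt(outer(ref[, 1], mov[, 1] + s[1], "-")^2 +
              outer(ref[, 2], mov[, 2] + s[2], "-")^2)
    sum(pmin(apply(d, 1, min), cfg$congruence_threshold))
  }
  grid <- expand.grid(sx = -10:10, sy = -10:10)
  objs <- mapply(function(sx, sy) objective_at(c(sx, sy)), grid$sx, grid$sy)
  expect_equal(min(objs), res$objective)
  # identity and degenerate inputs
  expect_equal(optimal_patch_shift(ref, ref, cfg)$shift, c(0, 0))
  expect_equal(optimal_patch_shift(ref[0, ], mov, cfg)$shift, c(0, 0))
  expect_equal(optimal_patch_shift(ref, mov[0, ], cfg)$shift, c(0, 0))
})

test_that("the congruence rule is a strict four-pixel inequality", {
  ref <- rbind(c(0, 0))
  expect_equal(nrow(match_points(ref, rbind(c(3.9, 0)), 4)$pairs), 1L)
  expect_equal(nrow(match_points(ref, rbind(c(4.0, 0)), 4)$pairs), 0L)
  # identical sets: perfect matching at distance zero
  set.seed(2)
  pts <- cbind(runif(10, 0, 50), runif(10, 0, 50))
  m <- match_points(pts, pts, 4)
  expect_equal(nrow(m$pairs), 10L)
  expect_equal(max(m$pairs$dist), 0)
})

test_that("greedy matching is as large as brute-force optimal on small instances", {
  # instances mirror the pipeline regime: detections are sub-threshold
  # perturbations of a layout whose minimum separation exceeds the
  # congruence threshold
  set.seed(99)
  for (rep in 1:40) {
    base <- puckcall:::sample_positions_disc(8, c(30, 30), 28, 12)
    nr <- sample(0:8, 1); nm <- sample(0:8, 1)
    ref <- base[sample.int(8, nr), , drop = FALSE] +
      matrix(runif(2 * nr, -1.5, 1.5), ncol = 2)
    mov <- base[sample.int(8, nm), , drop = FALSE] +
      matrix(runif(2 * nm, -1.5, 1.5), ncol = 2)
    greedy <- nrow(match_points(ref, mov, 4)$pairs)
    optimal <- optimal_match_cardinality(ref, mov, 4)
    expect_equal(greedy, optimal)
  }
})

test_that("cross-round linking is complete on noise-free data and one-to-one always", {
  cfg <- noise_free_config(tiny_config(n_sequences = 3L, n_beads = 100L, seed = 23L))
  acq <- generate_acquisition(cfg)
  srs <- lapply(acq$stacks, function(st) stitch_round(st, cfg$acquisition))
  beads <- lapply(srs, `[[`, "beads")
  transforms <- c(list(rigid_transform()),
                  lapply(2:3, function(r)
                    register_round(beads[[1]], beads[[r]])$transform))
  tracks <- link_across_sequences(beads[[1]], beads, transforms)
  mc <- paste0("match_r", 1:3)
  # noise-free: every reference bead matched in every round
  for (col in mc) expect_false(any(is.na(tracks[[col]])))
  # one-to-one: no bead id appears twice in any round's column
  for (col in mc) expect_false(any(duplicated(tracks[[col]])))
})

test_that("washout shows up as missing entries, not as false matches", {
  cfg <- tiny_config(n_sequences = 3L, tile_size = 160L, n_beads = 220L,
                     washout_prob = 0.1, appear_rate = 0, seed = 31L)
  acq <- generate_acquisition(cfg)
  srs <- lapply(acq$stacks, function(st) stitch_round(st, cfg$acquisition))
  beads <- lapply(srs, `[[`, "beads")
  transforms <- c(list(rigid_transform()),
                  lapply(2:3, function(r)
                    register_round(beads[[1]], beads[[r]])$transform))
  tracks <- link_across_sequences(beads[[1]], beads, transforms)
  truth <- acq$truth
  # detections -> truth maps per round
  for (r in 2:3) {
    gt <- truth_positions_round(truth, r, present_only = FALSE)
    det <- beads[[r]]
    m <- match_points(bead_xy(det), gt[truth$present[, r], , drop = FALSE], 5)
    gt_ids <- attr(truth_positions_round(truth, r), "gt_id")
    det2gt <- rep(NA_integer_, max(det$id))
    det2gt[det$id[m$pairs$ref]] <- gt_ids[m$pairs$mov]
    gt1 <- truth_positions_round(truth, 1L)
    m1 <- match_points(bead_xy(beads[[1]]), gt1, 5)
    ref2gt <- rep(NA_integer_, max(beads[[1]]$id))
    ref2gt[beads[[1]]$id[m1$pairs$ref]] <- attr(gt1, "gt_id")[m1$pairs$mov]
    matched <- !is.na(tracks[[paste0("match_r", r)]])
    g_ref <- ref2gt[tracks$bead_id]
    g_mov <- det2gt[tracks[[paste0("match_r", r)]][matched]]
    # no false matches: every match links detections of the same bead
    ok <- !is.na(g_ref[matched]) & !is.na(g_mov) & g_ref[matched] == g_mov
    expect_gte(mean(ok), 0.99)
    # washed-out beads are missing, not matched
    washed <- which(!truth$present[, r] & truth$first_round == 1L)
    rows_washed <- which(g_ref %in% washed)
    expect_true(all(is.na(tracks[[paste0("match_r", r)]][rows_washed])))
  }
})

test_that("no accepted correspondence reaches the congruence threshold", {
  cfg <- tiny_config(n_sequences = 2L, n_beads = 120L, seed = 41L)
  acq <- generate_acquisition(cfg)
  srs <- lapply(acq$stacks, function(st) stitch_round(st, cfg$acquisition))
  beads <- lapply(srs, `[[`, "beads")
  tr2 <- register_round(beads[[1]], beads[[2]])$transform
  fcfg <- fine_reg_config()
  mov_xy <- transform_points(bead_xy(beads[[2]]), tr2)
  cp <- puckcall:::round_candidate_pairs(beads[[1]], mov_xy, fcfg)
  expect_true(all(cp$pairs$dist < fcfg$congruence_threshold))
})
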