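# Synthetic puck acquisitions with full ground truth.
#
# The generator emulates the acquisition the pipeline is built for: a disc of
# DNA-barcoded beads imaged over n_sequences rounds as a grid of overlapping
# brightfield + 4-channel fluorescence tiles.  Between rounds the puck is
# removed and re-mounted (rigid motion), some beads wash away permanently,
# a few spurious beads appear, the optics add a smooth low-frequency
# distortion field, per-tile gain varies, and fluorescence channels mix
# through a crosstalk matrix.  Every nuisance is recorded as ground truth.

#' Default spectral crosstalk matrix
#'
#' Row-stochastic mixing of pure dye signal into observed channels: observed
#' channel i receives `diag` of its own dye plus equal bleed from the others.
#'
#' @param diagonal fraction of a dye's signal seen in its own channel.
#' @return 4x4 matrix; `observed = crosstalk %*% pure`.
#' @export
crosstalk_matrix <- function(diagonal = 0.7) {
  stopifnot(diagonal > 0.25, diagonal <= 1)
  m <- matrix((1 - diagonal) / 3, 4, 4)
  diag(m) <- diagonal
  dimnames(m) <- list(FLUOR_CHANNELS, FLUOR_CHANNELS)
  m
}

#' Configuration of a synthetic puck acquisition
#'
#' Defaults describe the nominal study conditions: per-round re-mounting
#' motion up to 3 degrees and 20 px, 1% per-round bead washout, a smooth
#' few-pixel distortion field, 0.7-diagonal channel crosstalk, per-tile gain
#' variation and additive Gaussian noise.
#'
#' @param acquisition an [acquisition_spec()].
#' @param n_beads number of beads on the puck.
#' @param bead_radius nominal bead radius in px (photometric Gaussian profile
#'   with sigma = bead_radius / 2, truncated at 3 sigma).
#' @param min_separation minimal pairwise bead distance in px.
#' @param washout_prob per-bead, per-round probability of permanent loss
#'   (applied from round 2 on).
#' @param appear_rate expected number of spurious new beads per round, as a
#'   fraction of `n_beads`; appeared beads persist.
#' @param theta_range,shift_range per-round rigid motion: |theta| <=
#'   `theta_range` (degrees), |tx|,|ty| <= `shift_range` (px).  Round 1 is
#'   the reference and has no motion.
#' @param jitter_sigma amplitude (px) of the smooth local distortion field.
#' @param tile_jitter max integer stage placement error per tile per round (px).
#' @param gain_range per-tile, per-round multiplicative intensity gain range.
#' @param crosstalk 4x4 mixing matrix, see [crosstalk_matrix()].
#' @param noise_sigma sd of additive Gaussian intensity noise.
#' @param base_to_channel named mapping base -> fluorescence channel label.
#' @param seed RNG seed; every simulation quantity derives from it.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(acquisition = acquisition_spec(),
                              n_beads = 800L,
                              bead_radius = 5,
                              min_separation = 12,
                              washout_prob = 0.01,
                              appear_rate = 0.005,
                              theta_range = 3,
                              shift_range = 20,
                              jitter_sigma = 1.5,
                              tile_jitter = 3L,
                              gain_range = c(0.7, 1.3),
                              crosstalk = crosstalk_matrix(),
                              noise_sigma = 0.05,
                              base_to_channel = c(A = "475", C = "555",
                                                  G = "575", T = "635"),
                              seed = 1L) {
  stopifnot(inherits(acquisition, "acquisition_spec"),
            n_beads >= 0, bead_radius >= 1, min_separation > 0,
            washout_prob >= 0, washout_prob <= 1,
            appear_rate >= 0, appear_rate <= 1,
            theta_range >= 0, shift_range >= 0, jitter_sigma >= 0,
            tile_jitter >= 0, length(gain_range) == 2L,
            gain_range[1] > 0, gain_range[2] >= gain_range[1],
            noise_sigma >= 0)
  crosstalk <- as.matrix(crosstalk)
  stopifnot(nrow(crosstalk) == 4L, ncol(crosstalk) == 4L,
            all(crosstalk >= 0), all(diag(crosstalk) >= apply(crosstalk, 1, max)))
  if (!setequal(names(base_to_channel), DNA_BASES) ||
      !setequal(base_to_channel, FLUOR_CHANNELS))
    stop("base_to_channel must be a bijection {A,C,G,T} -> fluorescence channels")
  structure(list(acquisition = acquisition, n_beads = as.integer(n_beads),
                 bead_radius = bead_radius, min_separation = min_separation,
                 washout_prob = washout_prob, appear_rate = appear_rate,
                 theta_range = theta_range, shift_range = shift_range,
                 jitter_sigma = jitter_sigma, tile_jitter = as.integer(tile_jitter),
                 gain_range = gain_range, crosstalk = crosstalk,
                 noise_sigma = noise_sigma,
                 base_to_channel = base_to_channel[DNA_BASES],
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' A noise-free, motion-free variant of a simulation config
#'
#' Convenience used for oracle-limit checks: zero motion, jitter, washout,
#' appearance, tile jitter and noise; identity crosstalk; unit gain.
#' @param config a [simulation_config()].
#' @export
noise_free_config <- function(config) {
  config$washout_prob <- 0; config$appear_rate <- 0
  config$theta_range <- 0; config$shift_range <- 0
  config$jitter_sigma <- 0; config$tile_jitter <- 0L
  config$gain_range <- c(1, 1); config$noise_sigma <- 0
  config$crosstalk <- diag(4)
  config
}

mosaic_centre <- function(spec) {
  sh <- nominal_layout(spec)$mosaic_shape
  c(sh[2] / 2, sh[1] / 2)  # (x, y)
}

# margin keeping the whole puck inside every round's field of view
puck_margin <- function(config) {
  sh <- nominal_layout(config$acquisition)$mosaic_shape
  r <- min(sh) / 2
  config$shift_range + r * sin(config$theta_range * pi / 180) +
    config$tile_jitter + 3 * config$jitter_sigma + 3 * config$bead_radius
}

#' Sample non-overlapping bead positions on the puck disc
#'
#' Positions are uniform over a disc inscribed in the mosaic (shrunk by a
#' motion margin so the puck stays imaged in every round), with pairwise
#' distance >= `min_separation`; deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @param n number of beads (defaults to `config$n_beads`).
#' @return n x 2 matrix of (x, y) positions in the reference mosaic frame.
#' @export
sample_bead_layout <- function(config, n = config$n_beads) {
  set.seed(sub_seed(config$seed, "layout"))
  ctr <- mosaic_centre(config$acquisition)
  radius <- min(nominal_layout(config$acquisition)$mosaic_shape) / 2 -
    puck_margin(config)
  if (n > 0 && radius <= config$min_separation)
    stop("puck too small for the requested density; lower n_beads or margins")
  sample_positions_disc(n, ctr, radius, config$min_separation)
}

# dart throwing with a grid hash; error when density is infeasible
sample_positions_disc <- function(n, ctr, radius, min_sep) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  cell <- min_sep / sqrt(2)
  ncell <- ceiling(2 * radius / cell) + 2L
  grid <- vector("list", ncell * ncell)
  key <- function(x, y) {
    gx <- floor((x - ctr[1] + radius) / cell) + 1L
    gy <- floor((y - ctr[2] + radius) / cell) + 1L
    (gy - 1L) * ncell + gx
  }
  pts <- matrix(NA_real_, n, 2)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 4000L * n
  while (placed < n && attempts < max_attempts) {
    attempts <- attempts + 1L
    u <- stats::runif(1); a <- stats::runif(1, 0, 2 * pi)
    r <- radius * sqrt(u)
    x <- ctr[1] + r * cos(a); y <- ctr[2] + r * sin(a)
    k0 <- key(x, y)
    gx0 <- (k0 - 1L) %% ncell
    ok <- TRUE
    for (dgy in -2:2) for (dgx in -2:2) {
      k <- k0 + dgy * ncell + dgx
      if (k < 1L || k > length(grid)) next
      for (j in grid[[k]]) {
        if ((pts[j, 1] - x)^2 + (pts[j, 2] - y)^2 < min_sep^2) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      pts[placed, ] <- c(x, y)
      grid[[k0]] <- c(grid[[k0]], placed)
    }
  }
  if (placed < n)
    stop(sprintf("could only place %d of %d beads at min_separation %.1f; lower the density",
                 placed, n, min_sep))
  colnames(pts) <- c("x", "y")
  pts
}

# smooth low-frequency displacement field: sum of 3 random plane-wave modes
sample_jitter_field <- function(sigma, mosaic_shape) {
  L <- max(mosaic_shape)
  modes <- lapply(1:3, function(i) {
    list(fx = stats::runif(1, 0.3, 1.2) / L, fy = stats::runif(1, 0.3, 1.2) / L,
         phx = stats::runif(1, 0, 2 * pi), phy = stats::runif(1, 0, 2 * pi),
         ax = stats::rnorm(1, 0, sigma / sqrt(3)),
         ay = stats::rnorm(1, 0, sigma / sqrt(3)))
  })
  modes
}

eval_jitter <- function(modes, xy) {
  if (NROW(xy) == 0L) return(cbind(dx = numeric(0), dy = numeric(0)))
  dx <- dy <- numeric(nrow(xy))
  for (m in modes) {
    ph <- 2 * pi * (m$fx * xy[, 1] + m$fy * xy[, 2])
    dx <- dx + m$ax * sin(ph + m$phx)
    dy <- dy + m$ay * sin(ph + m$phy)
  }
  cbind(dx = dx, dy = dy)
}

#' Sample the full ground truth of a synthetic acquisition
#'
#' Draws bead positions and barcodes, per-round rigid motion, tile stage
#' errors, distortion fields, washout/appearance schedule, per-tile gains and
#' per-bead brightness.  Purely a function of the config (seeded).
#'
#' @param config a [simulation_config()].
#' @return object of class `puck_truth`; see fields in the implementation.
#' @export
sample_truth <- function(config) {
  spec <- config$acquisition
  R <- spec$n_sequences
  nt <- n_tiles(spec)
  lay <- nominal_layout(spec)
  ctr <- mosaic_centre(spec)

  pos <- sample_bead_layout(config)

  set.seed(sub_seed(config$seed, "truth"))
  # spurious beads appearing in later rounds (persist once appeared)
  n_appear <- if (R > 1) stats::rpois(1, config$appear_rate * config$n_beads * (R - 1)) else 0L
  if (n_appear > 0) {
    extra <- sample_positions_disc(
      n_appear, ctr,
      min(lay$mosaic_shape) / 2 - puck_margin(config),
      config$min_separation / 2)
    appear_round <- sort(sample(2:R, n_appear, replace = TRUE))
  } else {
    extra <- cbind(x = numeric(0), y = numeric(0))
    appear_round <- integer(0)
  }
  n_all <- nrow(pos) + n_appear
  positions <- rbind(pos, extra)
  first_round <- c(rep(1L, nrow(pos)), appear_round)

  barcodes <- matrix(sample(DNA_BASES, n_all * R, replace = TRUE), n_all, R)

  # washout: permanent, applied between rounds
  present <- matrix(FALSE, n_all, R)
  for (i in seq_len(n_all)) {
    alive <- TRUE
    for (r in seq_len(R)) {
      if (r < first_round[i]) next
      if (r > first_round[i] && alive && stats::runif(1) < config$washout_prob)
        alive <- FALSE
      present[i, r] <- alive
    }
  }

  transforms <- vector("list", R)
  jitter <- vector("list", R)
  tile_offsets <- vector("list", R)
  for (r in seq_len(R)) {
    if (r == 1L) {
      transforms[[r]] <- rigid_transform(0, 0, 0, ctr)
      jitter[r] <- list(NULL)
    } else {
      th <- stats::runif(1, -config$theta_range, config$theta_range) * pi / 180
      tx <- stats::runif(1, -config$shift_range, config$shift_range)
      ty <- stats::runif(1, -config$shift_range, config$shift_range)
      transforms[[r]] <- rigid_transform(th, tx, ty, ctr)
      jitter[r] <- list(if (config$jitter_sigma > 0)
        sample_jitter_field(config$jitter_sigma, lay$mosaic_shape) else NULL)
    }
    tj <- config$tile_jitter
    tile_offsets[[r]] <- cbind(
      dx = lay$offsets$dx + if (tj > 0) sample(-tj:tj, nt, TRUE) else 0L,
      dy = lay$offsets$dy + if (tj > 0) sample(-tj:tj, nt, TRUE) else 0L)
  }

  gains <- matrix(stats::runif(R * nt, config$gain_range[1], config$gain_range[2]),
                  R, nt)
  brightness <- stats::runif(n_all, 0.75, 1.0)

  structure(list(config = config, positions = positions,
                 first_round = first_round, barcodes = barcodes,
                 present = present, transforms = transforms, jitter = jitter,
                 tile_offsets = tile_offsets, gains = gains,
                 brightness = brightness, seed = config$seed),
            class = "puck_truth")
}

#' @export
print.puck_truth <- function(x, ...) {
  cat(sprintf("Ground truth: %d beads (%d original + %d appeared), %d rounds\n",
              nrow(x$positions), sum(x$first_round == 1L),
              sum(x$first_round > 1L), ncol(x$present)))
  cat(sprintf("  beads present in all rounds: %d\n",
              sum(rowSums(x$present) == ncol(x$present))))
  invisible(x)
}

#' True bead positions in a given round's mosaic frame
#'
#' Applies that round's rigid motion and distortion field, then shifts into
#' the round's mosaic frame (anchored at tile 1's true stage origin).
#'
#' @param truth a `puck_truth`.
#' @param round round index.
#' @param present_only drop beads not present in that round.
#' @return matrix with columns x, y and attribute `gt_id` (row index into
#'   `truth$positions`).
#' @export
truth_positions_round <- function(truth, round, present_only = TRUE) {
  p <- transform_points(truth$positions, truth$transforms[[round]])
  if (!is.null(truth$jitter[[round]])) {
    p <- p + eval_jitter(truth$jitter[[round]], p)
  }
  anchor <- truth$tile_offsets[[round]][1, ]
  p[, 1] <- p[, 1] - anchor[["dx"]]
  p[, 2] <- p[, 2] - anchor[["dy"]]
  ids <- seq_len(nrow(p))
  if (present_only) {
    keep <- truth$present[, round]
    p <- p[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  attr(p, "gt_id") <- ids
  p
}

#' Render one sequencing round as a stack of tiles
#'
#' Each present bead is drawn as a truncated-Gaussian spot into the
#' brightfield channel of every tile whose field of view contains it; the
#' four fluorescence channels carry the crosstalk-mixed one-hot signal of the
#' bead's true base in that round, scaled by the tile gain, plus noise.
#' Deterministic given the truth (per-round sub-seeded noise).
#'
#' @param truth a `puck_truth` from [sample_truth()].
#' @param round round index (1-based).
#' @return object of class `tile_stack`: list with `sequence_index` and
#'   `images`, a list over tiles of named lists of channel rasters in [0, 1].
#' @export
render_round <- function(truth, round) {
  config <- truth$config
  spec <- config$acquisition
  stopifnot(round >= 1L, round <= spec$n_sequences)
  set.seed(sub_seed(truth$seed, paste0("render", round)))

  ts <- spec$tile_size
  nt <- n_tiles(spec)
  sigma <- config$bead_radius / 2
  halo <- ceiling(3 * sigma)

  # positions in the global (stage) frame of this round
  p <- transform_points(truth$positions, truth$transforms[[round]])
  if (!is.null(truth$jitter[[round]])) p <- p + eval_jitter(truth$jitter[[round]], p)
  present <- truth$present[, round]
  base_r <- truth$barcodes[, round]
  chan_of_base <- match(config$base_to_channel[base_r], FLUOR_CHANNELS)

  off <- disc_offsets(halo)
  prof <- exp(-(off$dx^2 + off$dy^2) / (2 * sigma^2))

  images <- vector("list", nt)
  for (k in seq_len(nt)) {
    o <- truth$tile_offsets[[round]][k, ]
    chans <- lapply(spec$channels, function(ch) matrix(0, ts, ts))
    names(chans) <- spec$channels
    sel <- which(present &
                   p[, 1] >= o[["dx"]] - halo & p[, 1] < o[["dx"]] + ts + halo &
                   p[, 2] >= o[["dy"]] - halo & p[, 2] < o[["dy"]] + ts + halo)
    gain <- truth$gains[round, k]
    for (i in sel) {
      lx <- p[i, 1] - o[["dx"]]; ly <- p[i, 2] - o[["dy"]]
      cx <- round(lx); cy <- round(ly)
      # sub-pixel-correct profile around the true centre
      w <- exp(-(((cx + off$dx) - lx)^2 + ((cy + off$dy) - ly)^2) / (2 * sigma^2))
      px <- cx + off$dx; py <- cy + off$dy
      ok <- px >= 0 & px < ts & py >= 0 & py < ts
      if (!any(ok)) next
      cells <- cbind(py[ok] + 1L, px[ok] + 1L)
      amp <- truth$brightness[i] * gain
      chans[["brightfield"]][cells] <- chans[["brightfield"]][cells] + amp * w[ok]
      mix <- config$crosstalk[, chan_of_base[i]]
      for (c4 in 1:4) {
        ch <- FLUOR_CHANNELS[c4]
        if (mix[c4] > 0)
          chans[[ch]][cells] <- chans[[ch]][cells] + amp * mix[c4] * w[ok]
      }
    }
    if (config$noise_sigma > 0) {
      for (ch in spec$channels)
        chans[[ch]] <- chans[[ch]] + matrix(stats::rnorm(ts * ts, 0, config$noise_sigma), ts, ts)
    }
    images[[k]] <- lapply(chans, function(m) pmin(pmax(m, 0), 1))
  }
  structure(list(sequence_index = as.integer(round), images = images,
                 tile_size = ts),
            class = "tile_stack")
}

#' @export
print.tile_stack <- function(x, ...) {
  cat(sprintf("TileStack: round %d, %d tiles of %d px, %d channels\n",
              x$sequence_index, length(x$images), x$tile_size,
              length(x$images[[1]])))
  invisible(x)
}

#' Generate a complete synthetic acquisition
#'
#' @param config a [simulation_config()].
#' @return list with `truth` (a `puck_truth`) and `stacks` (one `tile_stack`
#'   per round).  Reproducible: the same config yields identical rasters.
#' @export
generate_acquisition <- function(config) {
  truth <- sample_truth(config)
  stacks <- lapply(seq_len(config$acquisition$n_sequences),
                   function(r) render_round(truth, r))
  list(truth = truth, stacks = stacks)
}

# ---- disk I/O ---------------------------------------------------------------

#' Write an acquisition to disk as TIFF tiles + manifest + ground-truth TSV
#'
#' File naming: `seq{SS}_tile{T}_{channel}.tif`; a `manifest.csv` with columns
#' (sequence, tile, channel, path) indexes every raster.
#'
#' @param acq result of [generate_acquisition()].
#' @param dir output directory (created).
#' @export
write_acquisition <- function(acq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (st in acq$stacks) {
    for (k in seq_along(st$images)) {
      for (ch in names(st$images[[k]])) {
        fn <- sprintf("seq%02d_tile%d_%s.tif", st$sequence_index, k, ch)
        path <- file.path(dir, fn)
        tiff::writeTIFF(st$images[[k]][[ch]], path, bits.per.sample = 16L)
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = st$sequence_index, tile = k, channel = ch, path = fn)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  if (!is.null(acq$truth)) {
    tr <- acq$truth
    gt <- data.frame(bead_id = seq_len(nrow(tr$positions)),
                     x = tr$positions[, 1], y = tr$positions[, 2],
                     barcode = apply(tr$barcodes, 1, paste0, collapse = ""),
                     presence = apply(tr$present, 1, function(v)
                       paste0(as.integer(v), collapse = "")))
    utils::write.table(gt, file.path(dir, "ground_truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(file.path(dir, "manifest.csv"))
}

#' Read an acquisition from a manifest
#'
#' @param manifest path to a `manifest.csv` (sequence, tile, channel, path;
#'   paths relative to the manifest's directory).  Intensities are normalised
#'   to [0, 1].
#' @return list of `tile_stack` objects, one per sequence round.
#' @export
read_acquisition <- function(manifest) {
  man <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("sequence", "tile", "channel", "path") %in% names(man)))
  base <- dirname(manifest)
  stacks <- lapply(sort(unique(man$sequence)), function(s) {
    ms <- man[man$sequence == s, ]
    tiles <- sort(unique(ms$tile))
    images <- lapply(tiles, function(k) {
      mk <- ms[ms$tile == k, ]
      chans <- lapply(seq_len(nrow(mk)), function(i) {
        img <- tiff::readTIFF(file.path(base, mk$path[i]))
        if (length(dim(img)) == 3L) img <- img[, , 1]
        if (max(img) > 1) img <- img / max(img)
        img
      })
      names(chans) <- mk$channel
      chans[intersect(PUCK_CHANNELS, names(chans))]
    })
    structure(list(sequence_index = s, images = images,
                   tile_size = nrow(images[[1]][[1]])),
              class = "tile_stack")
  })
  stacks
}
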