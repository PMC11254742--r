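# Base calling from fluorescence gray values.
#
# Epifluorescence channels bleed into each other (crosstalk), and bead gray
# values vary with tile and round, so a fixed threshold per channel does not
# work.  A small dense network (4 inputs -> 16 -> 8 -> 4 outputs) is trained
# on labelled intensity 4-vectors with ADAM and a mean-squared-error loss
# against one-hot targets; each input vector is normalised by its maximum
# first, which makes the caller invariant to global gain.

#' Base-caller configuration
#'
#' @param channel_to_base named bijection from fluorescence channel label
#'   ("475","555","575","635") to base; the wavelength-ascending default is
#'   an arbitrary convention and must match the assay's dye chemistry.
#' @param hidden sizes of the two hidden layers.
#' @param learning_rate ADAM learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param seed RNG seed for the split, init and shuffling.
#' @return object of class `base_caller_config`.
#' @export
base_caller_config <- function(channel_to_base = c("475" = "A", "555" = "C",
                                                   "575" = "G", "635" = "T"),
                               hidden = c(16L, 8L), learning_rate = 0.001,
                               epochs = 100L, batch_size = 32L, seed = 1L) {
  if (!setequal(names(channel_to_base), FLUOR_CHANNELS) ||
      !setequal(channel_to_base, DNA_BASES))
    stop("channel_to_base must be a bijection channels -> {A,C,G,T}")
  stopifnot(learning_rate > 0, epochs >= 1L, batch_size >= 1L,
            length(hidden) == 2L)
  structure(list(channel_to_base = channel_to_base[FLUOR_CHANNELS],
                 hidden = as.integer(hidden), learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "base_caller_config")
}

# dense net forward pass; x is n x 4 (already max-normalised)
dense_forward <- function(par, x) {
  z1 <- x %*% par$W1 + matrix(par$b1, nrow(x), length(par$b1), byrow = TRUE)
  a1 <- tanh(z1)
  z2 <- a1 %*% par$W2 + matrix(par$b2, nrow(x), length(par$b2), byrow = TRUE)
  a2 <- tanh(z2)
  z3 <- a2 %*% par$W3 + matrix(par$b3, nrow(x), length(par$b3), byrow = TRUE)
  list(z1 = z1, a1 = a1, z2 = z2, a2 = a2, out = z3)
}

dense_backward <- function(par, fwd, x, y) {
  n <- nrow(x)
  dout <- 2 * (fwd$out - y) / (n * ncol(y))      # MSE gradient
  dW3 <- t(fwd$a2) %*% dout; db3 <- colSums(dout)
  da2 <- dout %*% t(par$W3)
  dz2 <- da2 * (1 - fwd$a2^2)
  dW2 <- t(fwd$a1) %*% dz2; db2 <- colSums(dz2)
  da1 <- dz2 %*% t(par$W2)
  dz1 <- da1 * (1 - fwd$a1^2)
  dW1 <- t(x) %*% dz1; db1 <- colSums(dz1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

max_normalise <- function(x) {
  m <- pmax(apply(x, 1, max), 1e-8)
  x / m
}

#' Train the base-calling network
#'
#' Splits the labelled samples into train/test, trains the dense 4 -> 16 ->
#' 8 -> 4 network with ADAM on the mean squared error against one-hot
#' targets, and reports held-out accuracy.  Seeded and repeatable.
#'
#' @param samples n x 4 matrix of fluorescence gray values, channel order
#'   (475, 555, 575, 635) nm.
#' @param labels character vector of true bases.
#' @param config a [base_caller_config()].
#' @param n_train number of training samples; the rest are the test set
#'   (default: 90% train).
#' @return object of class `base_caller` with the weights, config, per-epoch
#'   `history` (train MSE) and `test_accuracy`.
#' @export
train_base_caller <- function(samples, labels, config = base_caller_config(),
                              n_train = NULL) {
  samples <- as.matrix(samples)
  stopifnot(ncol(samples) == 4L, nrow(samples) == length(labels))
  if (any(!is.finite(samples))) stop("non-finite intensities in training data")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training data contains a single class; cannot train a classifier")
  if (!all(labels %in% DNA_BASES)) stop("labels must be in {A,C,G,T}")
  n <- nrow(samples)
  if (is.null(n_train)) n_train <- floor(0.9 * n)
  stopifnot(n_train >= 2L, n_train < n)

  base_of_channel <- config$channel_to_base          # channel idx -> base
  target_col <- match(labels, base_of_channel)       # output unit per sample
  y <- matrix(0, n, 4); y[cbind(seq_len(n), target_col)] <- 1

  set.seed(sub_seed(config$seed, "caller-split"))
  idx <- sample.int(n)
  tr <- idx[seq_len(n_train)]; te <- idx[-seq_len(n_train)]
  xall <- max_normalise(samples)
  xtr <- xall[tr, , drop = FALSE]; ytr <- y[tr, , drop = FALSE]
  xte <- xall[te, , drop = FALSE]; yte_col <- target_col[te]

  set.seed(sub_seed(config$seed, "caller-init"))
  h <- config$hidden
  par <- list(W1 = matrix(stats::rnorm(4 * h[1], 0, sqrt(1 / 4)), 4, h[1]),
              b1 = numeric(h[1]),
              W2 = matrix(stats::rnorm(h[1] * h[2], 0, sqrt(1 / h[1])), h[1], h[2]),
              b2 = numeric(h[2]),
              W3 = matrix(stats::rnorm(h[2] * 4, 0, sqrt(1 / h[2])), h[2], 4),
              b3 = numeric(4))
  st <- adam_init(par)
  hist <- numeric(config$epochs)
  set.seed(sub_seed(config$seed, "caller-train"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nrow(xtr))
    tot <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      xb <- xtr[bi, , drop = FALSE]; yb <- ytr[bi, , drop = FALSE]
      fwd <- dense_forward(par, xb)
      tot <- tot + mean((fwd$out - yb)^2); nb <- nb + 1L
      grad <- dense_backward(par, fwd, xb, yb)
      upd <- adam_step(par, grad, st, config$learning_rate)
      par <- upd$par; st <- upd$state
    }
    hist[ep] <- tot / nb
  }
  model <- structure(list(par = par, config = config,
                          history = data.frame(epoch = seq_len(config$epochs),
                                               train_mse = hist)),
                     class = "base_caller")
  pred <- dense_forward(par, xte)$out
  acc <- mean(max.col(pred, ties.method = "first") == yte_col)
  model$test_accuracy <- acc
  model$n_train <- n_train
  model$n_test <- n - n_train
  model
}

#' @export
print.base_caller <- function(x, ...) {
  cat(sprintf("Base caller: 4-%s-4 dense net, %d/%d train/test, held-out accuracy %.3f\n",
              paste(x$config$hidden, collapse = "-"), x$n_train, x$n_test,
              x$test_accuracy))
  invisible(x)
}

#' Call the DNA base for fluorescence intensity vectors
#'
#' Forward pass through the trained network; the called base is the
#' channel-to-base image of the arg-max output, the confidence the margin
#' between the two largest outputs.  Exact output ties resolve in channel
#' order.
#'
#' @param intensities length-4 vector or n x 4 matrix, channel order
#'   (475, 555, 575, 635) nm.
#' @param model a trained `base_caller`.
#' @return data.frame with columns `base` and `confidence`.
#' @export
call_base <- function(intensities, model) {
  x <- if (is.null(dim(intensities))) matrix(intensities, 1) else as.matrix(intensities)
  stopifnot(ncol(x) == 4L)
  if (any(!is.finite(x))) stop("non-finite intensity input")
  out <- dense_forward(model$par, max_normalise(x))$out
  k <- max.col(out, ties.method = "first")
  second <- vapply(seq_len(nrow(out)), function(i) max(out[i, -k[i]]), numeric(1))
  data.frame(base = unname(model$config$channel_to_base[k]),
             confidence = out[cbind(seq_len(nrow(out)), k)] - second)
}

#' Simulate labelled intensity 4-vectors under the acquisition noise model
#'
#' Draws uniformly random true bases and produces the observed gray values a
#' bead with that base would show: crosstalk-mixed one-hot dye signal, random
#' gain, plus additive Gaussian noise (clipped to [0, 1]).  This is the
#' synthetic stand-in for confocal-labelled training data.
#'
#' @param n number of samples.
#' @param config a [simulation_config()] (crosstalk, gain and noise used).
#' @param seed RNG seed.
#' @return list with `samples` (n x 4) and `labels` (bases).
#' @export
simulate_intensity_samples <- function(n, config = simulation_config(),
                                       seed = config$seed) {
  set.seed(sub_seed(seed, "caller-samples"))
  bases <- sample(DNA_BASES, n, replace = TRUE)
  chan <- match(config$base_to_channel[bases], FLUOR_CHANNELS)
  pure <- matrix(0, n, 4); pure[cbind(seq_len(n), chan)] <- 1
  mixed <- pure %*% t(config$crosstalk)
  gain <- stats::runif(n, config$gain_range[1], config$gain_range[2]) *
    stats::runif(n, 0.75, 1.0)                       # per-bead brightness
  obs <- mixed * gain + matrix(stats::rnorm(n * 4, 0, config$noise_sigma), n, 4)
  obs <- pmin(pmax(obs, 0), 1)
  colnames(obs) <- paste0("i", FLUOR_CHANNELS)
  list(samples = obs, labels = bases)
}

#' Arg-max accuracy after exact crosstalk unmixing (testing baseline)
#'
#' Classifies by multiplying the observed vectors with the inverse crosstalk
#' matrix and taking the arg-max channel.  A non-learned reference the
#' trained caller is compared against.
#'
#' @param samples n x 4 observed intensities.
#' @param labels true bases.
#' @param config a [simulation_config()] supplying crosstalk and the
#'   base/channel mapping.
#' @return fraction correct.
#' @export
unmix_argmax_accuracy <- function(samples, labels, config) {
  un <- as.matrix(samples) %*% t(solve(config$crosstalk))
  chan <- max.col(un, ties.method = "first")
  called <- names(config$base_to_channel)[match(FLUOR_CHANNELS[chan],
                                                config$base_to_channel)]
  mean(called == labels)
}

#' Read per-bead, per-round fluorescence intensity vectors
#'
#' For every tracked bead and every round in which it was matched, averages
#' each fluorescence mosaic over a disc at the matched detection's position
#' and subtracts the local annulus-median background.  Missing rounds stay
#' missing (NA), never zero-filled.
#'
#' @param tracks a `track_table` from [link_across_sequences()].
#' @param per_round_beads list of [bead_set()]s per round (detection frames).
#' @param fluor_mosaics list over rounds of named lists of the four
#'   fluorescence mosaics in that round's own frame; each raster may carry an
#'   `origin` attribute (x0, y0) of its frame.
#' @param radius disc radius in px.
#' @return numeric array [beads x rounds x 4] with NA where missing.
#' @export
read_bead_intensities <- function(tracks, per_round_beads, fluor_mosaics,
                                  radius = 3) {
  R <- length(per_round_beads)
  n <- nrow(tracks)
  out <- array(NA_real_, c(n, R, 4),
               dimnames = list(NULL, NULL, FLUOR_CHANNELS))
  for (r in seq_len(R)) {
    ids <- tracks[[paste0("match_r", r)]]
    hit <- which(!is.na(ids))
    if (length(hit) == 0L) next
    beads <- per_round_beads[[r]]
    pos <- bead_xy(beads)[match(ids[hit], beads$id), , drop = FALSE]
    mos <- fluor_mosaics[[r]]
    org <- attr(mos[[1]], "origin")
    if (is.null(org)) org <- c(0, 0)
    for (c4 in seq_along(FLUOR_CHANNELS)) {
      m <- mos[[FLUOR_CHANNELS[c4]]]
      for (i in seq_along(hit)) {
        v <- disc_mean(m, pos[i, 1] - org[1], pos[i, 2] - org[2], radius)
        out[hit[i], r, c4] <- if (is.na(v)) NA_real_ else max(v, 0)
      }
    }
  }
  # a bead whose disc left the mosaic in one channel is missing in all
  miss <- apply(is.na(out), c(1, 2), any)
  for (c4 in 1:4) out[, , c4][miss] <- NA_real_
  out
}

#' Assemble per-bead barcodes from per-round base calls
#'
#' @param tracks a `track_table`.
#' @param intensities array from [read_bead_intensities()].
#' @param model a trained `base_caller`.
#' @return a [barcode_table()]; rounds without a match (or without readable
#'   intensities) are called N.
#' @export
assemble_barcodes <- function(tracks, intensities, model) {
  n <- dim(intensities)[1]; R <- dim(intensities)[2]
  bases <- matrix("N", n, R)
  for (r in seq_len(R)) {
    ok <- which(!is.na(intensities[, r, 1]))
    if (length(ok) == 0L) next
    calls <- call_base(intensities[ok, r, , drop = TRUE], model)
    bases[ok, r] <- calls$base
  }
  barcode_table(tracks$bead_id, tracks$x, tracks$y, bases)
}
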