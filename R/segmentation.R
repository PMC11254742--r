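# Bead segmentation on brightfield tiles.
#
# Two detectors are provided:
#   * a small fully-convolutional network (conv 3x3 -> conv 3x3 -> conv 1x1,
#     sigmoid), trained on 50x50 patches with ADAM + binary cross-entropy —
#     the trainable path, kept deliberately tiny so a handful of labelled
#     patches suffices;
#   * oracle_segment(), a classical blur + local-maxima detector used as a
#     non-learned reference and as the pipeline's fast default.
# Both produce sub-pixel centroids; render_mask() turns centroids into the
# radius-3 disc masks all downstream stages operate on.

#' Segmenter configuration
#'
#' @param patch_size training/inference patch edge (px).
#' @param prob_threshold probability cut for binarising network output.
#' @param min_component_area components smaller than this (px^2) are dropped.
#' @param circle_radius radius of the discs rendered at detected centres.
#' @param hidden_channels feature channels of the two hidden conv layers.
#' @param epochs,batch_size,learning_rate ADAM training schedule (binary
#'   cross-entropy loss).
#' @param n_patches number of training patches cropped from the labelled
#'   tiles.
#' @param val_frac fraction of patches held out for validation.
#' @param seed RNG seed for patch sampling and weight init.
#' @return object of class `segmenter_config`.
#' @export
segmenter_config <- function(patch_size = 50L, prob_threshold = 0.5,
                             min_component_area = 3L, circle_radius = 3L,
                             hidden_channels = 8L, epochs = 40L,
                             batch_size = 8L, learning_rate = 1e-3,
                             n_patches = 48L, val_frac = 0.2, seed = 1L) {
  stopifnot(patch_size >= 8L, prob_threshold > 0, prob_threshold < 1,
            min_component_area >= 1L, circle_radius >= 1L,
            hidden_channels >= 1L, epochs >= 1L, batch_size >= 1L,
            learning_rate > 0, n_patches >= 2L, val_frac >= 0, val_frac < 1)
  structure(list(patch_size = as.integer(patch_size),
                 prob_threshold = prob_threshold,
                 min_component_area = as.integer(min_component_area),
                 circle_radius = as.integer(circle_radius),
                 hidden_channels = as.integer(hidden_channels),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_patches = as.integer(n_patches), val_frac = val_frac,
                 seed = as.integer(seed)),
            class = "segmenter_config")
}

# ---- tiny fully-convolutional net ------------------------------------------
# Feature maps are lists over channels of [H, W, N] arrays (N = batch).

pad_hw <- function(a, p = 1L) {
  d <- dim(a)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), ] <- a
  out
}

conv3_forward <- function(x, w, b) {
  # x: list Cin of [H,W,N]; w: [3,3,Cin,Cout]; b: [Cout]
  cin <- length(x); cout <- length(b)
  d <- dim(x[[1]])
  pads <- lapply(x, pad_hw)
  out <- vector("list", cout)
  for (co in seq_len(cout)) {
    z <- array(b[co], d)
    for (ci in seq_len(cin)) {
      p <- pads[[ci]]
      for (di in 1:3) for (dj in 1:3) {
        wv <- w[di, dj, ci, co]
        if (wv != 0)
          z <- z + wv * p[di:(di + d[1] - 1L), dj:(dj + d[2] - 1L), , drop = FALSE]
      }
    }
    dim(z) <- d
    out[[co]] <- z
  }
  out
}

conv3_backward <- function(x, w, dz) {
  cin <- length(x); cout <- length(dz)
  d <- dim(x[[1]])
  padx <- lapply(x, pad_hw)
  paddz <- lapply(dz, pad_hw)
  dw <- array(0, dim(w)); db <- numeric(cout)
  dx <- lapply(seq_len(cin), function(i) array(0, d))
  for (co in seq_len(cout)) {
    db[co] <- sum(dz[[co]])
    for (ci in seq_len(cin)) {
      px <- padx[[ci]]; pz <- paddz[[co]]
      for (di in 1:3) for (dj in 1:3) {
        xs <- px[di:(di + d[1] - 1L), dj:(dj + d[2] - 1L), , drop = FALSE]
        dw[di, dj, ci, co] <- sum(xs * dz[[co]])
        # transposed conv for input gradient: opposite shift
        oi <- 4L - di; oj <- 4L - dj
        dx[[ci]] <- dx[[ci]] +
          w[di, dj, ci, co] * pz[oi:(oi + d[1] - 1L), oj:(oj + d[2] - 1L), , drop = FALSE]
      }
    }
  }
  list(dw = dw, db = db, dx = dx)
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

segnet_init <- function(cfg) {
  set.seed(sub_seed(cfg$seed, "segnet-init"))
  C <- cfg$hidden_channels
  he <- function(n_in) sqrt(2 / n_in)
  list(w1 = array(stats::rnorm(3 * 3 * 1 * C, 0, he(9)), c(3, 3, 1, C)),
       b1 = numeric(C),
       w2 = array(stats::rnorm(3 * 3 * C * C, 0, he(9 * C)), c(3, 3, C, C)),
       b2 = numeric(C),
       w3 = stats::rnorm(C, 0, he(C)),     # 1x1 conv to 1 channel
       b3 = -1)                            # bias towards background
}

segnet_forward <- function(par, xbatch) {
  # xbatch: [H, W, N] input (single channel)
  a0 <- list(xbatch)
  z1 <- conv3_forward(a0, par$w1, par$b1)
  a1 <- lapply(z1, relu)
  z2 <- conv3_forward(a1, par$w2, par$b2)
  a2 <- lapply(z2, relu)
  d <- dim(xbatch)
  z3 <- array(par$b3, d)
  for (ci in seq_along(a2)) z3 <- z3 + par$w3[ci] * a2[[ci]]
  p <- sigmoid(z3)
  list(a0 = a0, z1 = z1, a1 = a1, z2 = z2, a2 = a2, p = p)
}

segnet_backward <- function(par, fwd, ybatch) {
  d <- dim(ybatch)
  n_el <- prod(d)
  dz3 <- (fwd$p - ybatch) / n_el          # sigmoid + BCE gradient
  dw3 <- vapply(fwd$a2, function(a) sum(a * dz3), numeric(1))
  db3 <- sum(dz3)
  da2 <- lapply(par$w3, function(w) w * dz3)
  dz2 <- mapply(function(da, z) da * (z > 0), da2, fwd$z2, SIMPLIFY = FALSE)
  g2 <- conv3_backward(fwd$a1, par$w2, dz2)
  dz1 <- mapply(function(da, z) da * (z > 0), g2$dx, fwd$z1, SIMPLIFY = FALSE)
  g1 <- conv3_backward(fwd$a0, par$w1, dz1)
  list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db, w3 = dw3, b3 = db3)
}

bce_loss <- function(p, y) {
  eps <- 1e-7
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

# generic ADAM state over a named list of arrays
adam_init <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

adam_step <- function(par, grad, state, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(par)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grad[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    par[[nm]] <- par[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(par = par, state = state)
}

# robust per-tile brightness normalisation: the conv net sees tiles whose
# gain varies between rounds and stage positions; rescaling by the bright
# quantile makes it invariant to that gain
norm_tile <- function(m) {
  mx <- as.numeric(stats::quantile(m, 0.999))
  if (mx > 0.05) pmin(m / mx, 1) else m
}

# crop patches covering the labelled area; guarantees positive patches
crop_patches <- function(images, masks, cfg, n_patches = cfg$n_patches) {
  ps <- cfg$patch_size
  xs <- list(); ys <- list()
  for (i in seq_along(images)) {
    img <- images[[i]]; msk <- masks[[i]]
    if (nrow(img) < ps || ncol(img) < ps)
      stop("image smaller than patch_size")
    fg <- which(msk > 0, arr.ind = TRUE)
    n_i <- ceiling(n_patches / length(images))
    for (k in seq_len(n_i)) {
      if (nrow(fg) > 0 && k %% 2 == 1L) {
        # centre a patch near a random labelled bead
        j <- sample.int(nrow(fg), 1)
        r0 <- min(max(1L, fg[j, 1] - ps %/% 2), nrow(img) - ps + 1L)
        c0 <- min(max(1L, fg[j, 2] - ps %/% 2), ncol(img) - ps + 1L)
      } else {
        r0 <- sample.int(nrow(img) - ps + 1L, 1)
        c0 <- sample.int(ncol(img) - ps + 1L, 1)
      }
      xs[[length(xs) + 1L]] <- img[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
      ys[[length(ys) + 1L]] <- msk[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
    }
  }
  list(x = xs, y = ys)
}

stack_patches <- function(lst) {
  ps <- nrow(lst[[1]])
  array(unlist(lst), c(ps, ps, length(lst)))
}

#' Train the bead-segmentation network
#'
#' Trains the small fully-convolutional net on `patch_size` x `patch_size`
#' crops of brightfield images against binary centre labels (discs around
#' bead centres, kept a couple of pixels inside the bead boundary), with
#' ADAM and binary cross-entropy.  Seeded and repeatable.
#'
#' @param images a single matrix or list of brightfield tiles in [0, 1].
#' @param masks matching binary label rasters (1 = bead centre region).
#' @param config a [segmenter_config()].
#' @return object of class `bead_segmenter` with the weights, the config and
#'   a per-epoch `history` data.frame (epoch, train_loss, val_loss).
#' @export
train_segmenter <- function(images, masks, config = segmenter_config()) {
  if (is.matrix(images)) images <- list(images)
  if (is.matrix(masks)) masks <- list(masks)
  stopifnot(length(images) == length(masks))
  images <- lapply(images, norm_tile)
  if (!any(vapply(masks, function(m) any(m > 0), logical(1))))
    stop("label set contains no positive pixels; cannot train")
  set.seed(sub_seed(config$seed, "segnet-data"))
  patches <- crop_patches(images, masks, config)
  n <- length(patches$x)
  n_val <- max(1L, floor(config$val_frac * n))
  idx <- sample.int(n)
  val <- idx[seq_len(n_val)]; trn <- idx[-seq_len(n_val)]
  xtr <- patches$x[trn]; ytr <- patches$y[trn]
  xva <- stack_patches(patches$x[val]); yva <- stack_patches(patches$y[val])

  par <- segnet_init(config)
  st <- adam_init(par)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  set.seed(sub_seed(config$seed, "segnet-train"))
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(xtr))
    tl <- 0; nb <- 0L
    for (b0 in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[b0:min(b0 + config$batch_size - 1L, length(ord))]
      xb <- stack_patches(xtr[bi]); yb <- stack_patches(ytr[bi])
      fwd <- segnet_forward(par, xb)
      tl <- tl + bce_loss(fwd$p, yb); nb <- nb + 1L
      grad <- segnet_backward(par, fwd, yb)
      upd <- adam_step(par, grad, st, config$learning_rate)
      par <- upd$par; st <- upd$state
    }
    vl <- bce_loss(segnet_forward(par, xva)$p, yva)
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl / nb,
                                   val_loss = vl))
  }
  structure(list(par = par, config = config, history = hist),
            class = "bead_segmenter")
}

#' @export
print.bead_segmenter <- function(x, ...) {
  np <- sum(vapply(x$par, length, integer(1)))
  cat(sprintf("Bead segmenter: %d parameters, trained %d epochs, final val BCE %.4f\n",
              np, nrow(x$history), utils::tail(x$history$val_loss, 1)))
  invisible(x)
}

#' Per-pixel bead probability for a whole tile
#'
#' Runs the trained network over the tile in `patch_size` windows with 50%
#' overlap, keeping each window's central region, so patch borders leave no
#' seams.
#'
#' @param image brightfield raster in [0, 1]; must be at least
#'   `patch_size` on each side.
#' @param model a trained `bead_segmenter`.
#' @return probability raster of the same shape.
#' @export
segment_tile <- function(image, model) {
  ps <- model$config$patch_size
  if (nrow(image) < ps || ncol(image) < ps)
    stop(sprintf("image (%d x %d) smaller than patch_size (%d)",
                 nrow(image), ncol(image), ps))
  image <- norm_tile(image)
  stride <- ps %/% 2L
  margin <- (ps - stride) %/% 2L
  h <- nrow(image); w <- ncol(image)
  # pad so that central-crop tiling covers the full image
  ph <- margin + ceiling(h / stride) * stride + ps
  pw <- margin + ceiling(w / stride) * stride + ps
  pad <- matrix(0, ph, pw)
  pad[margin + seq_len(h), margin + seq_len(w)] <- image
  out <- matrix(0, ph, pw)
  r0s <- seq(1L, ph - ps + 1L, by = stride)
  c0s <- seq(1L, pw - ps + 1L, by = stride)
  patches <- list(); coords <- list()
  for (r0 in r0s) for (c0 in c0s) {
    patches[[length(patches) + 1L]] <- pad[r0:(r0 + ps - 1L), c0:(c0 + ps - 1L)]
    coords[[length(coords) + 1L]] <- c(r0, c0)
  }
  # batched inference
  bs <- 16L
  for (b0 in seq(1, length(patches), by = bs)) {
    bi <- b0:min(b0 + bs - 1L, length(patches))
    p <- segnet_forward(model$par, stack_patches(patches[bi]))$p
    for (j in seq_along(bi)) {
      rc <- coords[[bi[j]]]
      ctr <- (margin + 1L):(margin + stride)
      out[rc[1] + ctr - 1L, rc[2] + ctr - 1L] <- p[ctr, ctr, j]
    }
  }
  out[margin + seq_len(h), margin + seq_len(w), drop = FALSE]
}

#' Extract bead centroids from a probability raster
#'
#' Binarises at `prob_threshold`, labels 8-connected components, drops
#' components below `min_component_area`, and takes each component's mean
#' pixel position as the centroid.
#'
#' @param prob raster in [0, 1] (a binary mask also works).
#' @param config a [segmenter_config()].
#' @return a [bead_set()] of centroid positions (0-based, sub-pixel).
#' @export
extract_centroids <- function(prob, config = segmenter_config()) {
  lab <- label_components(prob >= config$prob_threshold)
  if (!any(lab > 0L)) return(bead_set())
  fg <- which(lab > 0L, arr.ind = TRUE)
  ids <- lab[fg]
  area <- tabulate(ids)
  keep <- which(area >= config$min_component_area)
  if (length(keep) == 0L) return(bead_set())
  cx <- tapply(fg[, 2] - 1, ids, mean)[as.character(keep)]
  cy <- tapply(fg[, 1] - 1, ids, mean)[as.character(keep)]
  b <- bead_set(as.numeric(cx), as.numeric(cy))
  b[order(b$y, b$x), ]
}

#' Render a binary disc mask from bead centroids
#'
#' Draws a filled disc of `radius` pixels at each (rounded) centroid;
#' overlapping discs union.  Centroids outside the raster are clipped with a
#' warning.
#'
#' @param beads a [bead_set()] (positions used).
#' @param radius disc radius in px.
#' @param shape c(height, width) of the output raster.
#' @export
render_mask <- function(beads, radius, shape) {
  paint_discs(shape, bead_xy(beads), radius)
}

#' Classical reference bead detector (blur + threshold + local maxima)
#'
#' Gaussian-blurs the brightfield tile, finds strict local maxima above an
#' adaptive threshold, and refines each to sub-pixel precision with an
#' intensity-weighted centroid.  Non-learned; used as an independent
#' reference for the network and as the pipeline's fast default detector.
#'
#' @param image brightfield raster in [0, 1].
#' @param config a [segmenter_config()] (only `circle_radius` used for
#'   de-duplication).
#' @param sigma blur sd in px (≈ half the bead radius works well).
#' @param threshold_rel maxima must exceed
#'   `background + threshold_rel * (max - background)`.
#' @return a [bead_set()] of sub-pixel centroids.
#' @export
oracle_segment <- function(image, config = segmenter_config(), sigma = 2,
                           threshold_rel = 0.25) {
  bl <- gaussian_blur(image, sigma)
  bg <- stats::median(bl)
  peak <- max(bl)
  if (peak - bg < 0.02) return(bead_set())   # blank image
  thr <- bg + threshold_rel * (peak - bg)
  pk <- local_maxima(bl, min_value = thr, merge_dist = max(2, config$circle_radius))
  if (nrow(pk) == 0L) return(bead_set())
  # sub-pixel refinement: intensity-weighted centroid in a 5x5 window
  h <- nrow(image); w <- ncol(image)
  off <- expand.grid(dx = -2:2, dy = -2:2)
  rx <- ry <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    cx <- round(pk$x[i]); cy <- round(pk$y[i])
    px <- cx + off$dx; py <- cy + off$dy
    ok <- px >= 0 & px < w & py >= 0 & py < h
    v <- pmax(bl[cbind(py[ok] + 1L, px[ok] + 1L)] - bg, 0)
    if (sum(v) <= 0) { rx[i] <- cx; ry[i] <- cy; next }
    rx[i] <- sum(px[ok] * v) / sum(v)
    ry[i] <- sum(py[ok] * v) / sum(v)
  }
  b <- bead_set(rx, ry)
  b[order(b$y, b$x), ]
}

#' Detect beads on one tile with either detector
#' @keywords internal
detect_beads_tile <- function(image, method, config, model = NULL) {
  if (method == "cnn") {
    prob <- segment_tile(image, model)
    extract_centroids(prob, config)
  } else {
    oracle_segment(image, config)
  }
}

#' Build training labels for the segmenter from known bead centres
#'
#' Discs of radius `bead_radius - 2` px (at least 1) around the true centres,
#' mirroring hand labels that stay a few pixels inside the bead boundary.
#'
#' @param xy bead centres (n x 2).
#' @param bead_radius bead radius in px.
#' @param shape raster shape c(height, width).
#' @export
segmentation_labels <- function(xy, bead_radius, shape) {
  paint_discs(shape, xy, max(1, bead_radius - 2), warn_clip = FALSE)
}
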