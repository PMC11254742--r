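# Mosaic stitching of tile masks.
#
# Operates on the binary centroid-disc masks (not the raw images): the
# overlap strips of neighbouring tiles show the same beads, so the mean
# absolute difference over the implied overlap, normalised by its area, is
# the alignment cost.  Pairwise alignment along the tile grid gives an
# initial layout; a coordinate-descent grid search over all tiles then
# minimises the total cost over every overlapping pair.

#' Pairwise tile alignment along one edge
#'
#' For two horizontally adjacent same-size tiles, exhaustively evaluates
#' offsets `dx` in `nominal ± search_radius` (where `nominal = tile_size -
#' nominal_overlap`) and `dy` in `[-search_radius, search_radius]`; the cost
#' of a candidate is the mean absolute difference over the implied overlap
#' strip.  Ties resolve towards the nominal offset, then the smallest |dy|.
#' For vertical neighbours pass transposed masks and swap the returned axes.
#'
#' @param left,right binary rasters of identical shape.
#' @param nominal_overlap nominal overlap width in px (> 0).
#' @param search_radius half-width of the search window in px.
#' @return list with integer `dx`, `dy` and the achieved `cost`.
#' @export
pairwise_offset <- function(left, right, nominal_overlap, search_radius = 15L) {
  stopifnot(all(dim(left) == dim(right)), nominal_overlap > 0)
  ts <- ncol(left)
  nominal_dx <- ts - as.integer(round(nominal_overlap))
  dxs <- (nominal_dx - search_radius):(nominal_dx + search_radius)
  dxs <- dxs[dxs >= 1L & dxs <= ts - 1L]
  dys <- (-search_radius):search_radius
  if (length(dxs) == 0L) stop("empty search window")
  # candidate order implements the tie-breaking rule with strict improvement
  cand <- expand.grid(dx = dxs, dy = dys)
  cand <- cand[order(abs(cand$dx - nominal_dx), abs(cand$dy), cand$dx, cand$dy), ]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    score <- strip_cost(left, right, cand$dx[i], cand$dy[i],
                        lambda = content_prior())
    if (is.na(score)) next
    if (is.null(best) || score < best$score)
      best <- list(dx = cand$dx[i], dy = cand$dy[i], score = score)
  }
  if (is.null(best)) stop("overlap strip narrower than 1 px for every candidate")
  raw <- strip_cost(left, right, best$dx, best$dy)
  list(dx = best$dx, dy = best$dy, cost = if (is.na(raw)) 0 else raw)
}

# normalised mask difference over the strip implied by placing `right` at
# (dx, dy): sum |left - right| divided by the total foreground in the strip.
# Bead masks are sparse, so normalising by strip *area* would score an empty
# (bead-free) overlap as perfect; content normalisation keeps the cost in
# [0, 1] with 0 = every bead matched and NA = nothing to compare.
strip_cost <- function(left, right, dx, dy, lambda = 0) {
  ts_r <- nrow(left); ts_c <- ncol(left)
  if (dx >= ts_c || dx < 0L || abs(dy) >= ts_r) return(NA_real_)
  xs_l <- (dx + 1L):ts_c
  xs_r <- seq_along(xs_l)
  if (dy >= 0L) { ys_l <- (dy + 1L):ts_r; ys_r <- seq_along(ys_l) }
  else { ys_r <- (-dy + 1L):ts_r; ys_l <- seq_along(ys_r) }
  if (length(ys_l) < 1L) return(NA_real_)
  a <- left[ys_l, xs_l, drop = FALSE]; b <- right[ys_r, xs_r, drop = FALSE]
  content <- sum(a) + sum(b)
  if (content + lambda == 0) return(NA_real_)
  (sum(abs(a - b)) + lambda) / (content + lambda)
}

# ---- fast pairwise cost tables ---------------------------------------------
# For square binary masks the overlap cost at any relative shift decomposes
# as (Sa + Sb - 2 * C) / (Sa + Sb): Sa, Sb are rectangle sums (integral
# images) and C the cross-correlation, computed for every shift at once by
# FFT and rounded back to exact integers.

integral_image <- function(m) {
  ci <- apply(m, 2, cumsum)
  t(apply(ci, 1, cumsum))
}

rect_sum <- function(ii, y0, y1, x0, x1) {
  # 0-based inclusive bounds
  s <- ii[y1 + 1L, x1 + 1L]
  if (y0 > 0L) s <- s - ii[y0, x1 + 1L]
  if (x0 > 0L) s <- s - ii[y1 + 1L, x0]
  if (y0 > 0L && x0 > 0L) s <- s + ii[y0, x0]
  s
}

make_pair_cost <- function(a, b) {
  ts <- nrow(a)
  n <- 2L * ts
  pa <- matrix(0, n, n); pa[1:ts, 1:ts] <- a
  pb <- matrix(0, n, n); pb[1:ts, 1:ts] <- b
  C <- round(Re(stats::fft(stats::fft(pa) * Conj(stats::fft(pb)),
                           inverse = TRUE)) / (n * n))
  list(C = C, ia = integral_image(a), ib = integral_image(b), ts = ts, n = n)
}

# cost of placing b at (rel_dx, rel_dy) relative to a; vectorised over
# equal-length shift vectors.  `lambda` adds a mismatch prior of about two
# bead discs so that a nearly empty overlap strip cannot score a spurious
# perfect match (sparse masks would otherwise bias towards minimal overlap);
# lambda = 0 gives the raw mismatch fraction.
pair_cost_query <- function(pc, rel_dx, rel_dy, lambda = 0) {
  ts <- pc$ts
  x0 <- pmax(0L, rel_dx); x1 <- pmin(ts, ts + rel_dx) - 1L
  y0 <- pmax(0L, rel_dy); y1 <- pmin(ts, ts + rel_dy) - 1L
  out <- rep(NA_real_, length(rel_dx))
  ok <- x1 >= x0 & y1 >= y0
  if (!any(ok)) return(out)
  rsum <- function(ii, y0, y1, x0, x1) {
    s <- ii[cbind(y1 + 1L, x1 + 1L)]
    s <- s - ifelse(y0 > 0L, ii[cbind(pmax(y0, 1L), x1 + 1L)], 0)
    s <- s - ifelse(x0 > 0L, ii[cbind(y1 + 1L, pmax(x0, 1L))], 0)
    s + ifelse(y0 > 0L & x0 > 0L, ii[cbind(pmax(y0, 1L), pmax(x0, 1L))], 0)
  }
  sa <- rsum(pc$ia, y0[ok], y1[ok], x0[ok], x1[ok])
  sb <- rsum(pc$ib, y0[ok] - rel_dy[ok], y1[ok] - rel_dy[ok],
             x0[ok] - rel_dx[ok], x1[ok] - rel_dx[ok])
  cr <- pc$C[cbind((rel_dy[ok] %% pc$n) + 1L, (rel_dx[ok] %% pc$n) + 1L)]
  tot <- sa + sb
  val <- (tot - 2 * cr + lambda) / (tot + lambda)
  val[tot + lambda == 0] <- NA_real_
  out[ok] <- val
  out
}

# default mismatch prior: about two rendered discs of the given radius
content_prior <- function(radius = 3) 2L * nrow(disc_offsets(radius))

# cost tables for every adjacent tile pair of a layout grid
build_pair_cache <- function(tiles, off) {
  cache <- list()
  for (i in seq_len(nrow(off) - 1L)) for (j in (i + 1L):nrow(off)) {
    if (abs(off$row[i] - off$row[j]) + abs(off$col[i] - off$col[j]) != 1L) next
    cache[[paste(off$tile[i], off$tile[j], sep = "_")]] <-
      make_pair_cost(tiles[[off$tile[i]]], tiles[[off$tile[j]]])
  }
  cache
}

# overlap cost of placed tiles i, j (tile numbers) from the cache;
# off_i may be a 2-column matrix of candidate positions
cached_pair_cost <- function(cache, i, j, off_i, off_j, lambda = 0) {
  key <- paste(min(i, j), max(i, j), sep = "_")
  pc <- cache[[key]]
  if (is.null(dim(off_i))) off_i <- matrix(off_i, 1)
  if (i < j) pair_cost_query(pc, off_j[1] - off_i[, 1], off_j[2] - off_i[, 2], lambda)
  else pair_cost_query(pc, off_i[, 1] - off_j[1], off_i[, 2] - off_j[2], lambda)
}

# mean abs difference over the intersection of two placed tiles; NA if the
# intersection is empty.  Offsets are 0-based mosaic positions.
placed_overlap_cost <- function(a, off_a, b, off_b) {
  ha <- nrow(a); wa <- ncol(a); hb <- nrow(b); wb <- ncol(b)
  x0 <- max(off_a[1], off_b[1]); x1 <- min(off_a[1] + wa, off_b[1] + wb) - 1L
  y0 <- max(off_a[2], off_b[2]); y1 <- min(off_a[2] + ha, off_b[2] + hb) - 1L
  if (x1 < x0 || y1 < y0) return(NA_real_)
  sa <- a[(y0 - off_a[2] + 1L):(y1 - off_a[2] + 1L),
          (x0 - off_a[1] + 1L):(x1 - off_a[1] + 1L), drop = FALSE]
  sb <- b[(y0 - off_b[2] + 1L):(y1 - off_b[2] + 1L),
          (x0 - off_b[1] + 1L):(x1 - off_b[1] + 1L), drop = FALSE]
  content <- sum(sa) + sum(sb)
  if (content == 0) return(NA_real_)
  sum(abs(sa - sb)) / content
}

# total normalised overlap cost of a layout over adjacent tile pairs
layout_cost <- function(tiles, layout) {
  off <- layout$offsets
  total <- 0
  for (i in seq_len(nrow(off) - 1L)) for (j in (i + 1L):nrow(off)) {
    if (abs(off$row[i] - off$row[j]) + abs(off$col[i] - off$col[j]) != 1L) next
    cst <- placed_overlap_cost(tiles[[off$tile[i]]], c(off$dx[i], off$dy[i]),
                               tiles[[off$tile[j]]], c(off$dx[j], off$dy[j]))
    if (!is.na(cst)) total <- total + cst
  }
  total
}

#' Initial layout from pairwise overlap alignment
#'
#' Places tiles in raster order.  Each new tile is positioned by an
#' exhaustive grid search within `search_radius` of its nominal offset
#' (relative to its placed left/top neighbour), scored against the summed
#' overlap cost with *all* already-placed adjacent tiles — the same pairwise
#' overlap-difference objective as [pairwise_offset()], but a tile with two
#' placed neighbours is constrained by both, which keeps a single sparse
#' overlap strip from derailing the chain.
#'
#' @param tiles list of binary tile masks in raster order.
#' @param spec an [acquisition_spec()].
#' @param search_radius search half-width in px.
#' @param pair_cache precomputed pair cost tables (internal reuse).
#' @return a [stitch_layout()].
#' @export
init_layout <- function(tiles, spec, search_radius = 15L, pair_cache = NULL) {
  lay <- nominal_layout(spec)
  off <- lay$offsets
  if (is.null(pair_cache)) pair_cache <- build_pair_cache(tiles, off)
  nominal <- off
  placed <- logical(nrow(off))
  for (i in seq_len(nrow(off))) {
    if (off$row[i] == 0L && off$col[i] == 0L) {
      off$dx[i] <- 0L; off$dy[i] <- 0L; placed[i] <- TRUE; next
    }
    nb <- which(placed & abs(off$row - off$row[i]) + abs(off$col - off$col[i]) == 1L)
    # predict from a placed neighbour plus the nominal relative step
    j <- nb[1]
    pred <- c(off$dx[j] + nominal$dx[i] - nominal$dx[j],
              off$dy[j] + nominal$dy[i] - nominal$dy[j])
    cand <- expand.grid(ddx = -search_radius:search_radius,
                        ddy = -search_radius:search_radius)
    cand <- cand[order(abs(cand$ddx) + abs(cand$ddy), abs(cand$ddy),
                       cand$ddx, cand$ddy), ]
    cand_abs <- cbind(pred[1] + cand$ddx, pred[2] + cand$ddy)
    tot <- matrix(NA_real_, nrow(cand_abs), length(nb))
    for (k2 in seq_along(nb)) {
      j2 <- nb[k2]
      tot[, k2] <- cached_pair_cost(pair_cache, off$tile[i], off$tile[j2],
                                    cand_abs, c(off$dx[j2], off$dy[j2]),
                                    lambda = content_prior())
    }
    n_ov <- rowSums(!is.na(tot))
    score <- ifelse(n_ov > 0, rowSums(tot, na.rm = TRUE) / n_ov, NA_real_)
    best <- pred
    if (any(!is.na(score))) {
      # candidates are pre-sorted closest-first, so which.min keeps ties near
      # the predicted (nominal) offset
      k <- which.min(score)
      best <- cand_abs[k, ]
    }
    off$dx[i] <- best[1]; off$dy[i] <- best[2]
    placed[i] <- TRUE
  }
  layout_from_offsets(off, spec$tile_size)
}

layout_from_offsets <- function(off, tile_size) {
  lay <- stitch_layout(off, c(max(off$dy) - min(off$dy) + tile_size,
                              max(off$dx) - min(off$dx) + tile_size))
  # mosaic raster origin in anchored coordinates (non-positive; the anchor
  # tile sits at (0,0) but a jittered neighbour may extend left/up of it)
  lay$origin <- c(min(off$dx), min(off$dy))
  lay
}

#' Global grid-search refinement of a stitch layout
#'
#' Coordinate descent: tiles are swept in raster order; for each tile every
#' integer offset within `search_radius` of its current position is scored
#' against the sum of normalised overlap costs with all adjacent tiles, and
#' strict improvements are accepted.  Sweeps repeat until no tile moves
#' (total cost is non-increasing by construction) or `max_sweeps` is hit, in
#' which case the best layout so far is returned with a warning.
#'
#' @param tiles list of binary tile masks in raster order.
#' @param init initial [stitch_layout()].
#' @param search_radius per-sweep search half-width in px.
#' @param max_sweeps sweep cap.
#' @param pair_cache precomputed pair cost tables (internal reuse).
#' @return a [stitch_layout()] with attribute `cost` (total overlap cost).
#' @export
global_refine <- function(tiles, init, search_radius = 15L, max_sweeps = 20L,
                          pair_cache = NULL) {
  off <- init$offsets
  n <- nrow(off)
  if (is.null(pair_cache)) pair_cache <- build_pair_cache(tiles, off)
  adj <- lapply(seq_len(n), function(i)
    which(abs(off$row - off$row[i]) + abs(off$col - off$col[i]) == 1L))
  cand <- expand.grid(ddx = -search_radius:search_radius,
                      ddy = -search_radius:search_radius)
  cand <- cand[order(abs(cand$ddx) + abs(cand$ddy), abs(cand$ddy),
                     cand$ddx, cand$ddy), ]
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      if (off$row[i] == 0L && off$col[i] == 0L) next   # anchor fixed
      cur <- c(off$dx[i], off$dy[i])
      cand_abs <- cbind(cur[1] + cand$ddx, cur[2] + cand$ddy)
      tot <- matrix(NA_real_, nrow(cand_abs), length(adj[[i]]))
      for (k2 in seq_along(adj[[i]])) {
        j <- adj[[i]][k2]
        tot[, k2] <- cached_pair_cost(pair_cache, off$tile[i], off$tile[j],
                                      cand_abs, c(off$dx[j], off$dy[j]),
                                      lambda = content_prior())
      }
      tot[is.na(tot)] <- 1                    # lost overlap = worst cost
      score <- rowSums(tot)
      cur_idx <- which(cand$ddx == 0L & cand$ddy == 0L)
      # accept strict improvements only; candidates are sorted closest-first
      k <- which.min(score)
      if (score[k] < score[cur_idx]) {
        off$dx[i] <- cand_abs[k, 1]; off$dy[i] <- cand_abs[k, 2]
        moved <- TRUE
      }
    }
    if (!moved) { converged <- TRUE; break }
  }
  if (!converged) warning("global_refine: sweep cap reached; returning best layout so far")
  # re-anchor at the top-left tile in case refinement was run on a shifted init
  a <- which(off$row == 0L & off$col == 0L)
  off$dx <- off$dx - off$dx[a]; off$dy <- off$dy - off$dy[a]
  out <- layout_from_offsets(off, nrow(tiles[[1]]))
  attr(out, "cost") <- layout_cost(tiles, out)
  out
}

#' Compose placed tiles into one mosaic raster
#'
#' @param tiles list of rasters in raster order.
#' @param layout a [stitch_layout()].
#' @param mode `"union"` (pixel max; the pipeline path for binary masks),
#'   `"difference"` (max - min over covering tiles, i.e. |a - b| where two
#'   tiles overlap; the QC visualisation), or `"mean"` (average, for
#'   grayscale mosaics).
#' @return mosaic raster of shape `layout$mosaic_shape`.
#' @export
compose_mosaic <- function(tiles, layout, mode = c("union", "difference", "mean")) {
  mode <- match.arg(mode)
  sh <- layout$mosaic_shape
  off <- layout$offsets
  org <- if (is.null(layout$origin)) c(0L, 0L) else layout$origin
  off$dx <- off$dx - org[1]; off$dy <- off$dy - org[2]
  if (mode == "mean") {
    acc <- matrix(0, sh[1], sh[2]); cnt <- matrix(0, sh[1], sh[2])
  } else {
    mx <- matrix(-Inf, sh[1], sh[2]); mn <- matrix(Inf, sh[1], sh[2])
  }
  for (i in seq_len(nrow(off))) {
    tl <- tiles[[off$tile[i]]]
    ys <- off$dy[i] + seq_len(nrow(tl)); xs <- off$dx[i] + seq_len(ncol(tl))
    if (mode == "mean") {
      acc[ys, xs] <- acc[ys, xs] + tl
      cnt[ys, xs] <- cnt[ys, xs] + 1
    } else {
      mx[ys, xs] <- pmax(mx[ys, xs], tl)
      mn[ys, xs] <- pmin(mn[ys, xs], tl)
    }
  }
  if (mode == "mean") {
    cnt[cnt == 0] <- 1
    return(acc / cnt)
  }
  mx[!is.finite(mx)] <- 0; mn[!is.finite(mn)] <- 0
  if (mode == "union") mx else mx - mn
}

#' Merge duplicate detections from tile overlap zones
#'
#' Beads in overlap strips are detected in two (or four) tiles; detections
#' closer than `radius` are single-linkage clustered and replaced by their
#' mean position.
#'
#' @param beads a [bead_set()] in mosaic coordinates.
#' @param radius merge distance in px (the rendered disc radius works well).
#' @return deduplicated [bead_set()] with fresh sequential ids.
#' @export
dedupe_beads <- function(beads, radius = 3) {
  if (nrow(beads) <= 1L) return(beads)
  cl <- cluster_points(bead_xy(beads), radius)
  x <- tapply(beads$x, cl, mean); y <- tapply(beads$y, cl, mean)
  b <- bead_set(as.numeric(x), as.numeric(y))
  b <- b[order(b$y, b$x), ]
  b$id <- seq_len(nrow(b))
  rownames(b) <- NULL
  b
}

#' Detect, stitch and merge one round's tiles
#'
#' Runs the chosen detector on every brightfield tile, renders per-tile disc
#' masks, recovers the stitch layout (pairwise then global refinement), and
#' returns the mosaic-frame bead set (overlap duplicates merged), the layout
#' and the mosaic mask.
#'
#' @param stack a `tile_stack`.
#' @param spec an [acquisition_spec()].
#' @param config a [segmenter_config()].
#' @param method `"oracle"` or `"cnn"`.
#' @param model trained `bead_segmenter` (required for `method = "cnn"`).
#' @param search_radius stitch search half-width (px).
#' @return list with `beads`, `layout`, `mask` (mosaic), `tile_beads`.
#' @export
stitch_round <- function(stack, spec, config = segmenter_config(),
                         method = c("oracle", "cnn"), model = NULL,
                         search_radius = 15L) {
  method <- match.arg(method)
  if (method == "cnn" && is.null(model)) stop("method='cnn' needs a trained model")
  tile_beads <- lapply(stack$images, function(chans)
    detect_beads_tile(chans[["brightfield"]], method, config, model))
  ts <- stack$tile_size
  masks <- lapply(tile_beads, function(b)
    paint_discs(c(ts, ts), bead_xy(b), config$circle_radius, warn_clip = FALSE))
  cache <- build_pair_cache(masks, nominal_layout(spec)$offsets)
  lay0 <- init_layout(masks, spec, search_radius, pair_cache = cache)
  lay <- global_refine(masks, lay0, search_radius, pair_cache = cache)
  pts <- do.call(rbind, lapply(seq_along(tile_beads), function(k) {
    if (nrow(tile_beads[[k]]) == 0L) return(NULL)
    global_coords(k, bead_xy(tile_beads[[k]]), lay)
  }))
  beads <- if (is.null(pts)) bead_set() else
    dedupe_beads(bead_set(pts[, 1], pts[, 2]), config$circle_radius)
  org <- if (is.null(lay$origin)) c(0L, 0L) else lay$origin
  mask <- paint_discs(lay$mosaic_shape,
                      cbind(beads$x - org[1], beads$y - org[2]),
                      config$circle_radius, warn_clip = FALSE)
  attr(mask, "origin") <- org
  list(beads = beads, layout = lay, mask = mask, tile_beads = tile_beads)
}
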