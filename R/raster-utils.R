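# Low-level raster helpers shared by the simulator, the segmenters and the
# registration stages.  All matrices are indexed [row, col] = [y + 1, x + 1];
# user-facing coordinates are 0-based, pixel-centre, x = column (rightward),
# y = row (downward).

#' Shift a matrix by whole pixels, filling vacated cells with zero
#'
#' @param m numeric matrix.
#' @param dy,dx integer shift in rows / columns (positive moves content
#'   down / right).
#' @return matrix of the same shape.
#' @keywords internal
mat_shift <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  if (length(ys) < 1L || length(xs) < 1L) return(out)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

#' 1D Gaussian kernel truncated at ~3 sigma
#' @keywords internal
gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Separable Gaussian blur
#'
#' Border handling: the kernel is renormalised over the in-image support
#' (`normalize = TRUE`), so values near the border are not attenuated and
#' weighted centroids of border spots are not biased inward.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels.
#' @param normalize renormalise at the borders.
#' @keywords internal
gaussian_blur <- function(m, sigma, normalize = TRUE) {
  k <- gaussian_kernel1d(sigma)
  r <- (length(k) - 1L) / 2L
  pass <- function(mm, vertical) {
    out <- matrix(0, nrow(mm), ncol(mm))
    for (i in seq_along(k)) {
      out <- out + k[i] * (if (vertical) mat_shift(mm, i - r - 1L, 0L)
                           else mat_shift(mm, 0L, i - r - 1L))
    }
    out
  }
  out <- pass(pass(m, FALSE), TRUE)
  if (normalize) {
    ones <- matrix(1, nrow(m), ncol(m))
    w <- pass(pass(ones, FALSE), TRUE)
    out <- out / w
  }
  out
}

#' Strict local maxima of a 2D raster over the 8-neighbourhood
#'
#' A pixel is a maximum if it is >= all eight neighbours and exceeds
#' `min_value`.  Plateau duplicates closer than `merge_dist` are merged to
#' their mean position.
#'
#' @return data.frame with 0-based columns x, y and the raster value.
#' @keywords internal
local_maxima <- function(m, min_value = -Inf, merge_dist = 2) {
  nb <- matrix(-Inf, nrow(m), ncol(m))
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    nb <- pmax(nb, mat_shift(m, dy, dx))
  }
  hit <- which(m >= nb & m > min_value, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), value = numeric(0)))
  }
  pts <- data.frame(x = hit[, 2] - 1, y = hit[, 1] - 1, value = m[hit])
  if (nrow(pts) > 1L) {
    cl <- cluster_points(as.matrix(pts[, c("x", "y")]), merge_dist)
    pts <- do.call(rbind, lapply(split(pts, cl), function(d) {
      data.frame(x = mean(d$x), y = mean(d$y), value = max(d$value))
    }))
    pts <- pts[order(pts$y, pts$x), , drop = FALSE]
    rownames(pts) <- NULL
  }
  pts
}

#' Single-linkage clustering of points at a distance cutoff
#'
#' Used to merge duplicate detections (overlap zones, plateau maxima).
#' Returns an integer cluster id per point; deterministic.
#' @keywords internal
cluster_points <- function(xy, cutoff) {
  n <- nrow(xy)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  d <- as.matrix(stats::dist(xy))
  adj <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(adj) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in raster-scan order of their first pixel.
#' @keywords internal
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask > 0)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  idx <- integer(h * w)            # linear index -> position in fg
  idx[fg] <- seq_along(fg)
  row <- (fg - 1L) %% h + 1L
  col <- (fg - 1L) %/% h + 1L
  edges <- list()
  # link each foreground pixel to its E, S, SE, SW neighbours
  for (k in seq_len(4L)) {
    dy <- c(0L, 1L, 1L,  1L)[k]
    dx <- c(1L, 0L, 1L, -1L)[k]
    r2 <- row + dy; c2 <- col + dx
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    nb <- (c2[ok] - 1L) * h + r2[ok]
    hitn <- idx[nb] > 0L
    if (any(hitn)) {
      edges[[length(edges) + 1L]] <-
        cbind(idx[fg[ok]][hitn], idx[nb][hitn])
    }
  }
  if (length(edges) == 0L) {
    memb <- seq_along(fg)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    memb <- as.integer(igraph::components(g)$membership)
  }
  # renumber components in raster-scan order of first occurrence
  first <- !duplicated(memb)
  renum <- integer(max(memb))
  renum[memb[first]] <- seq_len(sum(first))
  lab[fg] <- renum[memb]
  lab
}

#' Integer pixel offsets of a filled disc
#' @keywords internal
disc_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
}

#' Paint filled discs of a given radius into a binary raster
#'
#' Centres are rounded to the nearest pixel; discs falling partly outside are
#' clipped (with a warning when `warn_clip`).
#' @keywords internal
paint_discs <- function(shape, xy, radius, warn_clip = TRUE) {
  m <- matrix(0L, shape[1], shape[2])
  if (NROW(xy) == 0L) return(m)
  off <- disc_offsets(radius)
  clipped <- FALSE
  for (i in seq_len(NROW(xy))) {
    cx <- round(xy[i, 1]); cy <- round(xy[i, 2])
    px <- cx + off$dx; py <- cy + off$dy
    ok <- px >= 0 & px < shape[2] & py >= 0 & py < shape[1]
    if (!all(ok)) clipped <- TRUE
    m[cbind(py[ok] + 1L, px[ok] + 1L)] <- 1L
  }
  if (clipped && warn_clip) warning("some discs were clipped at the raster border")
  m
}

#' Mean value in a disc around a point, minus the annulus median background
#'
#' @param m numeric raster.
#' @param x,y 0-based centre.
#' @param radius disc radius (px).
#' @param annulus inner/outer radii of the background annulus.
#' @return background-subtracted disc mean, or NA if the disc leaves the raster.
#' @keywords internal
disc_mean <- function(m, x, y, radius, annulus = c(radius + 2, radius + 5)) {
  cx <- round(x); cy <- round(y)
  r_out <- ceiling(annulus[2])
  if (cx - r_out < 0 || cy - r_out < 0 ||
      cx + r_out >= ncol(m) || cy + r_out >= nrow(m)) {
    # fall back to the disc alone if only the annulus is clipped
    r_in <- floor(radius)
    if (cx - r_in < 0 || cy - r_in < 0 ||
        cx + r_in >= ncol(m) || cy + r_in >= nrow(m)) return(NA_real_)
    off <- disc_offsets(radius)
    return(mean(m[cbind(cy + off$dy + 1L, cx + off$dx + 1L)]))
  }
  g <- expand.grid(dx = -r_out:r_out, dy = -r_out:r_out)
  d2 <- g$dx^2 + g$dy^2
  vals <- m[cbind(cy + g$dy + 1L, cx + g$dx + 1L)]
  fgv <- vals[d2 <= radius^2]
  bgv <- vals[d2 >= annulus[1]^2 & d2 <= annulus[2]^2]
  mean(fgv) - stats::median(bgv)
}
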