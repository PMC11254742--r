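# Domain types and coordinate conventions.
#
# Conventions used throughout the package:
#   * pixel coordinates are 0-based, pixel-centre, x = column (rightward),
#     y = row (downward); matrix element [r, c] is the pixel (x = c-1, y = r-1)
#   * intensities are normalised to [0, 1] at load time
#   * fluorescence 4-vectors are always ordered (475, 555, 575, 635) nm

PUCK_CHANNELS <- c("brightfield", "475", "555", "575", "635")
FLUOR_CHANNELS <- PUCK_CHANNELS[-1]
DNA_BASES <- c("A", "C", "G", "T")

#' Acquisition geometry of a puck imaging run
#'
#' Describes one sequencing experiment: how many hybridisation/imaging rounds
#' were run, how the microscope tiles the puck, and which channels are
#' recorded.  The study design this mirrors images a ~3 mm puck as a 3x3 grid
#' of 1024x1024 px tiles with 10% nominal overlap, in brightfield plus four
#' fluorescence wavelengths, for 14 rounds.
#'
#' @param n_sequences number of sequencing rounds (>= 1).
#' @param n_tiles_x,n_tiles_y tile grid dimensions.
#' @param tile_size tile edge length in pixels.
#' @param overlap_frac nominal tile overlap as a fraction of `tile_size`,
#'   in (0, 0.5).
#' @param channels channel labels; exactly five, brightfield first.
#' @return an object of class `acquisition_spec`.
#' @export
acquisition_spec <- function(n_sequences = 14L, n_tiles_x = 3L, n_tiles_y = 3L,
                             tile_size = 1024L, overlap_frac = 0.10,
                             channels = PUCK_CHANNELS) {
  stopifnot(n_sequences >= 1L, n_tiles_x >= 1L, n_tiles_y >= 1L,
            tile_size >= 8L, overlap_frac > 0, overlap_frac < 0.5)
  if (length(channels) != 5L || channels[1] != "brightfield")
    stop("exactly 5 channels required, with 'brightfield' first")
  structure(list(n_sequences = as.integer(n_sequences),
                 n_tiles_x = as.integer(n_tiles_x),
                 n_tiles_y = as.integer(n_tiles_y),
                 tile_size = as.integer(tile_size),
                 overlap_frac = overlap_frac,
                 channels = channels),
            class = "acquisition_spec")
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat(sprintf("Acquisition: %d rounds, %dx%d tiles of %d px (%.0f%% overlap), channels: %s\n",
              x$n_sequences, x$n_tiles_y, x$n_tiles_x, x$tile_size,
              100 * x$overlap_frac, paste(x$channels, collapse = ", ")))
  invisible(x)
}

n_tiles <- function(spec) spec$n_tiles_x * spec$n_tiles_y

#' Stitch layout: per-tile integer offsets in the mosaic frame
#'
#' Tile 1 (top-left) is the anchor at offset (0, 0).  Tiles are numbered in
#' raster order (row-major, left to right).
#'
#' @param offsets data.frame with columns tile, row, col, dx, dy (integer px).
#' @param mosaic_shape c(height, width) of the implied mosaic.
#' @return an object of class `stitch_layout`.
#' @export
stitch_layout <- function(offsets, mosaic_shape) {
  stopifnot(all(c("tile", "row", "col", "dx", "dy") %in% names(offsets)))
  a <- offsets[offsets$tile == min(offsets$tile), ]
  if (a$dx != 0L || a$dy != 0L) stop("anchor tile must sit at offset (0, 0)")
  structure(list(offsets = offsets,
                 mosaic_shape = as.integer(mosaic_shape)),
            class = "stitch_layout")
}

#' @export
print.stitch_layout <- function(x, ...) {
  cat(sprintf("Stitch layout: %d tiles, mosaic %d x %d px\n",
              nrow(x$offsets), x$mosaic_shape[1], x$mosaic_shape[2]))
  print(x$offsets, row.names = FALSE)
  invisible(x)
}

#' Nominal tile layout implied by an acquisition spec
#'
#' Tiles step by `tile_size - round(overlap_frac * tile_size)` pixels in each
#' direction.
#' @param spec an [acquisition_spec()].
#' @return a [stitch_layout()].
#' @export
nominal_layout <- function(spec) {
  step <- spec$tile_size - as.integer(round(spec$overlap_frac * spec$tile_size))
  g <- expand.grid(col = seq_len(spec$n_tiles_x) - 1L,
                   row = seq_len(spec$n_tiles_y) - 1L)
  g <- g[order(g$row, g$col), ]
  offsets <- data.frame(tile = seq_len(nrow(g)), row = g$row, col = g$col,
                        dx = g$col * step, dy = g$row * step)
  mosaic_shape <- c((spec$n_tiles_y - 1L) * step + spec$tile_size,
                    (spec$n_tiles_x - 1L) * step + spec$tile_size)
  stitch_layout(offsets, mosaic_shape)
}

layout_offset <- function(layout, tile_index) {
  i <- match(tile_index, layout$offsets$tile)
  if (is.na(i)) stop(sprintf("unknown tile index: %s", tile_index))
  c(dx = layout$offsets$dx[i], dy = layout$offsets$dy[i])
}

#' Convert tile-local pixel coordinates to mosaic coordinates
#'
#' @param tile_index tile number as in the layout.
#' @param local_xy length-2 vector or 2-column matrix of (x, y), 0-based.
#' @param layout a [stitch_layout()].
#' @return coordinates offset into the mosaic frame, same shape as input.
#' @export
global_coords <- function(tile_index, local_xy, layout) {
  off <- layout_offset(layout, tile_index)
  if (is.matrix(local_xy) || is.data.frame(local_xy)) {
    out <- as.matrix(local_xy)
    out[, 1] <- out[, 1] + off[["dx"]]
    out[, 2] <- out[, 2] + off[["dy"]]
    out
  } else {
    c(local_xy[1] + off[["dx"]], local_xy[2] + off[["dy"]])
  }
}

#' Inverse of [global_coords()]
#' @inheritParams global_coords
#' @param global_xy coordinates in the mosaic frame.
#' @export
local_coords <- function(tile_index, global_xy, layout) {
  off <- layout_offset(layout, tile_index)
  if (is.matrix(global_xy) || is.data.frame(global_xy)) {
    out <- as.matrix(global_xy)
    out[, 1] <- out[, 1] - off[["dx"]]
    out[, 2] <- out[, 2] - off[["dy"]]
    out
  } else {
    c(global_xy[1] - off[["dx"]], global_xy[2] - off[["dy"]])
  }
}

#' A set of bead detections
#'
#' @param x,y sub-pixel bead centre coordinates (mosaic or tile frame).
#' @param id unique bead identifiers (default 1..n).
#' @param intensity optional n x 4 matrix of fluorescence gray values, channel
#'   order (475, 555, 575, 635) nm.
#' @return data.frame of class `bead_set` with columns id, x, y (and
#'   intensity columns i475..i635 when given).
#' @export
bead_set <- function(x = numeric(0), y = numeric(0), id = NULL, intensity = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(id)) id <- seq_along(x)
  if (anyDuplicated(id)) stop("bead ids must be unique")
  if (length(x) && any(!is.finite(x) | !is.finite(y)))
    stop("bead positions must be finite")
  d <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y))
  if (!is.null(intensity)) {
    intensity <- as.matrix(intensity)
    stopifnot(nrow(intensity) == length(x), ncol(intensity) == 4L)
    if (any(intensity < 0, na.rm = TRUE)) stop("intensities must be non-negative")
    colnames(intensity) <- paste0("i", FLUOR_CHANNELS)
    d <- cbind(d, intensity)
  }
  class(d) <- c("bead_set", "data.frame")
  d
}

#' @export
print.bead_set <- function(x, ...) {
  cat(sprintf("BeadSet: %d beads\n", nrow(x)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat(sprintf("... and %d more\n", nrow(x) - 6))
  invisible(x)
}

bead_xy <- function(beads) cbind(x = beads$x, y = beads$y)

# ---- rigid transforms -------------------------------------------------------

#' A 2D rigid transform (rotation about a pivot, then translation)
#'
#' Maps a point p to `R(theta) (p - center) + center + t`.
#'
#' @param theta rotation angle in radians (positive = from +x towards +y,
#'   i.e. clockwise on screen with y downward).
#' @param tx,ty translation in pixels.
#' @param center rotation pivot `c(x, y)` in pixels.
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0, center = c(0, 0)) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty), all(is.finite(center)))
  structure(list(theta = unname(theta), tx = unname(tx), ty = unname(ty),
                 center = unname(as.numeric(center))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("RigidTransform: theta = %.4f deg, t = (%.2f, %.2f), pivot = (%.1f, %.1f)\n",
              x$theta * 180 / pi, x$tx, x$ty, x$center[1], x$center[2]))
  invisible(x)
}

transform_points <- function(xy, t) {
  xy <- as.matrix(xy)
  if (nrow(xy) == 0L) return(xy)
  co <- cos(t$theta); si <- sin(t$theta)
  xc <- xy[, 1] - t$center[1]
  yc <- xy[, 2] - t$center[2]
  cbind(x = co * xc - si * yc + t$center[1] + t$tx,
        y = si * xc + co * yc + t$center[2] + t$ty)
}

#' Invert a rigid transform
#' @param t a [rigid_transform()].
#' @export
invert_rigid <- function(t) {
  co <- cos(-t$theta); si <- sin(-t$theta)
  # inverse: p = R^-1 (q - center - t) + center
  # expressed with the same pivot: R^-1(q - c) + c + t', where
  # t' = R^-1 * (-t) rotated appropriately
  tpx <- -(co * t$tx - si * t$ty)
  tpy <- -(si * t$tx + co * t$ty)
  rigid_transform(-t$theta, tpx, tpy, t$center)
}

#' Express a rigid transform as (theta, tx, ty) about a given pivot
#'
#' Two transforms with different pivots can be compared by converting both to
#' a common pivot; the rotation angle is pivot-independent.
#' @param t a [rigid_transform()].
#' @param center pivot `c(x, y)`.
#' @export
rigid_params <- function(t, center = c(0, 0)) {
  p <- transform_points(rbind(center), t)
  c(theta = t$theta, tx = p[1, 1] - center[1], ty = p[1, 2] - center[2])
}

#' Apply a rigid transform to points or to a binary mask
#'
#' Points are transformed exactly (real-valued).  Masks are resampled by
#' inverse nearest-neighbour mapping, so the mask path agrees with the point
#' path to within one pixel.
#'
#' @param x either a 2-column matrix / `bead_set` of points, or a numeric
#'   matrix raster when `type = "mask"`.
#' @param t a [rigid_transform()].
#' @param type `"points"` or `"mask"`; by default points when `x` has two
#'   columns or is a `bead_set`.
#' @export
apply_rigid <- function(x, t, type = NULL) {
  if (is.null(type)) {
    type <- if (inherits(x, "bead_set") || (NCOL(x) == 2L && !inherits(x, "matrix_mask")))
      "points" else "mask"
  }
  if (type == "points") {
    if (inherits(x, "bead_set")) {
      p <- transform_points(bead_xy(x), t)
      x$x <- p[, 1]; x$y <- p[, 2]
      return(x)
    }
    return(transform_points(x, t))
  }
  # mask: inverse nearest-neighbour resampling
  h <- nrow(x); w <- ncol(x)
  inv <- invert_rigid(t)
  g <- expand.grid(x = 0:(w - 1L), y = 0:(h - 1L))
  src <- transform_points(as.matrix(g), inv)
  sx <- round(src[, 1]); sy <- round(src[, 2])
  ok <- sx >= 0 & sx < w & sy >= 0 & sy < h
  out <- matrix(0, h, w)
  out[cbind(g$y + 1L, g$x + 1L)[ok, , drop = FALSE]] <-
    x[cbind(sy + 1L, sx + 1L)[ok, , drop = FALSE]]
  out
}

# ---- barcode table ----------------------------------------------------------

#' Assemble and validate a per-bead barcode table
#'
#' One row per reference bead: position, per-round called base (N where the
#' bead was not matched in that round), the assembled barcode string, and the
#' fraction of rounds matched.
#'
#' @param bead_id,x,y reference bead identity and mosaic position.
#' @param bases character matrix [beads x rounds] over A, C, G, T, N.
#' @return data.frame of class `barcode_table` with per-round `base_r*`
#'   columns.
#' @export
barcode_table <- function(bead_id, x, y, bases) {
  bases <- as.matrix(bases)
  stopifnot(length(bead_id) == nrow(bases), length(x) == nrow(bases))
  if (!all(bases %in% c(DNA_BASES, "N"))) stop("bases must be in {A,C,G,T,N}")
  barcode <- apply(bases, 1, paste0, collapse = "")
  completeness <- rowMeans(bases != "N")
  colnames(bases) <- paste0("base_r", seq_len(ncol(bases)))
  d <- data.frame(bead_id = bead_id, x = x, y = y, barcode = barcode,
                  completeness = completeness)
  d <- cbind(d, as.data.frame(bases, stringsAsFactors = FALSE))
  class(d) <- c("barcode_table", "data.frame")
  d
}

#' @export
print.barcode_table <- function(x, ...) {
  cat(sprintf("BarcodeTable: %d beads, %d rounds, mean completeness %.3f\n",
              nrow(x), sum(startsWith(names(x), "base_r")),
              if (nrow(x)) mean(x$completeness) else NA_real_))
  if (nrow(x)) print(utils::head(as.data.frame(x)[, 1:5], 6), row.names = FALSE)
  invisible(x)
}

#' Write / read a barcode table as TSV
#'
#' @param tab a [barcode_table()].
#' @param path file path.
#' @export
write_barcode_table <- function(tab, path) {
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "bead_id"
  df[num] <- lapply(df[num], function(v) formatC(v, format = "f", digits = 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_table
#' @export
read_barcode_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(d) <- c("barcode_table", "data.frame")
  d
}

# deterministic sub-seed derivation: one user seed fans out into named streams
sub_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 104729L)
}
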