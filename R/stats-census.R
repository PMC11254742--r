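# Patch-wise bead-count change census across sequencing rounds.
#
# The registered bead sets of every round are counted over a grid of small
# square patches (50 x 50 px); a bead counts for a patch only if its whole
# rendered disc lies inside the patch.  A patch "changes" in round r when
# its count differs from the reference round.  This quantifies how often
# liquid handling removes (or adds) beads, and where.

#' Patch-wise bead-count change census
#'
#' @param per_round_beads list of [bead_set()]s, one per round, all in the
#'   reference mosaic frame (registered).
#' @param patch_size patch edge in px.
#' @param circle_radius rendered disc radius; a bead is counted only when
#'   the whole disc of this radius around its (rounded) centre lies inside
#'   the patch.
#' @param mosaic_shape c(height, width) of the reference mosaic.
#' @param reference_round round counts are compared against (default 1).
#' @return object of class `change_census`: list with `counts` (matrix
#'   patches x rounds), `patch_grid` (data.frame patch, px, py),
#'   `changed_per_round` (integer per round; 0 for the reference round) and
#'   `n_patches`.
#' @export
patch_census <- function(per_round_beads, patch_size = 50L, circle_radius = 3L,
                         mosaic_shape, reference_round = 1L) {
  R <- length(per_round_beads)
  npx <- ceiling(mosaic_shape[2] / patch_size)
  npy <- ceiling(mosaic_shape[1] / patch_size)
  grid <- expand.grid(px = 0:(npx - 1L), py = 0:(npy - 1L))
  n_patches <- nrow(grid)
  counts <- matrix(0L, n_patches, R)
  for (r in seq_len(R)) {
    b <- per_round_beads[[r]]
    if (nrow(b) == 0L) next
    cx <- round(b$x); cy <- round(b$y)
    # whole disc inside the patch: every disc pixel shares the patch index
    pix <- floor((cx - circle_radius) / patch_size)
    same_x <- pix == floor((cx + circle_radius) / patch_size)
    piy <- floor((cy - circle_radius) / patch_size)
    same_y <- piy == floor((cy + circle_radius) / patch_size)
    ok <- same_x & same_y & pix >= 0 & piy >= 0 & pix < npx & piy < npy
    if (!any(ok)) next
    idx <- piy[ok] * npx + pix[ok] + 1L
    tab <- tabulate(idx, nbins = n_patches)
    counts[, r] <- tab
  }
  changed <- vapply(seq_len(R), function(r)
    sum(counts[, r] != counts[, reference_round]), integer(1))
  structure(list(counts = counts,
                 patch_grid = data.frame(patch = seq_len(n_patches),
                                         px = grid$px, py = grid$py),
                 changed_per_round = changed, n_patches = n_patches,
                 reference_round = reference_round),
            class = "change_census")
}

#' @export
print.change_census <- function(x, ...) {
  cat(sprintf("ChangeCensus: %d patches, %d rounds\n", x$n_patches,
              length(x$changed_per_round)))
  cat("changed patches per round:",
      paste(x$changed_per_round, collapse = " "), "\n")
  invisible(x)
}

#' Bar chart of changed-patch frequency per round
#'
#' @param x a `change_census`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.change_census <- function(x, ...) {
  graphics::barplot(x$changed_per_round,
                    names.arg = seq_along(x$changed_per_round),
                    xlab = "sequence round",
                    ylab = "patches with changed bead count", ...)
  invisible(x)
}

#' Write a census as CSV (one row per patch, one count column per round)
#' @param census a `change_census`.
#' @param path output file.
#' @export
write_census <- function(census, path) {
  d <- cbind(census$patch_grid,
             as.data.frame(census$counts,
                           col.names = paste0("count_r", seq_len(ncol(census$counts)))))
  names(d)[-(1:3)] <- paste0("count_r", seq_len(ncol(census$counts)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
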