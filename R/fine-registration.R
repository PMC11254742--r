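# Patch-wise fine registration and cross-round bead linking.
#
# After coarse rigid registration the two rounds agree globally, but smooth
# optical distortion leaves a few pixels of position-dependent misalignment.
# The mosaic is cut into patches; each patch of moving-round detections gets
# its own integer shift minimising the (threshold-truncated) sum of
# nearest-point distances; detections are then matched one-to-one under the
# strict congruence rule: two points are the same bead iff their post-shift
# distance is < 4 px.

#' Fine registration configuration
#'
#' @param patch_size patch edge length (px) in the mosaic frame.
#' @param congruence_threshold congruence distance in px; matches require
#'   strictly smaller distance.
#' @param max_patch_shift largest per-patch shift searched (px).
#' @return object of class `fine_reg_config`.
#' @export
fine_reg_config <- function(patch_size = 128L, congruence_threshold = 4,
                            max_patch_shift = 10L) {
  stopifnot(congruence_threshold > 0, patch_size > 2 * max_patch_shift,
            max_patch_shift >= 0)
  structure(list(patch_size = as.integer(patch_size),
                 congruence_threshold = congruence_threshold,
                 max_patch_shift = as.integer(max_patch_shift)),
            class = "fine_reg_config")
}

#' Assign beads to disjoint patches of the mosaic
#'
#' Half-open convention: a bead at exactly `patch_size` on an axis belongs to
#' the next patch.
#'
#' @param beads a [bead_set()] in mosaic coordinates.
#' @param patch_size patch edge (px).
#' @return data.frame (id, px, py) with the 0-based patch indices per bead.
#' @export
partition_beads <- function(beads, patch_size) {
  data.frame(id = beads$id,
             px = floor(beads$x / patch_size),
             py = floor(beads$y / patch_size))
}

#' Best integer shift aligning a moving point set onto a reference set
#'
#' Scores every integer shift within `max_patch_shift`: the objective is the
#' sum over reference points of the distance to the nearest shifted moving
#' point, truncated at the congruence threshold (an unmatched point
#' contributes the threshold).  Ties resolve to the smallest shift.  Either
#' set empty returns (0, 0).
#'
#' @param ref_pts,mov_pts 2-column matrices of (x, y).
#' @param config a [fine_reg_config()].
#' @return list with `shift` c(dx, dy) and `objective`.
#' @export
optimal_patch_shift <- function(ref_pts, mov_pts, config = fine_reg_config()) {
  if (NROW(ref_pts) == 0L || NROW(mov_pts) == 0L)
    return(list(shift = c(0, 0), objective = NROW(ref_pts) * config$congruence_threshold))
  ref_pts <- as.matrix(ref_pts); mov_pts <- as.matrix(mov_pts)
  thr <- config$congruence_threshold
  r <- config$max_patch_shift
  dx0 <- outer(ref_pts[, 1], mov_pts[, 1], "-")
  dy0 <- outer(ref_pts[, 2], mov_pts[, 2], "-")
  cand <- expand.grid(sx = -r:r, sy = -r:r)
  cand <- cand[order(cand$sx^2 + cand$sy^2, abs(cand$sx), abs(cand$sy),
                     cand$sx, cand$sy), ]
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    d2 <- (dx0 - cand$sx[i])^2 + (dy0 - cand$sy[i])^2
    nearest <- sqrt(apply(d2, 1, min))
    obj <- sum(pmin(nearest, thr))
    if (is.null(best) || obj < best$objective)
      best <- list(shift = c(cand$sx[i], cand$sy[i]), objective = obj)
  }
  best
}

#' One-to-one point matching under the congruence rule
#'
#' Candidate pairs are those at distance strictly below `threshold`; they are
#' accepted greedily in order of ascending distance, each point used at most
#' once.
#'
#' @param ref_pts,mov_pts 2-column matrices (shift already applied to
#'   `mov_pts`).
#' @param threshold congruence distance (px, strict).
#' @return list with `pairs` (data.frame ref, mov, dist; indices into the
#'   inputs) and `unmatched_ref`, `unmatched_mov` index vectors.
#' @export
match_points <- function(ref_pts, mov_pts, threshold = 4) {
  nr <- NROW(ref_pts); nm <- NROW(mov_pts)
  empty <- data.frame(ref = integer(0), mov = integer(0), dist = numeric(0))
  if (nr == 0L || nm == 0L)
    return(list(pairs = empty, unmatched_ref = seq_len(nr),
                unmatched_mov = seq_len(nm)))
  ref_pts <- as.matrix(ref_pts); mov_pts <- as.matrix(mov_pts)
  d <- sqrt(outer(ref_pts[, 1], mov_pts[, 1], "-")^2 +
            outer(ref_pts[, 2], mov_pts[, 2], "-")^2)
  cand <- which(d < threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(list(pairs = empty, unmatched_ref = seq_len(nr),
                unmatched_mov = seq_len(nm)))
  dist <- d[cand]
  ord <- order(dist, cand[, 1], cand[, 2])
  used_r <- logical(nr); used_m <- logical(nm)
  out <- list()
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (used_r[i] || used_m[j]) next
    used_r[i] <- TRUE; used_m[j] <- TRUE
    out[[length(out) + 1L]] <- c(i, j, dist[k])
  }
  pairs <- as.data.frame(do.call(rbind, out))
  names(pairs) <- c("ref", "mov", "dist")
  pairs$ref <- as.integer(pairs$ref); pairs$mov <- as.integer(pairs$mov)
  list(pairs = pairs, unmatched_ref = which(!used_r),
       unmatched_mov = which(!used_m))
}

# candidate (ref, mov, dist) pairs for one round, using per-patch shifts.
# mov candidates for a patch come from the patch box expanded by the shift
# search radius plus the congruence threshold, so border beads are kept.
round_candidate_pairs <- function(ref_beads, mov_xy, config) {
  ps <- config$patch_size
  thr <- config$congruence_threshold
  pad <- config$max_patch_shift + thr
  part <- partition_beads(ref_beads, ps)
  keys <- unique(part[, c("px", "py")])
  out <- list()
  shifts <- list()
  for (k in seq_len(nrow(keys))) {
    sel_r <- which(part$px == keys$px[k] & part$py == keys$py[k])
    x0 <- keys$px[k] * ps; y0 <- keys$py[k] * ps
    sel_m <- which(mov_xy[, 1] >= x0 - pad & mov_xy[, 1] < x0 + ps + pad &
                   mov_xy[, 2] >= y0 - pad & mov_xy[, 2] < y0 + ps + pad)
    rp <- bead_xy(ref_beads)[sel_r, , drop = FALSE]
    mp <- mov_xy[sel_m, , drop = FALSE]
    sh <- optimal_patch_shift(rp, mp, config)$shift
    shifts[[k]] <- c(keys$px[k], keys$py[k], sh)
    if (length(sel_m) == 0L) next
    mps <- cbind(mp[, 1] + sh[1], mp[, 2] + sh[2])
    d <- sqrt(outer(rp[, 1], mps[, 1], "-")^2 + outer(rp[, 2], mps[, 2], "-")^2)
    hit <- which(d < thr, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    out[[length(out) + 1L]] <- data.frame(ref = sel_r[hit[, 1]],
                                          mov = sel_m[hit[, 2]],
                                          dist = d[hit])
  }
  pairs <- if (length(out)) do.call(rbind, out) else
    data.frame(ref = integer(0), mov = integer(0), dist = numeric(0))
  shifts <- as.data.frame(do.call(rbind, shifts))
  if (nrow(shifts)) names(shifts) <- c("px", "py", "sx", "sy")
  list(pairs = pairs, shifts = shifts)
}

# resolve candidate pairs to a one-to-one matching (greedy by distance);
# a ref bead may collect candidates from its own patch only, but a mov bead
# can appear in several patches' candidate lists — the global pass keeps the
# closest assignment and guarantees one-to-one.
resolve_pairs <- function(pairs, n_ref) {
  match_r <- rep(NA_integer_, n_ref)
  if (nrow(pairs) == 0L) return(match_r)
  ord <- order(pairs$dist, pairs$ref, pairs$mov)
  used_m <- integer(0)
  for (k in ord) {
    i <- pairs$ref[k]; j <- pairs$mov[k]
    if (!is.na(match_r[i]) || j %in% used_m) next
    match_r[i] <- j
    used_m <- c(used_m, j)
  }
  match_r
}

#' Link reference-round beads across all sequencing rounds
#'
#' For each round: map the round's detections into the reference frame with
#' its coarse transform, compute per-patch shifts, collect congruent
#' candidate pairs, and resolve them to a one-to-one matching.  Beads missing
#' in a round (washed out or undetected) are recorded as missing, never
#' imputed.
#'
#' @param ref_beads reference-round [bead_set()] (mosaic frame).
#' @param per_round_beads list of [bead_set()]s, one per round, in their own
#'   mosaic frames; entry for the reference round may be the reference set
#'   itself.
#' @param transforms list of [rigid_transform()]s mapping each round's frame
#'   to the reference frame (identity for the reference round).
#' @param config a [fine_reg_config()].
#' @param reference_round index of the reference round (default 1).
#' @return object of class `track_table`: data.frame with bead_id, x, y and
#'   per-round `match_r*` columns holding the matched bead id in that round's
#'   bead set (NA = missing).  Attribute `shifts` stores per-round patch
#'   shifts.
#' @export
link_across_sequences <- function(ref_beads, per_round_beads, transforms,
                                  config = fine_reg_config(),
                                  reference_round = 1L) {
  R <- length(per_round_beads)
  n <- nrow(ref_beads)
  tab <- data.frame(bead_id = ref_beads$id, x = ref_beads$x, y = ref_beads$y)
  all_shifts <- vector("list", R)
  for (r in seq_len(R)) {
    col <- paste0("match_r", r)
    if (r == reference_round) {
      tab[[col]] <- ref_beads$id
      next
    }
    mov <- per_round_beads[[r]]
    if (nrow(mov) == 0L) { tab[[col]] <- NA_integer_; next }
    mov_xy <- transform_points(bead_xy(mov), transforms[[r]])
    cp <- round_candidate_pairs(ref_beads, mov_xy, config)
    all_shifts[[r]] <- cp$shifts
    m <- resolve_pairs(cp$pairs, n)
    tab[[col]] <- mov$id[m]
  }
  class(tab) <- c("track_table", "data.frame")
  attr(tab, "shifts") <- all_shifts
  attr(tab, "reference_round") <- reference_round
  tab
}

#' @export
print.track_table <- function(x, ...) {
  mc <- grep("^match_r", names(x))
  full <- if (nrow(x)) mean(rowSums(!is.na(as.data.frame(x)[mc])) == length(mc)) else NA
  cat(sprintf("TrackTable: %d reference beads, %d rounds, %.1f%% tracked in all rounds\n",
              nrow(x), length(mc), 100 * full))
  invisible(x)
}

#' Brute-force optimal one-to-one matching cardinality (testing oracle)
#'
#' Maximum-cardinality matching between two small point sets under a strict
#' distance threshold, found by exhaustive recursion.  Exponential; intended
#' for point sets of up to ~8 points in tests.
#'
#' @inheritParams match_points
#' @return the maximum number of simultaneously matchable pairs.
#' @export
optimal_match_cardinality <- function(ref_pts, mov_pts, threshold = 4) {
  nr <- NROW(ref_pts); nm <- NROW(mov_pts)
  if (nr == 0L || nm == 0L) return(0L)
  ref_pts <- as.matrix(ref_pts); mov_pts <- as.matrix(mov_pts)
  d <- sqrt(outer(ref_pts[, 1], mov_pts[, 1], "-")^2 +
            outer(ref_pts[, 2], mov_pts[, 2], "-")^2)
  ok <- d < threshold
  recurse <- function(i, used) {
    if (i > nr) return(0L)
    best <- recurse(i + 1L, used)           # leave ref i unmatched
    for (j in which(ok[i, ])) {
      if (used[j]) next
      used[j] <- TRUE
      best <- max(best, 1L + recurse(i + 1L, used))
      used[j] <- FALSE
    }
    best
  }
  recurse(1L, logical(nm))
}
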