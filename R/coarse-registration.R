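# Coarse rigid registration of one round's stitched mask onto the reference
# round.  Three steps, each a grid search on the sum-of-absolute-differences
# cost between the binary masks: (1) shift the bead-centroid of each mask to
# a common origin, (2) scan the rotation angle, (3) jointly refine angle and
# shift with a shrinking-step schedule.  Costs are evaluated at reduced
# resolution (factor 2 by default) for speed; internally the cost works on
# the sparse foreground pixel sets, where the sum of absolute differences of
# two binary masks equals the size of their symmetric difference.

#' Coarse registration configuration
#'
#' @param downsample_factor resolution reduction for cost evaluation.
#' @param angle_range,angle_step rotation scan: angles in
#'   `±angle_range` degrees at `angle_step` degree spacing.
#' @param schedule refinement schedule: list of `c(angle_step_deg, shift_step_px)`
#'   pairs with strictly decreasing steps; the last level runs at full
#'   resolution.
#' @param span half-width of each refinement grid, in steps.
#' @return object of class `coarse_reg_config`.
#' @export
coarse_reg_config <- function(downsample_factor = 2L, angle_range = 5,
                              angle_step = 0.5,
                              schedule = list(c(0.5, 4), c(0.2, 2), c(0.05, 1)),
                              span = 2L) {
  stopifnot(downsample_factor >= 1L, angle_range > 0, angle_step > 0, span >= 1L)
  if (length(schedule) > 1L) {
    a <- vapply(schedule, `[`, numeric(1), 1)
    s <- vapply(schedule, `[`, numeric(1), 2)
    if (any(diff(a) >= 0) || any(diff(s) >= 0))
      stop("schedule steps must be strictly decreasing")
  }
  structure(list(downsample_factor = as.integer(downsample_factor),
                 angle_range = angle_range, angle_step = angle_step,
                 schedule = schedule, span = as.integer(span)),
            class = "coarse_reg_config")
}

# foreground pixel coordinates (0-based x, y) of a binary mask
fg_points <- function(mask) {
  ij <- which(mask > 0, arr.ind = TRUE)
  cbind(x = ij[, 2] - 1, y = ij[, 1] - 1)
}

# downsample a 0-based integer pixel set by an integer factor (unique cells)
ds_pixels <- function(px, ds) {
  if (ds == 1L) return(unique(px))
  unique(cbind(x = floor(px[, 1] / ds), y = floor(px[, 2] / ds)))
}

# lookup structure for a reference pixel set: logical matrix over a padded
# bounding box
make_lookup <- function(px, pad = 4L) {
  x0 <- min(px[, 1]) - pad; y0 <- min(px[, 2]) - pad
  w <- max(px[, 1]) - x0 + pad + 1L; h <- max(px[, 2]) - y0 + pad + 1L
  m <- matrix(FALSE, h, w)
  m[cbind(px[, 2] - y0 + 1L, px[, 1] - x0 + 1L)] <- TRUE
  list(m = m, x0 = x0, y0 = y0, n = nrow(px))
}

# symmetric-difference cost between the reference lookup and the transformed
# moving pixel set; pivot at `center`, both in the same (downsampled) frame
sad_cost <- function(lookup, mov_px, theta, tx, ty, center) {
  co <- cos(theta); si <- sin(theta)
  xc <- mov_px[, 1] - center[1]; yc <- mov_px[, 2] - center[2]
  x <- round(co * xc - si * yc + center[1] + tx)
  y <- round(si * xc + co * yc + center[2] + ty)
  key <- x * 1e6 + y
  keep <- !duplicated(key)
  x <- x[keep]; y <- y[keep]
  r <- y - lookup$y0 + 1L; c <- x - lookup$x0 + 1L
  inb <- r >= 1L & r <= nrow(lookup$m) & c >= 1L & c <= ncol(lookup$m)
  hits <- sum(lookup$m[cbind(r[inb], c[inb])])
  lookup$n + length(x) - 2L * hits
}

#' Centre a binary mask on its bead centroid
#'
#' Computes the mean position of all foreground pixels and shifts the mask so
#' that this centroid lands on the raster centre (width/2, height/2).
#'
#' @param mask non-empty binary raster.
#' @return list with `translation` (the applied `c(dx, dy)`, real-valued) and
#'   `mask` (shifted by the rounded translation).
#' @export
center_mask <- function(mask) {
  px <- fg_points(mask)
  if (nrow(px) == 0L) stop("no beads to center: mask is empty")
  centroid <- colMeans(px)
  target <- c(ncol(mask) / 2, nrow(mask) / 2)
  translation <- target - centroid
  list(translation = translation,
       mask = mat_shift(mask, round(translation[2]), round(translation[1])),
       centroid = centroid)
}

#' Grid search over the rotation angle between two centred masks
#'
#' Both masks are downsampled by `downsample_factor`; the cost of each angle
#' in the grid is the sum of absolute mask differences after rotating the
#' moving mask about the raster centre.  Ties resolve to the smallest |angle|.
#'
#' @param ref,mov centred binary masks (see [center_mask()]).
#' @param config a [coarse_reg_config()].
#' @return list with `angle` (radians) and `cost_curve`
#'   (data.frame angle_deg, cost).
#' @export
search_rotation <- function(ref, mov, config = coarse_reg_config()) {
  ds <- config$downsample_factor
  ref_px <- ds_pixels(fg_points(ref), ds)
  mov_px <- ds_pixels(fg_points(mov), ds)
  centre <- c(ncol(ref) / 2, nrow(ref) / 2) / ds
  lookup <- make_lookup(ref_px)
  angles <- seq(-config$angle_range, config$angle_range, by = config$angle_step)
  angles <- angles[order(abs(angles), angles)]   # ties -> smallest |angle|
  costs <- vapply(angles, function(a)
    sad_cost(lookup, mov_px, a * pi / 180, 0, 0, centre), numeric(1))
  best <- which.min(costs)
  curve <- data.frame(angle_deg = angles, cost = costs)
  curve <- curve[order(curve$angle_deg), ]
  rownames(curve) <- NULL
  list(angle = angles[best] * pi / 180, cost = costs[best], cost_curve = curve)
}

#' Joint multi-level grid refinement of a rigid transform
#'
#' At each schedule level an exhaustive grid over (theta, tx, ty) around the
#' current optimum is scored, with that level's angle and shift steps; only
#' strict improvements are accepted, so the cost is non-increasing across
#' levels.  All levels except the last are evaluated at reduced resolution.
#'
#' @param ref,mov binary masks in a common frame.
#' @param init a [rigid_transform()] (mov -> ref) to start from.
#' @param config a [coarse_reg_config()].
#' @return list with `transform` (full-resolution units) and `cost`.
#' @export
refine_rigid <- function(ref, mov, init, config = coarse_reg_config()) {
  refine_rigid_px(fg_points(ref), fg_points(mov), init, config)
}

# same, on raw pixel sets (shared by the mask API and the bead-set path)
refine_rigid_px <- function(ref_px, mov_px, init, config) {
  if (length(config$schedule) == 0L)
    return(list(transform = init, cost = NA_real_))
  cur <- c(init$theta, init$tx, init$ty)
  pivot <- init$center
  cost <- NA_real_
  for (lev in seq_along(config$schedule)) {
    astep <- config$schedule[[lev]][1] * pi / 180
    sstep <- config$schedule[[lev]][2]
    ds <- if (lev < length(config$schedule)) config$downsample_factor else 1L
    rp <- ds_pixels(ref_px, ds); mp <- ds_pixels(mov_px, ds)
    lookup <- make_lookup(rp)
    k <- -config$span:config$span
    cand <- expand.grid(da = k * astep, dx = k * sstep, dy = k * sstep)
    cand <- cand[order(abs(cand$da) + (abs(cand$dx) + abs(cand$dy)) / 1e3,
                       abs(cand$dx), abs(cand$dy)), ]
    best_cost <- Inf; best <- cur
    for (i in seq_len(nrow(cand))) {
      th <- cur[1] + cand$da[i]
      tx <- cur[2] + cand$dx[i]; ty <- cur[3] + cand$dy[i]
      cst <- sad_cost(lookup, mp, th, tx / ds, ty / ds, pivot / ds)
      if (cst < best_cost) { best_cost <- cst; best <- c(th, tx, ty) }
    }
    cur <- best
    cost <- best_cost
  }
  list(transform = rigid_transform(cur[1], cur[2], cur[3], pivot), cost = cost)
}

#' Register one round's detections onto the reference round
#'
#' Full coarse-registration flow on bead sets (or masks): centre both on
#' their bead centroids, scan the rotation angle at reduced resolution, then
#' jointly refine angle and shift.  Returns the rigid transform mapping
#' moving-frame coordinates into the reference frame.
#'
#' @param ref,mov either [bead_set()]s or binary masks.
#' @param config a [coarse_reg_config()].
#' @param circle_radius disc radius used to rasterise bead sets for the cost.
#' @return list with `transform` (a [rigid_transform()]), `cost`,
#'   `cost_before` (identity-alignment cost) and `rotation` (scan result).
#' @export
register_round <- function(ref, mov, config = coarse_reg_config(),
                           circle_radius = 3) {
  as_px <- function(b) {
    if (inherits(b, "bead_set")) {
      off <- disc_offsets(circle_radius)
      xy <- bead_xy(b)
      px <- cbind(x = rep(round(xy[, 1]), each = nrow(off)) + off$dx,
                  y = rep(round(xy[, 2]), each = nrow(off)) + off$dy)
      unique(px)
    } else fg_points(b)
  }
  ref_px <- as_px(ref); mov_px <- as_px(mov)
  if (nrow(ref_px) == 0L || nrow(mov_px) == 0L)
    stop("cannot register empty bead sets")
  c_ref <- colMeans(ref_px); c_mov <- colMeans(mov_px)

  ds <- config$downsample_factor
  # rotation scan about the moving centroid, after centroid alignment
  rp <- ds_pixels(ref_px, ds); mp <- ds_pixels(mov_px, ds)
  lookup <- make_lookup(rp)
  shift0 <- (c_ref - c_mov)
  angles <- seq(-config$angle_range, config$angle_range, by = config$angle_step)
  angles <- angles[order(abs(angles), angles)]
  costs <- vapply(angles, function(a)
    sad_cost(lookup, mp, a * pi / 180, shift0[1] / ds, shift0[2] / ds, c_mov / ds),
    numeric(1))
  best_a <- angles[which.min(costs)] * pi / 180
  cost_before <- sad_cost(lookup, mp, 0, 0, 0, c_mov / ds)

  init <- rigid_transform(best_a, shift0[1], shift0[2], c_mov)
  ref_fine <- refine_rigid_px(ref_px, mov_px, init, config)
  list(transform = ref_fine$transform, cost = ref_fine$cost,
       cost_before = cost_before,
       rotation = data.frame(angle_deg = angles, cost = costs))
}
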