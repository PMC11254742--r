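make_mask_pair <- function(theta_deg, tx, ty, n = 250L, W = 400L, seed = 1L,
                           drop_frac = 0) {
  set.seed(seed)
  pts <- puckcall:::sample_positions_disc(n, c(W / 2, W / 2), W / 2 - 50, 12)
  t <- rigid_transform(theta_deg * pi / 180, tx, ty, c(W / 2, W / 2))
  mov_pts <- transform_points(pts, invert_rigid(t))
  keep_r <- runif(n) >= drop_frac
  keep_m <- runif(n) >= drop_frac
  ref <- puckcall:::paint_discs(c(W, W), pts[keep_r, , drop = FALSE], 3, warn_clip = FALSE)
  mov <- puckcall:::paint_discs(c(W, W), mov_pts[keep_m, , drop = FALSE], 3, warn_clip = FALSE)
  list(ref = ref, mov = mov, t = t, pts = pts, mov_pts = mov_pts, W = W)
}

test_that("centering shifts the bead centroid to the raster centre", {
  # single disc at (100, 60) in a 200^2 raster: translation (0, 40)
  m <- puckcall:::paint_discs(c(200, 200), cbind(100, 60), 3, warn_clip = FALSE)
  cm <- center_mask(m)
  expect_equal(unname(cm$translation), c(0, 40), tolerance = 1e-9)
  # centering twice is centering once
  cm2 <- center_mask(cm$mask)
  expect_lt(max(abs(cm2$translation)), 0.51)
  # symmetric mask: its geometric centre goes to the raster centre
  sym <- puckcall:::paint_discs(c(100, 100), rbind(c(30, 30), c(70, 70)), 3,
                                warn_clip = FALSE)
  cs <- center_mask(sym)
  expect_equal(unname(cs$translation), c(0, 0), tolerance = 0.1)
  expect_error(center_mask(matrix(0, 10, 10)), "empty")
})

test_that("the rotation scan finds the generating angle", {
  fx <- make_mask_pair(0, 0, 0)
  cr <- center_mask(fx$ref)
  rs <- search_rotation(cr$mask, cr$mask)
  expect_equal(rs$angle, 0)
  expect_equal(rs$cost, 0)
  # the returned angle is the argmin of the reported curve
  expect_equal(rs$cost, min(rs$cost_curve$cost))

  fx2 <- make_mask_pair(2.0, 0, 0, seed = 2L)
  c_ref <- center_mask(fx2$ref); c_mov <- center_mask(fx2$mov)
  rs2 <- search_rotation(c_ref$mask, c_mov$mask)
  expect_equal(rs2$angle * 180 / pi, 2.0, tolerance = 0.5 + 1e-9)
})

test_that("grid refinement recovers generating parameters", {
  fx <- make_mask_pair(1.3, 7, -4, seed = 3L)
  reg <- register_round(fx$ref, fx$mov)
  expect_equal(reg$transform$theta * 180 / pi, 1.3, tolerance = 0.2)
  p_rec <- transform_points(fx$mov_pts, reg$transform)
  p_true <- transform_points(fx$mov_pts, fx$t)
  expect_lt(max(sqrt(rowSums((p_rec - p_true)^2))), 1)
  # registration reduced the cost relative to no alignment
  expect_lt(reg$cost, reg$cost_before)

  # identity pair: identity transform, empty schedule returns init
  regi <- register_round(fx$ref, fx$ref)
  expect_equal(regi$transform$theta, 0)
  pr <- rigid_params(regi$transform, c(fx$W / 2, fx$W / 2))
  expect_lt(max(abs(pr[c("tx", "ty")])), 1)
  cfg0 <- coarse_reg_config(); cfg0$schedule <- list()
  init <- rigid_transform(0.01, 1, 1, c(0, 0))
  expect_equal(refine_rigid(fx$ref, fx$mov, init, cfg0)$transform, init)
})

test_that("parameter recovery holds across seeded transforms, with and without washout", {
  worst <- c(0, 0); worst_w <- c(0, 0)
  for (k in 1:6) {
    set.seed(200 + k)
    th <- runif(1, -3, 3); tx <- runif(1, -20, 20); ty <- runif(1, -20, 20)
    fx <- make_mask_pair(th, tx, ty, seed = 300 + k)
    reg <- register_round(fx$ref, fx$mov)
    p_err <- max(sqrt(rowSums((transform_points(fx$mov_pts, reg$transform) -
                               transform_points(fx$mov_pts, fx$t))^2)))
    worst <- pmax(worst, c(abs(reg$transform$theta * 180 / pi - th), p_err))
    fxw <- make_mask_pair(th, tx, ty, seed = 300 + k, drop_frac = 0.05)
    regw <- register_round(fxw$ref, fxw$mov)
    p_errw <- max(sqrt(rowSums((transform_points(fxw$mov_pts, regw$transform) -
                                transform_points(fxw$mov_pts, fxw$t))^2)))
    worst_w <- pmax(worst_w, c(abs(regw$transform$theta * 180 / pi - th), p_errw))
  }
  expect_lt(worst[1], 0.2); expect_lt(worst[2], 1)
  expect_lt(worst_w[1], 0.5); expect_lt(worst_w[2], 2)
})

test_that("schedules must shrink and identity transforms act trivially", {
  expect_error(coarse_reg_config(schedule = list(c(0.2, 2), c(0.5, 4))),
               "decreasing")
  pts <- cbind(x = c(1, 2, 3), y = c(4, 5, 6))
  expect_equal(apply_rigid(pts, rigid_transform()), pts,
               ignore_attr = TRUE)
})
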