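test_that("foot masks are deterministic, seed-sensitive and plausibly sized", {
  m1 <- make_foot_mask(384, 288, seed = 0)
  m2 <- make_foot_mask(384, 288, seed = 0)
  expect_identical(m1, m2)
  frac <- mean(m1)
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.40)
  expect_false(identical(make_foot_mask(384, 288, 1), make_foot_mask(384, 288, 2)))
  expect_error(make_foot_mask(20, 288, 0), "32")
  expect_true(all(m1 %in% c(0, 1)))
})

test_that("generators do not disturb the caller's random stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(make_foot_mask(64, 64, 5))
  invisible(make_scene_bundle(test_rig(), 800, seed = 3, world_shape = c(64, 64)))
  expect_identical(runif(1), before)
})

test_that("projection scale is inversely proportional to distance", {
  cam <- camera_model(384, 288, 50, 38, baseline_mm = 40, focal_plane_mm = 800)
  wm <- make_foot_mask(64, 64, 1)
  at_fp <- project_scene(cam, wm, 800, noise_sd = 0)
  expect_equal(at_fp$distance_scale, 1.0)
  far <- project_scene(cam, wm, 1500, noise_sd = 0)
  # at 2x the focal distance (clamped range permitting) scale halves;
  # verify the 1/d law through the transform entries
  expect_equal(far$transform$matrix[1, 1] / at_fp$transform$matrix[1, 1],
               800 / 1500, tolerance = 1e-12)
  expect_error(project_scene(cam, wm, 300), "distance")
})

test_that("pixel disparity from the baseline grows as distance shrinks", {
  cam <- camera_model(384, 288, 50, 38, baseline_mm = 50, focal_plane_mm = 800)
  cam0 <- camera_model(384, 288, 50, 38, baseline_mm = 0, focal_plane_mm = 800)
  shift_at <- function(d) {
    p1 <- camera_projection(cam, d)
    p0 <- camera_projection(cam0, d)
    abs(p1$matrix[1, 3] - p0$matrix[1, 3])
  }
  expect_gt(shift_at(760), shift_at(800))
})

test_that("scene bundles carry an exact ground-truth transform", {
  rig <- test_rig()
  b <- make_scene_bundle(rig, 800, seed = 1)
  warped <- warp_mask(b$gt_transform, b$visible_mask,
                      c(ncol(b$thermal_mask), nrow(b$thermal_mask)))
  expect_gte(overlap_metrics(warped, b$thermal_mask)$dice, 0.99)
  # determinism
  b2 <- make_scene_bundle(rig, 800, seed = 1)
  expect_identical(b$visible_image, b2$visible_image)
  expect_identical(b$gt_transform$matrix, b2$gt_transform$matrix)
  # gt composed with its inverse is the identity
  round <- tf_compose(b$gt_transform, tf_invert(b$gt_transform))
  expect_lt(max(abs(round$matrix - diag(3))), 1e-9)
  # different distances give different transforms
  b7 <- make_scene_bundle(rig, 760, seed = 1)
  expect_gt(max(abs(b7$gt_transform$matrix - b$gt_transform$matrix)), 1e-3)
})

test_that("the focal-plane transform degrades off the focal plane", {
  rig <- test_rig()
  b800 <- make_scene_bundle(rig, 800, seed = 4)
  shape <- c(384, 288)
  dice_with <- function(b, tf)
    overlap_metrics(warp_mask(tf, b$visible_mask, shape), b$thermal_mask)$dice
  b760 <- make_scene_bundle(rig, 760, seed = 4)
  expect_lt(dice_with(b760, b800$gt_transform), dice_with(b760, b760$gt_transform))
})

test_that("checkerboard keypoints follow the rig transform plus jitter", {
  rig <- test_rig()
  cs <- make_checkerboard_scene(rig, 5, 5, jitter_px = 0, n_outliers = 0, seed = 0)
  moved <- apply_transform(cs$transform, cs$true_keypoints_visible)
  expect_lt(max(abs(moved - cs$true_keypoints_thermal)), 1e-9)
  expect_equal(nrow(cs$true_keypoints_visible), 25)
  expect_error(make_checkerboard_scene(rig, 3, 5), "4 x 4")
  # outliers add blobs but not lattice keypoints
  cs5 <- make_checkerboard_scene(rig, 5, 5, jitter_px = 0, n_outliers = 5, seed = 1)
  expect_equal(nrow(cs5$outliers_thermal), 5)
  expect_equal(nrow(cs5$true_keypoints_thermal), 25)
})

test_that("keypoint jitter has the Rayleigh mean displacement", {
  rig <- test_rig()
  sigma <- 0.5
  cs <- make_checkerboard_scene(rig, 32, 32, jitter_px = sigma, n_outliers = 0,
                                seed = 2, spacing_mm = 11)
  moved <- apply_transform(cs$transform, cs$true_keypoints_visible)
  disp <- sqrt(rowSums((cs$true_keypoints_thermal - moved)^2))
  n <- length(disp)
  expect_equal(n, 1024)
  rayleigh_mean <- sigma * sqrt(pi / 2)
  rayleigh_sd <- sigma * sqrt((4 - pi) / 2)
  expect_lt(abs(mean(disp) - rayleigh_mean), 4 * rayleigh_sd / sqrt(n))
})

test_that("Bernoulli raters hit foreground at their stated sensitivity", {
  truth <- disc_mask(160, 160, 80, 80, 60)
  expect_gte(sum(truth), 10000)
  st <- make_rater_stack(truth, sens = 0.9, spec = 0.99, seed = 5)
  hits <- sum(st$masks[[1]][truth == 1])
  n_fg <- sum(truth)
  expect_lt(abs(hits - 0.9 * n_fg), 3 * sqrt(n_fg * 0.9 * 0.1))
  # perfect raters reproduce the truth
  perfect <- make_rater_stack(truth, c(1, 1), c(1, 1), seed = 1)
  expect_identical(perfect$masks[[1]], truth)
  expect_identical(perfect$masks[[2]], truth)
  # reproducibility and identifiability guard
  again <- make_rater_stack(truth, sens = 0.9, spec = 0.99, seed = 5)
  expect_identical(st$masks, again$masks)
  expect_error(make_rater_stack(truth, 0.4, 0.9), "0.5")
})

test_that("frame streams run at the requested rates inside the window", {
  ss <- make_frame_streams(30, 9, window_s = 2, seed = 1)
  expect_true(abs(nrow(ss$a) - 60) <= 1)
  expect_true(abs(nrow(ss$b) - 18) <= 1)
  expect_true(all(diff(ss$a$timestamp_s) >= 0))
  expect_true(all(ss$a$timestamp_s >= 0 & ss$a$timestamp_s <= 2))
  # identical rates with zero jitter synchronize perfectly
  same <- make_frame_streams(15, 15, window_s = 2, seed = 2, jitter_s = 0)
  expect_equal(sync_select(same$a, same$b)$delta_t_s, 0)
})
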