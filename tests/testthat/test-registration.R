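make_corr <- function(n) structure(cbind(src_idx = seq_len(n), dst_idx = seq_len(n)),
                                   class = "correspondences")
mk_kp <- function(pts, shape = c(1280, 720))
  structure(pts, image_shape = shape, class = "keypoint_set")

test_that("GOT recovers a pure scale-plus-shift rig from correspondences", {
  rig <- test_rig()
  cs <- make_checkerboard_scene(rig, 5, 5, jitter_px = 0, n_outliers = 0, seed = 1)
  kv <- mk_kp(cs$true_keypoints_visible)
  kt <- mk_kp(cs$true_keypoints_thermal, c(384, 288))
  corr <- make_corr(25)
  tf <- estimate_got(corr, kv, kt, rig)
  resid <- apply_transform(tf, unclass(kv)) - unclass(kt)
  expect_lt(max(sqrt(rowSums(resid^2))), 0.5)
  expect_error(estimate_got(make_corr(0), kv, kt, rig), "at least one")
})

test_that("GOT translation is the median offset and resists a gross outlier", {
  rig <- test_rig()
  sc <- angular_scale(rig$visible, rig$thermal)
  vis <- cbind(c(100, 300, 500, 700, 900), c(100, 200, 300, 400, 500))
  ir <- apply_transform(sc, vis) + matrix(c(7, -3), 5, 2, byrow = TRUE)
  tf <- estimate_got(make_corr(5), mk_kp(vis), mk_kp(ir, c(384, 288)), rig)
  # single pair at a known post-scaling offset
  tf1 <- estimate_got(make_corr(1), mk_kp(vis[1, , drop = FALSE]),
                      mk_kp(ir[1, , drop = FALSE], c(384, 288)), rig)
  expect_equal(apply_transform(tf1, vis[1, , drop = FALSE]),
               ir[1, , drop = FALSE], tolerance = 1e-9, ignore_attr = TRUE)
  # corrupt one pair grossly; the median translation barely moves
  ir_bad <- ir; ir_bad[3, ] <- ir_bad[3, ] + c(80, -60)
  tf_bad <- estimate_got(make_corr(5), mk_kp(vis), mk_kp(ir_bad, c(384, 288)), rig)
  expect_lt(max(abs(tf_bad$matrix[1:2, 3] - tf$matrix[1:2, 3])), 0.5)
})

test_that("normalized DLT is exact on noiseless correspondences", {
  H_true <- tf_homography(matrix(c(1.05, 0.02, 8,
                                   -0.03, 0.97, -5,
                                   1e-4, -6e-5, 1), 3, 3, byrow = TRUE))
  set.seed(42)
  src <- cbind(runif(4, 0, 600), runif(4, 0, 400))
  dst <- apply_transform(H_true, src)
  H_est <- homography_dlt(src, dst)
  expect_lt(max(abs(H_est$matrix - H_true$matrix)), 1e-8)
  # identity correspondences give the identity matrix
  H_id <- homography_dlt(src, src)
  expect_lt(max(abs(H_id$matrix - diag(3))), 1e-10)
  # pure translation pairs give a translation-only homography
  H_tr <- homography_dlt(src, src + matrix(c(11, -4), 4, 2, byrow = TRUE))
  off <- H_tr$matrix - diag(3); off[1, 3] <- off[1, 3] - 11; off[2, 3] <- off[2, 3] + 4
  expect_lt(max(abs(off)), 1e-10)
})

test_that("DLT rejects degenerate and undersized configurations", {
  line <- cbind(1:4, 2 * (1:4))
  expect_error(homography_dlt(line, line + 1), "collinear")
  expect_error(homography_dlt(cbind(1:3, c(1, 5, 2)), cbind(1:3, c(2, 1, 7))), ">= 4")
})

test_that("RANSAC recovers the exact inlier set and rejects all outliers", {
  H_true <- tf_homography(matrix(c(1.02, 0.01, 4,
                                   -0.01, 0.99, -2,
                                   5e-5, 2e-5, 1), 3, 3, byrow = TRUE))
  set.seed(7)
  src_in <- cbind(runif(20, 50, 1200), runif(20, 50, 650))
  dst_in <- apply_transform(H_true, src_in) + matrix(rnorm(40, 0, 0.3), 20, 2)
  src_out <- cbind(runif(8, 50, 1200), runif(8, 50, 650))
  ang <- runif(8, 0, 2 * pi)
  dst_out <- apply_transform(H_true, src_out) +
    cbind(cos(ang), sin(ang)) * runif(8, 10, 40)
  fit <- homography_ransac(rbind(src_in, src_out), rbind(dst_in, dst_out),
                           ransac_config(seed = 1))
  expect_identical(fit$inliers, 1:20)
  # all-inlier input keeps every pair
  fit_all <- homography_ransac(src_in, dst_in, ransac_config(seed = 2))
  expect_identical(fit_all$inliers, 1:20)
  expect_error(homography_ransac(src_in[1:3, ], dst_in[1:3, ]), ">= 4")
  # determinism under a fixed seed
  fit2 <- homography_ransac(rbind(src_in, src_out), rbind(dst_in, dst_out),
                            ransac_config(seed = 1))
  expect_identical(fit$transform$matrix, fit2$transform$matrix)
})

test_that("RANSAC reports failure when no consensus reaches min_inliers", {
  set.seed(3)
  src <- cbind(runif(10, 0, 100), runif(10, 0, 100))
  dst <- cbind(runif(10, 0, 100), runif(10, 0, 100))   # pure scatter
  expect_error(homography_ransac(src, dst, ransac_config(min_inliers = 9, seed = 1)),
               "no model supported")
})

test_that("contour keypoints sample the boundary at equal arc steps", {
  rect <- matrix(0, 50, 60); rect[11:40, 11:50] <- 1
  k4 <- unclass(extract_contour_keypoints(rect, 4))
  expect_equal(nrow(k4), 4)
  # all on the boundary ring
  expect_true(all(k4[, 1] %in% c(10:49)) && all(k4[, 2] %in% c(10:39)))
  on_edge <- k4[, 1] %in% c(10, 49) | k4[, 2] %in% c(10, 39)
  expect_true(all(on_edge))
  # saturation: asking for more points than boundary pixels returns each once
  all_pts <- unclass(extract_contour_keypoints(rect, 10000))
  perim <- 2 * (30 + 40) - 4
  expect_equal(nrow(all_pts), perim)
  expect_equal(nrow(unique(all_pts)), perim)
  expect_error(extract_contour_keypoints(matrix(0, 20, 20), 10), "empty")
})

test_that("contour keypoints split across two blobs by perimeter", {
  two <- matrix(0, 60, 120)
  two[16:45, 11:40] <- 1     # 30x30 square
  two[21:40, 71:110] <- 1    # 20x40 rectangle
  k <- unclass(extract_contour_keypoints(two, 60))
  left <- sum(k[, 1] < 60); right <- sum(k[, 1] >= 60)
  expect_equal(left + right, nrow(k))
  # perimeters 116 vs 116: roughly equal allocation
  expect_lt(abs(left - right), 8)
})

test_that("ICP recovers a rigid motion between mask contours", {
  m <- make_foot_mask(384, 288, 2)
  gt <- tf_rigid(5 * pi / 180, c(4, 2), c(191.5, 143.5))
  m2 <- warp_mask(gt, m, c(384, 288))
  fit <- estimate_icp(m, m2, cfg = icp_config())
  ang <- atan2(fit$transform$matrix[2, 1], fit$transform$matrix[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 0.5)
  R <- fit$transform$matrix[1:2, 1:2]
  t_rec <- fit$transform$matrix[1:2, 3] + as.numeric(R %*% c(191.5, 143.5)) - c(191.5, 143.5)
  expect_lt(max(abs(t_rec - c(4, 2))), 0.5)
  expect_true(all(diff(fit$rmse_trace) <= 1e-9))
})

test_that("ICP on identical masks returns the identity with zero RMSE", {
  m <- make_foot_mask(200, 150, 3)
  fit <- estimate_icp(m, m, cfg = icp_config())
  expect_lt(max(abs(fit$transform$matrix - diag(3))), 1e-9)
  expect_lt(fit$rmse, 1e-9)
  expect_error(estimate_icp(matrix(0, 50, 50), m), "nonempty")
})

test_that("degrees of freedom order the residuals on a perspective scene", {
  H_true <- tf_homography(matrix(c(1.03, 0.02, 6,
                                   0.01, 0.97, -4,
                                   8e-5, 4e-5, 1), 3, 3, byrow = TRUE))
  set.seed(11)
  src <- cbind(runif(30, 0, 380), runif(30, 0, 280))
  dst <- apply_transform(H_true, src)
  rms <- function(d) sqrt(mean(rowSums(d^2)))
  # homography: exact
  r_h <- rms(apply_transform(homography_dlt(src, dst), src) - dst)
  # affine: least squares on the same pairs
  X <- cbind(src, 1)
  beta <- solve(crossprod(X), crossprod(X, dst))
  r_a <- rms(X %*% beta - dst)
  # rigid: Procrustes fit
  cs <- colMeans(src); cd <- colMeans(dst)
  sv <- svd(crossprod(sweep(src, 2, cs), sweep(dst, 2, cd)))
  R <- sv$v %*% diag(c(1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
  r_r <- rms(sweep(sweep(src, 2, cs) %*% t(R), 2, cd, "+") - dst)
  expect_lte(r_h, r_a + 1e-9)
  expect_lte(r_a, r_r + 1e-9)
})
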