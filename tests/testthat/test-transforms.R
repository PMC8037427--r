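test_that("transforms apply to points according to their model", {
  # identity leaves points alone
  pts <- cbind(c(0, 10, 3.5), c(0, 5, -2))
  expect_equal(apply_transform(tf_identity(), pts), pts,
               ignore_attr = TRUE)
  # pure translation
  expect_equal(apply_transform(tf_translation(10, 5), cbind(0, 0)),
               cbind(10, 5), ignore_attr = TRUE)
  # 90-degree rotation about (100, 100) sends (110, 100) to (100, 110)
  r <- tf_rigid(pi / 2, c(0, 0), center = c(100, 100))
  expect_equal(apply_transform(r, cbind(110, 100)), cbind(100, 110),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("perspective division is exact for non-homography models", {
  a <- tf_affine(matrix(c(1.2, 0.1, -0.2, 0.9), 2, 2), c(3, 4), c(10, 10))
  expect_equal(a$matrix[3, ], c(0, 0, 1))
  H <- tf_homography(matrix(c(1, 0, 0, 0, 1, 0, 1e-3, 0, 1), 3, 3, byrow = TRUE))
  p <- apply_transform(H, cbind(100, 50))
  expect_equal(p[1], 100 / (1 + 0.1), tolerance = 1e-12)
})

test_that("vanishing homogeneous coordinate names the offending point", {
  H <- tf_homography(matrix(c(1, 0, 0, 0, 1, 0, -0.01, 0, 1), 3, 3, byrow = TRUE))
  expect_error(apply_transform(H, cbind(100, 0)), "index 1")
})

test_that("composition and inversion behave like matrix algebra", {
  t1 <- tf_translation(3, -2)
  t2 <- tf_translation(-1, 7)
  both <- tf_compose(t1, t2)
  expect_equal(both$model, "translation")
  expect_equal(both$matrix[1:2, 3], c(2, 5))
  r <- tf_rigid(0.3, c(4, 1), c(50, 60))
  round_trip <- tf_compose(r, tf_invert(r))
  expect_lt(max(abs(round_trip$matrix - diag(3))), 1e-12)
  expect_equal(tf_compose(tf_identity(), r)$matrix, r$matrix)
})

test_that("model class closure: rigid compositions stay orthonormal", {
  r1 <- tf_rigid(0.2, c(1, 2), c(10, 10))
  r2 <- tf_rigid(-0.5, c(-3, 4), c(30, 5))
  comp <- tf_compose(r1, r2)
  expect_equal(comp$model, "rigid")
  B <- comp$matrix[1:2, 1:2]
  expect_lt(max(abs(crossprod(B) - diag(2))), 1e-10)
  # least-restrictive model propagates
  expect_equal(tf_compose(r1, tf_homography(diag(3)))$model, "homography")
})

test_that("rigid constructor rejects improper rotation blocks", {
  m <- diag(3); m[1, 1] <- -1   # reflection
  expect_error(transform2d(m, "rigid"), "orthonormal")
})

test_that("angular scaling equalizes degrees per pixel", {
  vis <- camera_model(1280, 720, 65, 40)
  ir <- camera_model(384, 288, 50, 38)
  sc <- angular_scale(vis, ir)
  expect_equal(sc$matrix[1, 1], (65 / 1280) / (50 / 384), tolerance = 1e-12)
  expect_equal(sc$matrix[2, 2], (40 / 720) / (38 / 288), tolerance = 1e-12)
  expect_lt(max(abs(angular_scale(vis, vis)$matrix - diag(3))), 1e-12)
  # doubling the destination width halves its degrees-per-pixel, doubling sx
  ir2 <- camera_model(768, 288, 50, 38)
  expect_equal(angular_scale(vis, ir2)$matrix[1, 1], sc$matrix[1, 1] * 2,
               tolerance = 1e-12)
})

test_that("cropping shifts the output frame bookkeeping only", {
  t0 <- tf_affine(matrix(c(2, 0, 0, 2), 2, 2), c(5, 5))
  same <- crop_to(t0, c(100, 100), offset = c(0, 0))
  expect_equal(same$matrix, t0$matrix)
  shifted <- crop_to(t0, c(100, 100), offset = c(30, 20))
  expect_equal(shifted$matrix[1:2, 3], t0$matrix[1:2, 3] - c(30, 20))
  # the window corner maps to the output origin
  corner_src <- apply_transform(tf_invert(t0), cbind(30, 20))
  expect_equal(apply_transform(shifted, corner_src), cbind(0, 0),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("mask warping is binary, inverse-mapped, zero outside", {
  m <- disc_mask(60, 50, 30, 25, 12)
  expect_equal(warp_mask(tf_identity(), m), m)
  single <- matrix(0, 20, 20); single[6, 6] <- 1    # pixel (x=5, y=5)
  moved <- warp_mask(tf_translation(3, 0), single, c(20, 20))
  expect_equal(which(moved == 1), which(matrix(0, 20, 20) |
    (row(single) == 6 & col(single) == 9)))
  expect_true(all(moved %in% c(0, 1)))
  # warping out of bounds gives zeros
  gone <- warp_mask(tf_translation(100, 0), single, c(20, 20))
  expect_equal(sum(gone), 0)
})

test_that("warp round trip preserves a smooth blob almost exactly", {
  m <- disc_mask(120, 100, 60, 50, 30)
  r <- tf_rigid(0.2, c(5, -3), c(59.5, 49.5))
  back <- warp_mask(tf_invert(r), warp_mask(r, m, c(120, 100)), c(120, 100))
  expect_gte(overlap_metrics(back, m)$dice, 0.98)
})

test_that("point mapping and mask warping agree", {
  single <- matrix(0, 40, 40); single[11, 16] <- 1   # (x=15, y=10)
  tf <- tf_rigid(0.1, c(2, 1), c(20, 20))
  w <- warp_mask(tf, single, c(40, 40))
  expect_equal(sum(w), 1)
  hit <- which(w == 1, arr.ind = TRUE)
  centroid <- c(hit[1, "col"] - 1, hit[1, "row"] - 1)
  target <- apply_transform(tf, cbind(15, 10))
  expect_lt(max(abs(centroid - target)), 0.5 + 1e-9)
})

test_that("JSON round trip preserves matrix, model and center", {
  tf <- tf_rigid(0.25, c(3.5, -1.25), c(191.5, 143.5))
  js <- tf_to_json(tf)
  back <- tf_from_json(js)
  expect_equal(back$matrix, tf$matrix, tolerance = 1e-12)
  expect_equal(back$model, "rigid")
  expect_equal(back$center, c(191.5, 143.5))
})
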