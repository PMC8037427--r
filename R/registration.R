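#' Geometric optical translation (GOT) registration
#'
#' The simplest of the four estimators: scale the visible image to the
#' thermal camera's angular resolution (degrees per pixel) with
#' [angular_scale()], then translate by the robust (component-wise median)
#' offset between paired checkerboard keypoints, expressed in the thermal
#' frame. The resulting transform maps visible pixels to thermal pixels;
#' the output frame is the thermal resolution (the crop step).
#'
#' @param corr a `correspondences` object pairing visible to thermal keypoints.
#' @param kp_vis,kp_ir the keypoint sets the correspondences index into.
#' @param cams list with `visible` and `thermal` [camera_model]s.
#' @return a [transform2d] mapping visible to thermal pixel coordinates.
#' @export
estimate_got <- function(corr, kp_vis, kp_ir, cams) {
  if (is.null(corr) || nrow(corr) < 1) stop("GOT needs at least one correspondence")
  sc <- angular_scale(cams$visible, cams$thermal)
  p <- corr_points(corr, kp_vis, kp_ir)
  scaled <- apply_transform(sc, p$src)
  t_xy <- c(stats::median(p$dst[, 1] - scaled[, 1]),
            stats::median(p$dst[, 2] - scaled[, 2]))
  out <- tf_compose(tf_translation(t_xy[1], t_xy[2]), sc)
  crop_to(out, c(cams$thermal$width_px, cams$thermal$height_px))
}

#' Homography by the normalized direct linear transform
#'
#' Hartley-normalizes both point sets (centroid at the origin, mean distance
#' sqrt(2)), builds the 2n x 9 DLT system and takes the SVD null vector,
#' then denormalizes and scales so the bottom-right entry is 1. Exact for
#' noiseless inputs; least-squares for redundant ones.
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 4, with no
#'   four-point subset fully collinear.
#' @return a homography-model [transform2d].
#' @export
homography_dlt <- function(src, dst) {
  src <- rbind2col(src); dst <- rbind2col(dst)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n) stop("homography estimation needs >= 4 point pairs")
  if (is_degenerate(src) || is_degenerate(dst))
    stop("degenerate configuration: points are (nearly) collinear")
  ns <- hartley_normalize(src)
  nd <- hartley_normalize(dst)
  s <- ns$pts; d <- nd$pts
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  Hn <- matrix(h, 3, 3, byrow = TRUE)
  H <- solve(nd$T) %*% Hn %*% ns$T
  tf_homography(H)
}

hartley_normalize <- function(pts) {
  ctr <- colMeans(pts)
  d <- sweep(pts, 2, ctr)
  md <- mean(sqrt(rowSums(d^2)))
  s <- if (md > 1e-12) sqrt(2) / md else 1
  T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  list(pts = cbind(d[, 1] * s, d[, 2] * s), T = T)
}

# all points within a hair of one line
is_degenerate <- function(pts, tol = 1e-8) {
  if (nrow(pts) < 3) return(TRUE)
  d <- sweep(pts, 2, colMeans(pts))
  sv <- svd(d, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Configuration for RANSAC homography estimation
#'
#' @param n_iters number of random minimal samples.
#' @param inlier_thresh_px symmetric transfer error threshold, pixels.
#' @param min_inliers smallest admissible consensus set.
#' @param seed integer seed.
#' @export
ransac_config <- function(n_iters = 2000, inlier_thresh_px = 2,
                          min_inliers = 8, seed = 0) {
  stopifnot(n_iters >= 1, inlier_thresh_px > 0, min_inliers >= 4)
  structure(list(n_iters = as.integer(n_iters),
                 inlier_thresh_px = inlier_thresh_px,
                 min_inliers = as.integer(min_inliers),
                 seed = as.integer(seed)), class = "ransac_config")
}

# symmetric transfer error per pair, in pixels (worst of the two directions)
symmetric_transfer_error <- function(H, src, dst) {
  f <- apply_transform(H, src)
  b <- apply_transform(tf_invert(H), dst)
  pmax(sqrt(rowSums((f - dst)^2)), sqrt(rowSums((b - src)^2)))
}

#' Homography with RANSAC outlier rejection
#'
#' Repeatedly samples four pairs, fits a candidate homography by
#' [homography_dlt()], counts pairs whose symmetric transfer error is below
#' the threshold, keeps the largest consensus set (ties broken by lower mean
#' inlier error) and refits on all inliers. Deterministic given the seed in
#' `cfg`.
#'
#' @param src,dst n x 2 matrices of corresponding points, n >= 4.
#' @param cfg a [ransac_config()].
#' @return list with `transform` (homography [transform2d]) and `inliers`
#'   (indices of the supporting pairs).
#' @export
homography_ransac <- function(src, dst, cfg = ransac_config()) {
  src <- rbind2col(src); dst <- rbind2col(dst)
  n <- nrow(src)
  if (n < 4) stop("RANSAC homography needs >= 4 point pairs")
  best <- NULL
  with_seed(cfg$seed, {
    for (it in seq_len(cfg$n_iters)) {
      pick <- sample.int(n, 4L)
      H <- tryCatch(homography_dlt(src[pick, ], dst[pick, ]),
                    error = function(e) NULL)
      if (is.null(H)) next
      err <- symmetric_transfer_error(H, src, dst)
      inl <- which(err < cfg$inlier_thresh_px)
      if (length(inl) < 4) next
      score <- c(length(inl), -mean(err[inl]))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]))
        best <- list(inliers = inl, score = score)
    }
  })
  if (is.null(best) || length(best$inliers) < cfg$min_inliers)
    stop("no model supported: consensus below min_inliers = ", cfg$min_inliers)
  H <- homography_dlt(src[best$inliers, ], dst[best$inliers, ])
  err <- symmetric_transfer_error(H, src, dst)
  inl <- which(err < cfg$inlier_thresh_px)
  list(transform = H, inliers = sort(inl))
}
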