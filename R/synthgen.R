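#' @title Synthetic two-camera scenes with known ground truth
#' @description Generators for every input the registration pipeline needs:
#'   foot-shaped binary masks, paired visible/thermal projections of a scene
#'   at a chosen working distance with the exact visible-to-thermal transform,
#'   dual-spectrum checkerboard calibration scenes, imperfect Bernoulli
#'   raters, and timestamped frame streams. All generators are pure functions
#'   of their arguments and a seed; no global random state is touched.
#' @name synthgen
NULL

# evaluate expr under a temporary RNG state, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic sub-seed derivation, kept inside 32-bit range
sub_seed <- function(seed, k) as.integer((as.numeric(seed) * 7919 + 104729 * k) %% 2147483647)

#' Generate a foot-pair binary mask
#'
#' Draws two smooth foot-silhouette blobs (left and right sole) on a blank
#' grid. Each sole is an ellipse whose radius is modulated by a low-order
#' Fourier perturbation so the boundary is irregular but smooth at pixel
#' scale; the pair occupies roughly a quarter of the grid. Deterministic
#' given the seed.
#'
#' @param width,height grid size in pixels (at least 32 each).
#' @param seed integer seed.
#' @return binary mask matrix (`height` rows, `width` cols, values 0/1).
#' @export
make_foot_mask <- function(width, height, seed = 0) {
  if (width < 32 || height < 32)
    stop("mask dimensions must be at least 32 x 32 pixels")
  with_seed(seed, {
    W <- as.integer(width); H <- as.integer(height)
    xs <- matrix(rep(0:(W - 1L), each = H), nrow = H)
    ys <- matrix(rep(0:(H - 1L), times = W), nrow = H)
    mask <- matrix(0, H, W)
    for (side in c(-1, 1)) {
      cx <- (W - 1) / 2 + side * 0.16 * W * stats::runif(1, 0.94, 1.06)
      cy <- (H - 1) / 2 * stats::runif(1, 0.96, 1.04)
      a <- 0.115 * W * stats::runif(1, 0.92, 1.08)   # half-width of the sole
      b <- 0.36 * H * stats::runif(1, 0.94, 1.06)    # half-length of the sole
      th <- stats::runif(1, -3, 3) * pi / 180        # slight toe-out rotation
      eps <- stats::runif(3, -0.06, 0.06)
      psi <- stats::runif(3, 0, 2 * pi)
      dx <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      dy <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      u <- dx / a; v <- dy / b
      phi <- atan2(v, u)
      rmod <- 1 + eps[1] * cos(2 * phi + psi[1]) +
        eps[2] * cos(3 * phi + psi[2]) + eps[3] * cos(4 * phi + psi[3])
      mask[u * u + v * v <= rmod * rmod] <- 1
    }
    mask
  })
}

#' Project a world-plane mask into one camera
#'
#' Emulates the camera's view of a fronto-parallel scene plane at a working
#' distance: the world mask (1 grid cell = 1 mm, origin at grid center) is
#' warped through the camera's projection at that distance, and an intensity
#' image is synthesized as foreground/background levels plus additive
#' Gaussian noise.
#'
#' @param cam a [camera_model].
#' @param world_mask binary mask on the mm world grid.
#' @param distance_mm working distance, must lie in [500, 1500] mm.
#' @param noise_sd additive Gaussian noise as a fraction of dynamic range.
#' @param seed integer seed for the noise.
#' @return list with `image`, `mask`, the exact world-to-pixel `transform`
#'   (whose `distance_scale` attribute is `focal_plane_mm / distance_mm`),
#'   and `distance_scale`.
#' @export
project_scene <- function(cam, world_mask, distance_mm, noise_sd = 0.02, seed = 0) {
  if (distance_mm < 500 || distance_mm > 1500)
    stop("distance_mm must lie within [500, 1500] mm")
  proj <- camera_projection(cam, distance_mm)
  wcx <- (ncol(world_mask) - 1) / 2
  wcy <- (nrow(world_mask) - 1) / 2
  tf <- tf_compose(proj, tf_translation(-wcx, -wcy))
  attr(tf, "distance_scale") <- attr(proj, "distance_scale")
  shape <- c(cam$width_px, cam$height_px)
  mask <- warp_mask(tf, world_mask, shape)
  img <- 0.15 + 0.7 * mask
  if (noise_sd > 0)
    img <- img + with_seed(seed, matrix(stats::rnorm(length(img), 0, noise_sd),
                                        nrow = nrow(img)))
  img <- pmin(pmax(img, 0), 1)
  list(image = img, mask = mask, transform = tf,
       distance_scale = attr(proj, "distance_scale"))
}

#' Generate a paired visible/thermal scene bundle
#'
#' Composes [make_foot_mask()] and [project_scene()] for both cameras of a
#' rig at one working distance. The ground-truth visible-to-thermal pixel
#' transform is the thermal projection composed with the inverse visible
#' projection.
#'
#' @param rig list with `visible` and `thermal` [camera_model]s.
#' @param distance_mm working distance in mm.
#' @param seed integer seed.
#' @param world_shape (width, height) of the mm world grid.
#' @param noise_sd image noise level.
#' @return an object of class `scene_bundle`.
#' @export
make_scene_bundle <- function(rig, distance_mm, seed = 0,
                              world_shape = c(440, 330), noise_sd = 0.02) {
  wm <- make_foot_mask(world_shape[1L], world_shape[2L], seed = sub_seed(seed, 1))
  vis <- project_scene(rig$visible, wm, distance_mm, noise_sd, seed = sub_seed(seed, 2))
  th <- project_scene(rig$thermal, wm, distance_mm, noise_sd, seed = sub_seed(seed, 3))
  gt <- tf_compose(th$transform, tf_invert(vis$transform))
  structure(list(visible_image = vis$image, thermal_image = th$image,
                 visible_mask = vis$mask, thermal_mask = th$mask,
                 distance_mm = distance_mm, gt_transform = gt,
                 rng_seed = seed, world_mask = wm),
            class = "scene_bundle")
}

#' @export
print.scene_bundle <- function(x, ...) {
  cat(sprintf("<scene_bundle> distance %.0f mm; visible %dx%d, thermal %dx%d; seed %d\n",
              x$distance_mm, ncol(x$visible_mask), nrow(x$visible_mask),
              ncol(x$thermal_mask), nrow(x$thermal_mask), x$rng_seed))
  invisible(x)
}

# paint anti-aliased discs; fg may be above or below bg (polarity)
render_discs <- function(shape, pts, radius, fg, bg) {
  W <- shape[1L]; H <- shape[2L]
  img <- matrix(bg, H, W)
  cov <- matrix(0, H, W)
  if (nrow(pts)) for (i in seq_len(nrow(pts))) {
    x0 <- pts[i, 1]; y0 <- pts[i, 2]
    jj <- max(0, floor(x0 - radius - 1)):min(W - 1, ceiling(x0 + radius + 1))
    ii <- max(0, floor(y0 - radius - 1)):min(H - 1, ceiling(y0 + radius + 1))
    if (!length(jj) || !length(ii)) next
    d <- sqrt(outer((ii - y0)^2, (jj - x0)^2, "+"))
    c0 <- pmin(pmax(radius + 0.5 - d, 0), 1)
    cov[ii + 1, jj + 1] <- pmax(cov[ii + 1, jj + 1], c0)
  }
  img + (fg - bg) * cov
}

#' Generate a dual-spectrum checkerboard calibration scene
#'
#' Lays a `rows` x `cols` grid of circular calibration blobs on the rig's
#' focal plane and renders both cameras' views: bright blobs in the visible
#' image, cold (dark) blobs in the thermal image. Thermal keypoints are the
#' focal-plane transform of the visible keypoints plus i.i.d. Gaussian
#' jitter of `jitter_px` per axis; `n_outliers` spurious blobs are injected
#' per image, away from the lattice.
#'
#' @param rig list with `visible` and `thermal` [camera_model]s.
#' @param rows,cols lattice size, at least 4 x 4.
#' @param jitter_px standard deviation of the thermal keypoint jitter.
#' @param n_outliers spurious blobs injected per image.
#' @param seed integer seed.
#' @param spacing_mm blob spacing on the board.
#' @return an object of class `checkerboard_scene` with both images, the
#'   true keypoint sets, the outlier positions and the exact focal-plane
#'   visible-to-thermal `transform`.
#' @export
make_checkerboard_scene <- function(rig, rows = 5, cols = 5, jitter_px = 0.3,
                                    n_outliers = 0, seed = 0, spacing_mm = 40) {
  if (rows < 4 || cols < 4)
    stop("checkerboard grid must be at least 4 x 4 (>= 4 correspondences needed)")
  fp <- rig$visible$focal_plane_mm
  gx <- (seq_len(cols) - (cols + 1) / 2) * spacing_mm
  gy <- (seq_len(rows) - (rows + 1) / 2) * spacing_mm
  world <- cbind(x = rep(gx, times = rows), y = rep(gy, each = cols)) # row-major lattice
  pv <- camera_projection(rig$visible, fp)
  pt <- camera_projection(rig$thermal, fp)
  kv <- apply_transform(pv, world)
  kt <- apply_transform(pt, world)
  tf <- tf_compose(pt, tf_invert(pv))
  with_seed(seed, {
    if (jitter_px > 0)
      kt <- kt + matrix(stats::rnorm(length(kt), 0, jitter_px), ncol = 2)
    draw_outliers <- function(kps, shape, spacing_px) {
      out <- matrix(numeric(0), 0, 2)
      guard <- 0
      while (nrow(out) < n_outliers && guard < 1000) {
        guard <- guard + 1
        p <- c(stats::runif(1, 8, shape[1] - 9), stats::runif(1, 8, shape[2] - 9))
        dmin <- min(sqrt((kps[, 1] - p[1])^2 + (kps[, 2] - p[2])^2))
        if (dmin > 1.5 * spacing_px) out <- rbind(out, p)
      }
      out
    }
    sp_v <- spacing_mm * camera_k(rig$visible)[1] / fp
    sp_t <- spacing_mm * camera_k(rig$thermal)[1] / fp
    ov <- draw_outliers(kv, c(rig$visible$width_px, rig$visible$height_px), sp_v)
    ot <- draw_outliers(kt, c(rig$thermal$width_px, rig$thermal$height_px), sp_t)
    vis_img <- render_discs(c(rig$visible$width_px, rig$visible$height_px),
                            rbind(kv, ov), radius = 7, fg = 0.95, bg = 0.15)
    th_img <- render_discs(c(rig$thermal$width_px, rig$thermal$height_px),
                           rbind(kt, ot), radius = 4, fg = 0.05, bg = 0.85)
    structure(list(visible_image = vis_img, thermal_image = th_img,
                   true_keypoints_visible = kv, true_keypoints_thermal = kt,
                   outliers_visible = ov, outliers_thermal = ot,
                   grid_rows = as.integer(rows), grid_cols = as.integer(cols),
                   transform = tf),
              class = "checkerboard_scene")
  })
}

#' Simulate imperfect raters over a true segmentation
#'
#' Each rater marks a true-foreground pixel as foreground with probability
#' `sens[j]` and a true-background pixel as foreground with probability
#' `1 - spec[j]`, independently per pixel. Sensitivities and specificities
#' must exceed 0.5 (raters better than chance), which keeps the STAPLE
#' estimation identifiable.
#'
#' @param truth binary mask matrix.
#' @param sens,spec per-rater sensitivity and specificity, each in (0.5, 1].
#' @param seed integer seed.
#' @return an object of class `rater_stack`: list of rater masks plus the
#'   simulated `sens`/`spec` used (ground truth for parameter-recovery tests).
#' @export
make_rater_stack <- function(truth, sens, spec, seed = 0) {
  stopifnot(length(sens) == length(spec), length(sens) >= 1)
  if (any(sens <= 0.5) || any(sens > 1) || any(spec <= 0.5) || any(spec > 1))
    stop("sens and spec must lie in (0.5, 1] for STAPLE identifiability")
  fg <- truth == 1
  masks <- with_seed(seed, lapply(seq_along(sens), function(j) {
    m <- matrix(0, nrow(truth), ncol(truth))
    u <- stats::runif(length(truth))
    m[fg & u <= sens[j]] <- 1
    m[!fg & u <= (1 - spec[j])] <- 1
    m
  }))
  structure(list(masks = masks, sens = sens, spec = spec,
                 rater_ids = paste0("rater", seq_along(sens))),
            class = "rater_stack")
}

#' Simulate timestamped frame streams from two free-running cameras
#'
#' Frames arrive at the nominal rates with small Gaussian timing jitter,
#' both within a shared acquisition buffer window.
#'
#' @param rate_a_fps,rate_b_fps nominal frame rates (frames per second).
#' @param window_s buffer window length, seconds (the acquisition buffer
#'   stores this much video; default 2 s).
#' @param seed integer seed.
#' @param jitter_s timing jitter standard deviation, seconds.
#' @return list of two `frame_stream` data frames with columns
#'   `timestamp_s` (non-decreasing) and `frame_id`.
#' @export
make_frame_streams <- function(rate_a_fps, rate_b_fps, window_s = 2.0,
                               seed = 0, jitter_s = 0.002) {
  stopifnot(rate_a_fps > 0, rate_b_fps > 0, window_s > 0)
  mk <- function(rate, sd_seed) with_seed(sd_seed, {
    n <- floor(rate * window_s)
    t0 <- (seq_len(n) - 0.5) / rate
    if (jitter_s > 0) t0 <- t0 + stats::rnorm(n, 0, jitter_s)
    t0 <- sort(pmin(pmax(t0, 0), window_s))
    structure(data.frame(timestamp_s = t0, frame_id = seq_len(n)),
              class = c("frame_stream", "data.frame"))
  })
  list(a = mk(rate_a_fps, sub_seed(seed, 1)), b = mk(rate_b_fps, sub_seed(seed, 2)))
}
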