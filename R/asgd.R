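#' Configuration for affine registration by adaptive stochastic gradient descent
#'
#' The optimizer minimizes the mean squared intensity difference between the
#' fixed image and the warped moving image (both Gaussian-smoothed), over a
#' coarse-to-fine pyramid, drawing a fresh random batch of sample coordinates
#' at every iteration. The step size follows the adaptive gain schedule
#' `gamma_k = a / (A + t_k)^alpha`, where the "time" `t_k` grows when
#' successive stochastic gradients disagree (through a sigmoid of the
#' negative normalized inner product) and shrinks when they agree, so steps
#' stay large while progress is consistent.
#'
#' @param max_iters iterations per pyramid level.
#' @param samples_per_iter random sample coordinates per iteration (>= 16).
#' @param a,A,alpha gain schedule constants; `alpha` in (0.5, 1].
#' @param pyramid_levels number of resolution levels (level 0 is full size).
#' @param smooth_sigma Gaussian smoothing of the binary masks, pixels.
#' @param seed integer seed.
#' @export
asgd_config <- function(max_iters = 500, samples_per_iter = 2048,
                        a = 600, A = 20, alpha = 1,
                        pyramid_levels = 3, smooth_sigma = 2, seed = 0) {
  stopifnot(max_iters >= 1, samples_per_iter >= 16,
            alpha > 0.5, alpha <= 1, a > 0, A > 0, pyramid_levels >= 1)
  structure(list(max_iters = as.integer(max_iters),
                 samples_per_iter = as.integer(samples_per_iter),
                 a = a, A = A, alpha = alpha,
                 pyramid_levels = as.integer(pyramid_levels),
                 smooth_sigma = smooth_sigma, seed = as.integer(seed)),
            class = "asgd_config")
}

# 2x block-mean downsample (pads the last row/col by replication if odd)
downsample2 <- function(img) {
  H <- nrow(img); W <- ncol(img)
  if (H %% 2) img <- rbind(img, img[H, ]); H <- nrow(img)
  if (W %% 2) img <- cbind(img, img[, W]); W <- ncol(img)
  (img[seq(1, H, 2), seq(1, W, 2)] + img[seq(2, H, 2), seq(1, W, 2)] +
     img[seq(1, H, 2), seq(2, W, 2)] + img[seq(2, H, 2), seq(2, W, 2)]) / 4
}

# central-difference spatial gradient images
grad_images <- function(img) {
  H <- nrow(img); W <- ncol(img)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (img[, 3:W] - img[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (img[3:H, ] - img[1:(H - 2), ]) / 2
  list(gx = gx, gy = gy)
}

#' Affine registration by adaptive stochastic gradient descent
#'
#' Estimates the affine transform (six parameters: a 2x2 matrix and a
#' translation, about the fixed image center) that maps the moving mask onto
#' the fixed mask, by stochastic minimization of the mean squared difference
#' between the Gaussian-smoothed masks. Stochastic but fully reproducible
#' given the seed.
#'
#' @param moving,fixed binary masks (the moving mask may have a different
#'   resolution when an `init` transform mapping moving to fixed pixels is
#'   supplied).
#' @param cfg an [asgd_config()].
#' @param init optional initializing [transform2d] (moving to fixed pixels);
#'   defaults to the identity. If the initialized masks do not overlap at
#'   all the fit aborts and asks for pre-alignment (e.g. the GOT transform
#'   or an angular-scale plus center alignment).
#' @return list with `transform` (affine [transform2d], moving to fixed
#'   pixels), `cost_trace` (per-level final costs), and `n_iters`.
#' @export
estimate_affine_asgd <- function(moving, fixed, cfg = asgd_config(), init = NULL) {
  if (sum(moving) == 0 || sum(fixed) == 0) stop("ASGD needs nonempty masks")
  if (is.null(init)) init <- tf_identity()
  overlap <- sum(warp_mask(init, moving, c(ncol(fixed), nrow(fixed))) * fixed)
  # internally the warp is driven from the fixed frame: each sample x in the
  # fixed image reads the moving image at dT(init^{-1}(x)); the public
  # moving-to-fixed transform is recovered by inversion at the end
  inv_init <- tf_invert(init)
  if (overlap == 0)
    stop("initial masks do not overlap; pre-align first (e.g. GOT ",
         "initialization or angular-scale plus center alignment)")
  # each pyramid level is smoothed at its own scale (sigma in level pixels),
  # so coarse levels have proportionally wide capture ranges; the moving
  # image's sigma is widened by the inverse of the init scale so the two
  # boundary profiles share the same physical width after warping
  s_init <- sqrt(abs(det(init$matrix[1:2, 1:2])))
  nlev <- cfg$pyramid_levels
  movs <- vector("list", nlev); fixs <- vector("list", nlev)
  raw_m <- moving; raw_f <- fixed
  for (l in seq_len(nlev)) {
    movs[[l]] <- EBImage::gblur(raw_m, sigma = max(0.5, cfg$smooth_sigma / s_init))
    fixs[[l]] <- EBImage::gblur(raw_f, sigma = cfg$smooth_sigma)
    if (l < nlev) {
      raw_m <- downsample2(raw_m)
      raw_f <- downsample2(raw_f)
    }
  }
  center <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
  # the perturbation dT acts on init-mapped points, which live in the moving
  # frame; centering it on the image of the fixed-frame center (and scaling
  # by the mask radius in that frame) keeps the six parameters decoupled
  cen_mov <- as.numeric(apply_transform(inv_init, matrix(center, 1, 2)))
  Rscale <- max(1, sqrt(sum(fixed) / pi))
  mov_R_full <- Rscale / s_init
  q <- c(0, 0, 0, 0, 0, 0)   # (dA - I) * Rscale (4), dt (2)
  total_iters <- 0L
  cost_trace <- numeric(0)
  with_seed(cfg$seed, {
    for (lev in seq(nlev, 1)) {
      sc <- 2^(lev - 1)
      mv <- movs[[lev]]; fx <- fixs[[lev]]
      g <- grad_images(mv)
      lv_cmov <- cen_mov / sc
      lv_mR <- mov_R_full / sc
      # init transform expressed at this level's resolution
      lvl_tf <- function(q) {
        dA <- diag(2) + matrix(q[1:4], 2, 2) / lv_mR
        step_init <- tf_compose(tf_compose(tf_scaling(1 / sc), inv_init), tf_scaling(sc))
        tf_compose(tf_affine(dA, q[5:6], lv_cmov), step_init)
      }
      W <- ncol(fx); H <- nrow(fx)
      g_prev <- NULL
      tk <- 0
      for (it in seq_len(cfg$max_iters)) {
        xs <- stats::runif(cfg$samples_per_iter, 0, W - 1)
        ys <- stats::runif(cfg$samples_per_iter, 0, H - 1)
        tf <- lvl_tf(q)
        p <- apply_transform(tf, cbind(xs, ys))
        mval <- bilinear_sample(mv, p[, 1], p[, 2])
        fval <- bilinear_sample(fx, xs, ys)
        diff <- mval - fval
        gxv <- bilinear_sample(g$gx, p[, 1], p[, 2])
        gyv <- bilinear_sample(g$gy, p[, 1], p[, 2])
        # position of the samples in the dT input frame (after init)
        step_init <- tf_compose(tf_compose(tf_scaling(1 / sc), inv_init), tf_scaling(sc))
        y0 <- apply_transform(step_init, cbind(xs, ys))
        ux <- (y0[, 1] - lv_cmov[1]) / lv_mR
        uy <- (y0[, 2] - lv_cmov[2]) / lv_mR
        # parameter order follows column-major dA: (11, 21, 12, 22), then t
        gq <- 2 * c(mean(diff * gxv * ux), mean(diff * gyv * ux),
                    mean(diff * gxv * uy), mean(diff * gyv * uy),
                    mean(diff * gxv), mean(diff * gyv))
        if (!is.null(g_prev)) {
          nn <- sqrt(sum(gq^2)) * sqrt(sum(g_prev^2))
          x <- if (nn > 0) -sum(gq * g_prev) / nn else 0
          tk <- max(0, tk + sigmoid_time_step(x))
        }
        gamma <- cfg$a / (cfg$A + tk)^cfg$alpha
        q <- q - gamma * gq
        g_prev <- gq
        total_iters <- total_iters + 1L
      }
      tf <- lvl_tf(q)
      p_all <- apply_transform(tf, cbind(rep(0:(W - 1), each = H), rep(0:(H - 1), W)))
      cost_trace <- c(cost_trace,
                      mean((bilinear_sample(mv, p_all[, 1], p_all[, 2]) - as.numeric(fx))^2))
      # carry parameters to the next (finer) level: both the radius-scaled
      # matrix entries and the pixel translation double with resolution
      if (lev > 1) q <- q * 2
    }
  })
  dA <- diag(2) + matrix(q[1:4], 2, 2) / mov_R_full
  final <- tf_invert(tf_compose(tf_affine(dA, q[5:6], cen_mov), inv_init))
  list(transform = final, cost_trace = cost_trace, n_iters = total_iters)
}

# bounded sigmoid controlling the adaptive time update: agreement between
# successive gradients (x < 0) shrinks the time (larger steps), disagreement
# grows it
sigmoid_time_step <- function(x, f_min = -0.8, f_max = 1, omega = 0.15) {
  f_min + (f_max - f_min) / (1 + exp(-x / omega))
}
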