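#' Fit a visible-to-thermal registration
#'
#' The common front-end to the four estimators. Feature-based methods
#' (`"got"`, `"homography"`) consume checkerboard keypoint correspondences;
#' mask-based methods (`"icp"`, `"asgd"`) consume the two segmentation
#' masks. Returns a classed fit with `print`, `coef`, `predict` and `plot`
#' methods.
#'
#' @param method one of `"got"`, `"homography"`, `"icp"`, `"asgd"`.
#' @param moving,fixed binary masks (visible and thermal segmentations);
#'   required for `"icp"` and `"asgd"`.
#' @param correspondences a `correspondences` object over `kp_moving`,
#'   `kp_fixed`; required for `"got"` and `"homography"`.
#' @param kp_moving,kp_fixed `keypoint_set`s indexed by the correspondences.
#' @param rig list of the two [camera_model]s; required for `"got"` and as
#'   the pre-scaling source for `"icp"`/`"asgd"`.
#' @param cfg method configuration ([ransac_config()], [icp_config()] or
#'   [asgd_config()]); defaults per method.
#' @param init optional initializing transform for `"asgd"`; defaults to
#'   the rig's angular scaling plus image-center alignment.
#' @return an object of class `foot_registration`.
#' @export
register_images <- function(method = c("got", "homography", "icp", "asgd"),
                            moving = NULL, fixed = NULL,
                            correspondences = NULL, kp_moving = NULL,
                            kp_fixed = NULL, rig = NULL, cfg = NULL,
                            init = NULL) {
  method <- match.arg(method)
  details <- list()
  tf <- switch(method,
    got = {
      if (is.null(rig)) stop("GOT needs the camera rig")
      estimate_got(correspondences, kp_moving, kp_fixed, rig)
    },
    homography = {
      if (is.null(correspondences)) stop("homography needs correspondences")
      cp <- corr_points(correspondences, kp_moving, kp_fixed)
      fit <- homography_ransac(cp$src, cp$dst,
                               cfg %||% ransac_config())
      details$inliers <- fit$inliers
      details$n_pairs <- nrow(correspondences)
      fit$transform
    },
    icp = {
      if (is.null(moving) || is.null(fixed)) stop("ICP needs both masks")
      pre <- if (!is.null(rig)) angular_scale(rig$visible, rig$thermal)
             else tf_identity()
      fit <- estimate_icp(moving, fixed, pre_scale = pre,
                          cfg = cfg %||% icp_config())
      details$rmse <- fit$rmse
      details$rmse_trace <- fit$rmse_trace
      details$converged <- fit$converged
      fit$transform
    },
    asgd = {
      if (is.null(moving) || is.null(fixed)) stop("ASGD needs both masks")
      if (is.null(init) && !is.null(rig)) init <- center_align_init(rig)
      fit <- estimate_affine_asgd(moving, fixed,
                                  cfg = cfg %||% asgd_config(), init = init)
      details$cost_trace <- fit$cost_trace
      fit$transform
    })
  structure(list(method = method, transform = tf, details = details,
                 moving = moving, fixed = fixed, call = match.call()),
            class = "foot_registration")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.foot_registration <- function(x, ...) {
  cat("Registration fit, method:", x$method, "\n")
  print(x$transform)
  if (!is.null(x$details$rmse))
    cat(sprintf("final contour RMSE: %.4f px (%d iterations, %s)\n",
                x$details$rmse, length(x$details$rmse_trace),
                if (x$details$converged) "converged" else "not converged"))
  if (!is.null(x$details$inliers))
    cat(sprintf("RANSAC inliers: %d / %d pairs\n",
                length(x$details$inliers), x$details$n_pairs))
  invisible(x)
}

#' @export
coef.foot_registration <- function(object, ...) {
  m <- object$transform$matrix
  stats::setNames(as.numeric(t(m[1:3, ])),
                  c("h11", "h12", "h13", "h21", "h22", "h23", "h31", "h32", "h33"))
}

#' Apply a fitted registration to points or a mask
#'
#' @param object a `foot_registration`.
#' @param newdata an n x 2 point matrix, or a binary mask matrix.
#' @param out_shape (width, height) of the output frame for mask warping;
#'   defaults to the fixed mask's shape.
#' @param ... unused.
#' @export
predict.foot_registration <- function(object, newdata,
                                      out_shape = NULL, ...) {
  if (is.matrix(newdata) && ncol(newdata) == 2 && !all(newdata %in% c(0, 1)))
    return(apply_transform(object$transform, newdata))
  if (is.matrix(newdata) && all(newdata %in% c(0, 1)) && !is.null(dim(newdata))) {
    if (is.null(out_shape))
      out_shape <- if (!is.null(object$fixed))
        c(ncol(object$fixed), nrow(object$fixed)) else c(ncol(newdata), nrow(newdata))
    return(warp_mask(object$transform, newdata, out_shape))
  }
  apply_transform(object$transform, newdata)
}

#' Plot a registration fit as a mask overlay
#'
#' Shows the fixed mask with the registered moving mask's contour on top.
#'
#' @param x a `foot_registration` fitted from masks.
#' @param ... passed to [graphics::image()].
#' @export
plot.foot_registration <- function(x, ...) {
  if (is.null(x$fixed) || is.null(x$moving))
    stop("plotting needs a fit made from masks")
  warped <- warp_mask(x$transform, x$moving, c(ncol(x$fixed), nrow(x$fixed)))
  comp <- x$fixed + 2 * warped   # 0 bg, 1 fixed only, 2 moving only, 3 overlap
  graphics::image(t(comp)[, nrow(comp):1], col = c("white", "steelblue",
                                                   "indianred", "grey30"),
                  axes = FALSE, asp = nrow(comp) / ncol(comp), ...)
  invisible(x)
}
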