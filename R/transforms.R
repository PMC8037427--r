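#' Planar homogeneous transforms
#'
#' A `transform2d` is a 3x3 homogeneous matrix tagged with its model class
#' (`"translation"`, `"rigid"`, `"affine"` or `"homography"`) and, for the
#' centered models, the rotation center in pixels. All coordinates are
#' 0-based pixel-center coordinates, x rightward (columns), y downward (rows).
#'
#' The four model classes correspond to the four registration estimators:
#' a pure translation `x + t`, a rigid motion `R(x - c) + t + c` with proper
#' orthonormal `R`, an unrestricted affine `A(x - c) + t + c`, and a full
#' projective homography with 8 free parameters (normalized so the bottom-right
#' entry is 1).
#'
#' @param matrix numeric 3x3 homogeneous matrix.
#' @param model one of `"translation"`, `"rigid"`, `"affine"`, `"homography"`.
#' @param center length-2 rotation center (pixels); informational for
#'   translation/homography.
#' @return an object of class `transform2d`.
#' @export
transform2d <- function(matrix, model = c("affine", "translation", "rigid", "homography"),
                        center = c(0, 0)) {
  model <- match.arg(model)
  matrix <- base::matrix(as.numeric(matrix), 3L, 3L)
  if (!all(is.finite(matrix))) stop("transform matrix must be finite")
  if (model == "homography") {
    if (abs(matrix[3L, 3L]) < 1e-14) stop("homography matrix has vanishing scale entry")
    matrix <- matrix / matrix[3L, 3L]
  } else {
    if (max(abs(matrix[3L, ] - c(0, 0, 1))) > 1e-9)
      stop("bottom row must be [0, 0, 1] for model '", model, "'")
    matrix[3L, ] <- c(0, 0, 1)
  }
  if (model == "rigid") {
    R <- matrix[1:2, 1:2]
    if (max(abs(crossprod(R) - diag(2))) > 1e-8 || det(R) < 0)
      stop("rigid model requires a proper orthonormal 2x2 block")
  }
  if (abs(det(matrix)) < 1e-14) stop("transform matrix is singular")
  structure(list(matrix = matrix, model = model, center = as.numeric(center)),
            class = "transform2d")
}

model_rank <- c(translation = 1L, rigid = 2L, affine = 3L, homography = 4L)

#' @export
print.transform2d <- function(x, ...) {
  cat("<transform2d> model:", x$model, "\n")
  print(round(x$matrix, 6))
  if (any(x$center != 0)) cat("center:", paste(round(x$center, 3), collapse = ", "), "\n")
  invisible(x)
}

#' Identity transform
#' @return a translation-model `transform2d` equal to the identity.
#' @export
tf_identity <- function() transform2d(diag(3), "translation")

#' Pure translation
#' @param tx,ty translation in pixels.
#' @export
tf_translation <- function(tx, ty) {
  m <- diag(3); m[1, 3] <- tx; m[2, 3] <- ty
  transform2d(m, "translation")
}

#' Rigid motion about a center
#'
#' `x -> R(x - c) + t + c` with `R` the rotation by `theta` (radians,
#' counter-clockwise in the x-right / y-down pixel frame this is a clockwise
#' rotation on screen; the convention only has to be self-consistent).
#'
#' @param theta rotation angle in radians.
#' @param t length-2 translation (pixels).
#' @param center length-2 rotation center (pixels).
#' @export
tf_rigid <- function(theta, t = c(0, 0), center = c(0, 0)) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  m <- diag(3)
  m[1:2, 1:2] <- R
  m[1:2, 3] <- -R %*% center + t + center
  transform2d(m, "rigid", center = center)
}

#' Affine transform about a center
#' @param A 2x2 matrix.
#' @param t length-2 translation (pixels).
#' @param center length-2 center (pixels).
#' @export
tf_affine <- function(A, t = c(0, 0), center = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  m <- diag(3)
  m[1:2, 1:2] <- A
  m[1:2, 3] <- -A %*% center + t + center
  transform2d(m, "affine", center = center)
}

#' Axis-wise scaling about the origin
#' @param sx,sy scale factors.
#' @export
tf_scaling <- function(sx, sy = sx) {
  transform2d(diag(c(sx, sy, 1)), "affine")
}

#' Homography from a 3x3 matrix
#' @param H 3x3 matrix, normalized internally so `H[3,3] = 1`.
#' @export
tf_homography <- function(H) transform2d(H, "homography")

#' Apply a transform to points
#'
#' Homogeneous multiply followed by perspective division. For non-homography
#' models the division is by exactly 1.
#'
#' @param tf a [transform2d].
#' @param pts n x 2 matrix of (x, y) pixel coordinates.
#' @return n x 2 matrix of transformed coordinates.
#' @export
apply_transform <- function(tf, pts) {
  stopifnot(inherits(tf, "transform2d"))
  pts <- rbind2col(pts)
  if (!all(is.finite(pts))) stop("points must be finite")
  h <- tf$matrix %*% rbind(t(pts), 1)
  w <- h[3L, ]
  bad <- which(abs(w) < 1e-12)
  if (length(bad))
    stop("homogeneous coordinate vanishes at point index ", bad[1L],
         " (", pts[bad[1L], 1L], ", ", pts[bad[1L], 2L], ")")
  cbind(x = h[1L, ] / w, y = h[2L, ] / w)
}

# accept vectors/data.frames, always return an n x 2 numeric matrix
rbind2col <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(as.numeric(pts), ncol = 2L, byrow = FALSE,
                                       nrow = length(pts) / 2L)
  pts <- as.matrix(pts)
  stopifnot(ncol(pts) == 2L)
  storage.mode(pts) <- "double"
  pts
}

#' Compose two transforms
#'
#' `tf_compose(A, B)` applies `B` first: `(A o B)(x) = A(B(x))`. The result's
#' model class is the least restrictive of the operands.
#'
#' @param a,b [transform2d] objects.
#' @export
tf_compose <- function(a, b) {
  stopifnot(inherits(a, "transform2d"), inherits(b, "transform2d"))
  m <- a$matrix %*% b$matrix
  model <- names(model_rank)[max(model_rank[a$model], model_rank[b$model])]
  center <- if (model_rank[a$model] >= model_rank[b$model]) a$center else b$center
  transform2d(m, model, center = center)
}

#' Invert a transform
#' @param tf a [transform2d].
#' @export
tf_invert <- function(tf) {
  stopifnot(inherits(tf, "transform2d"))
  m <- tryCatch(solve(tf$matrix), error = function(e) stop("transform is singular"))
  transform2d(m, tf$model, center = tf$center)
}

#' Angular-resolution matching scale between two cameras
#'
#' Returns the axis-wise scaling that equalizes degrees-per-pixel between a
#' source and destination camera: `sx = (hfov_src/width_src) / (hfov_dst/width_dst)`
#' and analogously for y. This is the fixed scaling step of the geometric
#' optical translation method and the pre-scaling handed to ICP.
#'
#' @param cam_src,cam_dst [camera_model] objects.
#' @return an affine-model scaling [transform2d].
#' @export
angular_scale <- function(cam_src, cam_dst) {
  stopifnot(inherits(cam_src, "camera_model"), inherits(cam_dst, "camera_model"))
  sx <- (cam_src$hfov_deg / cam_src$width_px) / (cam_dst$hfov_deg / cam_dst$width_px)
  sy <- (cam_src$vfov_deg / cam_src$height_px) / (cam_dst$vfov_deg / cam_dst$height_px)
  tf_scaling(sx, sy)
}

#' Re-express a transform in a cropped output window
#'
#' Composes `tf` with a translation so that coordinates are relative to a
#' window whose top-left corner sits at `offset` in the old output frame.
#' Pure bookkeeping on the homogeneous matrix; `dst_shape` is carried along
#' as the output frame size attribute.
#'
#' @param tf a [transform2d].
#' @param dst_shape length-2 (width, height) of the output window, pixels.
#' @param offset length-2 (dx, dy) of the window corner in the old frame.
#' @export
crop_to <- function(tf, dst_shape, offset = c(0, 0)) {
  out <- tf_compose(tf_translation(-offset[1L], -offset[2L]), tf)
  attr(out, "out_shape") <- as.integer(dst_shape)
  out
}

#' Warp a binary mask through a transform
#'
#' Inverse-mapping warp: every output pixel samples the source mask at
#' `tf^{-1}(pixel)` with nearest-neighbour interpolation (preserving
#' binariness exactly); out-of-bounds samples are 0.
#'
#' @param tf the forward source-to-output [transform2d]; must be invertible.
#' @param src binary mask matrix (rows = y, cols = x, values in {0, 1}).
#' @param out_shape length-2 (width, height) of the output, pixels.
#' @return a binary mask matrix of dimension `(height, width)`.
#' @export
warp_mask <- function(tf, src, out_shape = c(ncol(src), nrow(src))) {
  uv <- inverse_grid(tf, out_shape)
  j <- round(uv$x) + 1L
  i <- round(uv$y) + 1L
  ok <- i >= 1L & i <= nrow(src) & j >= 1L & j <= ncol(src)
  out <- numeric(length(ok))
  out[ok] <- src[cbind(i[ok], j[ok])]
  matrix(out, nrow = out_shape[2L], ncol = out_shape[1L])
}

#' Warp an intensity image through a transform (bilinear)
#'
#' @inheritParams warp_mask
#' @param src intensity image matrix.
#' @export
warp_image <- function(tf, src, out_shape = c(ncol(src), nrow(src))) {
  uv <- inverse_grid(tf, out_shape)
  bilinear_sample(src, uv$x, uv$y, out_shape)
}

inverse_grid <- function(tf, out_shape) {
  stopifnot(inherits(tf, "transform2d"))
  W <- as.integer(out_shape[1L]); H <- as.integer(out_shape[2L])
  stopifnot(W > 0L, H > 0L)
  minv <- tryCatch(solve(tf$matrix), error = function(e)
    stop("transform is not invertible"))
  x <- rep(0:(W - 1L), each = H)       # column-major over the output matrix
  y <- rep(0:(H - 1L), times = W)
  u <- minv[1, 1] * x + minv[1, 2] * y + minv[1, 3]
  v <- minv[2, 1] * x + minv[2, 2] * y + minv[2, 3]
  w <- minv[3, 1] * x + minv[3, 2] * y + minv[3, 3]
  list(x = u / w, y = v / w)
}

bilinear_sample <- function(src, xs, ys, out_shape = NULL) {
  H <- nrow(src); W <- ncol(src)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  val <- numeric(length(xs))
  get <- function(ii, jj) {
    ok <- ii >= 0 & ii <= (H - 1) & jj >= 0 & jj <= (W - 1)
    g <- numeric(length(ii))
    g[ok] <- src[cbind(ii[ok] + 1L, jj[ok] + 1L)]
    g
  }
  val <- (1 - fx) * (1 - fy) * get(y0, x0) +
    fx * (1 - fy) * get(y0, x0 + 1) +
    (1 - fx) * fy * get(y0 + 1, x0) +
    fx * fy * get(y0 + 1, x0 + 1)
  if (is.null(out_shape)) val else matrix(val, nrow = out_shape[2L], ncol = out_shape[1L])
}

#' Serialize / deserialize a transform as JSON
#'
#' @param tf a [transform2d].
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @export
tf_to_json <- function(tf, path = NULL) {
  stopifnot(inherits(tf, "transform2d"))
  obj <- list(model = tf$model,
              matrix = unname(apply(tf$matrix, 1, as.numeric, simplify = FALSE)),
              center = as.numeric(tf$center))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname tf_to_json
#' @param json a JSON string or file path produced by [tf_to_json()].
#' @export
tf_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  m <- obj$matrix
  if (is.list(m)) m <- do.call(rbind, m)
  transform2d(m, model = obj$model, center = obj$center)
}
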