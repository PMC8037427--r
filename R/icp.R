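#' Extract equally spaced contour keypoints from a mask
#'
#' Boundary pixels are the morphological gradient (mask minus its 3x3
#' erosion). Each closed contour is traced in order (Moore neighbourhood
#' tracing), and `n` keypoints are sampled at equal arc-length steps,
#' allocated to contours proportionally to their perimeter. If `n` meets or
#' exceeds the total boundary pixel count, every boundary pixel is returned
#' once. Deterministic.
#'
#' @param mask binary mask matrix.
#' @param n number of keypoints, at least 3.
#' @return a `keypoint_set` (n x 2 matrix of 0-based pixel coordinates).
#' @export
extract_contour_keypoints <- function(mask, n = 200) {
  if (sum(mask) == 0) stop("cannot extract contours from an empty mask")
  stopifnot(n >= 3)
  contours <- trace_contours(mask)
  lens <- vapply(contours, function(cc) attr(cc, "arc_length"), numeric(1))
  npts <- vapply(contours, nrow, integer(1))
  total_px <- sum(npts)
  if (n >= total_px) {
    pts <- do.call(rbind, lapply(contours, function(cc) cc[, , drop = FALSE]))
  } else {
    alloc <- pmax(1L, round(n * lens / sum(lens)))
    # trim the largest allocations until the total matches n
    while (sum(alloc) > n) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
    while (sum(alloc) < n) alloc[which.max(lens / alloc)] <- alloc[which.max(lens / alloc)] + 1L
    pts <- do.call(rbind, Map(function(cc, k) {
      s <- attr(cc, "arc_pos")
      L <- attr(cc, "arc_length")
      targets <- (seq_len(k) - 1L) * L / k
      idx <- findInterval(targets, s)
      cc[pmax(1L, idx), , drop = FALSE]
    }, contours, as.list(alloc)))
  }
  pts <- unique(pts)
  colnames(pts) <- c("x", "y")
  structure(pts, image_shape = c(ncol(mask), nrow(mask)), class = "keypoint_set")
}

# Moore-neighbour contour tracing of every connected component's outer
# boundary. Returns a list of m x 2 coordinate matrices (0-based x, y) in
# traversal order, with cumulative arc position and total arc length
# (diagonal steps count sqrt(2)) as attributes.
trace_contours <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  ncomp <- max(lab)
  H <- nrow(mask); W <- ncol(mask)
  # clockwise Moore neighbourhood, starting from W and going around
  dj <- c(-1L, -1L, 0L, 1L, 1L, 1L, 0L, -1L)
  di <- c(0L, -1L, -1L, -1L, 0L, 1L, 1L, 1L)
  out <- vector("list", ncomp)
  for (comp in seq_len(ncomp)) {
    idx <- which(lab == comp)
    # topmost then leftmost pixel of the component
    ii <- (idx - 1L) %% H; jj <- (idx - 1L) %/% H
    o <- order(ii, jj)
    i0 <- ii[o[1L]]; j0 <- jj[o[1L]]
    inside <- function(i, j) i >= 0L && i < H && j >= 0L && j < W && lab[i + 1L, j + 1L] == comp
    nmax <- 8L * length(idx) + 16L
    path_i <- integer(nmax); path_j <- integer(nmax)
    np <- 0L
    ci <- i0; cj <- j0
    bi <- i0 - 1L; bj <- j0         # backtrack: the row above the topmost
    seen <- new.env(hash = TRUE, parent = emptyenv())  # pixel is background
    cycle_from <- 1L
    repeat {
      # the traversal is a deterministic function of (pixel, backtrack);
      # a repeated state marks one full tour of the boundary
      key <- paste0(ci, ",", cj, "|", bi, ",", bj)
      prev <- seen[[key]]
      if (!is.null(prev)) {
        cycle_from <- prev
        break
      }
      np <- np + 1L
      seen[[key]] <- np
      path_i[np] <- ci; path_j[np] <- cj
      # scan the Moore neighbourhood clockwise starting just past the
      # backtrack pixel; the first foreground pixel is the next boundary
      # pixel and the background pixel scanned before it the new backtrack
      bidx <- which(di == bi - ci & dj == bj - cj) - 1L
      found <- FALSE
      for (step in 1:8) {
        d <- (bidx + step) %% 8L
        ni <- ci + di[d + 1L]; nj <- cj + dj[d + 1L]
        if (inside(ni, nj)) {
          found <- TRUE
          break
        }
        bi <- ni; bj <- nj
      }
      if (!found) break   # isolated pixel: path is just the start
      ci <- ni; cj <- nj
      if (np >= nmax) break   # safety stop
    }
    keep <- seq.int(cycle_from, max(np, cycle_from))
    cc <- cbind(x = path_j[keep], y = path_i[keep])
    steps <- if (nrow(cc) > 1L)
      sqrt(rowSums((cc - rbind(cc[-1L, , drop = FALSE], cc[1L, , drop = FALSE]))^2))
    else 1
    arc_pos <- c(0, cumsum(steps))[seq_len(nrow(cc))]
    attr(cc, "arc_pos") <- arc_pos
    attr(cc, "arc_length") <- sum(steps)
    out[[comp]] <- cc
  }
  out[order(-vapply(out, function(cc) attr(cc, "arc_length"), numeric(1)))]
}

#' Configuration for contour ICP
#'
#' @param n_keypoints contour keypoints sampled per mask (>= 3). The default
#'   of 400 keeps the arc spacing of the sampled contour near 3 px on a
#'   384x288 foot mask; much sparser sampling quantizes the nearest-neighbour
#'   correspondences and leaves a fraction-of-a-pixel bias in the recovered
#'   translation.
#' @param max_iters iteration cap.
#' @param rmse_tol convergence tolerance on the RMSE decrease, pixels.
#' @param seed integer seed (ICP itself is deterministic; kept for interface
#'   uniformity).
#' @export
icp_config <- function(n_keypoints = 400, max_iters = 100, rmse_tol = 1e-6, seed = 0) {
  stopifnot(n_keypoints >= 3, max_iters >= 1, rmse_tol > 0)
  structure(list(n_keypoints = as.integer(n_keypoints),
                 max_iters = as.integer(max_iters),
                 rmse_tol = rmse_tol, seed = as.integer(seed)),
            class = "icp_config")
}

# closed-form rigid fit src -> dst (cross-covariance SVD with reflection
# correction), rotation expressed about a fixed center
rigid_fit <- function(src, dst, center) {
  ms <- colMeans(src); md <- colMeans(dst)
  Sm <- crossprod(sweep(src, 2, ms), sweep(dst, 2, md))
  sv <- svd(Sm)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, d)) %*% t(sv$u)
  t_free <- md - as.numeric(R %*% ms)
  # convert x -> Rx + t_free into the centered form R(x - c) + t + c
  t_cen <- t_free + as.numeric(R %*% center) - center
  theta <- atan2(R[2, 1], R[1, 1])
  tf_rigid(theta, t_cen, center)
}

#' Rigid registration of mask contours by iterative closest point
#'
#' Extracts equally spaced contour keypoints from both masks, applies the
#' fixed angular pre-scaling to the moving (visible) keypoints, pre-aligns
#' centroids, then alternates exact nearest-neighbour correspondence (ties
#' broken by the smallest target index) with a closed-form rigid fit about
#' the thermal image center until the RMSE decrease falls below `rmse_tol`
#' or `max_iters` is reached. The RMSE sequence is non-increasing.
#'
#' @param vis_mask moving (visible) binary mask.
#' @param ir_mask fixed (thermal) binary mask.
#' @param pre_scale fixed scaling [transform2d] from [angular_scale()]
#'   handling any resolution difference; ICP itself is scale-free.
#' @param cfg an [icp_config()].
#' @return list with `transform` (rigid o pre_scale, visible to thermal
#'   pixels), `rmse` (final value), `rmse_trace`, `n_iters`, `converged`.
#' @export
estimate_icp <- function(vis_mask, ir_mask, pre_scale = tf_identity(),
                         cfg = icp_config()) {
  if (sum(vis_mask) == 0 || sum(ir_mask) == 0) stop("ICP needs nonempty masks")
  src0 <- unclass(extract_contour_keypoints(vis_mask, cfg$n_keypoints))
  dst <- unclass(extract_contour_keypoints(ir_mask, cfg$n_keypoints))
  src <- apply_transform(pre_scale, src0)
  center <- c((ncol(ir_mask) - 1) / 2, (nrow(ir_mask) - 1) / 2)
  # centroid pre-alignment as the initial translation
  t0 <- colMeans(dst) - colMeans(src)
  cur <- tf_translation(t0[1], t0[2])
  rmse_trace <- numeric(0)
  prev_rmse <- Inf
  converged <- FALSE
  for (it in seq_len(cfg$max_iters)) {
    moved <- apply_transform(cur, src)
    nn <- nearest_target(moved, dst)
    fit <- rigid_fit(src, dst[nn, , drop = FALSE], center)
    moved2 <- apply_transform(fit, src)
    rmse <- sqrt(mean(rowSums((moved2 - dst[nn, , drop = FALSE])^2)))
    rmse_trace <- c(rmse_trace, rmse)
    cur <- fit
    if (is.finite(prev_rmse) && abs(prev_rmse - rmse) < cfg$rmse_tol) {
      converged <- TRUE
      break
    }
    prev_rmse <- rmse
  }
  list(transform = tf_compose(cur, pre_scale), rmse = rmse_trace[length(rmse_trace)],
       rmse_trace = rmse_trace, n_iters = length(rmse_trace), converged = converged)
}

# exact nearest neighbour of each query row among target rows; ties go to the
# smallest target index (which.min's convention)
nearest_target <- function(query, target) {
  d2 <- outer(rowSums(query^2), rep(1, nrow(target))) +
    outer(rep(1, nrow(query)), rowSums(target^2)) -
    2 * query %*% t(target)
  max.col(-d2, ties.method = "first")
}
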