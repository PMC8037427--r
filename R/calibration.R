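#' Detect blob keypoints in a calibration image
#'
#' Otsu-thresholds the image, labels connected components of the requested
#' polarity, filters them by pixel area and returns one sub-pixel centroid
#' per surviving component (intensity-weighted by contrast above the
#' threshold). Fully deterministic; an image with no blobs yields an empty
#' keypoint set, not an error.
#'
#' @param img intensity image matrix with values in [0, 1].
#' @param min_area_px,max_area_px inclusive component area filter, pixels.
#' @param polarity `"bright"` for blobs brighter than background (visible
#'   checkerboard), `"dark"` for cold/dark blobs (thermal checkerboard).
#' @return a `keypoint_set`: n x 2 matrix of (x, y) centroids with the source
#'   image shape attached as attribute `image_shape` (width, height).
#' @export
detect_blobs <- function(img, min_area_px = 5, max_area_px = 5000,
                         polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  stopifnot(min_area_px > 0, min_area_px < max_area_px)
  work <- if (polarity == "dark") 1 - img else img
  work <- pmin(pmax(work, 0), 1)
  thr <- EBImage::otsu(work, range = c(0, 1))
  bw <- work > thr
  lab <- EBImage::bwlabel(bw)
  pts <- matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y")))
  nlab <- max(lab)
  if (nlab > 0) {
    idx <- which(lab > 0)
    lv <- lab[idx]
    area <- tabulate(lv, nbins = nlab)
    keep <- which(area >= min_area_px & area <= max_area_px)
    if (length(keep)) {
      wgt <- work[idx] - thr                     # contrast-weighted centroid
      ii <- (idx - 1L) %% nrow(img)              # 0-based row (y)
      jj <- (idx - 1L) %/% nrow(img)             # 0-based col (x)
      sw <- rowsum(wgt, lv)[, 1]
      sx <- rowsum(wgt * jj, lv)[, 1] / sw
      sy <- rowsum(wgt * ii, lv)[, 1] / sw
      ord <- sort(keep)
      pts <- cbind(x = sx[ord], y = sy[ord])
      rownames(pts) <- NULL
    }
  }
  structure(pts, image_shape = c(ncol(img), nrow(img)), class = "keypoint_set")
}

#' @export
print.keypoint_set <- function(x, ...) {
  cat("<keypoint_set>", nrow(x), "points in a",
      paste(attr(x, "image_shape"), collapse = " x "), "image\n")
  if (nrow(x)) print(utils::head(round(unclass(x), 3), 5))
  invisible(x)
}

# in-plane board rotation estimated from nearest-neighbour step directions,
# folded modulo 90 degrees (the lattice has two equivalent axes); the median
# is robust to a few outlier detections
lattice_rotation <- function(pts) {
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  nn <- apply(D, 1, which.min)
  d <- pts[nn, , drop = FALSE] - pts
  ang <- atan2(d[, 2], d[, 1])
  stats::median(((ang + pi / 4) %% (pi / 2)) - pi / 4)
}

#' Pair checkerboard keypoints across the two spectra
#'
#' Sorts each detected keypoint set onto the known `rows` x `cols` lattice
#' (row-major, by y then x, after removing any small in-plane board rotation
#' estimated from the principal axes) and pairs keypoints occupying the same
#' lattice cell. Extra detections far from the lattice remain unpaired; a
#' lattice that cannot be completed raises an error naming the deficient
#' rows. Board rotations beyond 5 degrees are rejected: the rig is fixed.
#'
#' @param a,b `keypoint_set`s (e.g. visible and thermal detections).
#' @param rows,cols lattice dimensions.
#' @return a `correspondences` object: integer matrix with columns
#'   `src_idx`, `dst_idx` (1-based indices into `a` and `b`).
#' @export
pair_grid_keypoints <- function(a, b, rows, cols) {
  stopifnot(rows >= 2, cols >= 2)
  if (nrow(a) < rows * cols || nrow(b) < rows * cols)
    stop("need at least rows x cols = ", rows * cols, " keypoints in each set")
  ia <- lattice_index(a, rows, cols, "first")
  ib <- lattice_index(b, rows, cols, "second")
  key_a <- ia$cell_row * cols + ia$cell_col    # lattice cell id per kept point
  key_b <- ib$cell_row * cols + ib$cell_col
  m <- match(key_a, key_b)
  ok <- !is.na(m)
  pairs <- cbind(src_idx = ia$index[ok], dst_idx = ib$index[m[ok]])
  structure(pairs, class = "correspondences")
}

#' @export
print.correspondences <- function(x, ...) {
  cat("<correspondences>", nrow(x), "pairs\n")
  invisible(x)
}

# Assign points to lattice cells. Robust to outliers: 1-D cluster rows by
# sorted-gap cutting, keep clusters populated by at least half a row/column,
# then snap points to the nearest (row, col) center and keep the closest
# candidate per cell.
lattice_index <- function(pts, rows, cols, which_set) {
  th <- lattice_rotation(unclass(pts))
  if (abs(th) > 5 * pi / 180)
    stop("board rotation of ", round(th * 180 / pi, 1),
         " degrees exceeds the 5 degree tolerance in set ", which_set)
  R <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
  q <- unclass(pts) %*% t(R)
  # robust lattice spacing: most points are lattice points, whose nearest
  # neighbour sits one grid step away
  D <- as.matrix(stats::dist(q))
  diag(D) <- Inf
  spacing <- stats::median(apply(D, 1, min))
  centers_1d <- function(vals, k, min_count, axis) {
    v <- sort(vals)
    cuts <- which(diff(v) > spacing / 2)
    grp <- rep(seq_len(length(cuts) + 1L), diff(c(0L, cuts, length(v))))
    counts <- tabulate(grp)
    keep <- which(counts >= min_count)
    if (length(keep) < k)
      stop("cannot form a complete lattice along ", axis, " in set ", which_set,
           ": found ", length(keep), " populated lines, need ", k)
    if (length(keep) > k) keep <- keep[order(counts[keep], decreasing = TRUE)[seq_len(k)]]
    sort(vapply(keep, function(g) stats::median(v[grp == g]), numeric(1)))
  }
  rc <- centers_1d(q[, 2], rows, max(2, floor(cols / 2)), "y")
  cc <- centers_1d(q[, 1], cols, max(2, floor(rows / 2)), "x")
  row_sp <- if (rows > 1) stats::median(diff(rc)) else Inf
  col_sp <- if (cols > 1) stats::median(diff(cc)) else Inf
  tol <- 0.35 * min(row_sp, col_sp)
  ri <- vapply(q[, 2], function(y) which.min(abs(rc - y)), integer(1))
  ci <- vapply(q[, 1], function(x) which.min(abs(cc - x)), integer(1))
  dist <- sqrt((q[, 2] - rc[ri])^2 + (q[, 1] - cc[ci])^2)
  cand <- which(abs(q[, 2] - rc[ri]) < tol & abs(q[, 1] - cc[ci]) < tol)
  if (!length(cand)) stop("no keypoints near the lattice in set ", which_set)
  cell <- (ri[cand] - 1L) * cols + ci[cand]
  # keep the nearest candidate per cell
  best <- cand[order(cell, dist[cand])]
  cell_sorted <- cell[order(cell, dist[cand])]
  first <- !duplicated(cell_sorted)
  kept <- best[first]
  cells <- cell_sorted[first]
  have <- tabulate((cells - 1L) %/% cols + 1L, nbins = rows)
  if (any(have < cols)) {
    miss <- which(have < cols)
    stop("cannot form a complete lattice in set ", which_set,
         ": deficient row(s) ", paste(miss, collapse = ", "))
  }
  list(index = kept,
       cell_row = (cells - 1L) %/% cols,
       cell_col = (cells - 1L) %% cols)
}

# gather matched point coordinates for a correspondence set
corr_points <- function(corr, kp_src, kp_dst) {
  list(src = unclass(kp_src)[corr[, 1L], , drop = FALSE],
       dst = unclass(kp_dst)[corr[, 2L], , drop = FALSE])
}
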