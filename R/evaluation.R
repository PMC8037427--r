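#' Overlap metrics between a registered mask and a reference mask
#'
#' With `TP` the overlap pixel count, `FN` the reference pixels missed and
#' `FP` the test pixels outside the reference:
#' Dice `= 2TP / (2TP + FN + FP)`, Jaccard `= TP / (TP + FN + FP)`,
#' volume similarity `= 2(|test| - |ref|) / (|test| + |ref|)` (signed),
#' and the false-negative / false-positive fractions `FN / |ref|`,
#' `FP / |ref|` (both normalized by the reference volume, which reproduces
#' the magnitude regime of registration overlap studies).
#'
#' @param test registered binary mask.
#' @param ref reference binary mask, same shape, nonempty.
#' @return an `overlap_report`: list with `dice`, `jaccard`,
#'   `volume_similarity`, `fn_fraction`, `fp_fraction`, `n_ref_px`,
#'   `n_test_px`.
#' @export
overlap_metrics <- function(test, ref) {
  if (!identical(dim(test), dim(ref))) stop("mask shapes differ")
  nref <- sum(ref == 1)
  if (nref == 0) stop("reference mask is empty")
  ntest <- sum(test == 1)
  tp <- sum(test == 1 & ref == 1)
  fn <- nref - tp
  fp <- ntest - tp
  structure(list(dice = 2 * tp / (2 * tp + fn + fp),
                 jaccard = tp / (tp + fn + fp),
                 volume_similarity = 2 * (ntest - nref) / (ntest + nref),
                 fn_fraction = fn / nref,
                 fp_fraction = fp / nref,
                 n_ref_px = nref, n_test_px = ntest),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("dice %.4f  jaccard %.4f  vol.sim %+.4f  fn %.4f  fp %.4f\n",
              x$dice, x$jaccard, x$volume_similarity, x$fn_fraction, x$fp_fraction))
  invisible(x)
}

#' Working-distance robustness experiment
#'
#' Mirrors the distance study: transforms are estimated once from focal-plane
#' (800 mm) data — GOT and homography from the checkerboard correspondences,
#' ICP and affine-ASGD from the focal-plane reference masks — and the fixed
#' transforms are then applied to the visible reference mask at every
#' distance, scoring the result against that distance's thermal reference
#' mask in the thermal frame.
#'
#' @param bundles list of `scene_bundle`s; exactly one must sit at the focal
#'   plane (800 mm by default).
#' @param calib a `checkerboard_scene` rendered at the focal plane.
#' @param rig list of the two [camera_model]s.
#' @param methods subset of `c("got", "homography", "icp", "asgd")`.
#' @param masks optional list (same length as `bundles`) of
#'   `list(visible =, thermal =)` reference masks, e.g. STAPLE-fused rater
#'   segmentations; defaults to the bundles' clean masks.
#' @param ransac,icp,asgd method configurations.
#' @param focal_mm the focal-plane distance.
#' @return a `robustness_table` data frame with columns `metric`,
#'   `distance_mm`, `method`, `value`, plus a `transforms` attribute.
#' @export
run_distance_experiment <- function(bundles, calib, rig,
                                    methods = c("got", "homography", "icp", "asgd"),
                                    masks = NULL,
                                    ransac = ransac_config(),
                                    icp = icp_config(),
                                    asgd = asgd_config(),
                                    focal_mm = 800) {
  dists <- vapply(bundles, function(b) b$distance_mm, numeric(1))
  i_fp <- which(abs(dists - focal_mm) < 1e-9)
  if (length(i_fp) != 1)
    stop("need exactly one bundle at the focal plane (", focal_mm, " mm)")
  if (is.null(masks))
    masks <- lapply(bundles, function(b) list(visible = b$visible_mask,
                                              thermal = b$thermal_mask))
  methods <- match.arg(methods, several.ok = TRUE)
  tfs <- estimate_all_methods(calib, rig, masks[[i_fp]], methods,
                              ransac = ransac, icp = icp, asgd = asgd)
  th_shape <- c(rig$thermal$width_px, rig$thermal$height_px)
  rows <- list()
  for (k in seq_along(bundles)) {
    for (m in names(tfs)) {
      warped <- warp_mask(tfs[[m]], masks[[k]]$visible, th_shape)
      rep_k <- overlap_metrics(warped, masks[[k]]$thermal)
      rows[[length(rows) + 1L]] <- data.frame(
        metric = c("dice", "jaccard", "volume_similarity", "fn_fraction", "fp_fraction"),
        distance_mm = dists[k], method = m,
        value = c(rep_k$dice, rep_k$jaccard, rep_k$volume_similarity,
                  rep_k$fn_fraction, rep_k$fp_fraction))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$metric, out$distance_mm, out$method), ]
  rownames(out) <- NULL
  class(out) <- c("robustness_table", "data.frame")
  attr(out, "transforms") <- tfs
  out
}

# estimate every requested method's visible-to-thermal transform from
# focal-plane data
estimate_all_methods <- function(calib, rig, fp_masks, methods,
                                 ransac = ransac_config(), icp = icp_config(),
                                 asgd = asgd_config()) {
  tfs <- list()
  needs_kp <- any(c("got", "homography") %in% methods)
  if (needs_kp) {
    kv <- detect_blobs(calib$visible_image, min_area_px = 20, max_area_px = 2000,
                       polarity = "bright")
    kt <- detect_blobs(calib$thermal_image, min_area_px = 5, max_area_px = 2000,
                       polarity = "dark")
    corr <- pair_grid_keypoints(kv, kt, calib$grid_rows, calib$grid_cols)
    cp <- corr_points(corr, kv, kt)
  }
  if ("got" %in% methods)
    tfs$got <- estimate_got(corr, kv, kt, rig)
  if ("homography" %in% methods)
    tfs$homography <- homography_ransac(cp$src, cp$dst, ransac)$transform
  if ("icp" %in% methods)
    tfs$icp <- estimate_icp(fp_masks$visible, fp_masks$thermal,
                            pre_scale = angular_scale(rig$visible, rig$thermal),
                            cfg = icp)$transform
  if ("asgd" %in% methods) {
    init <- center_align_init(rig)
    tfs$asgd <- estimate_affine_asgd(fp_masks$visible, fp_masks$thermal,
                                     cfg = asgd, init = init)$transform
  }
  tfs
}

# angular scaling plus image-center alignment: a deliberately rough
# initializer representing what is known without any calibration data
center_align_init <- function(rig) {
  sc <- angular_scale(rig$visible, rig$thermal)
  cv <- c((rig$visible$width_px - 1) / 2, (rig$visible$height_px - 1) / 2)
  ct <- c((rig$thermal$width_px - 1) / 2, (rig$thermal$height_px - 1) / 2)
  cs <- apply_transform(sc, matrix(cv, 1, 2))
  tf_compose(tf_translation(ct[1] - cs[1], ct[2] - cs[2]), sc)
}

#' Pivot a robustness table to the wide layout (distance x method)
#'
#' @param tab a `robustness_table`.
#' @param metric which metric to tabulate.
#' @return a data frame with one row per distance and one column per method.
#' @export
robustness_wide <- function(tab, metric = "dice") {
  sub <- tab[tab$metric == metric, ]
  stats::reshape(sub[, c("distance_mm", "method", "value")],
                 idvar = "distance_mm", timevar = "method",
                 direction = "wide") -> w
  names(w) <- sub("^value\\.", "", names(w))
  rownames(w) <- NULL
  w
}
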