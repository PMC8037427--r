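#' Select the best-synchronized frame pair from two streams
#'
#' Returns the cross-stream frame pair with the smallest absolute timestamp
#' difference, the software-synchronization rule for two free-running
#' cameras buffered over a shared window. Ties are broken by the earliest
#' timestamp in stream `a`, then the earliest in stream `b`. Runs in
#' O(n log n) via a sorted merge rather than the O(n m) exhaustive scan.
#'
#' @param a,b `frame_stream` data frames (columns `timestamp_s`, `frame_id`).
#' @return list with `frame_id_a`, `frame_id_b`, `delta_t_s`, `t_a`, `t_b`.
#' @export
sync_select <- function(a, b) {
  if (!nrow(a) || !nrow(b)) stop("frame streams must be nonempty")
  ta <- a$timestamp_s; tb <- b$timestamp_s
  ob <- order(tb, b$frame_id)
  tbs <- tb[ob]
  # nearest b-timestamp for each a-frame: predecessor or successor in sorted b
  pos <- findInterval(ta, tbs)
  cand_lo <- pmax(pos, 1L)
  cand_hi <- pmin(pos + 1L, length(tbs))
  d_lo <- abs(ta - tbs[cand_lo])
  d_hi <- abs(ta - tbs[cand_hi])
  use_hi <- d_hi < d_lo | (d_hi == d_lo & tbs[cand_hi] < tbs[cand_lo])
  best_b <- ifelse(use_hi, cand_hi, cand_lo)
  d <- pmin(d_lo, d_hi)
  # global minimum with the stated tie-breaks
  o <- order(d, ta, tbs[best_b])
  i <- o[1L]
  j <- ob[best_b[i]]
  list(frame_id_a = a$frame_id[i], frame_id_b = b$frame_id[j],
       delta_t_s = d[i], t_a = ta[i], t_b = tb[j])
}

#' Default pipeline configuration
#'
#' Collects every tunable of the end-to-end synthetic experiment: the rig,
#' the working distances, generator noise levels, the per-method estimator
#' configurations, rater performance levels and the master seed. Unknown
#' fields passed through `...` are rejected.
#'
#' @param distances_mm working distances for the robustness experiment; must
#'   include the focal plane.
#' @param seed master seed; all stage seeds derive from it.
#' @param noise_sd image noise (fraction of dynamic range).
#' @param jitter_px checkerboard keypoint jitter.
#' @param n_outliers spurious calibration blobs per image.
#' @param rater_sens,rater_spec per-rater Bernoulli performance levels.
#' @param checkerboard_rows,checkerboard_cols calibration lattice size.
#' @param ransac,icp,asgd estimator configurations.
#' @param rig the two-camera rig, see [default_rig()].
#' @param frame_rates (visible, thermal) frame rates for the sync stage, fps.
#' @param buffer_window_s synchronization buffer length, seconds.
#' @param ... rejected; misspelled fields error out.
#' @export
pipeline_config <- function(distances_mm = c(760, 780, 800, 820, 835, 850),
                            seed = 1,
                            noise_sd = 0.02,
                            jitter_px = 0.3,
                            n_outliers = 2,
                            rater_sens = c(0.995, 0.99),
                            rater_spec = c(0.9995, 0.999),
                            checkerboard_rows = 5, checkerboard_cols = 5,
                            ransac = ransac_config(),
                            icp = icp_config(),
                            asgd = asgd_config(),
                            rig = default_rig(),
                            frame_rates = c(30, 9),
                            buffer_window_s = 2.0,
                            ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown pipeline_config field(s): ", paste(names(extra), collapse = ", "))
  if (!any(abs(distances_mm - rig$visible$focal_plane_mm) < 1e-9))
    stop("distances_mm must include the focal plane (",
         rig$visible$focal_plane_mm, " mm)")
  structure(list(distances_mm = distances_mm, seed = as.integer(seed),
                 noise_sd = noise_sd, jitter_px = jitter_px,
                 n_outliers = as.integer(n_outliers),
                 rater_sens = rater_sens, rater_spec = rater_spec,
                 checkerboard_rows = as.integer(checkerboard_rows),
                 checkerboard_cols = as.integer(checkerboard_cols),
                 ransac = ransac, icp = icp, asgd = asgd, rig = rig,
                 frame_rates = frame_rates, buffer_window_s = buffer_window_s),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields override the defaults of [pipeline_config()]; estimator
#' sub-configurations may be given as nested maps (`ransac:`, `icp:`,
#' `asgd:`).
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (nm in c("ransac", "icp", "asgd")) {
    if (!is.null(y[[nm]]))
      y[[nm]] <- do.call(paste0(nm, "_config"), y[[nm]])
  }
  do.call(pipeline_config, y)
}

#' Run the full synthetic registration pipeline
#'
#' Generates frame streams and selects the synchronized pair, renders the
#' focal-plane checkerboard and one scene bundle per working distance,
#' simulates the raters and fuses their segmentations with STAPLE in both
#' spectra, estimates all four registration transforms from the focal-plane
#' data, and evaluates every method at every distance. Fully reproducible
#' from the configuration (which embeds all seeds).
#'
#' @param cfg a [pipeline_config()].
#' @param output_dir optional directory; when given, the robustness table
#'   (CSV), the estimated transforms (JSON), the reference masks and fused
#'   overlay images (PNG) and a scene manifest (CSV) are written there.
#' @param methods methods to evaluate.
#' @return list with the `table` (`robustness_table`), `transforms`, `sync`
#'   (selected frame pair), `staple` fits at the focal plane, the `bundles`
#'   and fused `masks`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), output_dir = NULL,
                         methods = c("got", "homography", "icp", "asgd")) {
  stopifnot(inherits(cfg, "pipeline_config"))
  streams <- make_frame_streams(cfg$frame_rates[1], cfg$frame_rates[2],
                                window_s = cfg$buffer_window_s,
                                seed = sub_seed(cfg$seed, 11))
  sync <- sync_select(streams$a, streams$b)
  calib <- make_checkerboard_scene(cfg$rig, cfg$checkerboard_rows,
                                   cfg$checkerboard_cols,
                                   jitter_px = cfg$jitter_px,
                                   n_outliers = cfg$n_outliers,
                                   seed = sub_seed(cfg$seed, 12))
  bundles <- lapply(seq_along(cfg$distances_mm), function(k)
    make_scene_bundle(cfg$rig, cfg$distances_mm[k],
                      seed = sub_seed(cfg$seed, 20 + k),
                      noise_sd = cfg$noise_sd))
  staple_fits <- vector("list", length(bundles))
  masks <- vector("list", length(bundles))
  for (k in seq_along(bundles)) {
    sv <- make_rater_stack(bundles[[k]]$visible_mask, cfg$rater_sens,
                           cfg$rater_spec, seed = sub_seed(cfg$seed, 40 + k))
    st <- make_rater_stack(bundles[[k]]$thermal_mask, cfg$rater_sens,
                           cfg$rater_spec, seed = sub_seed(cfg$seed, 60 + k))
    fit_v <- run_staple(sv)
    fit_t <- run_staple(st)
    staple_fits[[k]] <- list(visible = fit_v, thermal = fit_t)
    masks[[k]] <- list(visible = clean_binary_mask(threshold_consensus(fit_v)),
                       thermal = clean_binary_mask(threshold_consensus(fit_t)))
  }
  tab <- run_distance_experiment(bundles, calib, cfg$rig, methods = methods,
                                 masks = masks, ransac = cfg$ransac,
                                 icp = cfg$icp, asgd = cfg$asgd,
                                 focal_mm = cfg$rig$visible$focal_plane_mm)
  i_fp <- which(abs(cfg$distances_mm - cfg$rig$visible$focal_plane_mm) < 1e-9)
  out <- list(table = tab, transforms = attr(tab, "transforms"), sync = sync,
              staple = staple_fits[[i_fp]], bundles = bundles, masks = masks,
              config = cfg)
  if (!is.null(output_dir)) write_pipeline_artifacts(out, output_dir)
  out
}

write_pipeline_artifacts <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(res$table),
                   file.path(output_dir, "robustness_table.csv"),
                   row.names = FALSE)
  for (m in names(res$transforms))
    tf_to_json(res$transforms[[m]],
               file.path(output_dir, paste0("transform_", m, ".json")))
  manifest <- do.call(rbind, lapply(seq_along(res$bundles), function(k) {
    b <- res$bundles[[k]]
    data.frame(distance_mm = b$distance_mm, seed = b$rng_seed,
               thermal_image = sprintf("thermal_%04.0fmm.png", b$distance_mm),
               thermal_mask = sprintf("thermal_mask_%04.0fmm.png", b$distance_mm),
               visible_mask = sprintf("visible_mask_%04.0fmm.png", b$distance_mm))
  }))
  utils::write.csv(manifest, file.path(output_dir, "manifest.csv"),
                   row.names = FALSE)
  for (k in seq_along(res$bundles)) {
    b <- res$bundles[[k]]
    png::writePNG(b$thermal_image,
                  file.path(output_dir, manifest$thermal_image[k]))
    png::writePNG(res$masks[[k]]$thermal,
                  file.path(output_dir, manifest$thermal_mask[k]))
    png::writePNG(res$masks[[k]]$visible,
                  file.path(output_dir, manifest$visible_mask[k]))
  }
  # fused overlays at the focal plane: thermal grayscale + registered mask
  i_fp <- which(abs(vapply(res$bundles, function(b) b$distance_mm, numeric(1)) -
                      res$config$rig$visible$focal_plane_mm) < 1e-9)
  b <- res$bundles[[i_fp]]
  for (m in names(res$transforms)) {
    warped <- warp_mask(res$transforms[[m]], res$masks[[i_fp]]$visible,
                        c(ncol(b$thermal_image), nrow(b$thermal_image)))
    png::writePNG(overlay_rgb(b$thermal_image, warped),
                  file.path(output_dir, paste0("overlay_", m, ".png")))
  }
  invisible(output_dir)
}

# thermal grayscale with the registered mask's contour burned in red
overlay_rgb <- function(img, mask) {
  edge <- mask - EBImage::erode(mask, EBImage::makeBrush(3, "box"))
  rgb <- array(rep(pmin(pmax(img, 0), 1), 3), dim = c(nrow(img), ncol(img), 3))
  rgb[, , 1][edge == 1] <- 1
  rgb[, , 2][edge == 1] <- 0.1
  rgb[, , 3][edge == 1] <- 0.1
  rgb
}
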