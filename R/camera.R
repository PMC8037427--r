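#' Camera model for the two-sensor rig
#'
#' Describes one camera of the fixed rig by its pixel resolution, field of
#' view, lateral offset from the rig origin (baseline) and the rig's fixed
#' focal-plane distance. The emulated projection is angular: a point at
#' lateral position X mm on a fronto-parallel plane at distance d subtends
#' an angle of about X/d radians, mapped to pixels through the camera's
#' angular resolution. Pixels-per-mm at distance d is therefore
#' `K/d` with `K = width_px / hfov_rad`, so image scale is inversely
#' proportional to distance and the inter-camera scale equals the ratio of
#' angular resolutions exactly.
#'
#' @param width_px,height_px sensor resolution in pixels.
#' @param hfov_deg,vfov_deg horizontal/vertical field of view, degrees.
#' @param baseline_mm lateral offset of the optical axis from the rig origin.
#' @param focal_plane_mm the rig's fixed focal-plane distance.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(width_px, height_px, hfov_deg, vfov_deg,
                         baseline_mm = 0, focal_plane_mm = 800) {
  stopifnot(width_px > 0, height_px > 0)
  if (hfov_deg <= 0 || hfov_deg >= 180 || vfov_deg <= 0 || vfov_deg >= 180)
    stop("fields of view must lie strictly between 0 and 180 degrees")
  cam <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
              hfov_deg = hfov_deg, vfov_deg = vfov_deg,
              baseline_mm = baseline_mm, focal_plane_mm = focal_plane_mm)
  ares <- c(hfov_deg / width_px, vfov_deg / height_px)
  if (!all(is.finite(ares)) || any(ares <= 0))
    stop("angular resolution must be finite and positive")
  structure(cam, class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> %d x %d px, FOV %.1f x %.1f deg, baseline %.0f mm, focal plane %.0f mm\n",
              x$width_px, x$height_px, x$hfov_deg, x$vfov_deg,
              x$baseline_mm, x$focal_plane_mm))
  invisible(x)
}

# px-per-radian constants for both axes
camera_k <- function(cam) {
  c(cam$width_px / (cam$hfov_deg * pi / 180),
    cam$height_px / (cam$vfov_deg * pi / 180))
}

#' World-to-pixel projection at a working distance
#'
#' Maps rig-plane coordinates (mm, origin on the rig axis, x right, y down)
#' to this camera's pixel coordinates for a fronto-parallel plane at
#' `distance_mm`: `u = (Kx/d)(X - baseline) + cx`, `v = (Ky/d) Y + cy`,
#' with the principal point at the image center.
#'
#' @param cam a [camera_model].
#' @param distance_mm plane distance, mm.
#' @return an affine [transform2d]; its `distance_scale` attribute holds the
#'   scale relative to the focal plane, `focal_plane_mm / distance_mm`.
#' @export
camera_projection <- function(cam, distance_mm) {
  stopifnot(inherits(cam, "camera_model"), distance_mm > 0)
  k <- camera_k(cam)
  sx <- k[1] / distance_mm
  sy <- k[2] / distance_mm
  cx <- (cam$width_px - 1) / 2
  cy <- (cam$height_px - 1) / 2
  m <- diag(3)
  m[1, ] <- c(sx, 0, -sx * cam$baseline_mm + cx)
  m[2, ] <- c(0, sy, cy)
  tf <- transform2d(m, "affine")
  attr(tf, "distance_scale") <- cam$focal_plane_mm / distance_mm
  tf
}

#' Default two-camera rig
#'
#' Visible: 1280x720, 65 x 40 degree FOV, on the rig axis. Thermal: 384x288,
#' 50 x 38 degree FOV, 40 mm lateral baseline. Focal plane at 800 mm.
#'
#' @return list with `visible` and `thermal` [camera_model]s.
#' @export
default_rig <- function() {
  list(visible = camera_model(1280, 720, 65, 40, baseline_mm = 0, focal_plane_mm = 800),
       thermal = camera_model(384, 288, 50, 38, baseline_mm = 40, focal_plane_mm = 800))
}
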