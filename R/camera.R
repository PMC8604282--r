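#' Two-sensor camera rig
#'
#' Pinhole model of an RGB-D rig: intrinsics of the depth and colour sensors
#' plus the rigid transform (rotation `R`, translation `t` in mm) taking
#' points from the depth-camera frame to the colour-camera frame. The pixel
#' convention is `(u, v) = (column, row)`, 0-based, pixel-centre sampling;
#' deprojection of pixel `(u, v)` at depth `d` is `X = d * K^-1 (u, v, 1)'`.
#'
#' @param fx_depth,fy_depth,cx_depth,cy_depth depth-sensor intrinsics (pixels).
#' @param fx_color,fy_color,cx_color,cy_color colour-sensor intrinsics; default
#'   to the depth intrinsics.
#' @param R 3x3 rotation matrix, depth frame to colour frame.
#' @param t length-3 translation (mm), depth frame to colour frame.
#' @return an object of class `camera_rig`.
#' @export
camera_rig <- function(fx_depth, fy_depth, cx_depth, cy_depth,
                       fx_color = fx_depth, fy_color = fy_depth,
                       cx_color = cx_depth, cy_color = cy_depth,
                       R = diag(3), t = c(0, 0, 0)) {
  stopifnot(fx_depth > 0, fy_depth > 0, fx_color > 0, fy_color > 0)
  R <- matrix(as.numeric(R), 3, 3)
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6) {
    stop("camera_rig(): R must be a proper rotation (orthonormal, det = 1)")
  }
  structure(list(
    K_depth = list(fx = fx_depth, fy = fy_depth, cx = cx_depth, cy = cy_depth),
    K_color = list(fx = fx_color, fy = fy_color, cx = cx_color, cy = cy_color),
    R = R, t = as.numeric(t)
  ), class = "camera_rig")
}

#' @export
print.camera_rig <- function(x, ...) {
  cat("<camera_rig>\n")
  cat(sprintf("  depth K: fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              x$K_depth$fx, x$K_depth$fy, x$K_depth$cx, x$K_depth$cy))
  cat(sprintf("  color K: fx=%.1f fy=%.1f cx=%.1f cy=%.1f\n",
              x$K_color$fx, x$K_color$fy, x$K_color$cx, x$K_color$cy))
  cat(sprintf("  |t| = %.1f mm, rotation angle = %.2f deg\n",
              sqrt(sum(x$t^2)),
              acos(pmin(1, pmax(-1, (sum(diag(x$R)) - 1) / 2))) * 180 / pi))
  invisible(x)
}

#' Read / write a camera rig as YAML
#'
#' The on-disk layout has named scalar fields per sensor (`fx`, `fy`, `cx`,
#' `cy`), the rotation row-major as `R`, and `t` in millimetres.
#'
#' @param rig a [camera_rig()].
#' @param path file path.
#' @export
write_camera_rig <- function(rig, path) {
  stopifnot(inherits(rig, "camera_rig"))
  yaml::write_yaml(list(
    depth = rig$K_depth, color = rig$K_color,
    R = as.numeric(t(rig$R)), t = rig$t
  ), path)
  invisible(path)
}

#' @rdname write_camera_rig
#' @export
read_camera_rig <- function(path) {
  y <- yaml::read_yaml(path)
  camera_rig(y$depth$fx, y$depth$fy, y$depth$cx, y$depth$cy,
             y$color$fx, y$color$fy, y$color$cx, y$color$cy,
             R = matrix(as.numeric(y$R), 3, 3, byrow = TRUE), t = y$t)
}

# Deproject 0-based pixel coordinates (u = col, v = row) at depth d (mm) to
# camera-frame 3D points; returns an n x 3 matrix.
deproject_pixels <- function(u, v, d, K) {
  cbind((u - K$cx) / K$fx * d, (v - K$cy) / K$fy * d, d)
}

# Project camera-frame points to 0-based pixel coordinates.
project_points <- function(P, K) {
  cbind(u = P[, 1] / P[, 3] * K$fx + K$cx,
        v = P[, 2] / P[, 3] * K$fy + K$cy)
}
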