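#' Align a depth raster to the colour camera's pixel grid
#'
#' Each valid depth pixel is deprojected with the depth intrinsics, moved
#' through the rig's rigid transform `(R, t)` into the colour-camera frame,
#' reprojected with the colour intrinsics and splatted to the nearest output
#' pixel. When several depth pixels land on one colour pixel the nearest
#' surface (smallest depth) wins (z-buffering). Output pixels no depth point
#' maps to are invalid, as are points that end up behind the camera or
#' outside the output raster.
#'
#' The stored values are metric depths in the colour-camera frame, so for a
#' pure-translation rig the depth values themselves are preserved and only
#' their pixel positions shift.
#'
#' @param depth a [depth_raster()] in the depth camera's grid.
#' @param rig a [camera_rig()].
#' @param out_size output `c(width, height)` in pixels; defaults to the input
#'   size.
#' @return a [depth_raster()] on the colour camera's grid.
#' @export
align_depth_to_color <- function(depth, rig, out_size = NULL) {
  stopifnot(inherits(depth, "depth_raster"), inherits(rig, "camera_rig"))
  if (is.null(out_size)) out_size <- c(ncol(depth$values), nrow(depth$values))
  w_out <- out_size[1]; h_out <- out_size[2]
  out <- matrix(0, h_out, w_out)
  idx <- which(depth$valid)
  if (length(idx)) {
    h <- nrow(depth$values)
    v <- (idx - 1) %% h          # 0-based row
    u <- (idx - 1) %/% h         # 0-based col
    d <- depth$values[idx]
    P <- deproject_pixels(u, v, d, rig$K_depth)
    Pc <- P %*% t(rig$R) + matrix(rig$t, length(idx), 3, byrow = TRUE)
    front <- Pc[, 3] > 0
    Pc <- Pc[front, , drop = FALSE]
    if (nrow(Pc)) {
      uv <- project_points(Pc, rig$K_color)
      uo <- round(uv[, 1]); vo <- round(uv[, 2])
      inside <- uo >= 0 & uo < w_out & vo >= 0 & vo < h_out
      uo <- uo[inside]; vo <- vo[inside]; z <- Pc[inside, 3]
      # z-buffer: write in decreasing depth order so the nearest point,
      # written last, wins at duplicated target pixels
      ord <- order(z, decreasing = TRUE)
      out[cbind(vo[ord] + 1, uo[ord] + 1)] <- z[ord]
    }
  }
  depth_raster(out)
}

#' Fill invalid pixels of a depth raster
#'
#' Iterative median-of-valid-neighbours fill: each pass replaces every
#' invalid pixel that has at least one valid pixel inside the current square
#' window (initially 3x3) with the median of those valid values; if a pass
#' makes no progress the window grows (5x5, 7x7, ...). Originally valid
#' pixels are never touched, every filled value lies within the range of the
#' valid input values, and the operation is idempotent (a hole-free raster is
#' returned unchanged).
#'
#' @param depth a [depth_raster()] with at least one valid pixel.
#' @return a fully valid [depth_raster()].
#' @export
fill_holes <- function(depth) {
  stopifnot(inherits(depth, "depth_raster"))
  if (!any(depth$valid)) stop("fill_holes(): raster has no valid pixels")
  vals <- depth$values
  valid <- depth$valid
  h <- nrow(vals); w <- ncol(vals)
  win <- 3L
  while (!all(valid)) {
    holes <- which(!valid)
    r <- (holes - 1L) %% h + 1L
    cc <- (holes - 1L) %/% h + 1L
    half <- (win - 1L) %/% 2L
    offs <- expand.grid(dr = -half:half, dc = -half:half)
    offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
    # neighbour value matrix (holes x window cells), NA outside / invalid
    nb <- matrix(NA_real_, length(holes), nrow(offs))
    for (k in seq_len(nrow(offs))) {
      rr <- r + offs$dr[k]; ck <- cc + offs$dc[k]
      ok <- rr >= 1 & rr <= h & ck >= 1 & ck <= w
      li <- rr[ok] + (ck[ok] - 1L) * h
      good <- valid[li]
      tmp <- rep(NA_real_, length(holes))
      tmp[which(ok)[good]] <- vals[li[good]]
      nb[, k] <- tmp
    }
    fillable <- rowSums(!is.na(nb)) > 0
    if (!any(fillable)) { win <- win + 2L; next }
    med <- apply(nb[fillable, , drop = FALSE], 1, stats::median, na.rm = TRUE)
    vals[holes[fillable]] <- med
    valid[holes[fillable]] <- TRUE
    win <- 3L
  }
  depth_raster(vals)
}
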