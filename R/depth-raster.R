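#' Depth raster
#'
#' A single-channel distance image in millimetres with an explicit validity
#' mask. Invalid pixels carry the sentinel value 0 mm, matching common 16-bit
#' depth-PNG practice, and the mask is false exactly where the value is 0.
#'
#' @param values numeric matrix of distances (mm), `>= 0`; 0 marks invalid.
#' @return an object of class `depth_raster` with fields `values` (numeric
#'   matrix) and `valid` (logical matrix).
#' @export
depth_raster <- function(values) {
  values <- as.matrix(values)
  if (any(values < 0, na.rm = TRUE)) stop("depth_raster(): negative depth values")
  values[is.na(values)] <- 0
  structure(list(values = values, valid = values > 0), class = "depth_raster")
}

#' @export
print.depth_raster <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<depth_raster> %d x %d, %.1f%% valid",
              nrow(x$values), ncol(x$values), 100 * mean(x$valid)))
  if (length(v)) cat(sprintf(", range %.0f-%.0f mm", min(v), max(v)))
  cat("\n")
  invisible(x)
}

#' @export
dim.depth_raster <- function(x) dim(x$values)
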