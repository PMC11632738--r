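#' Detect the circular fiducial pad
#'
#' The 10 mm silicone pad is rendered/photographed as a uniform
#' high-contrast disc on the upper third of the face. Detection thresholds
#' the image (bright pixels by default), labels connected components inside
#' the search region, keeps components whose circularity
#' `4 * pi * area / perimeter^2` passes `min_circularity`, and returns the
#' largest. The diameter is the area-equivalent diameter
#' `2 * sqrt(area / pi)`, which is robust to mild anti-aliasing.
#'
#' @param image A [face_image()].
#' @param search_region `c(x0, y0, x1, y1)` bounding box (0-based, x1/y1
#'   exclusive) to search; default the upper third of the frame.
#' @param threshold Foreground threshold on mean channel intensity, 0-255
#'   scale (default 230, roughly midway between skin and the white pad,
#'   so an anti-aliased disc edge is segmented at its half-intensity
#'   contour and the diameter estimate is unbiased).
#' @param min_circularity Minimum circularity (default 0.8).
#' @return List with `center` (`c(x, y)` px), `diameter_px`, `area_px`.
#' @export
detect_pad <- function(image, search_region = NULL, threshold = 230,
                       min_circularity = 0.8) {
  stopifnot(inherits(image, "face_image"))
  if (is.null(search_region)) {
    search_region <- c(0, 0, image$width, floor(image$height / 3))
  }
  x0 <- max(0, floor(search_region[1])); y0 <- max(0, floor(search_region[2]))
  x1 <- min(image$width, ceiling(search_region[3]))
  y1 <- min(image$height, ceiling(search_region[4]))
  if (x1 <= x0 || y1 <= y0) {
    fm_stop("fm_value_error", "empty pad search region")
  }
  sub <- image$pixels[(y0 + 1):y1, (x0 + 1):x1, , drop = FALSE]
  fg <- (sub[, , 1] + sub[, , 2] + sub[, , 3]) / 3 >= threshold
  if (!any(fg)) {
    fm_stop("fm_detection_error", "no pad candidate above threshold %g", threshold)
  }
  lab <- EBImage::bwlabel(t(fg))                 # x-major for EBImage
  feats <- EBImage::computeFeatures.shape(lab)
  area <- feats[, "s.area"]
  perim <- pmax(feats[, "s.perimeter"], 1)
  circ <- 4 * pi * area / perim^2
  ok <- which(circ >= min_circularity & area >= 9)
  if (!length(ok)) {
    fm_stop("fm_detection_error",
            "no component passes circularity >= %g", min_circularity)
  }
  best <- ok[order(area[ok], decreasing = TRUE)]
  if (length(best) > 1 && area[best[2]] >= 0.8 * area[best[1]]) {
    fm_stop("fm_ambiguity_error",
            "multiple circular candidates of comparable size in search region")
  }
  sel <- best[1]
  idx <- which(lab == sel, arr.ind = TRUE)
  center <- c(x = mean(idx[, 1] - 1) + x0, y = mean(idx[, 2] - 1) + y0)
  list(center = center,
       diameter_px = 2 * sqrt(area[sel] / pi),
       area_px = unname(area[sel]))
}

#' Build a calibration scale
#'
#' @param mm_per_px Millimetres per pixel (> 0, finite).
#' @param source Either `"pad"` (derived from a detected fiducial) or
#'   `"manifest"` (manual override).
#' @return A `calibration_scale` object (list with `mm_per_px`, `source`).
#' @export
calibration_scale <- function(mm_per_px, source = c("pad", "manifest")) {
  source <- match.arg(source)
  if (!is.finite(mm_per_px) || mm_per_px <= 0) {
    fm_stop("fm_value_error", "mm_per_px must be positive and finite")
  }
  structure(list(mm_per_px = mm_per_px, source = source),
            class = "calibration_scale")
}

#' Scale from a detected pad of known physical diameter
#'
#' @param det Detection from [detect_pad()].
#' @param known_mm Physical pad diameter in mm (default 10, the 1 cm pad).
#' @return A [calibration_scale()] with `mm_per_px = known_mm / diameter_px`.
#' @export
scale_from_pad <- function(det, known_mm = 10) {
  if (!is.finite(det$diameter_px) || det$diameter_px <= 0) {
    fm_stop("fm_value_error", "pad diameter must be positive")
  }
  calibration_scale(known_mm / det$diameter_px, source = "pad")
}

#' Convert a pixel distance to millimetres
#'
#' @param d Pixel distance (>= 0).
#' @param scale A [calibration_scale()].
#' @return Distance in mm.
#' @export
px_to_mm <- function(d, scale) {
  if (any(d < 0)) fm_stop("fm_value_error", "pixel distance must be >= 0")
  d * scale$mm_per_px
}
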