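#' Names of the 13 facial landmarks, in schema order
#'
#' The fixed landmark schema used throughout the package, indexed 0-12:
#' 0 Mentoniano (soft-tissue menton), 1 UnderLipBotton (lower lip, lower
#' vermilion border), 2 UnderLipTop (stomion inferius), 3 UpperLipBottom
#' (stomion superius), 4/5 UpperLipTopRight/Left (Cupid's bow), 6 Subnasal
#' (subnasale), 7/8 NoseRightAlarOutTip/NoseLeftAlarOutTip (alar base),
#' 9/10 EyeRightInner/EyeLeftInner (medial canthi), 11/12
#' EyebrowRightInner/EyebrowLeftInner. "Right"/"Left" refer to the
#' subject's right/left, which appear on the image's left/right.
#'
#' @return Character vector of length 13.
#' @export
landmark_names <- function() {
  c("Mentoniano", "UnderLipBotton", "UnderLipTop", "UpperLipBottom",
    "UpperLipTopRight", "UpperLipTopLeft", "Subnasal",
    "NoseRightAlarOutTip", "NoseLeftAlarOutTip",
    "EyeRightInner", "EyeLeftInner",
    "EyebrowRightInner", "EyebrowLeftInner")
}

#' Bilateral landmark pairs
#'
#' Index pairs (1-based rows of a landmark set) that are mirror images of
#' each other across the facial midline: Cupid's bow points, alar tips,
#' inner eye corners, inner eyebrow points. Used by the horizontal-flip
#' augmentation and by the generator's symmetry invariant.
#'
#' @return Two-column integer matrix of 1-based row indices.
#' @export
bilateral_pairs <- function() {
  # schema indices (4,5), (7,8), (9,10), (11,12) -> 1-based rows
  cbind(c(5L, 8L, 10L, 12L), c(6L, 9L, 11L, 13L))
}

#' Construct a landmark set
#'
#' A landmark set is a 13 x 2 numeric matrix of (x, y) pixel coordinates in
#' schema order (see [landmark_names()]), with the reference frame (width,
#' height in pixels) attached. The coordinate convention is 0-based with the
#' origin at the top-left pixel centre, x rightward and y downward.
#'
#' @param points Numeric 13 x 2 matrix (or object coercible to it) of
#'   (x, y) coordinates in schema order.
#' @param frame Integer vector `c(width, height)` of the reference image.
#' @return A `landmark_set` object.
#' @export
landmark_set <- function(points, frame) {
  points <- as.matrix(points)
  if (nrow(points) != 13L || ncol(points) != 2L) {
    fm_stop("fm_schema_error", "a landmark set needs exactly 13 (x, y) points, got %d x %d",
            nrow(points), ncol(points))
  }
  if (!all(is.finite(points))) {
    fm_stop("fm_schema_error", "all landmark coordinates must be finite")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- list(landmark_names(), c("x", "y"))
  structure(points, frame = as.numeric(frame[1:2]), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("Landmark set (frame %g x %g px)\n",
              attr(x, "frame")[1], attr(x, "frame")[2]))
  print(round(unclass(x), 2))
  invisible(x)
}

#' Frame (width, height) of a landmark set
#' @param landmarks A `landmark_set`.
#' @return Numeric vector `c(width, height)`.
#' @export
landmark_frame <- function(landmarks) attr(landmarks, "frame")

#' Translate landmark coordinates
#'
#' Shifts all coordinates by `-offset`, as needed after [crop_centered()]
#' (whose return value carries the offset of the crop origin in the source
#' image), and re-declares the frame.
#'
#' @param landmarks A `landmark_set`.
#' @param offset Numeric `c(x, y)` of the new frame's origin in the old frame.
#' @param frame New frame `c(width, height)`.
#' @return A shifted `landmark_set`.
#' @export
shift_landmarks <- function(landmarks, offset, frame) {
  pts <- unclass(landmarks)
  pts[, 1] <- pts[, 1] - offset[1]
  pts[, 2] <- pts[, 2] - offset[2]
  landmark_set(pts, frame)
}

#' Rescale landmark coordinates to a new frame
#'
#' Coordinates are multiplied by the ratio of frame sizes per axis, e.g.
#' (512, 512) in a 1024 frame becomes (20, 20) in a 40 frame.
#'
#' @param landmarks A `landmark_set`.
#' @param frame Target frame `c(width, height)`.
#' @return A rescaled `landmark_set`.
#' @export
rescale_landmarks <- function(landmarks, frame) {
  old <- landmark_frame(landmarks)
  pts <- unclass(landmarks)
  pts[, 1] <- pts[, 1] * frame[1] / old[1]
  pts[, 2] <- pts[, 2] * frame[2] / old[2]
  landmark_set(pts, frame)
}

#' Intercanthal distance of a landmark set (pixels)
#'
#' Euclidean distance between the two inner eye corners (schema indices
#' 9 and 10), the face-scale reference used to normalize landmark errors.
#'
#' @param landmarks A `landmark_set`.
#' @return Distance in pixels.
#' @export
intercanthal_px <- function(landmarks) {
  sqrt(sum((landmarks["EyeRightInner", ] - landmarks["EyeLeftInner", ])^2))
}
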