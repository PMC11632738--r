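#' Construct a face image
#'
#' In-memory RGB image: a `height x width x 3` numeric array with channel
#' values on the 0-255 scale (fractional values allowed until written to
#' disk). Pixel (x, y) in the 0-based coordinate convention lives at
#' `pixels[y + 1, x + 1, ]`.
#'
#' @param pixels Numeric `h x w x 3` array, values in \[0, 255\].
#' @param id Opaque image identifier (defaults to "").
#' @return A `face_image` object.
#' @export
face_image <- function(pixels, id = "") {
  d <- dim(pixels)
  if (length(d) != 3L || d[3] != 3L) {
    fm_stop("fm_format_error", "pixels must be an h x w x 3 array")
  }
  if (d[1] < 1L || d[2] < 1L) {
    fm_stop("fm_format_error", "image must be at least 1 x 1")
  }
  rng <- range(pixels)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255) {
    fm_stop("fm_format_error", "channel values must be finite and in [0, 255]")
  }
  structure(list(pixels = pixels, width = d[2], height = d[1],
                 id = as.character(id)),
            class = "face_image")
}

#' @export
print.face_image <- function(x, ...) {
  cat(sprintf("Face image '%s': %d x %d px, RGB\n", x$id, x$width, x$height))
  invisible(x)
}

#' Read a PNG or JPEG image
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return A [face_image()] whose id is the filename stem.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", "image file not found: %s", path)
  }
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           fm_stop("fm_format_error", "unsupported image format: .%s", ext)),
    error = function(e) {
      if (inherits(e, "fm_error")) stop(e)
      fm_stop("fm_format_error", "cannot decode %s: %s", path, conditionMessage(e))
    })
  if (length(dim(arr)) == 2L) {                    # grayscale -> replicate
    arr <- array(arr, dim = c(dim(arr), 3L))
  } else if (dim(arr)[3] == 4L) {                  # drop alpha
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (dim(arr)[3] == 2L) {                  # gray + alpha
    arr <- array(arr[, , 1L], dim = c(dim(arr)[1:2], 3L))
  }
  face_image(arr * 255, id = tools::file_path_sans_ext(basename(path)))
}

#' Write a face image as PNG
#'
#' Channels are quantized to 8 bits; PNG round-trips losslessly for
#' integer-valued channels.
#'
#' @param image A [face_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "face_image"))
  png::writePNG(image$pixels / 255, target = path)
  invisible(path)
}

#' Centred square crop with black padding
#'
#' Extracts a `size x size` window whose centre is as close as possible to
#' `center`; regions outside the source are filled with black. The origin of
#' the window in the source frame is returned so that landmark coordinates
#' can be shifted identically (see [shift_landmarks()]).
#'
#' @param image A [face_image()].
#' @param center Numeric `c(x, y)`, 0-based pixel coordinates.
#' @param size Side length in pixels (>= 1).
#' @return List with `image` (the `size x size` crop) and `offset`
#'   (`c(x, y)` of the crop origin in the source frame).
#' @export
crop_centered <- function(image, center, size) {
  stopifnot(inherits(image, "face_image"))
  size <- as.integer(size)
  if (size < 1L) fm_stop("fm_value_error", "crop size must be >= 1")
  x0 <- floor(center[1] - size / 2 + 0.5)
  y0 <- floor(center[2] - size / 2 + 0.5)
  out <- array(0, dim = c(size, size, 3L))
  # overlap of [x0, x0+size) with [0, width)
  xs <- max(x0, 0); xe <- min(x0 + size, image$width)
  ys <- max(y0, 0); ye <- min(y0 + size, image$height)
  if (xs < xe && ys < ye) {
    out[(ys - y0 + 1):(ye - y0), (xs - x0 + 1):(xe - x0), ] <-
      image$pixels[(ys + 1):ye, (xs + 1):xe, , drop = FALSE]
  }
  list(image = face_image(out, id = image$id), offset = c(x = x0, y = y0))
}

# Separable bilinear resampling with pixel-centre alignment.
bilinear_resize <- function(pixels, out_w, out_h) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  coord <- function(n_out, n_in) {
    s <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    pmin(pmax(s, 0), n_in - 1)
  }
  xs <- coord(out_w, w); ys <- coord(out_h, h)
  x0 <- floor(xs); x1 <- pmin(x0 + 1, w - 1); wx <- xs - x0
  y0 <- floor(ys); y1 <- pmin(y0 + 1, h - 1); wy <- ys - y0
  out <- array(0, dim = c(out_h, out_w, 3L))
  for (c in 1:3) {
    ch <- pixels[, , c]
    rows <- ch[y0 + 1, , drop = FALSE] * (1 - wy) + ch[y1 + 1, , drop = FALSE] * wy
    out[, , c] <- sweep(rows[, x0 + 1, drop = FALSE], 2, 1 - wx, `*`) +
      sweep(rows[, x1 + 1, drop = FALSE], 2, wx, `*`)
  }
  out
}

#' Resize an image to the network input size
#'
#' Bilinear resampling to `size x size` (default 40, the network's input).
#' When a landmark set is supplied its coordinates are rescaled by the same
#' width/height ratios and returned alongside.
#'
#' @param image A [face_image()].
#' @param landmarks Optional `landmark_set` in the image's frame.
#' @param size Output side length (default 40).
#' @return The resized `face_image`, or `list(image, landmarks)` when
#'   landmarks are supplied.
#' @export
resize_to_input <- function(image, landmarks = NULL, size = 40L) {
  stopifnot(inherits(image, "face_image"))
  size <- as.integer(size)
  if (image$width == size && image$height == size) {
    out <- image
  } else {
    out <- face_image(bilinear_resize(image$pixels, size, size), id = image$id)
  }
  if (is.null(landmarks)) return(out)
  list(image = out, landmarks = rescale_landmarks(landmarks, c(size, size)))
}

#' Render landmarks as a binarized mask
#'
#' Draws one small foreground disc per landmark on a black background, the
#' gold-standard representation used when annotations are exchanged as
#' masks. Because a mask alone cannot encode landmark identity, the
#' component-to-landmark assignment is attached as attribute `ordering`
#' (landmark row index of each component in raster scan order).
#'
#' @param landmarks A `landmark_set`; all points must lie inside `dims`.
#' @param dims `c(width, height)` of the mask (defaults to the landmark
#'   frame).
#' @param radius Disc radius in pixels (default 1).
#' @return Integer 0/1 matrix (`height x width`) with attribute `ordering`.
#' @export
render_mask <- function(landmarks, dims = landmark_frame(landmarks), radius = 1) {
  stopifnot(inherits(landmarks, "landmark_set"))
  w <- dims[1]; h <- dims[2]
  pts <- round(unclass(landmarks))
  if (any(pts[, 1] < 0 | pts[, 1] >= w | pts[, 2] < 0 | pts[, 2] >= h)) {
    fm_stop("fm_range_error", "landmark outside mask dimensions %g x %g", w, h)
  }
  mask <- matrix(0L, nrow = h, ncol = w)
  r <- ceiling(radius)
  for (i in 1:13) {
    cx <- pts[i, 1]; cy <- pts[i, 2]
    xs <- max(cx - r, 0):min(cx + r, w - 1)
    ys <- max(cy - r, 0):min(cy + r, h - 1)
    d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
    mask[ys + 1, xs + 1][d2 <= radius^2] <- 1L
  }
  # ordering[k] = landmark row held by the k-th component when components
  # are sorted by rounded centroid (x, then y); disc centroids coincide
  # with the rounded landmark positions, so the sort is reproducible
  structure(mask, ordering = order(pts[, 1], pts[, 2]))
}

#' Recover landmark coordinates from a binarized mask
#'
#' Labels the mask's connected components (via EBImage), takes per-component
#' centroids, and assigns them to schema positions through `ordering`.
#'
#' @param mask 0/1 matrix (`height x width`).
#' @param ordering Integer vector of length 13: `ordering[k]` is the schema
#'   row held by the k-th component when components are sorted by rounded
#'   centroid (x, then y). Defaults to the `ordering` attribute written by
#'   [render_mask()].
#' @return A `landmark_set` of component centroids.
#' @export
mask_to_landmarks <- function(mask, ordering = attr(mask, "ordering")) {
  if (is.null(ordering) || length(ordering) != 13L) {
    fm_stop("fm_schema_error", "no component-to-landmark ordering supplied")
  }
  # EBImage images are x-major: transpose so dim1 = x
  lab <- EBImage::bwlabel(t(mask != 0))
  n <- max(lab)
  if (n != 13L) {
    fm_stop("fm_mask_error", "mask has %d connected components, expected 13", n)
  }
  idx <- which(lab > 0, arr.ind = TRUE)
  labels <- lab[lab > 0]
  cx <- tapply(idx[, 1] - 1, labels, mean)   # dim1 of t(mask) is x
  cy <- tapply(idx[, 2] - 1, labels, mean)
  comp <- cbind(cx, cy)[order(round(cx), round(cy)), , drop = FALSE]
  pts <- matrix(NA_real_, 13L, 2L)
  pts[ordering, ] <- comp
  landmark_set(pts, frame = c(ncol(mask), nrow(mask)))
}
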