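# Shared fixtures, built in code. Datasets are generated once per test run
# and cached in the session tempdir keyed by their parameters.

tiny_dataset <- local({
  cache <- new.env(parent = emptyenv())
  function(n = 8, seed = 11, test_fraction = 0.25) {
    key <- sprintf("n%d_s%d_t%g", n, seed, test_fraction)
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("fm_ds_", key))
      cfg <- generator_config(n_subjects = n, seed = seed,
                              test_fraction = test_fraction)
      cache[[key]] <- generate_dataset(cfg, dir)
    }
    cache[[key]]
  }
})

# A deterministic, hand-placed landmark set in a 1024 frame (anatomically
# ordered, bilateral pairs symmetric about x = 512).
demo_landmarks <- function(frame = 1024) {
  pts <- rbind(
    c(512, 800),   # 0 menton
    c(512, 680),   # 1 lower vermilion border
    c(512, 620),   # 2 stomion inferius
    c(512, 610),   # 3 stomion superius
    c(487, 560),   # 4 Cupid's bow right
    c(537, 560),   # 5 Cupid's bow left
    c(512, 510),   # 6 subnasale
    c(432, 495),   # 7 alar right
    c(592, 495),   # 8 alar left
    c(432, 360),   # 9 eye right inner
    c(592, 360),   # 10 eye left inner
    c(462, 300),   # 11 brow right inner
    c(562, 300))   # 12 brow left inner
  landmark_set(pts, frame = c(frame, frame))
}

# Random but valid pixel array helper
random_pixels <- function(h, w) {
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

# Flat-colour image
flat_image <- function(h, w, rgb = c(0, 0, 0), id = "flat") {
  face_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)), id = id)
}

# Draw a hard-edged white disc onto a pixel array (independent of the
# package's renderer).
stamp_disc <- function(pixels, cx, cy, diameter) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  xx <- matrix(rep(0:(w - 1), each = h), h, w)
  yy <- matrix(rep(0:(h - 1), times = w), h, w)
  inside <- (xx - cx)^2 + (yy - cy)^2 <= (diameter / 2)^2
  for (c in 1:3) {
    ch <- pixels[, , c]
    ch[inside] <- 255
    pixels[, , c] <- ch
  }
  pixels
}
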