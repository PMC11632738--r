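#' Configuration for the synthetic face generator
#'
#' The generator emulates the kind of cohort the landmark network is meant
#' for: frontal, centred faces of adults with or without dentofacial
#' deformities, photographed with a 10 mm fiducial pad on the upper third
#' of the face. Subject anthropometry is sampled in millimetres around
#' typical adult soft-tissue values (middle third ~62 mm, lower third
#' ~67 mm, intercanthal distance ~32 mm, ...) and converted to pixels with
#' a per-subject scale derived from the pad diameter.
#'
#' @param n_subjects Number of subjects (default 100: 80 train + 20 test,
#'   the database scale the pipeline is designed around).
#' @param seed Integer seed driving the whole dataset.
#' @param test_fraction Fraction of subjects held out as the test group
#'   (default 0.2).
#' @param canvas Canvas side length in px (default 1024, the crop frame).
#' @param pad_diameter_px Range of the rendered pad diameter in px
#'   (default c(46, 54); the pad is 10 mm, so this fixes mm-per-px per
#'   subject).
#' @param face_half_width_mm Range of the face outline half width (mm).
#' @param forehead_mm Range of forehead height above the brows (mm).
#' @param upper_lip_mm Mean and SD of upper lip length M5 (mm).
#' @param upper_vermilion_mm Mean and SD of upper vermilion height M6 (mm).
#' @param lower_vermilion_mm Mean and SD of lower vermilion height M8 (mm).
#' @param interlabial_mm Mean and SD of the interlabial gap M9 (mm);
#'   truncated at 0 so lips may touch.
#' @param middle_third_mm,lower_third_mm,intercanthal_mm,alar_mm Mean and
#'   SD of M1, M2, M3, M4 (mm).
#' @param deformity_fraction Fraction of subjects with exaggerated
#'   lower-third or lip proportions (default 0.25, i.e. 5 in 20).
#' @param asymmetry_jitter_px Maximum deviation of bilateral landmark pairs
#'   from exact mirror symmetry (default 1.5 px, must be <= 3).
#' @param noise_sd Additive Gaussian pixel noise SD on the 0-255 scale
#'   (default 4).
#' @param caliper_sd SD in mm of the noise added to ground-truth
#'   measurements to emulate manual caliper error (default 0.3).
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_subjects = 100L, seed = 1L,
                             test_fraction = 0.2,
                             canvas = 1024L,
                             pad_diameter_px = c(46, 54),
                             face_half_width_mm = c(52, 62),
                             forehead_mm = c(28, 36),
                             middle_third_mm = c(62.5, 5.0),
                             lower_third_mm = c(67.4, 6.2),
                             intercanthal_mm = c(32.0, 2.4),
                             alar_mm = c(33.4, 3.5),
                             upper_lip_mm = c(20.6, 3.0),
                             upper_vermilion_mm = c(9.3, 1.4),
                             lower_vermilion_mm = c(12.0, 1.9),
                             interlabial_mm = c(2.2, 0.9),
                             deformity_fraction = 0.25,
                             asymmetry_jitter_px = 1.5,
                             noise_sd = 4,
                             caliper_sd = 0.3) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
              test_fraction = test_fraction, canvas = as.integer(canvas),
              pad_diameter_px = pad_diameter_px,
              face_half_width_mm = face_half_width_mm,
              forehead_mm = forehead_mm,
              middle_third_mm = middle_third_mm,
              lower_third_mm = lower_third_mm,
              intercanthal_mm = intercanthal_mm,
              alar_mm = alar_mm,
              upper_lip_mm = upper_lip_mm,
              upper_vermilion_mm = upper_vermilion_mm,
              lower_vermilion_mm = lower_vermilion_mm,
              interlabial_mm = interlabial_mm,
              deformity_fraction = deformity_fraction,
              asymmetry_jitter_px = asymmetry_jitter_px,
              noise_sd = noise_sd, caliper_sd = caliper_sd)
  ranges <- cfg[c("pad_diameter_px", "face_half_width_mm", "forehead_mm")]
  if (any(vapply(ranges, function(r) r[2] < r[1] || r[1] <= 0, logical(1)))) {
    fm_stop("fm_config_error", "generator ranges must be non-empty and positive")
  }
  if (deformity_fraction < 0 || deformity_fraction > 1) {
    fm_stop("fm_config_error", "deformity_fraction must be in [0, 1]")
  }
  if (asymmetry_jitter_px < 0 || asymmetry_jitter_px > 3) {
    fm_stop("fm_config_error", "asymmetry_jitter_px must be in [0, 3]")
  }
  if (n_subjects < 1) fm_stop("fm_config_error", "n_subjects must be >= 1")
  structure(cfg, class = "generator_config")
}

rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:100) {
    x <- rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

runif1 <- function(r) runif(1, r[1], r[2])

#' Sample one subject's face geometry
#'
#' Draws subject anthropometry (mm), the per-subject scale from the pad
#' diameter, and appearance parameters, then lays out the 13 landmarks on
#' the canvas. Bilateral pairs are mirror-symmetric about the face midline
#' up to the configured asymmetry jitter; the vertical order follows
#' anatomy (brows, eyes, alar base, subnasale, lips, menton); all
#' landmarks stay at least 32 px from the canvas border and the pad sits
#' on the forehead, never overlapping a landmark. Consumes the current R
#' random stream (seed it with `set.seed()` for reproducibility).
#'
#' @param config A [generator_config()].
#' @return A `face_geometry` list: `landmarks` ([landmark_set()], canvas
#'   frame), `pad` (centre + diameter px), `mm_per_px`, `truth_mm`
#'   (noiseless M1-M9), `appearance` and `shape` parameter lists.
#' @export
sample_geometry <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cv <- config$canvas
  u <- cv / 1024                      # layout scale relative reference canvas
  for (attempt in 1:100) {
    pad_d <- runif1(config$pad_diameter_px) * u
    mmpp <- 10 / pad_d
    m1 <- rnorm_trunc(config$middle_third_mm[1], config$middle_third_mm[2], 48, 78)
    m2 <- rnorm_trunc(config$lower_third_mm[1], config$lower_third_mm[2], 52, 85)
    m3 <- rnorm_trunc(config$intercanthal_mm[1], config$intercanthal_mm[2], 25, 40)
    m4 <- rnorm_trunc(config$alar_mm[1], config$alar_mm[2], 25, 43)
    m5 <- rnorm_trunc(config$upper_lip_mm[1], config$upper_lip_mm[2], 14, 28)
    m6 <- rnorm_trunc(config$upper_vermilion_mm[1], config$upper_vermilion_mm[2], 6, 13)
    m8 <- rnorm_trunc(config$lower_vermilion_mm[1], config$lower_vermilion_mm[2], 7.5, 17)
    m9 <- rnorm_trunc(config$interlabial_mm[1], config$interlabial_mm[2], 0, 5)
    deformed <- runif(1) < config$deformity_fraction
    if (deformed) {
      if (runif(1) < 0.5) m2 <- min(m2 * runif(1, 1.12, 1.28), 92)
      else m8 <- min(m8 * runif(1, 1.15, 1.35), 19)
    }
    m2 <- max(m2, m5 + m9 + m8 + 8)   # chin stays below the lower lip

    cx <- (512 + runif(1, -25, 25)) * u
    sy <- (460 + runif(1, -20, 20)) * u   # subnasale y on canvas
    brow_sep <- runif(1, 18, 24)
    eye_drop <- runif(1, 8, 14)
    alar_up <- runif(1, 1.5, 4.5)
    cupid <- runif(1, 4, 7)

    # mm -> px, midline-relative layout; subject's right = image left
    px <- function(mm) mm / mmpp
    j <- function() if (config$asymmetry_jitter_px > 0)
      runif(2, -config$asymmetry_jitter_px, config$asymmetry_jitter_px) * u else c(0, 0)
    pts <- matrix(0, 13, 2)
    pts[1, ] <- c(cx, sy + px(m2))                       # 0 menton
    pts[2, ] <- c(cx, sy + px(m5 + m9 + m8))             # 1 lower vermilion border
    pts[3, ] <- c(cx, sy + px(m5 + m9))                  # 2 stomion inferius
    pts[4, ] <- c(cx, sy + px(m5))                       # 3 stomion superius
    pts[5, ] <- c(cx - px(cupid), sy + px(m5 - m6)) + j()  # 4 Cupid's bow R
    pts[6, ] <- c(cx + px(cupid), sy + px(m5 - m6)) + j()  # 5 Cupid's bow L
    pts[7, ] <- c(cx, sy)                                # 6 subnasale
    pts[8, ] <- c(cx - px(m4 / 2), sy - px(alar_up)) + j()   # 7 alar R
    pts[9, ] <- c(cx + px(m4 / 2), sy - px(alar_up)) + j()   # 8 alar L
    pts[10, ] <- c(cx - px(m3 / 2), sy - px(m1 - eye_drop)) + j()  # 9 eye R
    pts[11, ] <- c(cx + px(m3 / 2), sy - px(m1 - eye_drop)) + j()  # 10 eye L
    pts[12, ] <- c(cx - px(brow_sep / 2), sy - px(m1)) + j()  # 11 brow R
    pts[13, ] <- c(cx + px(brow_sep / 2), sy - px(m1)) + j()  # 12 brow L

    forehead <- runif1(config$forehead_mm)
    brow_y <- sy - px(m1)
    face_top <- brow_y - px(forehead)
    face_bottom <- sy + px(m2) + px(10)   # chin outline fixed below menton
    half_w <- px(runif1(config$face_half_width_mm))
    pad_r <- pad_d / 2
    pad_lo <- max(60 * u, face_top + pad_r + 8 * u)
    pad_hi <- brow_y - pad_r - 8 * u
    margin <- 32 * u
    if (pad_hi <= pad_lo) next
    if (min(pts) < margin || max(pts[, 1]) > cv - margin ||
        max(pts[, 2]) > cv - margin) next
    pad_center <- c(cx + runif(1, -0.3, 0.3) * half_w, runif(1, pad_lo, pad_hi))

    landmarks <- landmark_set(pts, frame = c(cv, cv))
    truth <- compute_measurements(landmarks,
                                  calibration_scale(mmpp, "manifest"),
                                  digits = NA)
    tone <- runif(1, 0.85, 1.1)
    appearance <- list(
      skin = c(225, 181, 150) * tone,
      contrast = runif(1, 0.65, 1.0),
      saturation = runif(1, 0.8, 1.2),
      lip = c(190, 95, 90) * tone,
      lower_lip = c(176, 84, 82) * tone)
    shape <- list(cx = cx, face_center_y = (face_top + face_bottom) / 2,
                  half_w = half_w, half_h = (face_bottom - face_top) / 2,
                  brow_len = px(runif(1, 20, 25)), brow_h = px(4),
                  eye_len = px(runif(1, 15, 18)), eye_h = px(5),
                  nostril_rx = px(3), nostril_ry = px(2.2),
                  nostril_in = px(3), lip_half_w = px(runif(1, 20, 26)),
                  cupid = px(cupid), mmpp_px = px(1))
    return(structure(list(landmarks = landmarks,
                          pad = list(center = pad_center, diameter = pad_d),
                          mm_per_px = mmpp, truth_mm = truth,
                          deformed = deformed,
                          appearance = appearance, shape = shape),
                     class = "face_geometry"))
  }
  fm_stop("fm_config_error", "could not sample a feasible face geometry")
}

# Alpha-composite a soft-edged ellipse onto the canvas (bbox-restricted).
# The feather is centred on the nominal boundary, so the half-intensity
# contour sits exactly at (rx, ry) — the drawn size IS the stated size.
draw_ellipse <- function(canvas, cx, cy, rx, ry, color, feather = 1.2) {
  h <- dim(canvas)[1]; w <- dim(canvas)[2]
  xs <- max(floor(cx - rx - 3), 0):min(ceiling(cx + rx + 3), w - 1)
  ys <- max(floor(cy - ry - 3), 0):min(ceiling(cy + ry + 3), h - 1)
  if (!length(xs) || !length(ys)) return(canvas)
  d <- sqrt(outer(((ys - cy) / ry)^2, ((xs - cx) / rx)^2, `+`))
  alpha <- pmin(1, pmax(0, 0.5 + (1 - d) * min(rx, ry) / feather))
  for (c in 1:3) {
    canvas[ys + 1, xs + 1, c] <-
      canvas[ys + 1, xs + 1, c] * (1 - alpha) + color[c] * alpha
  }
  canvas
}

#' Render a face geometry to an image
#'
#' Draws a schematic frontal face — shaded ellipses for the face outline,
#' brows, eyes, nose, lips and chin, each anchored to its landmarks — plus
#' the uniform white fiducial disc on the forehead, then adds Gaussian
#' pixel noise. The returned landmark set equals the geometry's exactly.
#' Faces are schematic rather than photorealistic: the network only needs
#' a consistent appearance-to-landmark mapping.
#'
#' @param geometry A `face_geometry` from [sample_geometry()].
#' @param noise_sd Gaussian noise SD on the 0-255 scale (default 4).
#'   Noise consumes the R random stream; with `noise_sd = 0` rendering is
#'   a pure function of the geometry.
#' @param id Image id for the returned [face_image()].
#' @return List: `image` ([face_image()]), `landmarks` ([landmark_set()]),
#'   `pad` (centre + diameter truth).
#' @export
render_face <- function(geometry, noise_sd = 4, id = "synthetic") {
  stopifnot(inherits(geometry, "face_geometry"))
  cv <- landmark_frame(geometry$landmarks)[1]
  sh <- geometry$shape; ap <- geometry$appearance
  pts <- unclass(geometry$landmarks)
  sat <- function(col) {                      # per-subject colourfulness
    m <- mean(col); pmin(pmax(m + (col - m) * ap$saturation, 0), 255)
  }
  skin <- sat(ap$skin)
  dark <- function(f) skin * (1 - f * ap$contrast)
  canvas <- array(rep(c(45, 45, 50), each = cv * cv), dim = c(cv, cv, 3))

  canvas <- draw_ellipse(canvas, sh$cx, sh$face_center_y, sh$half_w, sh$half_h,
                         skin, feather = 2.5)
  # nose bridge shading between the eyes and the subnasale
  ey <- pts[10, 2]
  canvas <- draw_ellipse(canvas, sh$cx, (ey + pts[7, 2]) / 2,
                         5 * sh$mmpp_px, (pts[7, 2] - ey) / 2,
                         skin * 0.93, feather = 6)
  # brows: inner end at the landmark, extending outward
  canvas <- draw_ellipse(canvas, pts[12, 1] - sh$brow_len / 2, pts[12, 2],
                         sh$brow_len / 2, sh$brow_h, dark(0.72))
  canvas <- draw_ellipse(canvas, pts[13, 1] + sh$brow_len / 2, pts[13, 2],
                         sh$brow_len / 2, sh$brow_h, dark(0.72))
  # eyes: inner corner at the landmark, with a darker medial-canthus mark
  canvas <- draw_ellipse(canvas, pts[10, 1] - sh$eye_len / 2, pts[10, 2],
                         sh$eye_len / 2, sh$eye_h, dark(0.8))
  canvas <- draw_ellipse(canvas, pts[11, 1] + sh$eye_len / 2, pts[11, 2],
                         sh$eye_len / 2, sh$eye_h, dark(0.8))
  canvas <- draw_ellipse(canvas, pts[10, 1], pts[10, 2],
                         2 * sh$mmpp_px, 2 * sh$mmpp_px, dark(0.9))
  canvas <- draw_ellipse(canvas, pts[11, 1], pts[11, 2],
                         2 * sh$mmpp_px, 2 * sh$mmpp_px, dark(0.9))
  # shaded nose base spanning the full alar width: its lateral extremes
  # sit exactly on the alar landmarks
  canvas <- draw_ellipse(canvas, (pts[8, 1] + pts[9, 1]) / 2,
                         (pts[8, 2] + pts[9, 2]) / 2,
                         (pts[9, 1] - pts[8, 1]) / 2, 5 * sh$mmpp_px,
                         dark(0.3))
  # nostrils just inward of the alar tips, alar-wing marks on the tips
  canvas <- draw_ellipse(canvas, pts[8, 1] + sh$nostril_in, pts[8, 2],
                         sh$nostril_rx, sh$nostril_ry, dark(0.6))
  canvas <- draw_ellipse(canvas, pts[9, 1] - sh$nostril_in, pts[9, 2],
                         sh$nostril_rx, sh$nostril_ry, dark(0.6))
  canvas <- draw_ellipse(canvas, pts[8, 1], pts[8, 2],
                         2.5 * sh$mmpp_px, 2.5 * sh$mmpp_px, dark(0.55))
  canvas <- draw_ellipse(canvas, pts[9, 1], pts[9, 2],
                         2.5 * sh$mmpp_px, 2.5 * sh$mmpp_px, dark(0.55))
  # subnasale shadow
  canvas <- draw_ellipse(canvas, pts[7, 1], pts[7, 2],
                         4.5 * sh$mmpp_px, 2.5 * sh$mmpp_px, dark(0.5))
  # upper lip: two lobes whose tops are the Cupid's bow points
  lip <- sat(ap$lip)
  ury <- (pts[5, 2] + pts[4, 2]) / 2
  urry <- (pts[4, 2] - pts[5, 2]) / 2
  lobe_rx <- sh$lip_half_w - sh$cupid
  canvas <- draw_ellipse(canvas, pts[5, 1], ury, lobe_rx, urry, lip)
  canvas <- draw_ellipse(canvas, pts[6, 1], ury, lobe_rx, urry, lip)
  # lower lip: spans stomion inferius to the lower vermilion border
  lly <- (pts[3, 2] + pts[2, 2]) / 2
  canvas <- draw_ellipse(canvas, sh$cx, lly, sh$lip_half_w * 0.9,
                         (pts[2, 2] - pts[3, 2]) / 2, sat(ap$lower_lip))
  # interlabial slit between stomion superius and inferius
  canvas <- draw_ellipse(canvas, sh$cx, (pts[4, 2] + pts[3, 2]) / 2,
                         sh$lip_half_w * 0.85,
                         max((pts[3, 2] - pts[4, 2]) / 2, 0.4 * sh$mmpp_px),
                         dark(0.78), feather = 0.8)
  # chin crease centred on the menton
  canvas <- draw_ellipse(canvas, pts[1, 1], pts[1, 2],
                         8 * sh$mmpp_px, 3 * sh$mmpp_px, dark(0.6))
  # fiducial pad: uniform white disc
  canvas <- draw_ellipse(canvas, geometry$pad$center[1], geometry$pad$center[2],
                         geometry$pad$diameter / 2, geometry$pad$diameter / 2,
                         c(255, 255, 255), feather = 1)
  if (noise_sd > 0) {
    canvas <- canvas + rnorm(length(canvas), 0, noise_sd)
  }
  canvas <- pmin(pmax(canvas, 0), 255)
  list(image = face_image(canvas, id = id),
       landmarks = geometry$landmarks,
       pad = geometry$pad)
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_subjects` face images (PNG), one annotation JSON with
#' landmark, pad and conventional-measurement ground truth, a train/test
#' manifest, a CSV of "conventional" measurements (ground truth plus
#' caliper noise, method tag CM) and a CSV of noiseless ground truth.
#' Fully deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param outdir Output directory (created if missing).
#' @return Path of the manifest JSON, invisibly.
#' @export
generate_dataset <- function(config, outdir) {
  stopifnot(inherits(config, "generator_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  n <- config$n_subjects
  records <- vector("list", n)
  truth <- conv <- matrix(0, n, 9, dimnames = list(NULL, paste0("M", 1:9)))
  ids <- sprintf("face_%03d", seq_len(n))
  for (i in seq_len(n)) {
    geom <- sample_geometry(config)
    rf <- render_face(geom, noise_sd = config$noise_sd, id = ids[i])
    write_image(rf$image, file.path(outdir, paste0(ids[i], ".png")))
    truth[i, ] <- geom$truth_mm
    conv[i, ] <- pmax(geom$truth_mm + rnorm(9, 0, config$caliper_sd), 0)
    records[[i]] <- annotation_record(
      ids[i], geom$landmarks,
      pad = list(center = geom$pad$center, diameter = geom$pad$diameter),
      conventional = conv[i, ])
  }
  write_annotations(records, file.path(outdir, "annotations.json"))
  n_test <- round(config$test_fraction * n)
  split <- rep(c("train", "test"), c(n - n_test, n_test))
  entries <- data.frame(image_id = ids, image = paste0(ids, ".png"),
                        split = split, mm_per_px = NA_real_)
  manifest <- file.path(outdir, "manifest.json")
  write_manifest(entries, "annotations.json", manifest,
                 crop_frame = config$canvas)
  write_measurements_csv(
    data.frame(subject_id = ids, method = "CM", conv),
    file.path(outdir, "measurements_cm.csv"))
  write_measurements_csv(
    data.frame(subject_id = ids, method = "truth", truth),
    file.path(outdir, "measurements_truth.csv"))
  invisible(manifest)
}
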