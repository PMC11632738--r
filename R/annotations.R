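#' Construct an annotation record
#'
#' One record per image: the 13 ground-truth landmarks, optionally the
#' fiducial pad truth (centre and diameter in pixels) and the subject's
#' conventional (caliper) measurements in millimetres.
#'
#' @param image_id Unique image identifier.
#' @param landmarks A [landmark_set()].
#' @param pad Optional list with `center` (`c(x, y)` px) and `diameter` (px).
#' @param conventional Optional named numeric vector of mm measurements
#'   (names `M1`-`M9`).
#' @return An `annotation_record` object.
#' @export
annotation_record <- function(image_id, landmarks, pad = NULL,
                              conventional = NULL) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!is.null(pad)) {
    stopifnot(is.list(pad), length(pad$center) == 2L, pad$diameter > 0)
  }
  structure(list(image_id = as.character(image_id), landmarks = landmarks,
                 pad = pad, conventional = conventional),
            class = "annotation_record")
}

record_to_list <- function(rec) {
  pts <- round(unclass(rec$landmarks), 2)
  lm <- lapply(seq_len(13), function(i) c(pts[i, 1], pts[i, 2]))
  names(lm) <- landmark_names()
  out <- list(image_id = rec$image_id,
              frame = landmark_frame(rec$landmarks),
              landmarks = lm)
  if (!is.null(rec$pad)) {
    out$pad <- list(center = round(as.numeric(rec$pad$center), 2),
                    diameter = round(rec$pad$diameter, 2))
  }
  if (!is.null(rec$conventional)) {
    out$conventional <- as.list(round(rec$conventional, 2))
  }
  out
}

list_to_record <- function(x) {
  nm <- landmark_names()
  got <- names(x$landmarks)
  missing <- setdiff(nm, got)
  if (length(missing)) {
    fm_stop("fm_schema_error", "%s missing", missing[1])
  }
  extra <- setdiff(got, nm)
  if (length(extra)) {
    fm_stop("fm_schema_error", "unknown landmark name: %s", extra[1])
  }
  pts <- t(vapply(x$landmarks[nm], function(p) as.numeric(p[1:2]),
                  numeric(2)))
  pad <- NULL
  if (!is.null(x$pad)) {
    pad <- list(center = as.numeric(x$pad$center),
                diameter = as.numeric(x$pad$diameter))
  }
  conv <- NULL
  if (!is.null(x$conventional)) {
    conv <- unlist(x$conventional)
  }
  annotation_record(x$image_id, landmark_set(pts, as.numeric(x$frame)),
                    pad = pad, conventional = conv)
}

#' Write annotation records as JSON
#'
#' Landmarks are keyed by their schema names; coordinates are stored to
#' 0.01 px so that write followed by read is the identity at that precision.
#'
#' @param records List of [annotation_record()]s with unique image ids.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  ids <- vapply(records, `[[`, character(1), "image_id")
  if (anyDuplicated(ids)) {
    fm_stop("fm_validation_error", "duplicated image id: %s",
            ids[duplicated(ids)][1])
  }
  jsonlite::write_json(lapply(records, record_to_list), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read annotation records from JSON
#'
#' @param path Path written by [write_annotations()].
#' @return List of `annotation_record`s.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", "annotation file not found: %s", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  records <- lapply(raw, list_to_record)
  ids <- vapply(records, `[[`, character(1), "image_id")
  if (anyDuplicated(ids)) {
    fm_stop("fm_validation_error", "duplicated image id: %s",
            ids[duplicated(ids)][1])
  }
  records
}

#' Export annotations as a flat CSV
#'
#' One row per landmark: `image_id, name, x, y` (2 dp), mirroring the JSON
#' schema for spreadsheet use.
#'
#' @param records List of [annotation_record()]s.
#' @param path Output path (`.csv`).
#' @return `path`, invisibly.
#' @export
write_landmarks_csv <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(rec) {
    pts <- round(unclass(rec$landmarks), 2)
    data.frame(image_id = rec$image_id, name = landmark_names(),
               x = pts[, 1], y = pts[, 2], row.names = NULL)
  }))
  write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset manifest
#'
#' The manifest ties images to their annotation file and train/test split,
#' and may carry a per-image manual scale override (mm per px) for images
#' without a detectable pad.
#'
#' @param entries Data frame with columns `image_id`, `image` (path,
#'   relative to the manifest), `split` ("train"/"test"), and optionally
#'   `mm_per_px` (NA when absent).
#' @param annotations Path of the annotation JSON, relative to the manifest.
#' @param path Output path (`.json`).
#' @param crop_frame Side length of the crop frame the annotations refer to.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, annotations, path, crop_frame = 1024) {
  jsonlite::write_json(list(annotations = annotations,
                            crop_frame = crop_frame,
                            images = entries),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows", na = "null")
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest path written by [write_manifest()].
#' @return List with `entries` (data frame), `records` (annotation records
#'   keyed by image id), `crop_frame`, and `dir` (the manifest's directory,
#'   against which image paths resolve).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", "manifest not found: %s", path)
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  entries <- as.data.frame(raw$images)
  if (is.null(entries$mm_per_px)) entries$mm_per_px <- NA_real_
  records <- read_annotations(file.path(dir, raw$annotations))
  names(records) <- vapply(records, `[[`, character(1), "image_id")
  list(entries = entries, records = records,
       crop_frame = raw$crop_frame, dir = dir)
}
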