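#' Registry of the nine facial measurements
#'
#' Endpoint definitions of the nine frontal soft-tissue measurements the
#' landmark schema supports, following Arnett/Bergman facial-analysis
#' conventions. Each endpoint is a schema index (0-12) or the midpoint of
#' two indices:
#' \describe{
#'   \item{M1 middle third}{midpoint(EyebrowRightInner, EyebrowLeftInner)
#'     (glabella proxy) to Subnasal}
#'   \item{M2 lower third}{Subnasal to Mentoniano}
#'   \item{M3 intercanthal distance}{EyeRightInner to EyeLeftInner}
#'   \item{M4 alar base}{NoseRightAlarOutTip to NoseLeftAlarOutTip}
#'   \item{M5 upper lip}{Subnasal to UpperLipBottom (stomion superius)}
#'   \item{M6 upper lip vermilion}{midpoint(UpperLipTopRight,
#'     UpperLipTopLeft) to UpperLipBottom}
#'   \item{M7 lower lip}{UnderLipTop (stomion inferius) to Mentoniano}
#'   \item{M8 lower lip vermilion}{UnderLipTop to UnderLipBotton}
#'   \item{M9 interlabial gap}{UpperLipBottom to UnderLipTop}
#' }
#' All distances are Euclidean between the two resolved points, matching a
#' two-jaw caliper placed on the soft-tissue points. An alternative pairing
#' can be supplied as a JSON override file with the same structure.
#'
#' @param override Optional path to a JSON file of alternative definitions
#'   (list of `{id, name, from, to}`, each endpoint an index or pair of
#'   indices).
#' @return Data frame with columns `id`, `name`, `from`, `to` (`from`/`to`
#'   are lists of integer schema indices; length 2 means midpoint).
#' @export
measurement_registry <- function(override = NULL) {
  if (!is.null(override)) {
    raw <- jsonlite::read_json(override, simplifyVector = FALSE)
    defs <- data.frame(
      id = vapply(raw, `[[`, character(1), "id"),
      name = vapply(raw, `[[`, character(1), "name")
    )
    defs$from <- lapply(raw, function(d) as.integer(unlist(d$from)))
    defs$to <- lapply(raw, function(d) as.integer(unlist(d$to)))
  } else {
    defs <- data.frame(
      id = paste0("M", 1:9),
      name = c("middle third", "lower third", "intercanthal distance",
               "alar base", "upper lip", "upper lip vermilion",
               "lower lip", "lower lip vermilion", "interlabial gap")
    )
    defs$from <- list(c(11L, 12L), 6L, 9L, 7L, 6L, c(4L, 5L), 2L, 2L, 3L)
    defs$to <- list(6L, 0L, 10L, 8L, 3L, 3L, 0L, 1L, 2L)
  }
  bad <- !vapply(c(defs$from, defs$to),
                 function(e) length(e) %in% 1:2 && all(e >= 0L & e <= 12L),
                 logical(1))
  if (any(bad)) {
    fm_stop("fm_schema_error", "registry endpoints must be schema indices 0-12")
  }
  defs
}

resolve_endpoint <- function(landmarks, idx) {
  pts <- unclass(landmarks)[idx + 1L, , drop = FALSE]
  colMeans(pts)
}

#' Compute the nine facial measurements in millimetres
#'
#' Resolves each registry definition against a landmark set, takes the
#' Euclidean pixel distance, and converts to mm with the calibration scale.
#' Values are reported at 0.01 mm resolution (digital-caliper precision);
#' set `digits = NA` to keep full precision.
#'
#' @param landmarks A [landmark_set()].
#' @param scale A [calibration_scale()] (mm per px).
#' @param registry Measurement definitions (default [measurement_registry()]).
#' @param digits Rounding applied to the mm values (default 2, `NA` for none).
#' @return Named numeric vector `M1`-`M9` in mm.
#' @export
compute_measurements <- function(landmarks, scale,
                                 registry = measurement_registry(),
                                 digits = 2) {
  stopifnot(inherits(landmarks, "landmark_set"))
  if (!all(is.finite(landmarks))) {
    fm_stop("fm_value_error", "non-finite landmark coordinate")
  }
  mm <- vapply(seq_len(nrow(registry)), function(i) {
    a <- resolve_endpoint(landmarks, registry$from[[i]])
    b <- resolve_endpoint(landmarks, registry$to[[i]])
    sqrt(sum((a - b)^2)) * scale$mm_per_px
  }, numeric(1))
  if (!is.na(digits)) mm <- round(mm, digits)
  setNames(mm, registry$id)
}

#' Write per-subject measurement vectors as CSV
#'
#' @param df Data frame with columns `subject_id`, `method` (CM/AM1/AM2),
#'   and `M1`-`M9` in mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(df, path) {
  need <- c("subject_id", "method", paste0("M", 1:9))
  if (!all(need %in% names(df))) {
    fm_stop("fm_data_error", "measurement table must have columns %s",
            paste(need, collapse = ", "))
  }
  df[paste0("M", 1:9)] <- lapply(df[paste0("M", 1:9)], round, digits = 2)
  write.csv(df[need], path, row.names = FALSE)
  invisible(path)
}

#' Read a per-subject measurement CSV
#'
#' @param path CSV written by [write_measurements_csv()].
#' @return Data frame with `subject_id`, `method`, `M1`-`M9`.
#' @export
read_measurements_csv <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", "measurement file not found: %s", path)
  }
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "method", paste0("M", 1:9))
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    fm_stop("fm_data_error", "measurement CSV misses column %s", missing[1])
  }
  df
}
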