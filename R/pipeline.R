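stage_log <- function(stage, fmt, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Generate a synthetic dataset (pipeline stage)
#'
#' Thin orchestration over [generate_dataset()] with logging; repeated runs
#' with the same config are idempotent on content.
#'
#' @param config A [generator_config()] or path to a JSON file of
#'   [generator_config()] arguments.
#' @param out Output directory (created if missing).
#' @param verbose Log stage lines (default TRUE).
#' @return Manifest path, invisibly.
#' @export
cmd_synth <- function(config, out, verbose = TRUE) {
  if (is.character(config)) {
    config <- do.call(generator_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  manifest <- generate_dataset(config, out)
  stage_log("synth", "seed=%d n=%d -> %s", config$seed, config$n_subjects,
            manifest, verbose = verbose)
  invisible(manifest)
}

#' Train a program version (pipeline stage)
#'
#' Version 1 trains 200 epochs, version 2 trains 1000 (both batch size 1).
#' Writes a checkpoint and the per-epoch loss trace as CSV next to it.
#'
#' @param manifest Manifest path (from [cmd_synth()] or hand-written).
#' @param version Program version, 1 or 2.
#' @param out Output directory for `checkpoint_v<version>.rds` and
#'   `loss_v<version>.csv`.
#' @param seed Training seed (default 1).
#' @param epochs Override the version's epoch preset (mainly for
#'   scaled-down runs); NULL uses the preset.
#' @param verbose Log stage lines.
#' @return Checkpoint path, invisibly.
#' @export
cmd_train <- function(manifest, version = 1L, out, seed = 1L, epochs = NULL,
                      verbose = TRUE) {
  if (!version %in% 1:2) {
    fm_stop("fm_usage_error", "version must be 1 or 2")
  }
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- training_config(version = version, seed = seed)
  if (!is.null(epochs)) cfg <- training_config(epochs = epochs, seed = seed)
  model <- build_model(cfg)
  fit <- train_model(model, manifest, cfg)
  ckpt <- file.path(out, sprintf("checkpoint_v%d.rds", version))
  save_checkpoint(fit$model, ckpt)
  write.csv(fit$history, file.path(out, sprintf("loss_v%d.csv", version)),
            row.names = FALSE)
  stage_log("train", "version=%d epochs=%d seed=%d final_loss=%.6f -> %s",
            version, cfg$epochs, seed, fit$history$loss[cfg$epochs], ckpt,
            verbose = verbose)
  invisible(ckpt)
}

#' Measure every image in a manifest (pipeline stage)
#'
#' For each image: predict the 13 landmarks, calibrate the scale from the
#' detected fiducial pad (or the manifest's manual mm-per-px override when
#' present), and derive the nine measurements. Images whose pad cannot be
#' detected and that have no override are logged and reported as NA rows.
#'
#' @param checkpoint Checkpoint path from [cmd_train()].
#' @param manifest Manifest path.
#' @param out Output CSV path.
#' @param split Which split(s) to measure (default "test").
#' @param method Method tag written to the CSV (default "AM1").
#' @param verbose Log stage lines.
#' @return The measurement data frame, invisibly (also written to `out`).
#' @export
cmd_measure <- function(checkpoint, manifest, out, split = "test",
                        method = "AM1", verbose = TRUE) {
  model <- load_checkpoint(checkpoint)
  mf <- read_manifest(manifest)
  keep <- mf$entries$split %in% split
  ids <- mf$entries$image_id[keep]
  if (!length(ids)) fm_stop("fm_data_error", "no images in split '%s'", split)
  paths <- file.path(mf$dir, mf$entries$image[keep])
  override <- mf$entries$mm_per_px[keep]
  rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    img <- read_image(paths[i])
    lm <- predict_landmarks(model, img, crop_frame = mf$crop_frame)
    scale <- if (!is.na(override[i])) {
      calibration_scale(override[i], source = "manifest")
    } else {
      tryCatch(scale_from_pad(detect_pad(img)), fm_error = function(e) NULL)
    }
    if (is.null(scale)) {
      stage_log("measure", "id=%s pad not detected and no override; NA row",
                ids[i], verbose = verbose)
      mm <- setNames(rep(NA_real_, 9), paste0("M", 1:9))
    } else {
      mm <- compute_measurements(lm, scale)
    }
    rows[[i]] <- data.frame(subject_id = ids[i], method = method,
                            as.list(mm))
  }
  df <- do.call(rbind, rows)
  write_measurements_csv(df, out)
  stage_log("measure", "split=%s n=%d -> %s", paste(split, collapse = "/"),
            nrow(df), out, verbose = verbose)
  invisible(df)
}

#' Compare measurement methods (pipeline stage)
#'
#' Builds the agreement report (per-measurement paired differences, group
#' means, paired t-tests at both the 5% and 1% conventions) between the
#' conventional measurements and one or two automated versions.
#'
#' @param cm_csv CSV of conventional measurements.
#' @param am1_csv CSV of automated measurements (version 1).
#' @param am2_csv Optional CSV for version 2.
#' @param out Output CSV path for the report.
#' @param verbose Log stage lines.
#' @return The report data frame, invisibly.
#' @export
cmd_compare <- function(cm_csv, am1_csv, am2_csv = NULL, out, verbose = TRUE) {
  cm <- read_measurements_csv(cm_csv)
  am1 <- read_measurements_csv(am1_csv)
  am2 <- if (!is.null(am2_csv)) read_measurements_csv(am2_csv)
  report <- build_report(cm, am1, am2)
  write_report_csv(report, out)
  stage_log("compare", "%d rows, %d measurement(s) discordant at 1%% -> %s",
            nrow(report), count_significant(report, 0.01), out,
            verbose = verbose)
  invisible(report)
}
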