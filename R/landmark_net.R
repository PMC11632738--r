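#' Training configuration for the landmark network
#'
#' The two published presets differ only in epochs: version 1 trains for
#' 200 epochs, version 2 for 1000. Batch size is fixed at 1 (loss
#' normalization over larger batches was found ineffective for this
#' architecture); the loss is mean squared error on coordinates normalized
#' to \[0, 1\] by the crop frame, optimized with Adam.
#'
#' @param epochs Number of passes over the training images (>= 1).
#'   `version = 1` is shorthand for 200, `version = 2` for 1000.
#' @param version Optional preset (1 or 2) overriding `epochs`.
#' @param learning_rate Adam learning rate (default 1e-3, default moments).
#' @param augment Apply per-presentation augmentation (default TRUE): with
#'   probability `p_flip` a horizontal inversion (with bilateral landmark
#'   index swap), otherwise a saturation change.
#' @param p_flip Probability of the flip branch (default 0.5).
#' @param saturation_range Uniform range of the HSV saturation factor
#'   (default c(0.6, 1.4)).
#' @param seed Integer seed for initialization, shuffling and augmentation.
#' @return A `training_config` list.
#' @export
training_config <- function(epochs = 200L, version = NULL,
                            learning_rate = 1e-3, augment = TRUE,
                            p_flip = 0.5, saturation_range = c(0.6, 1.4),
                            seed = 1L) {
  if (!is.null(version)) {
    if (!version %in% 1:2) {
      fm_stop("fm_config_error", "version must be 1 (200 epochs) or 2 (1000 epochs)")
    }
    epochs <- c(200L, 1000L)[version]
  }
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L) {
    fm_stop("fm_config_error", "epochs must be >= 1")
  }
  structure(list(epochs = epochs, batch_size = 1L,
                 learning_rate = learning_rate, augment = isTRUE(augment),
                 p_flip = p_flip, saturation_range = saturation_range,
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Build an untrained landmark model
#'
#' Four 3x3 convolution stages (channels 16, 32, 64, 128), tanh
#' activations, 2x2 max pooling after each stage, then for each of the 13
#' facial landmarks its own two-layer fully connected head (512 -> 64 -> 2)
#' with sigmoid output, so every prediction is a normalized (x, y) pair in
#' \[0, 1\]^2. Input is a 40 x 40 RGB image. Initialization is seeded
#' (Glorot uniform).
#'
#' @param config A [training_config()].
#' @return A `landmark_model` (opaque parameter container + config).
#' @export
build_model <- function(config = training_config()) {
  stopifnot(inherits(config, "training_config"))
  structure(list(params = net_init_cpp(config$seed), config = config,
                 input_size = 40L, trained_epochs = 0L),
            class = "landmark_model")
}

#' @export
print.landmark_model <- function(x, ...) {
  cat(sprintf(paste0("Tweaked-style landmark model: 4 conv stages ",
                     "(16/32/64/128) + 13 heads, %d training epochs\n"),
              x$trained_epochs))
  invisible(x)
}

#' Augment an image/landmark pair
#'
#' Applies exactly one of the two augmentations per presentation: with
#' probability `p_flip` a horizontal inversion — pixels mirrored,
#' `x <- (width - 1) - x` for every landmark, and the bilateral index
#' pairs (4,5), (7,8), (9,10), (11,12) swapped so anatomical left/right
#' labels stay correct — otherwise the HSV saturation is scaled by a
#' factor drawn uniformly from `saturation_range` (landmarks unchanged).
#' Consumes the R random stream.
#'
#' @param image A [face_image()].
#' @param landmarks A [landmark_set()] in the image's frame.
#' @param p_flip Probability of the flip branch (default 0.5); use 1 or 0
#'   to force a branch.
#' @param saturation_range Uniform range for the saturation factor.
#' @return List with `image`, `landmarks`, and `applied` ("flip" or
#'   "saturation").
#' @export
augment <- function(image, landmarks, p_flip = 0.5,
                    saturation_range = c(0.6, 1.4)) {
  stopifnot(inherits(image, "face_image"), inherits(landmarks, "landmark_set"))
  if (runif(1) < p_flip) {
    px <- image$pixels[, image$width:1, , drop = FALSE]
    pts <- unclass(landmarks)
    pts[, 1] <- (image$width - 1) - pts[, 1]
    for (i in seq_len(nrow(bilateral_pairs()))) {
      pr <- bilateral_pairs()[i, ]
      pts[pr, ] <- pts[rev(pr), ]
    }
    list(image = face_image(px, id = image$id),
         landmarks = landmark_set(pts, landmark_frame(landmarks)),
         applied = "flip")
  } else {
    f <- runif(1, saturation_range[1], saturation_range[2])
    px <- sat_scale_cpp(image$pixels / 255, f) * 255
    list(image = face_image(px, id = image$id), landmarks = landmarks,
         applied = "saturation")
  }
}

# Load a manifest split as network-ready arrays: images resized to 40x40
# and scaled to [0,1]; targets = interleaved (x, y) / crop_frame.
load_split <- function(manifest, split = "train") {
  keep <- manifest$entries$split %in% split
  ids <- manifest$entries$image_id[keep]
  paths <- file.path(manifest$dir, manifest$entries$image[keep])
  n <- length(ids)
  if (n == 0L) {
    fm_stop("fm_data_error", "manifest split '%s' is empty",
            paste(split, collapse = "/"))
  }
  frame <- manifest$crop_frame
  images <- array(0, dim = c(40, 40, 3, n))
  targets <- matrix(0, 26, n)
  for (i in seq_len(n)) {
    img <- read_image(paths[i])
    images[, , , i] <- resize_to_input(img)$pixels / 255
    rec <- manifest$records[[ids[i]]]
    if (is.null(rec)) {
      fm_stop("fm_data_error", "no annotation for image id %s", ids[i])
    }
    targets[, i] <- as.vector(t(unclass(rec$landmarks))) / frame
  }
  list(images = images, targets = targets, ids = ids, frame = frame)
}

#' Train the landmark model
#'
#' Runs `epochs` passes over the training split, one Adam step per image
#' (batch size 1), applying the augmentation independently at each
#' presentation. Fully reproducible from the config seed on a single
#' thread.
#'
#' @param model A [build_model()] result.
#' @param manifest Manifest path or the result of [read_manifest()].
#' @param config Optional [training_config()] overriding the model's.
#' @param validation_split Optional split name ("test") to score after
#'   every epoch; NULL (default) disables validation scoring.
#' @return List with `model` (trained) and `history` (data frame with
#'   `epoch`, `loss`, and `val_loss` when requested).
#' @export
train_model <- function(model, manifest, config = model$config,
                        validation_split = NULL) {
  stopifnot(inherits(model, "landmark_model"),
            inherits(config, "training_config"))
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  tr <- load_split(manifest, "train")
  val_images <- numeric(0)
  val_targets <- matrix(0, 26, 0)
  if (!is.null(validation_split)) {
    va <- load_split(manifest, validation_split)
    val_images <- va$images
    val_targets <- va$targets
  }
  fit <- net_train_cpp(model$params, tr$images, tr$targets,
                       epochs = config$epochs, lr = config$learning_rate,
                       seed = config$seed, augment = config$augment,
                       p_flip = config$p_flip,
                       sat_range = config$saturation_range,
                       frame = tr$frame,
                       val_images = val_images, val_targets = val_targets)
  model$params <- fit$params
  model$config <- config
  model$trained_epochs <- model$trained_epochs + config$epochs
  history <- data.frame(epoch = seq_len(config$epochs),
                        loss = as.numeric(fit$history$train))
  if (!is.null(fit$history$validation)) {
    history$val_loss <- as.numeric(fit$history$validation)
  }
  list(model = model, history = history)
}

#' Predict the 13 landmarks on an image
#'
#' Resizes the image to the 40 x 40 network input, runs the forward pass,
#' and rescales the normalized pairs back to the crop frame. An untrained
#' model is allowed (its output is meaningless but well-formed).
#'
#' @param model A `landmark_model`.
#' @param image A [face_image()] (any size; resized internally).
#' @param crop_frame Frame to scale predictions to (default 1024).
#' @return A [landmark_set()] in the crop frame.
#' @export
predict_landmarks <- function(model, image, crop_frame = 1024) {
  stopifnot(inherits(model, "landmark_model"), inherits(image, "face_image"))
  inp <- resize_to_input(image)$pixels / 255
  out <- net_forward_cpp(model$params, inp)
  pts <- matrix(out, ncol = 2, byrow = TRUE) * crop_frame
  landmark_set(pts, frame = c(crop_frame, crop_frame))
}

#' Evaluate landmark localization error on a manifest split
#'
#' Reports the Euclidean error of every predicted landmark divided by the
#' subject's true intercanthal distance (the standard face-scale
#' normalization), per landmark and averaged.
#'
#' @param model A trained `landmark_model`.
#' @param manifest Manifest path or [read_manifest()] result.
#' @param split Split to evaluate (default "test").
#' @return List: `per_landmark` (named mean normalized errors),
#'   `mean_error`, `n`.
#' @export
evaluate_model <- function(model, manifest, split = "test") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  keep <- manifest$entries$split %in% split
  ids <- manifest$entries$image_id[keep]
  if (!length(ids)) {
    fm_stop("fm_data_error", "manifest split '%s' is empty", split)
  }
  paths <- file.path(manifest$dir, manifest$entries$image[keep])
  frame <- manifest$crop_frame
  errs <- matrix(0, length(ids), 13, dimnames = list(ids, landmark_names()))
  for (i in seq_along(ids)) {
    truth <- manifest$records[[ids[i]]]$landmarks
    pred <- predict_landmarks(model, read_image(paths[i]), crop_frame = frame)
    errs[i, ] <- sqrt(rowSums((unclass(pred) - unclass(truth))^2)) /
      intercanthal_px(truth)
  }
  list(per_landmark = colMeans(errs), mean_error = mean(errs),
       n = length(ids))
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint with a format-version header.
#'
#' @param model A `landmark_model`.
#' @param path Checkpoint path.
#' @return `path` invisibly; `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "landmark_model"))
  saveRDS(list(format = "facemetrics-checkpoint", version = 1L,
               model = unclass(model)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) {
    fm_stop("fm_io_error", "checkpoint not found: %s", path)
  }
  x <- readRDS(path)
  if (!identical(x$format, "facemetrics-checkpoint")) {
    fm_stop("fm_format_error", "not a facemetrics checkpoint: %s", path)
  }
  structure(x$model, class = "landmark_model")
}
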