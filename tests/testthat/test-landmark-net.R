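test_that("a fresh model satisfies the output contract deterministically", {
  m1 <- build_model(training_config(seed = 4))
  m2 <- build_model(training_config(seed = 4))
  img <- flat_image(40, 40, rgb = c(128, 100, 90))
  p1 <- predict_landmarks(m1, img, crop_frame = 1024)
  p2 <- predict_landmarks(m2, img, crop_frame = 1024)
  expect_equal(dim(unclass(p1)), c(13, 2))
  expect_true(all(is.finite(p1)))
  expect_true(all(unclass(p1) >= 0 & unclass(p1) <= 1024))
  expect_identical(unclass(p1), unclass(p2))

  m3 <- build_model(training_config(seed = 5))
  expect_false(identical(unclass(predict_landmarks(m3, img)), unclass(p1)))

  expect_error(
    facemetrics:::net_forward_cpp(m1$params, array(0, dim = c(39, 40, 3))),
    "40 x 40")
})

test_that("prediction rescales the normalized network output by the crop frame", {
  m <- build_model(training_config(seed = 8))
  img <- flat_image(64, 64, rgb = c(90, 110, 130))
  inp <- resize_to_input(img)$pixels / 255
  raw <- facemetrics:::net_forward_cpp(m$params, inp)
  pred <- predict_landmarks(m, img, crop_frame = 1024)
  expect_equal(unclass(pred),
               matrix(raw, ncol = 2, byrow = TRUE) * 1024,
               ignore_attr = TRUE)
  # normalized 0.5 maps to frame centre
  expect_equal(matrix(rep(0.5, 26), ncol = 2) * 1024,
               matrix(512, 13, 2))
})

test_that("forced horizontal flip is an involution with the bilateral swap", {
  set.seed(31)
  img <- face_image(random_pixels(40, 40))
  lm <- rescale_landmarks(demo_landmarks(), c(40, 40))
  once <- augment(img, lm, p_flip = 1)
  expect_identical(once$applied, "flip")
  twice <- augment(once$image, once$landmarks, p_flip = 1)
  expect_equal(twice$image$pixels, img$pixels)
  expect_equal(unclass(twice$landmarks), unclass(lm))
})

test_that("flip maps the worked inner-eye example correctly", {
  pts <- unclass(rescale_landmarks(demo_landmarks(), c(40, 40)))
  pts[10, ] <- c(10, 20)   # EyeRightInner
  pts[11, ] <- c(30, 20)   # EyeLeftInner
  img <- face_image(random_pixels(40, 40))
  out <- augment(img, landmark_set(pts, c(40, 40)), p_flip = 1)
  # index 9 (EyeRightInner) must hold the mirrored former left point
  expect_equal(unname(unclass(out$landmarks)["EyeRightInner", ]),
               c(40 - 1 - 30, 20))
  expect_equal(unname(unclass(out$landmarks)["EyeLeftInner", ]),
               c(40 - 1 - 10, 20))
})

test_that("saturation factor 1 leaves the image essentially unchanged", {
  set.seed(13)
  img <- face_image(random_pixels(40, 40))
  lm <- rescale_landmarks(demo_landmarks(), c(40, 40))
  out <- augment(img, lm, p_flip = 0, saturation_range = c(1, 1))
  expect_identical(out$applied, "saturation")
  expect_lt(max(abs(out$image$pixels - img$pixels)), 1)
  expect_identical(unclass(out$landmarks), unclass(lm))

  # desaturation moves channels toward each other
  grey <- augment(img, lm, p_flip = 0, saturation_range = c(0, 0))
  spread <- function(a) max(a) - min(a)
  expect_lt(mean(apply(grey$image$pixels, c(1, 2), spread)),
            mean(apply(img$pixels, c(1, 2), spread)))
})

test_that("training reduces the loss and is reproducible from its seed", {
  mf <- tiny_dataset(n = 8, seed = 11)
  cfg <- training_config(epochs = 15, seed = 2)
  fit1 <- train_model(build_model(cfg), mf, cfg)
  expect_equal(nrow(fit1$history), 15)
  expect_lt(fit1$history$loss[15], fit1$history$loss[1])

  fit2 <- train_model(build_model(cfg), mf, cfg)
  expect_identical(fit1$history$loss, fit2$history$loss)

  cfg3 <- training_config(epochs = 15, seed = 3)
  fit3 <- train_model(build_model(cfg3), mf, cfg3)
  expect_false(identical(fit1$history$loss, fit3$history$loss))
})

test_that("invalid training setups raise classed errors", {
  expect_error(training_config(epochs = 0), class = "fm_config_error")
  expect_error(training_config(version = 3), class = "fm_config_error")
  # all subjects in the test split leaves the training split empty
  mf_path <- tiny_dataset(n = 4, seed = 12, test_fraction = 1)
  cfg <- training_config(epochs = 1, seed = 1)
  expect_error(train_model(build_model(cfg), mf_path, cfg),
               class = "fm_data_error")
})

test_that("a single-image run overfits to pixel accuracy and mirrors consistently", {
  mf_path <- tiny_dataset(n = 1, seed = 15, test_fraction = 0)
  mf <- read_manifest(mf_path)
  img <- read_image(file.path(mf$dir, mf$entries$image[1]))
  truth <- mf$records[[1]]$landmarks

  # plain overfit sanity run (no augmentation): sub-pixel recovery
  cfg <- training_config(epochs = 1000, seed = 6, augment = FALSE)
  fit <- train_model(build_model(cfg), mf_path, cfg)
  pred <- predict_landmarks(fit$model, img, crop_frame = 1024)
  err <- sqrt(rowSums((unclass(pred) - unclass(truth))^2))
  expect_lte(mean(err), 2)   # <= 2 px at the 1024 scale

  # trained WITH flip augmentation (so it converges on the mirrored pair),
  # the mirrored image is predicted as the mirror of the prediction
  cfga <- training_config(epochs = 1000, seed = 6, augment = TRUE)
  fita <- train_model(build_model(cfga), mf_path, cfga)
  base <- predict_landmarks(fita$model, img, crop_frame = 1024)
  flipped <- augment(img, truth, p_flip = 1)
  pred_f <- predict_landmarks(fita$model, flipped$image, crop_frame = 1024)
  mapped <- unclass(pred_f)
  mapped[, 1] <- (1024 - 1) - mapped[, 1]
  for (k in seq_len(nrow(bilateral_pairs()))) {
    pr <- bilateral_pairs()[k, ]
    mapped[pr, ] <- mapped[rev(pr), ]
  }
  expect_lt(mean(sqrt(rowSums((mapped - unclass(base))^2))), 25)
})

test_that("evaluation normalizes landmark error by the intercanthal distance", {
  mf_path <- tiny_dataset(n = 4, seed = 18, test_fraction = 0.5)
  mf <- read_manifest(mf_path)
  cfg <- training_config(epochs = 1, seed = 1)
  model <- train_model(build_model(cfg), mf, cfg)$model

  # rewrite truth := prediction -> error exactly 0
  ids <- mf$entries$image_id[mf$entries$split == "test"]
  paths <- file.path(mf$dir, mf$entries$image[mf$entries$split == "test"])
  recs <- lapply(seq_along(ids), function(i) {
    p <- predict_landmarks(model, read_image(paths[i]), mf$crop_frame)
    annotation_record(ids[i], p)
  })
  train_ids <- mf$entries$image_id[mf$entries$split == "train"]
  all_recs <- c(lapply(train_ids, function(id) mf$records[[id]]), recs)
  dir2 <- file.path(tempdir(), "fm_eval_zero")
  dir.create(dir2, showWarnings = FALSE)
  file.copy(list.files(mf$dir, pattern = "\\.png$", full.names = TRUE), dir2,
            overwrite = TRUE)
  write_annotations(all_recs, file.path(dir2, "annotations.json"))
  write_manifest(mf$entries, "annotations.json",
                 file.path(dir2, "manifest.json"), crop_frame = mf$crop_frame)
  # annotations are stored at 0.01 px, so "zero" is bounded by that rounding
  ev0 <- evaluate_model(model, file.path(dir2, "manifest.json"), "test")
  expect_lt(ev0$mean_error, 1e-4)

  # truth offset horizontally by one intercanthal distance -> error 1.0
  recs1 <- lapply(recs, function(r) {
    icd <- intercanthal_px(r$landmarks)
    annotation_record(r$image_id,
                      shift_landmarks(r$landmarks, c(icd, 0), c(1024, 1024)))
  })
  write_annotations(c(lapply(train_ids, function(id) mf$records[[id]]), recs1),
                    file.path(dir2, "annotations.json"))
  ev1 <- evaluate_model(model, file.path(dir2, "manifest.json"), "test")
  expect_equal(ev1$mean_error, 1, tolerance = 1e-4)

  expect_error(evaluate_model(model, mf, "nope"), class = "fm_data_error")
})

test_that("checkpoints round-trip the trained model", {
  mf <- tiny_dataset(n = 4, seed = 18, test_fraction = 0.5)
  cfg <- training_config(epochs = 2, seed = 9)
  model <- train_model(build_model(cfg), mf, cfg)$model
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  img <- flat_image(40, 40, rgb = c(100, 100, 100))
  expect_identical(unclass(predict_landmarks(back, img)),
                   unclass(predict_landmarks(model, img)))
  expect_error(load_checkpoint(tempfile()), class = "fm_io_error")
})
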