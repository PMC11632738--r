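test_that("PNG write/read round-trips pixels losslessly", {
  img <- face_image(random_pixels(16, 16), id = "rt")
  path <- tempfile(fileext = ".png")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back$pixels, img$pixels)
  expect_identical(back$id, tools::file_path_sans_ext(basename(path)))

  black <- flat_image(8, 8)
  p2 <- tempfile(fileext = ".png")
  write_image(black, p2)
  expect_true(all(read_image(p2)$pixels == 0))
})

test_that("unreadable image files raise classed errors", {
  expect_error(read_image(tempfile(fileext = ".png")), class = "fm_io_error")
  bad <- tempfile(fileext = ".png")
  writeBin(as.raw(c(137, 80, 78, 71, 13, 10)), bad)   # truncated header
  expect_error(read_image(bad), class = "fm_format_error")
  txt <- tempfile(fileext = ".txt")
  writeLines("x", txt)
  expect_error(read_image(txt), class = "fm_format_error")
})

test_that("crop_centered extracts the expected window and offset", {
  px <- array(0, dim = c(4, 4, 3))
  px[, , 1] <- matrix(1:16, 4, 4) * 10   # distinct values
  img <- face_image(px, id = "grid")

  cr <- crop_centered(img, center = c(2, 2), size = 2)
  expect_equal(dim(cr$image$pixels), c(2, 2, 3))
  expect_equal(cr$offset, c(x = 1, y = 1))
  expect_equal(cr$image$pixels[, , 1], px[2:3, 2:3, 1])

  # corner centre: padding fills the out-of-frame side with black
  cc <- crop_centered(img, center = c(0, 0), size = 4)
  expect_equal(cc$offset, c(x = -2, y = -2))
  expect_true(all(cc$image$pixels[1:2, , ] == 0))
  expect_true(all(cc$image$pixels[, 1:2, ] == 0))
  expect_equal(cc$image$pixels[3:4, 3:4, 1], px[1:2, 1:2, 1])

  # size equal to source, centred: identity
  id <- crop_centered(img, center = c(1.5, 1.5), size = 4)
  expect_equal(id$image$pixels, px)
  expect_equal(id$offset, c(x = 0, y = 0))
})

test_that("crop offset shift preserves pairwise landmark distances", {
  lm <- demo_landmarks()
  shifted <- shift_landmarks(lm, offset = c(137, -42), frame = c(512, 512))
  expect_equal(as.numeric(dist(unclass(shifted))),
               as.numeric(dist(unclass(lm))))
})

test_that("resize_to_input obeys the 40x40 contract", {
  img40 <- face_image(random_pixels(40, 40))
  expect_equal(resize_to_input(img40)$pixels, img40$pixels)

  const <- flat_image(80, 80, rgb = c(10, 120, 200))
  out <- resize_to_input(const)
  expect_equal(dim(out$pixels), c(40, 40, 3))
  expect_equal(max(abs(out$pixels[, , 1] - 10)), 0)
  expect_equal(max(abs(out$pixels[, , 3] - 200)), 0)
})

test_that("landmark rescale uses the exact frame ratio and keeps distance ratios", {
  lm <- demo_landmarks(1024)
  pts <- unclass(lm)
  pts[1, ] <- c(512, 512)
  lm <- landmark_set(pts, c(1024, 1024))
  small <- rescale_landmarks(lm, c(40, 40))
  expect_equal(unname(unclass(small)[1, ]), c(20, 20))

  d0 <- as.numeric(dist(unclass(lm)))
  d1 <- as.numeric(dist(unclass(small)))
  expect_equal(d1 / d0, rep(40 / 1024, length(d0)), tolerance = 1e-9)
})

test_that("annotation JSON round-trips records at 0.01 px precision", {
  set.seed(5)
  recs <- lapply(1:3, function(i) {
    pts <- unclass(demo_landmarks()) + round(runif(26, -20, 20), 2)
    annotation_record(paste0("img", i), landmark_set(pts, c(1024, 1024)),
                      pad = list(center = c(500.25, 120.5), diameter = 51.3),
                      conventional = setNames(round(runif(9, 1, 70), 2),
                                              paste0("M", 1:9)))
  })
  path <- tempfile(fileext = ".json")
  write_annotations(recs, path)
  back <- read_annotations(path)
  for (i in 1:3) {
    expect_equal(unclass(back[[i]]$landmarks), unclass(recs[[i]]$landmarks))
    expect_equal(back[[i]]$pad$diameter, recs[[i]]$pad$diameter)
    expect_equal(unname(back[[i]]$conventional),
                 unname(recs[[i]]$conventional))
  }
})

test_that("annotation schema violations are reported by name", {
  rec <- annotation_record("a", demo_landmarks())
  path <- tempfile(fileext = ".json")
  write_annotations(list(rec), path)
  doc <- jsonlite::read_json(path)
  doc[[1]]$landmarks$Mentoniano <- NULL
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_annotations(path), "Mentoniano missing",
               class = "fm_schema_error")

  expect_error(write_annotations(list(rec, rec), tempfile()),
               class = "fm_validation_error")
})

test_that("mask rendering and recovery round-trip within half a pixel", {
  lm <- demo_landmarks()
  mask <- render_mask(lm)
  lab <- EBImage::bwlabel(t(mask != 0))
  expect_equal(max(lab), 13)

  back <- mask_to_landmarks(mask)
  expect_lt(max(abs(unclass(back) - unclass(lm))), 0.5 + 1e-12)

  # single-pixel components sit exactly on integer landmark coordinates
  m0 <- render_mask(lm, radius = 0.1)
  b0 <- mask_to_landmarks(m0)
  expect_equal(unclass(b0), round(unclass(lm)))
})

test_that("mask errors: out-of-range landmarks and wrong component counts", {
  lm <- demo_landmarks()
  expect_error(render_mask(lm, dims = c(600, 600)), class = "fm_range_error")

  mask <- render_mask(lm)
  mask[360:362, 432:434] <- 0L   # erase the disc at landmark 9 (432, 360)
  broken <- structure(mask, ordering = attr(mask, "ordering"))
  expect_error(mask_to_landmarks(broken), class = "fm_mask_error")

  expect_error(mask_to_landmarks(matrix(0L, 4, 4), ordering = NULL),
               class = "fm_schema_error")
})
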