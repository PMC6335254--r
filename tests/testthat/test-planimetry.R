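test_that("contrast stretch maps the percentile anchors to the extremes", {
  img <- matrix(runif(400, 0.3, 0.6), 20, 20)
  out <- enhance_contrast(img)
  expect_equal(range(out), c(0, 1))
  # monotone: order of distinct pixels preserved
  o <- order(img)
  expect_true(all(diff(out[o]) >= 0))
  # two-level image maps to the extremes
  two <- matrix(c(rep(40, 200), rep(200, 200)) / 255, 20, 20)
  expect_equal(sort(unique(as.vector(enhance_contrast(two)))), c(0, 1))
  # idempotent on an already-stretched two-level image
  expect_equal(enhance_contrast(two), enhance_contrast(enhance_contrast(two)))
  expect_error(enhance_contrast(matrix(0.5, 10, 10)), "no contrast")
})

test_that("RGB input is reduced to luminance before processing", {
  rgb <- array(0, c(10, 10, 3))
  rgb[, , 1] <- 0.5; rgb[, , 2] <- 0.2; rgb[, , 3] <- 0.9
  gray <- pigspace:::to_gray(rgb)
  expect_equal(unique(as.vector(gray)), 0.299 * 0.5 + 0.587 * 0.2 + 0.114 * 0.9)
})

test_that("component labelling is 8-connective", {
  m <- matrix(FALSE, 6, 6)
  m[cbind(1:5, 1:5)] <- TRUE              # pure diagonal chain
  lab <- pigspace:::label_components(m)
  expect_equal(max(lab), 1)
  m[6, 1] <- TRUE                          # isolated pixel
  expect_equal(max(pigspace:::label_components(m)), 2)
})

test_that("segmentation recovers the rendered silhouette almost exactly", {
  for (code in c("A", "LL")) {
    sil <- make_silhouette(code, 108, shape_k[[code]], shape_seed = 8)
    rs <- render_single(sil)
    mask <- segment_silhouette(rs$image)
    expect_gte(iou(mask, rs$masks[[1]]), 0.99)
  }
  expect_error(segment_silhouette(matrix(0.5, 8, 8)), "no contrast")
})

test_that("segmentation works on both polarities and with fixed thresholds", {
  sil <- make_silhouette("C", 100, shape_k[["C"]], shape_seed = 2)
  dark_on_bright <- render_single(sil)
  inverted <- dark_on_bright
  inverted$image <- 1 - inverted$image
  m1 <- segment_silhouette(dark_on_bright$image)
  m2 <- segment_silhouette(inverted$image)
  expect_equal(m1, m2)
  m3 <- segment_silhouette(dark_on_bright$image,
                           segmentation_config(threshold_mode = "fixed",
                                               fixed_threshold = 0.5))
  expect_equal(m3, m1)
  expect_error(segmentation_config(threshold_mode = "fixed"),
               "fixed_threshold")
})

test_that("exclusion masks remove artifacts and never increase the count", {
  cam <- camera_model()
  sil <- make_silhouette("D", 112, shape_k[["D"]], shape_seed = 6)
  clean <- render_scene(scene_spec(cam, list(sil)))
  blob <- list(type = "speck", centre = c(-0.8, 0.35), radii = c(0.10, 0.08),
               level = 0.2)
  dirty <- render_scene(scene_spec(cam, list(sil), artifacts = list(blob)))
  excl <- matrix(FALSE, cam$image_height, cam$image_width)
  th <- seq(0, 2 * pi, length.out = 65)[-65]
  ppx <- pigspace:::project_polygon(cam, cbind(blob$centre[1] + 0.12 * cos(th),
                                               blob$centre[2] + 0.11 * sin(th)), 0)
  excl[pigspace:::rasterize_polygon(ppx, cam$image_width, cam$image_height)] <- TRUE

  cfg <- segmentation_config(min_component_fraction = 0)  # keep everything
  n_clean <- sum(segment_silhouette(clean$image, cfg))
  n_dirty <- sum(segment_silhouette(dirty$image, cfg))
  n_masked <- sum(segment_silhouette(dirty$image, cfg, exclusion_mask = excl))
  expect_gt(n_dirty, n_clean)            # the speck contaminates the count
  expect_equal(n_masked, n_clean)        # exclusion restores the clean count
  expect_lte(n_masked, n_dirty)
  # component filtering alone also rejects the small speck
  n_filtered <- sum(segment_silhouette(dirty$image, segmentation_config()))
  expect_equal(n_filtered, n_clean)
})

test_that("hole filling recovers enclosed background", {
  img <- matrix(0.9, 50, 50)
  img[10:40, 10:40] <- 0.1
  img[20:30, 20:30] <- 0.9                # enclosed hole
  filled <- segment_silhouette(img, segmentation_config(fill_holes = TRUE))
  open <- segment_silhouette(img, segmentation_config(fill_holes = FALSE))
  expect_equal(sum(filled), 31^2)
  expect_equal(sum(open), 31^2 - 11^2)
})

test_that("calibration converts the board count to pixel density", {
  rs <- render_single(reference_board(0.420, height = 69))
  cal <- calibrate(rs$image, 0.420, 69)
  expect_equal(cal$pixels_per_m2, cal$reference_pixel_count / 0.420)
  expect_equal(cal$reference_height, 69)
  expect_error(calibrate(rs$image, 0, 69), "> 0")
  # exposure-invariance: same board at different contrast levels
  dim_img <- render_scene(scene_spec(camera_model(),
                                     list(reference_board(0.420, height = 69)),
                                     background_level = 0.55,
                                     foreground_level = 0.25))
  cal2 <- calibrate(dim_img$image, 0.420, 69)
  expect_equal(cal2$pixels_per_m2, cal$pixels_per_m2, tolerance = 0.005)
})

test_that("measure_area is count / density and guards the calibration height", {
  cal <- structure(list(pixels_per_m2 = 238095.24, reference_area = 0.420,
                        reference_height = 69, reference_pixel_count = 100000),
                   class = "calibration")
  mask <- matrix(FALSE, 300, 300); mask[1:280, 1:250] <- TRUE  # 70,000 px
  m <- measure_area(mask, cal, "A")
  expect_equal(m$pixel_count, 70000)
  expect_equal(m$area, 0.294, tolerance = 1e-5)
  expect_warning(measure_area(mask, cal, "LL"), "29 cm calibration")
  expect_error(measure_area(mask, cal, "LL", strict_height = TRUE),
               "29 cm calibration")
})

test_that("measured areas match the analytic planform ground truth within 1%", {
  cam <- camera_model()
  cal69 <- calibrate(render_single(reference_board(0.42, height = 69), cam)$image,
                     0.42, 69)
  cal29 <- calibrate(render_single(reference_board(0.42, height = 29), cam)$image,
                     0.42, 29)
  for (code in c("A", "E", "LBC", "LL")) {
    sil <- make_silhouette(code, 115, shape_k[[code]], shape_seed = 31)
    rs <- render_single(sil, cam)
    cal <- if (reference_height_for(code) == 69) cal69 else cal29
    m <- measure_area(rs$image, cal, code)
    expect_equal(m$area, sil$planform_area, tolerance = 0.01,
                 label = paste("measured area for", code))
  }
})

test_that("a height-mismatched calibration biases the area by the squared magnification ratio", {
  cam <- camera_model()
  cal69 <- calibrate(render_single(reference_board(0.42, height = 69), cam)$image,
                     0.42, 69)
  board29 <- reference_board(0.300, height = 29)
  rs <- render_single(board29, cam)
  m <- suppressWarnings(measure_area(rs$image, cal69, "LBC"))
  expect_equal(m$area / 0.300, ((245 - 69) / (245 - 29))^2, tolerance = 0.01)
})

test_that("measured areas are invariant to the floor sampling density", {
  for (s in c(300, 600)) {
    cam <- camera_model(floor_scale = s)
    cal <- calibrate(render_single(reference_board(0.42, height = 69), cam)$image,
                     0.42, 69)
    sil <- make_silhouette("C", 110, shape_k[["C"]], shape_seed = 12)
    m <- measure_area(render_single(sil, cam)$image, cal, "C")
    expect_equal(m$area, sil$planform_area, tolerance = 0.01)
  }
})

test_that("enlarging a silhouette strictly increases its measured area", {
  cam <- camera_model()
  cal <- calibrate(render_single(reference_board(0.42, height = 69), cam)$image,
                   0.42, 69)
  areas <- vapply(c(90, 110, 130), function(w) {
    sil <- make_silhouette("B", w, shape_k[["B"]], shape_seed = 14)
    measure_area(render_single(sil, cam)$image, cal, "B")$area
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("batch measurement selects calibrations by posture and reports failures", {
  dir <- withr::local_tempdir()
  simulate_cohort(study_tab, n_per_posture = 1, seed = 21, dir = dir,
                  postures = c("A", "LL"))
  cals <- list(calibrate(file.path(dir, "calibration_h69.png"), 0.42, 69),
               calibrate(file.path(dir, "calibration_h29.png"), 0.42, 29))
  res <- measure_batch(dir, file.path(dir, "manifest.csv"), cals)
  expect_equal(nrow(res), 2)
  expect_equal(res$calibration_height,
               unname(reference_height_for(res$posture)))

  manifest <- read.csv(file.path(dir, "manifest.csv"))
  manifest <- rbind(manifest,
                    data.frame(filename = "ghost.png", subject_id = "g",
                               posture = "A", weight_kg = 100))
  expect_warning(res2 <- measure_batch(dir, manifest, cals), "1 of 3")
  expect_equal(nrow(res2), 2)
  fails <- attr(res2, "failures")
  expect_equal(fails$filename, "ghost.png")
  expect_match(fails$error, "not found")

  expect_warning(res3 <- measure_batch(dir, manifest[0, ], cals),
                 "empty manifest")
  expect_equal(nrow(res3), 0)
  # missing lying calibration is an itemized failure, not a crash
  expect_warning(res4 <- measure_batch(dir, read.csv(file.path(dir, "manifest.csv")),
                                       cals[1]), "1 of 2")
  expect_match(attr(res4, "failures")$error, "no calibration at 29")
})
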