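#' Describe a synthetic top-view scene
#'
#' A scene is a camera plus a list of objects (pig silhouettes from
#' [make_silhouette()] and/or reference boards from [reference_board()]),
#' rendered as a dark object on the brightly fluorescing floor:
#' `background_level` is the floor intensity, `foreground_level` the
#' object intensity (defaults emulate a dark animal on a UV-lit
#' fluorescent floor). Optional artifacts — elliptical `shadow` patches
#' and small contamination `speck` blobs at their own intensities — model
#' the disturbances that required retouching in the physical setup; here
#' they are handled by exclusion masks and component filtering instead.
#'
#' @param camera a [camera_model()].
#' @param objects list of `silhouette`/`reference_board` objects.
#' @param positions optional list/matrix of floor positions (x, y) in
#'   metres, origin under the lens; defaults to all objects centred.
#' @param background_level,foreground_level intensities in `[0, 1]`.
#' @param artifacts list of artifacts, each a list with `type`
#'   (`"shadow"` or `"speck"`), `centre` (m), `radii` (m, length 2),
#'   `level` (intensity).
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(camera = camera_model(), objects = list(),
                       positions = NULL,
                       background_level = 0.85, foreground_level = 0.12,
                       artifacts = list()) {
  stopifnot(inherits(camera, "camera_model"), is.list(objects))
  if (length(objects) > 0 &&
      abs(foreground_level - background_level) < 1e-12 &&
      length(artifacts) == 0) {
    warning("foreground and background levels are equal: objects will be invisible")
  }
  if (is.null(positions)) {
    positions <- replicate(length(objects), c(0, 0), simplify = FALSE)
  }
  if (is.matrix(positions)) positions <- asplit(positions, 1)
  stopifnot(length(positions) == length(objects))
  structure(list(camera = camera, objects = objects, positions = positions,
                 background_level = background_level,
                 foreground_level = foreground_level,
                 artifacts = artifacts),
            class = "scene_spec")
}

#' A planar rectangular reference board of known area
#'
#' The pixel-to-area calibration reference: a planar rectangle of known
#' area (study value 0.420 m^2, sized like a fattening pig seen from
#' above) mounted parallel to the floor at the height representative of
#' the posture class being measured (69 cm standing, 29 cm lying).
#'
#' @param known_area board area, m^2.
#' @param height mounting height above the floor, cm.
#' @param aspect length/width ratio of the rectangle.
#' @return an object of class `reference_board` (also usable wherever a
#'   scene object is expected).
#' @examples
#' reference_board(0.420, height = 69)
#' @export
reference_board <- function(known_area = 0.420, height = 0, aspect = 24 / 7) {
  stopifnot(known_area > 0, height >= 0, aspect > 0)
  w <- sqrt(known_area / aspect)
  l <- known_area / w
  poly <- cbind(x = c(-l, l, l, -l) / 2, y = c(-w, -w, w, w) / 2)
  structure(list(polygon = poly, planform_area = known_area,
                 target_area = known_area, posture = NA_character_,
                 weight = NA_real_, object_height = height,
                 known_area = known_area),
            class = c("reference_board", "silhouette"))
}

# Rasterize a polygon given in pixel coordinates onto a height x width
# grid. Pixel (r, c) is foreground iff its centre (c - 0.5, r - 0.5) lies
# inside the polygon (even-odd rule, half-open edge spans so shared
# edges are counted once).
rasterize_polygon <- function(polygon, width, height) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  x1 <- polygon[, 1]; y1 <- polygon[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  rmin <- max(1L, floor(min(y1) + 0.5))
  rmax <- min(height, ceiling(max(y1) + 0.5))
  if (rmin > rmax) return(mask)
  for (r in rmin:rmax) {
    y0 <- r - 0.5
    crosses <- (y1 <= y0) != (y2 <= y0)
    if (!any(crosses)) next
    xs <- x1[crosses] + (y0 - y1[crosses]) *
      (x2[crosses] - x1[crosses]) / (y2[crosses] - y1[crosses])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c_lo <- max(1L, floor(xs[i] + 0.5) + 1L)
      c_hi <- min(width, ceiling(xs[i + 1] + 0.5) - 1L)
      if (c_lo <= c_hi) mask[r, c_lo:c_hi] <- TRUE
    }
  }
  mask
}

# Project a polygon in floor-plane metres (origin under the lens) at a
# given object height into pixel coordinates.
project_polygon <- function(camera, polygon, object_height, position = c(0, 0)) {
  m <- project_scale(camera, object_height)
  s <- camera$floor_scale
  cx <- camera$image_width / 2
  cy <- camera$image_height / 2
  px <- cx + (polygon[, 1] + position[1]) * m * s
  py <- cy + (polygon[, 2] + position[2]) * m * s
  cbind(px, py)
}

#' Render a synthetic scene to a raster image with ground truth
#'
#' Draws each object at `foreground_level`, magnified according to its
#' height by the pinhole model and centred at its floor position;
#' artifacts are drawn at their own intensities beneath the objects;
#' everything else is `background_level`. Rasterization uses the
#' pixel-centre-inside rule, so the per-object ground-truth masks are the
#' exact reference for segmentation accuracy.
#'
#' @param scene a [scene_spec()].
#' @return list with `image` (numeric matrix, rows = image rows, values
#'   in `[0, 1]`), `truth` (data frame: `object`, `posture`, `weight`,
#'   `object_height`, `planform_area` m^2, `pixel_count` of the
#'   ground-truth raster, `expected_pixels` = analytic
#'   `planform_area * floor_scale^2 * magnification^2`), and `masks`
#'   (list of logical ground-truth masks, one per object).
#' @export
render_scene <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  cam <- scene$camera
  img <- matrix(scene$background_level, nrow = cam$image_height,
                ncol = cam$image_width)

  for (a in scene$artifacts) {
    stopifnot(a$type %in% c("shadow", "speck"))
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    poly <- cbind(a$centre[1] + a$radii[1] * cos(th),
                  a$centre[2] + a$radii[2] * sin(th))
    ppx <- project_polygon(cam, poly, 0)
    img[rasterize_polygon(ppx, cam$image_width, cam$image_height)] <- a$level
  }

  masks <- vector("list", length(scene$objects))
  truth <- vector("list", length(scene$objects))
  for (i in seq_along(scene$objects)) {
    obj <- scene$objects[[i]]
    stopifnot(inherits(obj, "silhouette"))
    ppx <- project_polygon(cam, obj$polygon, obj$object_height,
                           scene$positions[[i]])
    if (min(ppx[, 1]) < 0 || max(ppx[, 1]) > cam$image_width ||
        min(ppx[, 2]) < 0 || max(ppx[, 2]) > cam$image_height) {
      stop("object ", i, " projects outside the image frame", call. = FALSE)
    }
    m <- rasterize_polygon(ppx, cam$image_width, cam$image_height)
    img[m] <- scene$foreground_level
    masks[[i]] <- m
    mag <- project_scale(cam, obj$object_height)
    truth[[i]] <- data.frame(
      object = i, posture = obj$posture, weight = obj$weight,
      object_height = obj$object_height,
      planform_area = obj$planform_area,
      pixel_count = sum(m),
      expected_pixels = obj$planform_area * cam$floor_scale^2 * mag^2,
      stringsAsFactors = FALSE)
  }
  list(image = img, truth = do.call(rbind, truth), masks = masks)
}

#' Tune per-posture shape noise to the study's area spread
#'
#' Chooses the generator's relative area noise so that a simulated
#' cohort's per-posture area SD matches the study's printed area SD once
#' the weight-driven spread is accounted for. On the log scale the area
#' relative SD decomposes approximately into the allometric part
#' `0.66 * (weight_sd / weight_mean)` plus the independent shape noise,
#' so the tuned value is
#' `sqrt(max((area_sd/area_mean)^2 - (0.66 * weight_sd/weight_mean)^2, floor^2))`.
#'
#' @param tables study table from [load_study_tables()].
#' @param floor minimum relative SD returned (keeps a little biological
#'   shape variability even where the printed spread is fully explained
#'   by weight).
#' @return named numeric vector of relative SDs, one per posture.
#' @export
tune_shape_noise <- function(tables, floor = 0.02) {
  rel_area <- tables$area_sd / tables$area_mean
  rel_w <- ALLOMETRIC_EXPONENT * tables$weight_sd / tables$weight_mean
  out <- sqrt(pmax(rel_area^2 - rel_w^2, floor^2))
  names(out) <- tables$posture
  out
}

# Truncated-normal draw by rejection; bounds are a few SDs out so
# acceptance is high.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Simulate a cohort of posture scenes with analytic ground truth
#'
#' Generates `n_per_posture` animals for each of the 13 postures. Live
#' weights follow the study's per-posture distributions by default
#' (`weight_model = "group"`: normal at the printed group mean/SD,
#' truncated to the printed min/max), or a flat `"uniform"` draw over
#' `weight_range`. Shape coefficients default to
#' [fit_shape_coefficients()] on the study tables and area noise to
#' [tune_shape_noise()], so the simulated cohort reproduces the study's
#' per-posture area means and approximates its SDs. Per-scene seeds are
#' derived from `seed` by a counter, so cohorts are reproducible and any
#' single scene can be regenerated in isolation.
#'
#' With `dir` set, every scene is rendered and written as an 8-bit
#' grayscale PNG together with calibration-board images at both reference
#' heights, a `manifest.csv` (filename, subject_id, posture, weight_kg)
#' and a `ground_truth.csv`; otherwise the silhouettes are returned
#' in-memory without rasterization (fast path for statistical cohorts).
#'
#' @param tables study table from [load_study_tables()].
#' @param n_per_posture animals per posture.
#' @param seed master integer seed.
#' @param weight_model `"group"` or `"uniform"`.
#' @param weight_range used by the uniform model, kg (study range
#'   75--133).
#' @param shape_noise single relative SD for all postures, or a named
#'   per-posture vector; default [tune_shape_noise()] on `tables`.
#' @param k named per-posture coefficient vector; default fitted from
#'   `tables`.
#' @param camera a [camera_model()]; only used when rendering.
#' @param dir output directory for rendered scenes, or `NULL` for the
#'   in-memory cohort.
#' @param postures subset of posture codes to simulate.
#' @return data frame with one row per animal-scene: `subject_id`,
#'   `posture`, `weight`, `planform_area`, `object_height`, `scene_seed`,
#'   and (when `dir` is given) `filename`; the list of `silhouette`
#'   objects is attached as attribute `"silhouettes"` (in-memory mode).
#' @export
simulate_cohort <- function(tables = load_study_tables(), n_per_posture = 2,
                            seed = 1,
                            weight_model = c("group", "uniform"),
                            weight_range = c(75, 133),
                            shape_noise = NULL, k = NULL,
                            camera = camera_model(), dir = NULL,
                            postures = posture_codes()) {
  weight_model <- match.arg(weight_model)
  check_posture(postures)
  if (is.null(k)) k <- fit_shape_coefficients(tables)
  if (is.null(shape_noise)) shape_noise <- tune_shape_noise(tables)
  if (length(shape_noise) == 1 && is.null(names(shape_noise))) {
    shape_noise <- stats::setNames(rep(shape_noise, 13), posture_codes())
  }
  if (n_per_posture < 0) stop("n_per_posture must be >= 0", call. = FALSE)

  rows <- list(); sils <- list(); counter <- 0L
  for (code in postures) {
    row <- tables[tables$posture == code, ]
    for (j in seq_len(n_per_posture)) {
      counter <- counter + 1L
      sseed <- derive_seed(seed, counter)
      w <- with_seed(derive_seed(sseed, 10^6), {
        if (weight_model == "group") {
          rtruncnorm(1, row$weight_mean, row$weight_sd,
                     row$weight_min, row$weight_max)
        } else {
          stats::runif(1, weight_range[1], weight_range[2])
        }
      })
      sil <- make_silhouette(code, w, k[[code]], shape_seed = sseed,
                             shape_noise = shape_noise[[code]])
      sils[[counter]] <- sil
      rows[[counter]] <- data.frame(
        subject_id = sprintf("%s_%03d", code, j), posture = code,
        weight = w, planform_area = sil$planform_area,
        object_height = sil$object_height, scene_seed = sseed,
        stringsAsFactors = FALSE)
    }
  }
  cohort <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(subject_id = character(), posture = character(),
               weight = numeric(), planform_area = numeric(),
               object_height = numeric(), scene_seed = integer())

  if (is.null(dir)) {
    attr(cohort, "silhouettes") <- sils
    return(cohort)
  }

  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (nrow(cohort) == 0) warning("empty cohort: writing calibration images only")
  fnames <- character(nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    sc <- scene_spec(camera, objects = list(sils[[i]]))
    rs <- render_scene(sc)
    fnames[i] <- paste0(cohort$subject_id[i], ".png")
    png::writePNG(rs$image, file.path(dir, fnames[i]))
  }
  cohort$filename <- fnames
  for (h in c(69, 29)) {
    board <- reference_board(0.420, height = h)
    rs <- render_scene(scene_spec(camera, objects = list(board)))
    png::writePNG(rs$image, file.path(dir, sprintf("calibration_h%02d.png", h)))
  }
  utils::write.csv(
    data.frame(filename = cohort$filename, subject_id = cohort$subject_id,
               posture = cohort$posture, weight_kg = cohort$weight),
    file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(
    cohort[c("subject_id", "posture", "weight", "planform_area",
             "object_height", "scene_seed", "filename")],
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  cohort
}
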