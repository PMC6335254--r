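#' Segmentation configuration
#'
#' @param threshold_mode `"automatic"` uses the inter-class
#'   variance-maximizing (Otsu) threshold; `"fixed"` uses
#'   `fixed_threshold`.
#' @param fixed_threshold intensity in `[0, 1]`, required when
#'   `threshold_mode = "fixed"`.
#' @param min_component_fraction besides the largest connected component,
#'   keep any component whose pixel count is at least this fraction of
#'   the largest; in `[0, 1]`, default 0.5.
#' @param fill_holes fill enclosed background holes in the kept
#'   components (a pig seen from above is simply connected); default
#'   `TRUE`.
#' @param polarity which side of the threshold is the object: `"dark"`
#'   (dark animal on the fluorescing floor), `"bright"`, or `"auto"`
#'   (the minority side — the animal occupies less than half the frame).
#' @return an object of class `segmentation_config`.
#' @export
segmentation_config <- function(threshold_mode = c("automatic", "fixed"),
                                fixed_threshold = NULL,
                                min_component_fraction = 0.5,
                                fill_holes = TRUE,
                                polarity = c("auto", "dark", "bright")) {
  threshold_mode <- match.arg(threshold_mode)
  polarity <- match.arg(polarity)
  if (threshold_mode == "fixed") {
    if (is.null(fixed_threshold) || fixed_threshold < 0 || fixed_threshold > 1)
      stop("fixed_threshold must be given in [0, 1]", call. = FALSE)
  }
  if (min_component_fraction < 0 || min_component_fraction > 1)
    stop("min_component_fraction must be in [0, 1]", call. = FALSE)
  structure(list(threshold_mode = threshold_mode,
                 fixed_threshold = fixed_threshold,
                 min_component_fraction = min_component_fraction,
                 fill_holes = fill_holes, polarity = polarity),
            class = "segmentation_config")
}

# Reduce an image to one channel. 3-channel arrays use the Rec.601
# luminance weights; matrices pass through.
to_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (is.array(image) && length(dim(image)) == 3) {
    ch <- dim(image)[3]
    if (ch >= 3) {
      return(0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3])
    }
    return(image[, , 1])
  }
  stop("image must be a matrix or a 3-d array", call. = FALSE)
}

#' Linear contrast stretch
#'
#' Rescales intensities linearly so that the `lower` and `upper`
#' percentiles map to 0 and 1 (values beyond them are clipped). The map
#' is monotone, so thresholding after the stretch selects the same
#' pixels as an equivalently-placed threshold before it; the stretch
#' reproduces the manual "increase in contrast" step that most images
#' needed before automatic detection.
#'
#' @param image numeric matrix (or RGB array; reduced to luminance).
#' @param lower,upper percentile anchors in `[0, 1]`.
#' @return numeric matrix with range `[0, 1]`.
#' @export
enhance_contrast <- function(image, lower = 0.01, upper = 0.99) {
  img <- to_gray(image)
  q <- stats::quantile(img, c(lower, upper), names = FALSE, type = 7)
  if (diff(q) <= 0) {
    if (max(img) - min(img) <= .Machine$double.eps) {
      stop("image has no contrast (constant intensity)", call. = FALSE)
    }
    q <- range(img)
  }
  pmin(pmax((img - q[1]) / (q[2] - q[1]), 0), 1)
}

# 8-connectivity labelling: EBImage::bwlabel labels 4-connected sets, so
# labels that touch only diagonally are merged afterwards with a
# union-find pass over the label adjacency found on the four diagonal
# shifts.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow = nrow(mask))
  n <- max(lab)
  if (n <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  a <- lab[-nr, -nc]; b <- lab[-1, -1]      # down-right diagonal
  c_ <- lab[-nr, -1]; d <- lab[-1, -nc]     # down-left diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) > 0) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
    for (r in seq_len(nrow(pairs))) {
      ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
    root <- vapply(seq_len(n), find, integer(1))
    relab <- match(root, sort(unique(root)))
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  lab
}

#' Segment the animal silhouette from a top-view image
#'
#' Contrast-based detection of the object pixels: threshold the image
#' (automatic inter-class-variance threshold by default), orient the
#' mask by `config$polarity`, zero out any pixels covered by the
#' exclusion mask (the computable replacement for manual retouching of
#' shadows and contamination), label connected components with
#' 8-connectivity, keep the largest component plus any component at
#' least `min_component_fraction` of its size, and optionally fill
#' enclosed holes.
#'
#' @param image numeric matrix in `[0, 1]` (or RGB array).
#' @param config a [segmentation_config()].
#' @param exclusion_mask optional logical matrix of the same size;
#'   `TRUE` pixels are removed before component analysis.
#' @return logical matrix, `TRUE` on the segmented object.
#' @export
segment_silhouette <- function(image, config = segmentation_config(),
                               exclusion_mask = NULL) {
  stopifnot(inherits(config, "segmentation_config"))
  img <- to_gray(image)
  if (max(img) - min(img) <= .Machine$double.eps) {
    stop("image has no contrast (constant intensity)", call. = FALSE)
  }
  thr <- if (config$threshold_mode == "fixed") config$fixed_threshold else
    EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  fg <- img > thr
  fg <- switch(config$polarity,
               bright = fg,
               dark = !fg,
               auto = if (sum(fg) <= length(fg) / 2) fg else !fg)
  if (!is.null(exclusion_mask)) {
    stopifnot(identical(dim(exclusion_mask), dim(img)))
    fg[exclusion_mask] <- FALSE
  }
  if (!any(fg)) stop("no foreground pixels after thresholding", call. = FALSE)
  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= config$min_component_fraction * max(sizes))
  out <- matrix(lab %in% keep, nrow = nrow(lab))
  if (config$fill_holes) {
    out <- EBImage::fillHull(out) > 0
  }
  out
}

#' Pixel-to-area calibration from a reference image
#'
#' Segments the reference board of known area from an image taken under
#' the same camera geometry as the animals and returns the pixel density
#' `pixels_per_m2 = pixel_count / known_area`, tagged with the mounting
#' height so that measurements can verify they use a calibration taken
#' at the posture's reference height.
#'
#' @param reference_image numeric matrix (or RGB array) showing the
#'   board, or a PNG file path.
#' @param known_area board area in m^2 (study board: 0.420).
#' @param reference_height board mounting height in cm.
#' @param config a [segmentation_config()].
#' @return an object of class `calibration`: `pixels_per_m2`,
#'   `reference_area`, `reference_height`, `reference_pixel_count`.
#' @examples
#' \dontrun{
#' cal <- calibrate(board_img, known_area = 0.420, reference_height = 69)
#' }
#' @export
calibrate <- function(reference_image, known_area = 0.420, reference_height,
                      config = segmentation_config()) {
  if (known_area <= 0) stop("known_area must be > 0", call. = FALSE)
  if (is.character(reference_image)) {
    reference_image <- png::readPNG(reference_image)
  }
  mask <- segment_silhouette(reference_image, config)
  count <- sum(mask)
  structure(list(pixels_per_m2 = count / known_area,
                 reference_area = known_area,
                 reference_height = reference_height,
                 reference_pixel_count = count),
            class = "calibration")
}

#' Convert a segmented silhouette to a covered-area measurement
#'
#' `area = foreground pixel count / calibration$pixels_per_m2`. The
#' calibration's mounting height must match the posture's reference
#' height (69 cm standing, 29 cm lying): a mismatch biases the area by
#' the squared magnification ratio and is an error with
#' `strict_height = TRUE`, otherwise a warning.
#'
#' @param x logical mask, numeric image (segmented with `config`), or a
#'   PNG file path.
#' @param calibration a [calibrate()] result.
#' @param posture posture code of the photographed animal.
#' @param subject_id optional identifier carried into the result.
#' @param weight optional live weight (kg) carried into the result.
#' @param config a [segmentation_config()], used when `x` is an image.
#' @param exclusion_mask optional exclusion mask, used when `x` is an
#'   image.
#' @param strict_height fail (rather than warn) on a calibration-height
#'   mismatch.
#' @return one-row data frame: `subject_id`, `posture`, `weight`,
#'   `pixel_count`, `area` (m^2), `calibration_height`.
#' @export
measure_area <- function(x, calibration, posture, subject_id = NA_character_,
                         weight = NA_real_, config = segmentation_config(),
                         exclusion_mask = NULL, strict_height = FALSE) {
  stopifnot(inherits(calibration, "calibration"))
  check_posture(posture)
  want <- reference_height_for(posture)
  if (!isTRUE(all.equal(want, calibration$reference_height))) {
    msg <- sprintf(
      "posture %s expects a %g cm calibration but got %g cm", posture,
      want, calibration$reference_height)
    if (strict_height) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (is.character(x)) x <- png::readPNG(x)
  mask <- if (is.logical(x)) x else segment_silhouette(x, config, exclusion_mask)
  count <- sum(mask)
  if (count == 0) stop("empty mask: no object pixels", call. = FALSE)
  data.frame(subject_id = subject_id, posture = posture, weight = weight,
             pixel_count = count,
             area = count / calibration$pixels_per_m2,
             calibration_height = calibration$reference_height,
             stringsAsFactors = FALSE)
}

#' Measure a directory of images listed in a manifest
#'
#' Runs [measure_area()] over every manifest row, selecting for each
#' image the calibration whose mounting height matches the posture's
#' reference height. Per-image failures (missing file, unknown posture,
#' failed segmentation) are collected and reported, never silently
#' dropped.
#'
#' @param image_dir directory containing the images.
#' @param manifest data frame (or CSV path) with columns `filename`,
#'   `subject_id`, `posture` and optionally `weight_kg`.
#' @param calibrations list of [calibrate()] results covering the needed
#'   reference heights.
#' @param config a [segmentation_config()].
#' @return data frame of measurements (one row per successful image);
#'   failures are attached as attribute `"failures"` (data frame
#'   `filename`, `error`) and raised as a warning.
#' @export
measure_batch <- function(image_dir, manifest,
                          calibrations, config = segmentation_config()) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("filename", "subject_id", "posture") %in% names(manifest)))
  if (!"weight_kg" %in% names(manifest)) manifest$weight_kg <- NA_real_
  if (inherits(calibrations, "calibration")) calibrations <- list(calibrations)
  cal_heights <- vapply(calibrations, `[[`, numeric(1), "reference_height")

  if (nrow(manifest) == 0) {
    warning("empty manifest: no images to measure")
    res <- data.frame(subject_id = character(), posture = character(),
                      weight = numeric(), pixel_count = integer(),
                      area = numeric(), calibration_height = numeric())
    attr(res, "failures") <- data.frame(filename = character(),
                                        error = character())
    return(res)
  }

  results <- list(); failures <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    res <- tryCatch({
      check_posture(row$posture)
      h <- reference_height_for(row$posture)
      ci <- which(abs(cal_heights - h) < 1e-9)
      if (length(ci) == 0) {
        stop("no calibration at ", h, " cm for posture ", row$posture,
             call. = FALSE)
      }
      path <- file.path(image_dir, row$filename)
      if (!file.exists(path)) stop("file not found: ", row$filename,
                                   call. = FALSE)
      measure_area(path, calibrations[[ci[1]]], row$posture,
                   subject_id = row$subject_id, weight = row$weight_kg,
                   config = config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(filename = row$filename, error = conditionMessage(res),
                   stringsAsFactors = FALSE)
    } else {
      results[[length(results) + 1]] <- res
    }
  }
  out <- if (length(results) > 0) do.call(rbind, results) else
    data.frame(subject_id = character(), posture = character(),
               weight = numeric(), pixel_count = integer(),
               area = numeric(), calibration_height = numeric())
  fail <- if (length(failures) > 0) do.call(rbind, failures) else
    data.frame(filename = character(), error = character())
  if (nrow(fail) > 0) {
    warning(nrow(fail), " of ", nrow(manifest), " image(s) failed; see attr(x, 'failures')")
  }
  attr(out, "failures") <- fail
  out
}
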