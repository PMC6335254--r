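#' Pinhole camera over the planimetry box
#'
#' The measurement box is photographed from directly above with the lens
#' at `lens_height` cm over the floor; the principal axis passes through
#' the image centre. `floor_scale` is the sampling density at the floor
#' plane in pixels per metre, so an object lying on the floor maps 1 m to
#' `floor_scale` pixels, while a planar object raised to height `h` is
#' magnified by `lens_height / (lens_height - h)` (see [project_scale()]).
#' Lens distortion is not modelled.
#'
#' Defaults reproduce the study geometry: lens 245 cm above a
#' 2.45 x 1.25 m floor, imaged at 500 px/m.
#'
#' @param lens_height lens-to-floor distance, cm.
#' @param image_width,image_height image size in pixels.
#' @param floor_scale pixels per metre at the floor plane.
#' @return an object of class `camera_model`.
#' @examples
#' cam <- camera_model()
#' project_scale(cam, 69)
#' @export
camera_model <- function(lens_height = 245, image_width = 1226,
                         image_height = 626, floor_scale = 500) {
  stopifnot(lens_height > 0, floor_scale > 0,
            image_width >= 1, image_height >= 1)
  structure(list(lens_height = lens_height,
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 floor_scale = floor_scale),
            class = "camera_model")
}

#' Perspective magnification of a raised planar object
#'
#' A planar object parallel to the floor at height `object_height` (cm)
#' under a lens at `camera$lens_height` (cm) is magnified linearly by
#' `D / (D - h)`; its imaged area scales with the square of this factor.
#' This is the geometric reason the pixel-to-area calibration board must
#' be mounted at the back height of the posture class being measured.
#'
#' @param camera a [camera_model()].
#' @param object_height height of the object plane above the floor, cm;
#'   must satisfy `0 <= object_height < lens_height`.
#' @return linear magnification (dimensionless, >= 1).
#' @examples
#' project_scale(camera_model(), 0)    # floor plane: 1
#' project_scale(camera_model(), 69)   # 245/176
#' @export
project_scale <- function(camera, object_height) {
  stopifnot(inherits(camera, "camera_model"))
  if (any(object_height < 0)) {
    stop("object_height must be non-negative", call. = FALSE)
  }
  if (any(object_height >= camera$lens_height)) {
    stop("object_height must be below the lens (", camera$lens_height,
         " cm)", call. = FALSE)
  }
  camera$lens_height / (camera$lens_height - object_height)
}
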