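#' Shoelace area of a simple polygon
#'
#' @param polygon two-column matrix of vertex coordinates (x, y), open
#'   (last vertex need not repeat the first).
#' @return absolute polygon area in squared input units.
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
#' @export
polygon_area <- function(polygon) {
  stopifnot(is.matrix(polygon), ncol(polygon) == 2, nrow(polygon) >= 3)
  x <- polygon[, 1]; y <- polygon[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Per-posture allometric shape coefficients from the study tables
#'
#' For each posture group g the coefficient `k_g = area_mean_g /
#' weight_mean_g^0.66` (m^2 kg^-0.66) makes the allometric form
#' `a = k_g * W^0.66` pass exactly through the group's printed mean
#' weight and mean covered area. Silhouettes generated with these
#' coefficients therefore reproduce the study's per-posture mean areas at
#' the mean weights by construction; they are the generator's default
#' calibration.
#'
#' @param tables study table from [load_study_tables()].
#' @return named numeric vector of coefficients, one per posture code.
#' @examples
#' k <- fit_shape_coefficients(load_study_tables())
#' k[["LL"]]     # ~0.0222
#' @export
fit_shape_coefficients <- function(tables) {
  if (any(!is.finite(tables$weight_mean)) || any(tables$weight_mean <= 0)) {
    stop("weight means must be positive", call. = FALSE)
  }
  if (any(!is.finite(tables$area_mean)) || any(tables$area_mean <= 0)) {
    stop("area means must be positive", call. = FALSE)
  }
  k <- tables$area_mean / tables$weight_mean^ALLOMETRIC_EXPONENT
  names(k) <- tables$posture
  k
}

# Posture-specific outline parameters: planform aspect ratio
# (length/width), relative length of the head/snout lobe, sideways bend
# curvature for the "S" postures, and leg-lobe amplitude for lying
# postures. The outline is only qualitative; the measured quantity (the
# planform area) is set exactly by rescaling, so these values shape, but
# never bias, the generated cohorts.
posture_shape_params <- function(code) {
  check_posture(code)
  params <- list(
    A   = list(aspect = 3.0, head = 0.12, bend = 0.00, legs = 0.00),
    AS  = list(aspect = 3.0, head = 0.12, bend = 0.18, legs = 0.00),
    B   = list(aspect = 3.1, head = 0.20, bend = 0.00, legs = 0.00),
    BS  = list(aspect = 3.1, head = 0.20, bend = 0.18, legs = 0.00),
    C   = list(aspect = 3.2, head = 0.28, bend = 0.00, legs = 0.00),
    CS  = list(aspect = 3.2, head = 0.28, bend = 0.18, legs = 0.00),
    D   = list(aspect = 3.3, head = 0.33, bend = 0.00, legs = 0.00),
    DS  = list(aspect = 3.3, head = 0.33, bend = 0.18, legs = 0.00),
    E   = list(aspect = 3.3, head = 0.38, bend = 0.00, legs = 0.00),
    ES  = list(aspect = 3.3, head = 0.38, bend = 0.18, legs = 0.00),
    LBC = list(aspect = 2.2, head = 0.15, bend = 0.05, legs = 0.10),
    LSL = list(aspect = 2.0, head = 0.15, bend = 0.05, legs = 0.25),
    LL  = list(aspect = 1.8, head = 0.15, bend = 0.00, legs = 0.40)
  )
  params[[code]]
}

#' Generate a parametric pig silhouette with known planform area
#'
#' Builds a simple (non-self-intersecting) top-view outline for one
#' animal in one posture: a body ellipse expressed as a star-shaped
#' radius function with a head/snout lobe (longer for head-raised
#' postures), leg lobes for lying postures, a sideways bend for the
#' curved ("S") postures, and a smooth seeded perturbation of the
#' outline. The polygon is then rescaled uniformly so its shoelace area
#' equals
#'
#'   `k * W^0.66 * (1 + eps)`
#'
#' where `eps ~ N(0, shape_noise)` truncated at +/- 3 SD (so areas stay
#' positive). With `shape_noise = 0` the planform area is exact, which
#' makes the generator an analytic oracle for the measurement pipeline.
#' Identical inputs (including `shape_seed`) give identical polygons.
#'
#' @param posture posture code (see [posture_catalog()]).
#' @param weight live weight W in kg, > 0.
#' @param k shape coefficient in m^2 kg^-0.66, e.g. from
#'   [fit_shape_coefficients()].
#' @param shape_seed integer seed controlling outline jitter and the area
#'   noise draw.
#' @param shape_noise relative SD of the multiplicative area noise, >= 0.
#' @param n_vertices outline resolution.
#' @return an object of class `silhouette`: list with `polygon` (metres,
#'   centred on the body), `planform_area` (m^2), `target_area` (the
#'   noise-free `k W^0.66`), `posture`, `weight`, `object_height` (cm,
#'   the posture class's representative height).
#' @examples
#' sil <- make_silhouette("LL", weight = 107.5, k = 0.0222, shape_seed = 1)
#' sil$planform_area
#' @export
make_silhouette <- function(posture, weight, k, shape_seed = 1,
                            shape_noise = 0, n_vertices = 256) {
  check_posture(posture)
  stopifnot(length(posture) == 1, weight > 0, k > 0, n_vertices >= 16)
  if (shape_noise < 0) stop("shape_noise must be >= 0", call. = FALSE)
  p <- posture_shape_params(posture)

  with_seed(derive_seed(shape_seed, 0), {
    theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
    a <- p$aspect / 2                       # semi-length (arbitrary units)
    b <- 0.5                                # semi-width
    r <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)

    # head/snout lobe at theta = 0, width ~25 deg
    r <- r + p$head * a * exp(-(pmin(theta, 2 * pi - theta) / 0.45)^2)
    # leg lobes (lying postures): two bumps on one flank
    if (p$legs > 0) {
      for (th0 in c(pi / 3, 2 * pi / 3)) {
        r <- r + p$legs * b * exp(-((theta - th0) / 0.25)^2)
      }
    }
    # smooth seeded outline jitter: three low-order harmonics, small
    # fixed relative amplitude so the radius stays positive
    amp <- 0.03
    for (h in 2:4) {
      r <- r * (1 + amp * stats::runif(1, -1, 1) * cos(h * theta + stats::runif(1, 0, 2 * pi)))
    }

    x <- r * cos(theta)
    y <- r * sin(theta)
    # sideways bend: area-preserving shear y -> y + c x^2
    if (p$bend != 0) y <- y + p$bend * x^2

    eps <- 0
    if (shape_noise > 0) {
      eps <- stats::rnorm(1, 0, shape_noise)
      eps <- max(min(eps, 3 * shape_noise), -3 * shape_noise)
    }
    target <- k * weight^ALLOMETRIC_EXPONENT
    area_goal <- target * (1 + eps)
    s <- sqrt(area_goal / polygon_area(cbind(x, y)))
    poly <- cbind(x = x * s, y = y * s)

    structure(list(
      polygon = poly,
      planform_area = polygon_area(poly),
      target_area = target,
      posture = posture,
      weight = weight,
      object_height = reference_height_for(posture)
    ), class = "silhouette")
  })
}
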