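#' @name space_models
#' @title Allometric and legal space-allowance models
#'
#' @description
#' Two reference models for the floor area a finishing pig needs:
#'
#' * The allometric static-space formula `a = k * W^0.66` (a in m^2, W
#'   the live weight in kg), with the space-allowance coefficient `k`
#'   depending on posture class: 0.019 for standing animals and for
#'   lying in sternal recumbency with the legs folded beneath the body
#'   (postures `A`--`ES` and `LBC`), 0.025 for semilateral recumbency
#'   (`LSL`), and 0.047 for full lateral recumbency (`LL`). The exponent
#'   0.66 is fixed; alternative coefficients may be supplied as `k`.
#' * The EU road-transport loading-density minimum for pigs of around
#'   100 kg: at most 235 kg live weight per m^2 of vehicle floor, i.e. a
#'   minimum area of `W / 235` m^2 per animal, optionally increased by a
#'   surcharge of up to 20% (`legal_requirement(surcharge = 0.2)`).
NULL

#' Fixed allometric exponent relating live weight to planform area.
#' @rdname space_models
#' @export
ALLOMETRIC_EXPONENT <- 0.66

#' @rdname space_models
#' @param W live weight in kg, >= 0.
#' @param k space-allowance coefficient in m^2 kg^-0.66.
#' @return `allometric_area()`: covered area in m^2.
#' @examples
#' allometric_area(106.26, 0.019)   # ~0.41
#' allometric_area(107.50, 0.047)   # ~1.03
#' @export
allometric_area <- function(W, k = 0.019) {
  if (any(W < 0)) stop("live weight must be >= 0", call. = FALSE)
  if (any(k <= 0)) stop("coefficient k must be > 0", call. = FALSE)
  k * W^ALLOMETRIC_EXPONENT
}

#' @rdname space_models
#' @param code posture code(s).
#' @return `coefficient_for_posture()`: the recommended coefficient per
#'   posture code.
#' @export
coefficient_for_posture <- function(code) {
  check_posture(code)
  ifelse(code == "LL", 0.047, ifelse(code == "LSL", 0.025, 0.019))
}

#' @rdname space_models
#' @param density maximum loading density in kg/m^2 (regulatory value
#'   235).
#' @param surcharge additional area fraction in `[0, 0.20]` (the
#'   regulation allows an increase of up to 20% depending on breed,
#'   condition, weather and journey time); default 0.
#' @return `legal_requirement()`: an object of class `legal_requirement`.
#' @export
legal_requirement <- function(density = 235, surcharge = 0) {
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (surcharge < 0 || surcharge > 0.20)
    stop("surcharge must be in [0, 0.20]", call. = FALSE)
  structure(list(density = density, surcharge = surcharge),
            class = "legal_requirement")
}

#' @rdname space_models
#' @param requirement a [legal_requirement()].
#' @return `legal_min_area()`: minimum floor area in m^2 per animal.
#' @examples
#' legal_min_area(106.26)   # ~0.452
#' @export
legal_min_area <- function(W, requirement = legal_requirement()) {
  stopifnot(inherits(requirement, "legal_requirement"))
  if (any(W < 0)) stop("live weight must be >= 0", call. = FALSE)
  (W / requirement$density) * (1 + requirement$surcharge)
}

#' Per-posture comparison of measured, allometric and legal areas
#'
#' For each posture group, evaluates the posture's allometric formula
#' and the legal minimum at the group's mean live weight and compares
#' both with the measured mean covered area. Sign conventions:
#' `allometric_deviation = allometric - measured` (positive when the
#' formula over-allocates) and `free_space = legal_min - measured`
#' (positive when the legal minimum leaves the animal spare floor;
#' negative means the posture needs more than the legal minimum, and
#' `sufficient` is `FALSE`). Values are unrounded; round at the
#' reporting layer with [round_half_up()] (3 decimals for areas).
#'
#' @param tables study table from [load_study_tables()] (or any data
#'   frame with `posture`, `weight_mean`, `area_mean`).
#' @param requirement a [legal_requirement()].
#' @param k optional named per-posture coefficient vector overriding
#'   [coefficient_for_posture()].
#' @return data frame with one row per posture: `posture`, `W_mean`,
#'   `measured_area`, `k`, `allometric_area`, `allometric_deviation`,
#'   `legal_min_area`, `free_space`, `sufficient`.
#' @examples
#' cmp <- comparison_table(load_study_tables())
#' round_half_up(cmp$allometric_deviation[cmp$posture == "LL"], 3)  # 0.544
#' @export
comparison_table <- function(tables, requirement = legal_requirement(),
                             k = NULL) {
  missing_codes <- setdiff(posture_codes(), tables$posture)
  if (length(missing_codes) > 0) {
    stop("missing posture row(s): ", paste(missing_codes, collapse = ", "),
         call. = FALSE)
  }
  tab <- tables[match(posture_codes(), tables$posture), ]
  kk <- if (is.null(k)) coefficient_for_posture(tab$posture) else
    unname(k[tab$posture])
  allo <- allometric_area(tab$weight_mean, kk)
  legal <- legal_min_area(tab$weight_mean, requirement)
  data.frame(
    posture = tab$posture,
    W_mean = tab$weight_mean,
    measured_area = tab$area_mean,
    k = kk,
    allometric_area = allo,
    allometric_deviation = allo - tab$area_mean,
    legal_min_area = legal,
    free_space = legal - tab$area_mean,
    sufficient = legal - tab$area_mean >= 0,
    stringsAsFactors = FALSE)
}

#' Summary of allometric deviations over the ten standing postures
#'
#' @param comparison result of [comparison_table()].
#' @return list with `mean`, `sd`, `min`, `max` of
#'   `allometric_deviation` over postures `A`--`ES` (m^2, unrounded).
#' @examples
#' s <- standing_deviation_summary(comparison_table(load_study_tables()))
#' round_half_up(s$mean, 3)   # 0.107
#' @export
standing_deviation_summary <- function(comparison) {
  standing <- comparison$allometric_deviation[
    posture_class(comparison$posture) == "standing"]
  stopifnot(length(standing) == 10)
  list(mean = mean(standing), sd = stats::sd(standing),
       min = min(standing), max = max(standing))
}
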