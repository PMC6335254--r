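#' Read the per-posture study summary table
#'
#' Loads and validates a per-posture summary of the planimetric study:
#' image counts by gender, live-weight summaries (kg) and covered-area
#' summaries (m^2) for each of the 13 postures, plus an optional `Total`
#' row whose image count must equal the sum over postures. The packaged
#' fixture (`pigspace_extdata("study_summary.csv")`) transcribes the
#' published study's tables at printed precision: 1,583 images of 232
#' pigs, weights 75--133 kg.
#'
#' Validation enforces: all 13 posture codes present exactly once; numeric
#' cells parseable; `n_images = n_female + n_male_neutered` wherever the
#' gender split is recorded; `min <= mean <= max` for weights and areas;
#' and agreement of the `Total` image count with the per-posture sum.
#' Violations raise an error naming the offending row.
#'
#' @param path CSV path; defaults to the packaged study fixture.
#' @return data frame of 13 rows (posture order as in [posture_catalog()])
#'   with columns `posture`, `n_images`, `n_female`, `n_male_neutered`,
#'   `weight_mean`, `weight_sd`, `weight_min`, `weight_max`, `area_mean`,
#'   `area_sd`, `area_min`, `area_max`; the validated `Total` row (if
#'   present) is attached as attribute `"total"`.
#' @examples
#' tab <- load_study_tables()
#' sum(tab$n_images)
#' @export
load_study_tables <- function(path = pigspace_extdata("study_summary.csv")) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", strip.white = TRUE)
  needed <- c("posture", "n_images", "n_female", "n_male_neutered",
              "weight_mean", "weight_sd", "weight_min", "weight_max",
              "area_mean", "area_sd", "area_min", "area_max")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    stop("study table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  raw <- raw[needed]

  num <- function(x, col, row_label) {
    x[!nzchar(x)] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      stop("non-numeric value in column '", col, "', row ",
           row_label[bad][1], call. = FALSE)
    }
    out
  }
  for (col in setdiff(needed, "posture")) {
    raw[[col]] <- num(raw[[col]], col, raw$posture)
  }

  is_total <- raw$posture %in% c("Total", "total", "TOTAL")
  total <- if (any(is_total)) raw[is_total, , drop = FALSE][1, ] else NULL
  tab <- raw[!is_total, , drop = FALSE]

  codes <- posture_codes()
  dup <- tab$posture[duplicated(tab$posture)]
  if (length(dup) > 0) {
    stop("duplicate posture row(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(tab$posture, codes)
  if (length(unknown) > 0) {
    stop("unknown posture row(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(codes, tab$posture)
  if (length(absent) > 0) {
    stop("missing posture row(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[match(codes, tab$posture), , drop = FALSE]
  rownames(tab) <- NULL

  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    lab <- r$posture
    if (!is.na(r$n_female) && !is.na(r$n_male_neutered) &&
        r$n_images != r$n_female + r$n_male_neutered) {
      stop("row ", lab, ": n_images (", r$n_images,
           ") != n_female + n_male_neutered (",
           r$n_female + r$n_male_neutered, ")", call. = FALSE)
    }
    if (!(r$weight_min <= r$weight_mean && r$weight_mean <= r$weight_max)) {
      stop("row ", lab, ": weight summaries violate min <= mean <= max",
           call. = FALSE)
    }
    if (!(r$area_min <= r$area_mean && r$area_mean <= r$area_max)) {
      stop("row ", lab, ": area summaries violate min <= mean <= max",
           call. = FALSE)
    }
    if (any(c(r$weight_sd, r$area_sd) < 0, na.rm = TRUE)) {
      stop("row ", lab, ": negative standard deviation", call. = FALSE)
    }
  }
  if (!is.null(total) && !is.na(total$n_images) &&
      total$n_images != sum(tab$n_images)) {
    stop("Total row n_images (", total$n_images,
         ") != sum over postures (", sum(tab$n_images), ")", call. = FALSE)
  }
  attr(tab, "total") <- total
  tab
}

#' Write a study summary table
#'
#' Inverse of [load_study_tables()]: writes the 13 posture rows (and the
#' `Total` row, if attached) as CSV with comma separator, dot decimal and
#' a header row, at printed precision (2 decimals for kg, 3 for m^2), so
#' that write-then-read is the identity.
#'
#' @param tables validated table as returned by [load_study_tables()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_tables <- function(tables, path) {
  out <- tables
  if (!is.null(attr(tables, "total"))) out <- rbind(out, attr(tables, "total"))
  fmt <- function(x, d) ifelse(is.na(x), "", formatC(x, format = "f", digits = d))
  for (col in c("weight_mean", "weight_sd", "weight_min", "weight_max")) {
    out[[col]] <- fmt(out[[col]], 2)
  }
  for (col in c("area_mean", "area_sd", "area_min", "area_max")) {
    out[[col]] <- fmt(out[[col]], 3)
  }
  for (col in c("n_images", "n_female", "n_male_neutered")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", format(out[[col]], scientific = FALSE, trim = TRUE))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read per-posture weight-area rank correlations
#'
#' Loads a table of Spearman rank correlations between live weight and
#' covered floor area within each posture group. The packaged fixture
#' transcribes the study's published coefficients (standing postures
#' 0.779--0.923; lying 0.511--0.692, all reported significant at the 5%
#' level).
#'
#' @param path CSV path with columns `posture`, `rho`; defaults to the
#'   packaged fixture.
#' @return data frame with one row per posture, `|rho| <= 1` enforced.
#' @export
load_correlations <- function(path = pigspace_extdata("weight_area_correlations.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("posture", "rho") %in% names(tab))) {
    stop("correlation table needs columns 'posture' and 'rho'", call. = FALSE)
  }
  check_posture(tab$posture)
  if (anyDuplicated(tab$posture)) stop("duplicate posture in correlation table", call. = FALSE)
  if (length(setdiff(posture_codes(), tab$posture)) > 0) {
    stop("correlation table must cover all 13 postures", call. = FALSE)
  }
  if (any(!is.finite(tab$rho)) || any(abs(tab$rho) > 1)) {
    stop("rho must be finite and within [-1, 1]", call. = FALSE)
  }
  tab[match(posture_codes(), tab$posture), , drop = FALSE]
}
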