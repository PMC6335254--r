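#' The thirteen-posture taxonomy
#'
#' Finishing pigs were photographed from above in ten standing postures
#' (codes `A`--`ES`, varying head height and body curvature: the plain code
#' is a straight body, the `S` suffix a body curved sideways) and three
#' lying postures (`LBC` sternal recumbency, `LSL` semilateral recumbency,
#' `LL` full lateral recumbency). Pixel-to-area calibration uses a
#' reference board mounted at the posture class's representative back
#' height: 69 cm for standing animals, 29 cm for lying animals.
#'
#' Note: in the source study's running text one passage pairs the code
#' `LSL` with the sternal-recumbency description that the posture table
#' assigns to `LBC` (and once writes "LCL"); this catalog follows the
#' posture table.
#'
#' @return `posture_catalog()` returns a data frame with one row per
#'   posture: `code`, `description`, `posture_class` (`"standing"` or
#'   `"lying"`), and `reference_height` in cm.
#' @examples
#' posture_catalog()
#' posture_class(c("A", "LL"))
#' reference_height_for("ES")
#' @export
posture_catalog <- function() {
  data.frame(
    code = c("A", "AS", "B", "BS", "C", "CS", "D", "DS", "E", "ES",
             "LBC", "LSL", "LL"),
    description = c(
      "Standing up straight, nose touching the ground",
      "Standing curved sideways, nose touching the ground",
      "Standing up straight, head lowered to the ground",
      "Standing curved sideways, head lowered to the ground",
      "Standing up straight, head raised below the dorsal line",
      "Standing curved sideways, head raised below the dorsal line",
      "Standing up straight, head raised at the level of dorsal line",
      "Standing curved sideways, head raised at the level of dorsal line",
      "Standing up straight, head raised above the dorsal line",
      "Standing curved sideways, head raised above the dorsal line",
      "Lying in sternal (belly chest) recumbency",
      "Lying in semilateral (lateral chest) recumbency",
      "Lying in lateral (full) recumbency"),
    posture_class = c(rep("standing", 10), rep("lying", 3)),
    reference_height = c(rep(69, 10), rep(29, 3)),
    stringsAsFactors = FALSE
  )
}

#' @rdname posture_catalog
#' @return `posture_codes()` returns the 13 posture codes in catalog order.
#' @export
posture_codes <- function() posture_catalog()$code

check_posture <- function(code) {
  codes <- posture_codes()
  bad <- is.na(code) | !(code %in% codes)
  if (any(bad)) {
    stop("invalid posture code(s): ",
         paste(sQuote(unique(code[bad])), collapse = ", "),
         call. = FALSE)
  }
  invisible(code)
}

#' @rdname posture_catalog
#' @param code character vector of posture codes.
#' @return `posture_class()` returns `"standing"` or `"lying"` per code.
#' @export
posture_class <- function(code) {
  check_posture(code)
  cat <- posture_catalog()
  cat$posture_class[match(code, cat$code)]
}

#' @rdname posture_catalog
#' @return `reference_height_for()` returns the calibration reference
#'   height in cm per code (69 standing, 29 lying).
#' @export
reference_height_for <- function(code) {
  check_posture(code)
  cat <- posture_catalog()
  cat$reference_height[match(code, cat$code)]
}
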