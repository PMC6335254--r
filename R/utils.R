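#' Round half away from zero
#'
#' Rounds to `digits` decimal places with halves rounded away from zero
#' (so 0.0005 -> 0.001), the convention used for all reported areas and
#' deviations. R's [round()] rounds halves to even, which disagrees with
#' the printed tables in exactly the half-way cases.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.1765, 3)
#' round_half_up(-0.0285, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Per-scene seed protocol: scene i under master seed s uses (s + i) mod (2^31 - 1).
derive_seed <- function(master_seed, counter) {
  as.integer((as.numeric(master_seed) + as.numeric(counter)) %% 2147483647)
}

#' Path to a packaged example data file
#'
#' @param file file name under the package's `extdata` directory; if missing,
#'   lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
pigspace_extdata <- function(file) {
  if (missing(file)) {
    return(dir(system.file("extdata", package = "pigspace")))
  }
  path <- system.file("extdata", file, package = "pigspace", mustWork = FALSE)
  if (!nzchar(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}
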