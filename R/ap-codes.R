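## Meridian registry: canonical enumeration order fixes vocabulary and
## matrix column order throughout the package.
MERIDIANS <- c("LU", "LI", "ST", "SP", "HT", "SI", "BL", "KI",
               "PC", "TE", "GB", "LR", "GV", "CV")

MERIDIAN_MAX <- c(
  LU = 11L, LI = 20L, ST = 45L, SP = 21L, HT = 9L, SI = 19L, BL = 67L,
  KI = 27L, PC = 9L, TE = 23L, GB = 44L, LR = 14L, GV = 28L, CV = 24L
)

## Yin meridians of the twelve regular channels: on these, the source
## point coincides with the stream point.
YIN_MERIDIANS <- c("LU", "SP", "HT", "KI", "PC", "LR")

#' Parse acupuncture point codes
#'
#' Normalises free-form point codes ("sp3", " BL 13 ", "TB5") to the
#' canonical form: upper-case meridian abbreviation immediately followed by
#' the point number (e.g. `"SP3"`). The fourteen meridians carrying named
#' points are the twelve regular channels plus the governor (GV) and
#' conception (CV) vessels; point numbers must lie in each meridian's
#' standard range (LU 1-11, ..., BL 1-67, ..., CV 1-24). The alias `TB`
#' (triple burner) is accepted for `TE` (triple energizer).
#'
#' @param x Character vector of point codes.
#' @return Character vector of canonical codes, same length as `x`.
#'   Parsing a canonical code is the identity.
#' @examples
#' parse_ap_code(c("li4", "SP3", "bl 13"))
#' @export
parse_ap_code <- function(x) {
  if (length(x) == 0) return(character(0))
  if (!is.character(x)) {
    abort_input("`x` must be a character vector of point codes.")
  }
  clean <- toupper(gsub("[[:space:]]+", "", x))
  m <- regmatches(clean, regexec("^([A-Z]+)([0-9]+)$", clean))
  bad_shape <- vapply(m, length, 1L) != 3L | is.na(x) | !nzchar(clean)
  if (any(bad_shape)) {
    abort_input(sprintf(
      "Cannot parse point code(s): %s.",
      toString(sQuote(unique(x[bad_shape]), q = FALSE))
    ))
  }
  mer <- vapply(m, `[`, "", 2L)
  mer[mer == "TB"] <- "TE"
  num <- as.integer(vapply(m, `[`, "", 3L))
  unknown <- !(mer %in% MERIDIANS)
  if (any(unknown)) {
    abort_input(sprintf(
      "Unknown meridian prefix in code(s): %s.",
      toString(sQuote(unique(x[unknown]), q = FALSE))
    ))
  }
  out_of_range <- num < 1L | num > MERIDIAN_MAX[mer]
  if (any(out_of_range)) {
    abort_input(sprintf(
      "Point number out of the meridian's standard range in code(s): %s.",
      toString(sQuote(unique(x[out_of_range]), q = FALSE))
    ))
  }
  paste0(mer, num)
}

#' @rdname parse_ap_code
#' @export
ap_meridian <- function(x) {
  sub("[0-9]+$", "", parse_ap_code(x))
}

#' @rdname parse_ap_code
#' @export
ap_number <- function(x) {
  as.integer(sub("^[A-Z]+", "", parse_ap_code(x)))
}

#' Order point codes canonically
#'
#' Sorting key: meridian enumeration order (LU, LI, ST, SP, HT, SI, BL,
#' KI, PC, TE, GB, LR, GV, CV), then point number. This order fixes the
#' vocabulary of every score matrix, so columns are reproducible
#' bit-for-bit across runs.
#'
#' @param x Character vector of (parseable) point codes.
#' @return `x` sorted canonically, duplicates removed.
#' @export
sort_ap_codes <- function(x) {
  x <- unique(parse_ap_code(x))
  x[order(match(ap_meridian(x), MERIDIANS), ap_number(x))]
}

## classed conditions: validation errors vs computation errors
abort_input <- function(msg, ...) {
  rlang::abort(msg, class = "acustyle_input_error", ...)
}

abort_compute <- function(msg, ...) {
  rlang::abort(msg, class = "acustyle_compute_error", ...)
}
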