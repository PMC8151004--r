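## Five transport points (well, brook, stream, river, sea) of the twelve
## regular meridians, per the WHO standard acupuncture nomenclature.
## All lie distal to the elbow or knee.
TRANSPORT_POINTS <- list(
  LU = c(well = 11L, brook = 10L, stream = 9L,  river = 8L,  sea = 5L),
  LI = c(well = 1L,  brook = 2L,  stream = 3L,  river = 5L,  sea = 11L),
  ST = c(well = 45L, brook = 44L, stream = 43L, river = 41L, sea = 36L),
  SP = c(well = 1L,  brook = 2L,  stream = 3L,  river = 5L,  sea = 9L),
  HT = c(well = 9L,  brook = 8L,  stream = 7L,  river = 4L,  sea = 3L),
  SI = c(well = 1L,  brook = 2L,  stream = 3L,  river = 5L,  sea = 8L),
  BL = c(well = 67L, brook = 66L, stream = 65L, river = 60L, sea = 40L),
  KI = c(well = 1L,  brook = 2L,  stream = 3L,  river = 7L,  sea = 10L),
  PC = c(well = 9L,  brook = 8L,  stream = 7L,  river = 5L,  sea = 3L),
  TE = c(well = 1L,  brook = 2L,  stream = 3L,  river = 6L,  sea = 10L),
  GB = c(well = 44L, brook = 43L, stream = 41L, river = 38L, sea = 34L),
  LR = c(well = 1L,  brook = 2L,  stream = 3L,  river = 4L,  sea = 8L)
)

## Source (yuan) points: one per regular meridian; on the six yin
## meridians the source point is the stream point.
SOURCE_POINTS <- c(
  LU = 9L, LI = 4L, ST = 42L, SP = 3L, HT = 7L, SI = 4L,
  BL = 64L, KI = 3L, PC = 7L, TE = 4L, GB = 40L, LR = 3L
)

## Body-region summary per meridian, as number ranges. Four classes only:
## distal_limb (distal to elbow/knee), proximal_limb, head (incl. neck),
## trunk. A deliberately coarse synthetic summary of the standard point
## locations -- just enough to support a distant-point rule.
REGION_RANGES <- list(
  LU = list(trunk = 1:2,  proximal_limb = 3:4,  distal_limb = 5:11),
  LI = list(distal_limb = 1:11, proximal_limb = 12:16, head = 17:20),
  ST = list(head = 1:11, trunk = 12:30, proximal_limb = 31:35,
            distal_limb = 36:45),
  SP = list(distal_limb = 1:9, proximal_limb = 10:11, trunk = 12:21),
  HT = list(proximal_limb = 1:2, distal_limb = 3:9),
  SI = list(distal_limb = 1:8, proximal_limb = 9:10, trunk = 11:15,
            head = 16:19),
  BL = list(head = 1:10, trunk = c(11:35, 41:54),
            proximal_limb = 36:39, distal_limb = c(40L, 55:67)),
  KI = list(distal_limb = 1:10, trunk = 11:27),
  PC = list(trunk = 1L, proximal_limb = 2L, distal_limb = 3:9),
  TE = list(distal_limb = 1:10, proximal_limb = 11:15, head = 16:23),
  GB = list(head = 1:20, trunk = 21:29, proximal_limb = 30:33,
            distal_limb = 34:44),
  LR = list(distal_limb = 1:8, proximal_limb = 9:12, trunk = 13:14),
  GV = list(trunk = 1:14, head = 15:28),
  CV = list(trunk = 1:22, head = 23:24)
)

#' Reference acupuncture point attribute table
#'
#' One row per standard point code (361 points over the 14 meridians),
#' annotating the four theoretical attributes used in style analysis:
#'
#' * `is_extra_meridian` -- the point lies on the governor (GV) or
#'   conception (CV) vessel, the only extra meridians carrying their own
#'   points;
#' * `transport_class` -- the point's five-transport class (`well`,
#'   `brook`, `stream`, `river`, `sea`; `none` otherwise): 60 points,
#'   five per regular meridian, all distal to elbow/knee;
#' * `is_source_point` -- one source (yuan) point per regular meridian
#'   (12 points); on yin meridians it equals the stream point;
#' * `region` -- a coarse four-class location (`distal_limb`,
#'   `proximal_limb`, `head`, `trunk`) supporting distant-point rules.
#'
#' Annotations follow the WHO standard acupuncture nomenclature; the
#' region column is a synthetic four-class summary of the standard point
#' locations, not an anatomical atlas.
#'
#' @return A tibble with columns `ap_code`, `meridian`, `number`,
#'   `is_extra_meridian`, `transport_class`, `is_source_point`, `region`,
#'   in canonical vocabulary order.
#' @examples
#' tab <- default_attribute_table()
#' sum(tab$transport_class != "none")  # 60
#' sum(tab$is_source_point)            # 12
#' @export
default_attribute_table <- function() {
  if (!is.null(.acustyle_cache$attribute_table)) {
    return(.acustyle_cache$attribute_table)
  }
  rows <- purrr::map(MERIDIANS, function(mer) {
    n <- MERIDIAN_MAX[[mer]]
    num <- seq_len(n)
    transport <- rep("none", n)
    tp <- TRANSPORT_POINTS[[mer]]
    if (!is.null(tp)) transport[tp] <- names(tp)
    region <- rep(NA_character_, n)
    for (reg in names(REGION_RANGES[[mer]])) {
      region[REGION_RANGES[[mer]][[reg]]] <- reg
    }
    tibble::tibble(
      ap_code = paste0(mer, num),
      meridian = mer,
      number = num,
      is_extra_meridian = mer %in% c("GV", "CV"),
      transport_class = transport,
      is_source_point = !is.na(SOURCE_POINTS[mer]) &
        num == SOURCE_POINTS[mer] & !(mer %in% c("GV", "CV")),
      region = region
    )
  })
  tab <- dplyr::bind_rows(rows)
  tab$is_source_point[is.na(tab$is_source_point)] <- FALSE
  validate_attribute_table(tab)
  .acustyle_cache$attribute_table <- tab
  tab
}

.acustyle_cache <- new.env(parent = emptyenv())

#' Validate a point attribute table
#'
#' Checks the structural invariants any attribute table must satisfy:
#' parseable unique codes; extra-meridian flag true exactly for GV/CV;
#' transport classes only on the twelve regular meridians, every
#' transport point in the `distal_limb` region; source points only on
#' regular meridians, one per meridian at most; on yin meridians the
#' source point coincides with the stream point.
#'
#' @param table A data frame shaped like [default_attribute_table()].
#' @return `table`, invisibly, if valid; otherwise an error.
#' @export
validate_attribute_table <- function(table) {
  req <- c("ap_code", "is_extra_meridian", "transport_class",
           "is_source_point", "region")
  missing_cols <- setdiff(req, names(table))
  if (length(missing_cols)) {
    abort_input(sprintf("Attribute table lacks column(s): %s.",
                        toString(missing_cols)))
  }
  codes <- parse_ap_code(table$ap_code)
  if (anyDuplicated(codes)) {
    abort_input("Attribute table has duplicate point codes.")
  }
  mer <- ap_meridian(codes)
  extra <- mer %in% c("GV", "CV")
  if (!identical(as.logical(table$is_extra_meridian), extra)) {
    abort_input("is_extra_meridian must be true exactly for GV/CV codes.")
  }
  ok_class <- c("well", "brook", "stream", "river", "sea", "none")
  if (!all(table$transport_class %in% ok_class)) {
    abort_input("Unknown transport_class value.")
  }
  tp <- table$transport_class != "none"
  if (any(tp & extra)) {
    abort_input("Transport classes exist only on the twelve regular meridians.")
  }
  if (any(tp & table$region != "distal_limb")) {
    abort_input("Every five-transport point must have region distal_limb.")
  }
  if (any(table$is_source_point & extra)) {
    abort_input("Source points exist only on the twelve regular meridians.")
  }
  src_per_mer <- table(mer[table$is_source_point])
  if (any(src_per_mer > 1)) {
    abort_input("At most one source point per meridian.")
  }
  yin_src <- table$is_source_point & mer %in% YIN_MERIDIANS
  if (any(yin_src & table$transport_class != "stream")) {
    abort_input("On yin meridians the source point must be the stream point.")
  }
  if (!all(table$region %in% c("distal_limb", "proximal_limb",
                               "head", "trunk"))) {
    abort_input("region must be one of distal_limb/proximal_limb/head/trunk.")
  }
  invisible(table)
}

#' Read a point attribute table from CSV
#'
#' Expects columns `ap_code`, `is_extra_meridian`, `transport_class`,
#' `is_source_point`, `region`; validated on load.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A validated attribute tibble.
#' @export
read_attribute_table <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE)
  tab$ap_code <- parse_ap_code(tab$ap_code)
  tab$is_extra_meridian <- as.logical(tab$is_extra_meridian)
  tab$is_source_point <- as.logical(tab$is_source_point)
  validate_attribute_table(tab)
  tab
}

#' Disease-site regions for the packaged disease panel
#'
#' Maps each of the fourteen classical disease chapters the corpus design
#' uses to the coarse body region of the disease site, for the
#' region-based distant-point rule: a selected point is *distant* when it
#' lies on the distal limbs while the disease site does not.
#'
#' @return A tibble with columns `disease`, `region`.
#' @export
default_disease_regions <- function() {
  tibble::tibble(
    disease = DISEASE_PANEL,
    region = c(
      aggregation = "trunk", vomiting = "trunk", cough = "trunk",
      eye_disease = "head", ear_disease = "head", nasal_disease = "head",
      throat_disease = "head", dental_disease = "head",
      mouth_disease = "head", cholera = "trunk",
      consumptive_disease = "trunk", head_disease = "head",
      lumbar_disease = "trunk", abdominal_disease = "trunk"
    )[DISEASE_PANEL]
  )
}

## The fourteen disease chapters shared by the three classical textbooks.
DISEASE_PANEL <- c(
  "aggregation", "vomiting", "cough", "eye_disease", "ear_disease",
  "nasal_disease", "throat_disease", "dental_disease", "mouth_disease",
  "cholera", "consumptive_disease", "head_disease", "lumbar_disease",
  "abdominal_disease"
)
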