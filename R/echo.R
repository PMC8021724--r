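# Echocardiographic hsPDA criterion and infant-level labelling.

#' Classify hemodynamic significance from one echo assessment
#'
#' An assessment is hsPDA-positive when the ductal inner diameter indexed
#' to weight exceeds 1.5 mm/kg and/or the left-atrium to aortic-root ratio
#' exceeds 1.5, both as strict inequalities.
#'
#' @param la_ao LA/Ao ratio (unitless, vectorised).
#' @param duct_diameter Ductal inner diameter, mm.
#' @param weight Infant weight at the assessment, kg.
#' @return Logical vector, `TRUE` where the criterion is met.
#' @export
classify_hspda <- function(la_ao, duct_diameter, weight) {
  if (any(!is.finite(la_ao) | la_ao <= 0)) .stop_invalid("LA/Ao ratio must be positive")
  if (any(!is.finite(duct_diameter) | duct_diameter <= 0)) .stop_invalid("duct diameter must be positive")
  if (any(!is.finite(weight) | weight <= 0)) .stop_invalid("weight must be positive")
  (duct_diameter / weight) > 1.5 | la_ao > 1.5
}

#' Label one infant from its serial echo assessments
#'
#' The infant is labelled echo-positive if any assessment in the 24-72 h
#' window meets the hsPDA criterion; the earliest such hour is reported.
#'
#' @param assessments Data frame with columns `hour`, `la_ao`,
#'   `duct_diameter_mm`, `weight_kg` for one infant.
#' @return List with `positive` (logical) and `deciding_hour` (the earliest
#'   positive hour, or `NA` if none).
#' @export
label_infant <- function(assessments) {
  if (is.null(assessments) || nrow(assessments) == 0) {
    .stop_invalid("at least one echo assessment is required")
  }
  if (!all(assessments$hour %in% echo_schedule())) {
    .stop_invalid("echo hours must be in {24, 48, 72}")
  }
  a <- assessments[order(assessments$hour), , drop = FALSE]
  pos <- classify_hspda(a$la_ao, a$duct_diameter_mm, a$weight_kg)
  list(positive = any(pos),
       deciding_hour = if (any(pos)) a$hour[which(pos)[1]] else NA_integer_)
}

#' Label every infant in an echo table
#'
#' Adds the per-assessment criterion and reduces it to an infant-level
#' label. The study-level hsPDA group additionally requires clinical
#' symptoms (controls can transiently exceed the echo thresholds on day 1
#' without qualifying for treatment), so when a `symptomatic` lookup is
#' supplied the `hspda_group` column is the conjunction of the echo label
#' and the symptomatic flag.
#'
#' @param echo Data frame with columns `infant_id`, `hour`, `la_ao`,
#'   `duct_diameter_mm`, `weight_kg`.
#' @param symptomatic Optional named logical vector (names = infant ids).
#' @return List with `assessments` (the echo table plus `hspda_at_hour`)
#'   and `infants` (one row per infant: `infant_id`, `echo_positive`,
#'   `deciding_hour`, and `hspda_group` when `symptomatic` is given).
#' @export
label_cohort <- function(echo, symptomatic = NULL) {
  echo$hspda_at_hour <- as.integer(classify_hspda(echo$la_ao, echo$duct_diameter_mm,
                                                  echo$weight_kg))
  ids <- unique(echo$infant_id)
  per <- lapply(ids, function(id) {
    lab <- label_infant(echo[echo$infant_id == id, , drop = FALSE])
    data.frame(infant_id = id, echo_positive = lab$positive,
               deciding_hour = lab$deciding_hour, stringsAsFactors = FALSE)
  })
  infants <- do.call(rbind, per)
  if (!is.null(symptomatic)) {
    infants$hspda_group <- infants$echo_positive &
      as.logical(symptomatic[as.character(infants$infant_id)])
  }
  list(assessments = echo, infants = infants)
}
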