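#' Closed vocabularies used across the EHR tables
#'
#' The study tracks ten antithrombotic drugs in two classes, six chronic
#' liver conditions, the cardiovascular indications for each drug class,
#' the comorbidity and complication conditions needed for the clinical
#' scores, and six laboratory analytes with fixed units. Every table
#' reader validates its categorical columns against these sets, so no
#' free-text category can leak into downstream logic.
#'
#' @format Character vectors.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
anticoagulant_drugs <- c("apixaban", "dabigatran", "edoxaban", "rivaroxaban", "warfarin")

#' @rdname vocabularies
#' @export
antiplatelet_drugs <- c("aspirin", "clopidogrel", "dipyridamole", "prasugrel", "ticagrelor")

#' @rdname vocabularies
#' @export
antithrombotic_drugs <- c(anticoagulant_drugs, antiplatelet_drugs)

#' @rdname vocabularies
#' @export
drug_classes <- c("anticoagulant", "antiplatelet")

#' @rdname vocabularies
#' @export
liver_conditions <- c("ALD", "autoimmune_liver_disease", "cirrhosis", "HBV", "HCV", "NAFLD")

#' @rdname vocabularies
#' @export
indication_conditions <- list(
  anticoagulant = "atrial_fibrillation",
  antiplatelet = c(
    "myocardial_infarction", "peripheral_arterial_disease",
    "unstable_angina", "transient_ischaemic_attack"
  )
)

#' @rdname vocabularies
#' @export
condition_levels <- c(
  liver_conditions,
  "atrial_fibrillation", "myocardial_infarction", "peripheral_arterial_disease",
  "unstable_angina", "transient_ischaemic_attack",
  "chronic_kidney_disease", "ascites", "hepatic_encephalopathy", "varices",
  "heart_failure", "hypertension", "diabetes",
  "stroke_ischaemic", "bleeding_nonfatal", "vascular_disease",
  "proton_pump_inhibitor_use"
)

#' @rdname vocabularies
#' @export
analyte_levels <- c("INR", "bilirubin_total", "albumin", "AST", "ALT", "platelets")

# Fixed unit per analyte; mixed units per row are not representable.
analyte_units <- c(
  INR = "ratio", bilirubin_total = "mg/dL", albumin = "g/dL",
  AST = "U/L", ALT = "U/L", platelets = "10^9/L"
)

diagnosis_sources <- c("primary_care", "secondary_care")
sex_levels <- c("male", "female")

#' Map a drug name to its antithrombotic class
#'
#' @param drug Character vector of drug names drawn from
#'   [antithrombotic_drugs].
#' @return Character vector, `"anticoagulant"` or `"antiplatelet"`.
#' @examples
#' drug_class(c("warfarin", "aspirin"))
#' @export
drug_class <- function(drug) {
  bad <- setdiff(unique(drug), antithrombotic_drugs)
  if (length(bad) > 0) {
    abort(paste0("Unknown drug(s): ", paste(bad, collapse = ", ")))
  }
  if_else(drug %in% anticoagulant_drugs, "anticoagulant", "antiplatelet")
}

#' Drugs belonging to one antithrombotic class
#'
#' @param class `"anticoagulant"` or `"antiplatelet"`.
#' @return Character vector of five drug names.
#' @export
drugs_in_class <- function(class) {
  class <- match.arg(class, drug_classes)
  if (class == "anticoagulant") anticoagulant_drugs else antiplatelet_drugs
}
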