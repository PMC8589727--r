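#' Child-Pugh score and class
#'
#' Sums five components, each scored 1-3 with the standard thresholds:
#' total bilirubin (<2 / 2-3 / >3 mg/dL), serum albumin (>3.5 / 2.8-3.5 /
#' <2.8 g/dL), INR (<1.7 / 1.7-2.3 / >2.3), ascites (none / mild /
#' severe) and hepatic encephalopathy (none / grade 1-2 / grade 3-4).
#' Classes: A = 5-6 points (well-compensated), B = 7-9 (significant
#' functional compromise), C = 10-15 (decompensated). When severity
#' grading of ascites or encephalopathy is unavailable, presence scores
#' 2 points.
#'
#' @param bilirubin Total bilirubin in mg/dL.
#' @param albumin Serum albumin in g/dL.
#' @param inr INR.
#' @param ascites,encephalopathy `"none"`, `"mild"`/`"grade12"`,
#'   `"severe"`/`"grade34"`, or a logical (TRUE = present, scored 2).
#' @return Tibble `child_pugh_points`, `child_pugh_class`; components that
#'   are `NA` withhold the score and are named in `missing_components`.
#' @examples
#' child_pugh(2.5, 3.0, 1.8, "mild", "none")
#' @export
child_pugh <- function(bilirubin, albumin, inr, ascites = "none",
                       encephalopathy = "none") {
  grade3 <- function(x) {
    if (is.logical(x))

      return(ifelse(is.na(x), NA_real_, ifelse(x, 2, 1)))
    x <- as.character(x)
    pts <- dplyr::recode(x,
      none = 1, absent = 1,
      mild = 2, grade12 = 2, present = 2, moderate = 2,
      severe = 3, grade34 = 3,
      .default = NA_real_
    )
    pts
  }
  n <- max(length(bilirubin), length(albumin), length(inr), length(ascites), length(encephalopathy))
  comp <- tibble(
    bilirubin = rep(
      case_when(
        bilirubin < 2 ~ 1, bilirubin <= 3 ~ 2, bilirubin > 3 ~ 3,
        .default = NA_real_
      ),
      length.out = n
    ),
    albumin = rep(
      case_when(
        albumin > 3.5 ~ 1, albumin >= 2.8 ~ 2, albumin < 2.8 ~ 3,
        .default = NA_real_
      ),
      length.out = n
    ),
    inr = rep(
      case_when(inr < 1.7 ~ 1, inr <= 2.3 ~ 2, inr > 2.3 ~ 3, .default = NA_real_),
      length.out = n
    ),
    ascites = rep(grade3(ascites), length.out = n),
    encephalopathy = rep(grade3(encephalopathy), length.out = n)
  )
  missing <- purrr::pmap(comp, function(...) {
    names(comp)[is.na(c(...))]
  })
  points <- rowSums(comp)
  tibble(
    child_pugh_points = as.integer(points),
    child_pugh_class = case_when(
      points <= 6 ~ "A", points <= 9 ~ "B", points <= 15 ~ "C",
      .default = NA_character_
    ),
    missing_components = missing
  )
}

#' FIB-4 liver fibrosis index
#'
#' `FIB-4 = age * AST / (platelets * sqrt(ALT))` with age in years, AST
#' and ALT in U/L and platelets in 10^9/L. Strata: `<1.45` (approximate
#' fibrosis stage 0-1), `1.45-3.25` (stage 2-3, boundaries inclusive) and
#' `>3.25` (stage 4-6).
#'
#' @param age_years Age in years.
#' @param ast,alt Aminotransferase levels (U/L).
#' @param platelets Platelet count (10^9/L).
#' @return Tibble `fib4_value`, `fib4_stratum`.
#' @examples
#' fib4(60, 40, 25, 150)
#' @export
fib4 <- function(age_years, ast, alt, platelets) {
  for (nm in c("age_years", "ast", "alt", "platelets")) {
    v <- get(nm)
    if (any(!is.na(v) & v <= 0)) {
      abort(sprintf("fib4: '%s' must be positive", nm))
    }
  }
  value <- age_years * ast / (platelets * sqrt(alt))
  tibble(
    fib4_value = value,
    fib4_stratum = case_when(
      value < 1.45 ~ "<1.45",
      value <= 3.25 ~ "1.45-3.25",
      value > 3.25 ~ ">3.25",
      .default = NA_character_
    )
  )
}

chadsvasc_strata <- c("0-1", "2", "3-4", "5-9")

#' CHA2DS2-VASc stroke-risk score
#'
#' Standard additive weights: congestive heart failure 1, hypertension 1,
#' age 75+ 2, diabetes 1, prior stroke/TIA 2, vascular disease 1, age
#' 65-74 1, female sex 1 (range 0-9). Strata: 0-1, 2, 3-4, 5-9.
#'
#' @param sex `"male"` or `"female"`.
#' @param age_years Age at the index date.
#' @param heart_failure,hypertension,diabetes,stroke_tia,vascular_disease
#'   Logical comorbidity flags (vectorised, default `FALSE`).
#' @return Tibble `chadsvasc_points`, `chadsvasc_stratum`.
#' @examples
#' cha2ds2_vasc("female", 72, hypertension = TRUE, diabetes = TRUE)
#' @export
cha2ds2_vasc <- function(sex, age_years, heart_failure = FALSE,
                         hypertension = FALSE, diabetes = FALSE,
                         stroke_tia = FALSE, vascular_disease = FALSE) {
  points <- (sex == "female") +
    (age_years >= 75) * 2 + (age_years >= 65 & age_years < 75) +
    heart_failure + hypertension + diabetes + 2 * stroke_tia +
    vascular_disease
  tibble(
    chadsvasc_points = as.integer(points),
    chadsvasc_stratum = case_when(
      points <= 1 ~ "0-1", points == 2 ~ "2", points <= 4 ~ "3-4",
      .default = "5-9"
    )
  )
}

#' Score a cohort at the index date
#'
#' Looks up, per patient, the most recent qualifying laboratory value per
#' analyte within the lookback window around the index date (default 365
#' days before to 30 days after), reads ascites/encephalopathy and the
#' CHA2DS2-VASc comorbidities from the diagnosis stream (events on or
#' before index), and computes all three scores.
#'
#' @param index_tbl Tibble `patient_id`, `index_date`, `sex`,
#'   `age_at_index`.
#' @param labs Validated labs tibble.
#' @param diagnoses Validated diagnoses tibble.
#' @param config A [study_config()] (lab window).
#' @return `index_tbl` plus the scoring columns of [child_pugh()],
#'   [fib4()] and [cha2ds2_vasc()].
#' @export
score_cohort <- function(index_tbl, labs, diagnoses, config = study_config()) {
  lab_near <- labs |>
    inner_join(
      index_tbl |> select("patient_id", "index_date"),
      by = "patient_id", relationship = "many-to-many"
    ) |>
    filter(
      .data$date >= .data$index_date - config$lab_lookback_days,
      .data$date <= .data$index_date + config$lab_lookahead_days
    ) |>
    group_by(.data$patient_id, .data$analyte) |>
    slice_min(abs(as.numeric(.data$date - .data$index_date)),
      n = 1, with_ties = FALSE
    ) |>
    ungroup() |>
    select("patient_id", "analyte", "value") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  for (an in analyte_levels) {
    if (!an %in% names(lab_near)) lab_near[[an]] <- NA_real_
  }

  dx_flag <- function(cond) {
    hits <- diagnoses |>
      filter(.data$condition %in% cond) |>
      inner_join(index_tbl |> select("patient_id", "index_date"),
        by = "patient_id", relationship = "many-to-many"
      ) |>
      filter(.data$event_date <= .data$index_date) |>
      distinct(.data$patient_id)
    index_tbl$patient_id %in% hits$patient_id
  }

  scored <- index_tbl |>
    left_join(lab_near, by = "patient_id") |>
    mutate(
      ascites_flag = dx_flag("ascites"),
      enceph_flag = dx_flag("hepatic_encephalopathy"),
      heart_failure = dx_flag("heart_failure"),
      hypertension = dx_flag("hypertension"),
      diabetes = dx_flag("diabetes"),
      stroke_tia = dx_flag(c("stroke_ischaemic", "transient_ischaemic_attack")),
      vascular_disease = dx_flag(c(
        "vascular_disease", "myocardial_infarction",
        "peripheral_arterial_disease"
      )),
      chronic_kidney_disease = dx_flag("chronic_kidney_disease"),
      varices = dx_flag("varices"),
      cirrhosis = dx_flag("cirrhosis"),
      proton_pump_inhibitor_use = dx_flag("proton_pump_inhibitor_use")
    )

  bind_cols(
    scored,
    child_pugh(
      scored$bilirubin_total, scored$albumin, scored$INR,
      scored$ascites_flag, scored$enceph_flag
    ),
    fib4(scored$age_at_index, scored$AST, scored$ALT, scored$platelets),
    cha2ds2_vasc(
      scored$sex, scored$age_at_index, scored$heart_failure,
      scored$hypertension, scored$diabetes, scored$stroke_tia,
      scored$vascular_disease
    )
  )
}
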