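#' Study configuration
#'
#' Bundles every tunable rule of the analysis in one validated object:
#' the assumed prescription supply duration, the gap threshold that defines
#' discontinuation, the PDC adherence threshold, the 6/12-month landmark
#' window lengths, the normal quantile for confidence intervals, the TTR
#' cut-point used as a model covariate, and the censoring anchors.
#'
#' @param study_start Date the observation period opens.
#' @param admin_censor_date Administrative censoring date; follow-up never
#'   extends beyond it.
#' @param supply_days Assumed days of supply per prescription issue
#'   (default 30). A refill inside this window truncates the previous
#'   episode; there is no stockpiling.
#' @param gap_threshold_days Supply gap (days) at which a patient is
#'   considered to have discontinued (default 90, compared with `>=`).
#' @param pdc_threshold PDC above which a patient is adherent
#'   (default 0.80, strict `>`).
#' @param window_6m_days,window_12m_days Landmark window lengths in days
#'   (defaults 183 and 365).
#' @param ci_z Normal quantile for Wald intervals (default 1.96).
#' @param ttr_cut Percent TTR above which the TTR covariate is flagged
#'   (default 60).
#' @param lab_lookback_days,lab_lookahead_days Window around the index date
#'   in which a laboratory measurement may feed the clinical scores
#'   (defaults 365 before, 30 after).
#' @param gap_from Whether the discontinuation gap is measured from the end
#'   of assumed supply (`"supply_end"`, default) or from the issue date
#'   (`"issue"`).
#' @param seed Integer seed recorded alongside results.
#' @return A list with class `"study_config"`.
#' @examples
#' cfg <- study_config()
#' cfg$gap_threshold_days
#' @export
study_config <- function(study_start = as.Date("1998-01-01"),
                         admin_censor_date = as.Date("2020-06-30"),
                         supply_days = 30L,
                         gap_threshold_days = 90L,
                         pdc_threshold = 0.80,
                         window_6m_days = 183L,
                         window_12m_days = 365L,
                         ci_z = 1.96,
                         ttr_cut = 60,
                         lab_lookback_days = 365L,
                         lab_lookahead_days = 30L,
                         gap_from = c("supply_end", "issue"),
                         seed = 1L) {
  gap_from <- match.arg(gap_from)
  cfg <- list(
    study_start = as.Date(study_start),
    admin_censor_date = as.Date(admin_censor_date),
    supply_days = as.integer(supply_days),
    gap_threshold_days = as.integer(gap_threshold_days),
    pdc_threshold = pdc_threshold,
    window_6m_days = as.integer(window_6m_days),
    window_12m_days = as.integer(window_12m_days),
    ci_z = ci_z,
    ttr_cut = ttr_cut,
    lab_lookback_days = as.integer(lab_lookback_days),
    lab_lookahead_days = as.integer(lab_lookahead_days),
    gap_from = gap_from,
    seed = as.integer(seed)
  )
  validate_study_config(cfg)
  structure(cfg, class = "study_config")
}

validate_study_config <- function(cfg) {
  stopifnot(
    cfg$supply_days > 0,
    cfg$gap_threshold_days > cfg$supply_days,
    cfg$pdc_threshold > 0, cfg$pdc_threshold < 1,
    cfg$window_6m_days > 0, cfg$window_12m_days > 0,
    cfg$ci_z > 0,
    cfg$study_start < cfg$admin_censor_date
  )
  invisible(cfg)
}

#' Read a study configuration from a YAML file
#'
#' The file holds scalar keys mirroring the [study_config()] arguments;
#' absent keys fall back to the defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown study_config key(s): ", paste(extra, collapse = ", ")))
  }
  do.call(study_config, raw)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
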