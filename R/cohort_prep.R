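# Harmonization of raw survey records into risk-factor profiles.
#
# Raw records follow the canonical column layout produced by
# generate_population() or read_survey_csv():
#   sex, age, skin_color, smoking_response, hypertension_dx,
#   antihypertensive_use_2wk, diabetes_dx, hba1c, heart_disease_dx,
#   stroke_dx, sbp, tc, hdl, survey_weight
#
# Imputation rules mirror the survey's skip patterns: the medication question
# is only asked of people reporting hypertension, so a missing answer among
# people without the diagnosis (outside pregnancy) or never measured is a
# structural "no"; people never tested for glycemia are first taken as
# non-diabetic, then HbA1c >= 6.5% overrides any prior answer.

SMOKER_RESPONSES <- c("sim, diariamente", "sim, menos que diariamente")
BLACK_SKIN_COLORS <- c("parda", "preta")
.no_htn_dx <- c("no", "only-in-pregnancy", "never-measured")

#' Preparation configuration
#'
#' @param age_range Inclusive eligibility age window in years.
#' @param hba1c_threshold Glycated hemoglobin (%) at or above which diabetes
#'   is imputed regardless of prior diagnosis.
#' @param sbp_atypical_bounds,tc_atypical_bounds Inclusive intervals outside
#'   which systolic blood pressure (mmHg) / total cholesterol (mg/dL) count
#'   as atypical and are excluded.  Defaults follow the development
#'   exclusions of the laboratory recalibrated equation (SBP 70-270 mmHg,
#'   TC 2.6-13 mmol/L).
#' @param complete_case Require complete data for every variable used by any
#'   of the three scores (joint completeness).
#' @return An object of class `prep_config`.
#' @export
prep_config <- function(age_range = c(40, 74),
                        hba1c_threshold = 6.5,
                        sbp_atypical_bounds = c(70, 270),
                        tc_atypical_bounds = c(2.6, 13) * MGDL_PER_MMOLL,
                        complete_case = TRUE) {
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            sbp_atypical_bounds[1] < sbp_atypical_bounds[2],
            tc_atypical_bounds[1] < tc_atypical_bounds[2])
  structure(list(age_range = age_range,
                 hba1c_threshold = hba1c_threshold,
                 sbp_atypical_bounds = sbp_atypical_bounds,
                 tc_atypical_bounds = tc_atypical_bounds,
                 complete_case = isTRUE(complete_case)),
            class = "prep_config")
}

#' Impute the antihypertensive-use answer for skip-pattern missingness
#'
#' If the two-week antihypertensive question is unanswered and the person
#' reported no hypertension diagnosis (or only during pregnancy, or never had
#' blood pressure measured), the answer is imputed as "no".  All other
#' records are unchanged.  Idempotent.
#'
#' @param records Raw survey records (data.frame).
#' @return `records` with `antihypertensive_use_2wk` imputed.
#' @export
impute_antihypertensive <- function(records) {
  use <- records$antihypertensive_use_2wk
  fill <- is.na(use) & !is.na(records$hypertension_dx) &
    records$hypertension_dx %in% .no_htn_dx
  use[fill] <- "no"
  records$antihypertensive_use_2wk <- use
  records
}

#' Derive diabetes status with the HbA1c override
#'
#' Applies two rules in a fixed order: first, people who report never having
#' had their glycemia measured are taken as non-diabetic; second, an HbA1c at
#' or above the threshold (default 6.5%) imputes diabetes regardless of any
#' prior answer.  Idempotent.
#'
#' @param records Raw survey records.
#' @param threshold HbA1c threshold in %, inclusive.
#' @return `records` with a logical `diabetes` column added.
#' @export
impute_diabetes <- function(records, threshold = 6.5) {
  dx <- records$diabetes_dx
  diabetes <- rep(NA, nrow(records))
  diabetes[!is.na(dx) & dx == "yes"] <- TRUE
  diabetes[!is.na(dx) & dx == "no"] <- FALSE
  diabetes[!is.na(dx) & dx == "never-measured"] <- FALSE
  high <- !is.na(records$hba1c) & records$hba1c >= threshold
  diabetes[high] <- TRUE
  records$diabetes <- diabetes
  records
}

#' Derive cardiovascular history, smoking and race flags
#'
#' `cvd_history` is an OR of prior heart-disease and stroke diagnoses;
#' `smoker` covers daily and less-than-daily smoking; `black` maps
#' self-reported parda or preta skin color, per the survey's race question.
#'
#' @param records Raw survey records.
#' @return `records` with logical `cvd_history`, `smoker`, `black` columns.
#' @export
derive_flags <- function(records) {
  records$cvd_history <- records$heart_disease_dx | records$stroke_dx
  resp <- records$smoking_response
  records$smoker <- ifelse(is.na(resp), NA, resp %in% SMOKER_RESPONSES)
  col <- records$skin_color
  records$black <- ifelse(is.na(col), NA, col %in% BLACK_SKIN_COLORS)
  records
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("<exclusion_tally>\n")
  cat("  input records: ", x$n_input, "\n", sep = "")
  for (r in names(x$counts)) {
    cat(sprintf("  excluded, %-12s %d\n", paste0(r, ":"), x$counts[[r]]))
  }
  cat("  eligible:      ", x$n_eligible, "\n", sep = "")
  invisible(x)
}

#' Apply eligibility rules and tally exclusions
#'
#' Assumes imputation (and flag derivation) has been applied.  Exclusion
#' reasons are applied sequentially in the fixed order: age window, joint
#' completeness across all three scores, cardiovascular history, atypical
#' SBP/TC values.  The tally always conserves counts:
#' `n_input = n_eligible + sum(exclusions)`.
#'
#' @param records Imputed records with derived flags.
#' @param config A [prep_config()].
#' @return List with `profiles` (risk-factor profiles with a `weight`
#'   column) and `tally` (class `exclusion_tally`).
#' @export
apply_eligibility <- function(records, config = prep_config()) {
  stopifnot(inherits(config, "prep_config"))
  n_input <- nrow(records)
  counts <- c(age = 0L, completeness = 0L, cvd_history = 0L, atypical = 0L)

  in_age <- !is.na(records$age) &
    records$age >= config$age_range[1] & records$age <= config$age_range[2]
  counts["age"] <- sum(!in_age)
  records <- records[in_age, , drop = FALSE]

  on_aht <- records$antihypertensive_use_2wk == "yes"
  needed <- data.frame(sex = records$sex, age = records$age,
                       sbp = records$sbp, tc = records$tc, hdl = records$hdl,
                       smoker = records$smoker, diabetes = records$diabetes,
                       on_antihypertensive = on_aht, black = records$black,
                       weight = records$survey_weight)
  complete <- stats::complete.cases(needed) & !is.na(records$cvd_history)
  if (config$complete_case) {
    counts["completeness"] <- sum(!complete)
    records <- records[complete, , drop = FALSE]
    needed <- needed[complete, , drop = FALSE]
  }

  no_cvd <- is.na(records$cvd_history) | !records$cvd_history
  counts["cvd_history"] <- sum(!no_cvd)
  needed <- needed[no_cvd, , drop = FALSE]

  typical <- needed$sbp >= config$sbp_atypical_bounds[1] &
    needed$sbp <= config$sbp_atypical_bounds[2] &
    needed$tc >= config$tc_atypical_bounds[1] &
    needed$tc <= config$tc_atypical_bounds[2]
  typical[is.na(typical)] <- TRUE
  counts["atypical"] <- sum(!typical)
  profiles <- needed[typical, , drop = FALSE]
  rownames(profiles) <- NULL

  tally <- structure(list(n_input = n_input,
                          counts = as.list(counts),
                          n_eligible = nrow(profiles)),
                     class = "exclusion_tally")
  stopifnot(tally$n_input ==
              tally$n_eligible + sum(unlist(tally$counts)))
  if (nrow(profiles) == 0L) {
    warning("no eligible records remain after exclusions", call. = FALSE)
  }
  list(profiles = profiles, tally = tally)
}

#' Prepare a cohort end to end
#'
#' Convenience wrapper: antihypertensive imputation, diabetes derivation,
#' flag derivation, then eligibility filtering.
#'
#' @inheritParams apply_eligibility
#' @param records Raw survey records.
#' @return As [apply_eligibility()].
#' @export
prepare_cohort <- function(records, config = prep_config()) {
  records <- impute_antihypertensive(records)
  records <- impute_diabetes(records, config$hba1c_threshold)
  records <- derive_flags(records)
  apply_eligibility(records, config)
}

#' Read raw survey records from CSV with an optional column mapping
#'
#' @param path CSV path.
#' @param mapping Optional named character vector mapping raw column names to
#'   the canonical ones (`c(raw_name = "canonical_name")`), applied before
#'   validation.  A YAML/JSON mapping file path is also accepted when the
#'   value is a length-1 string ending in `.json`.
#' @return Data.frame of canonical raw survey records.
#' @export
read_survey_csv <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.character(mapping) && length(mapping) == 1 &&
      grepl("\\.json$", mapping)) {
    mapping <- unlist(jsonlite::fromJSON(mapping))
  }
  if (!is.null(mapping)) {
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  required <- c("sex", "age", "sbp", "tc", "hdl", "survey_weight")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop("survey CSV lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in c("heart_disease_dx", "stroke_dx")) {
    if (!is.null(df[[v]]) && !is.logical(df[[v]])) {
      df[[v]] <- as.logical(df[[v]])
    }
  }
  w <- df$survey_weight
  if (any(!is.na(w) & w <= 0)) {
    stop("survey weights must be positive", call. = FALSE)
  }
  df
}
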