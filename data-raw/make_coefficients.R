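# Builds the packaged coefficient files under inst/extdata/coefficients/.
# Run from the package root:  Rscript data-raw/make_coefficients.R
#
# framingham_gcvd.json transcribes the published general-CVD equation
# (sex-specific Cox models); the other two files are synthetic stand-ins
# reproducing the published functional forms (see the files' provenance
# fields and the package documentation).

devtools::load_all(".", quiet = TRUE)

out_dir <- file.path("inst", "extdata", "coefficients")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

term <- function(variable, coef, transform = "identity", interact = NULL,
                 condition = NULL) {
  tm <- list(variable = variable, transform = transform, coef = coef)
  if (!is.null(interact)) tm$interact <- interact
  if (!is.null(condition)) tm$condition <- condition
  tm
}

write_set <- function(x, file) {
  x$checksum <- coefficient_checksum(x)
  jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, null = "null")
  # round-trip check: must load and validate
  invisible(load_coefficient_set(file.path(out_dir, file)))
}

## ---- Framingham general cardiovascular disease (2008), Cox 10-year ----

framingham <- list(
  model_id = "framingham_gcvd",
  label = "Framingham general cardiovascular disease risk score (2008)",
  source = paste("D'Agostino RB Sr, Vasan RS, Pencina MJ, et al. General",
                 "cardiovascular risk profile for use in primary care: the",
                 "Framingham Heart Study. Circulation. 2008;117(6):743-53."),
  provenance = "transcribed",
  link = "cox_10yr",
  strata_by = list("sex"),
  strata_levels = list(sex = list("female", "male")),
  units = list(age = "years", sbp = "mmHg", tc = "mg/dL", hdl = "mg/dL"),
  valid_ranges = list(age = list(30, 74), sbp = list(60, 300),
                      tc = list(80, 550), hdl = list(5, 200)),
  strata = list(
    female = list(
      baseline = list(s0_10yr = 0.95012, mean_lp = 26.1931),
      terms = list(
        term("age", 2.32888, "natural_log"),
        term("tc", 1.20904, "natural_log"),
        term("hdl", -0.70833, "natural_log"),
        term("sbp", 2.76157, "natural_log",
             condition = list(on_antihypertensive = FALSE)),
        term("sbp", 2.82263, "natural_log",
             condition = list(on_antihypertensive = TRUE)),
        term("smoker", 0.52873),
        term("diabetes", 0.69154)
      )
    ),
    male = list(
      baseline = list(s0_10yr = 0.88936, mean_lp = 23.9802),
      terms = list(
        term("age", 3.06117, "natural_log"),
        term("tc", 1.12370, "natural_log"),
        term("hdl", -0.93263, "natural_log"),
        term("sbp", 1.93303, "natural_log",
             condition = list(on_antihypertensive = FALSE)),
        term("sbp", 1.99881, "natural_log",
             condition = list(on_antihypertensive = TRUE)),
        term("smoker", 0.65451),
        term("diabetes", 0.57367)
      )
    )
  )
)

write_set(framingham, "framingham_gcvd.json")

## ---- Pooled Cohort Equations, 2018 logistic revision (synthetic) ----
# Sex-stratified logistic model with black race as a covariate plus
# treatment/race interactions, mirroring the published revision's form.
# Numerical content is a reconstruction (see provenance field).

pce <- list(
  model_id = "pce2018",
  label = "Pooled Cohort Equations, 2018 logistic revision (synthetic stand-in)",
  source = paste("Modeled on: Yadlowsky S, Hayward RA, Sussman JB, et al.",
                 "Clinical implications of revised pooled cohort equations",
                 "for estimating atherosclerotic cardiovascular disease",
                 "risk. Ann Intern Med. 2018;169(1):20-9. Coefficient values",
                 "are a reconstruction of the published sex-specific",
                 "logistic equations, not a verified transcription;",
                 "re-transcribe from the source before real-data use."),
  provenance = "synthetic",
  link = "logistic",
  strata_by = list("sex"),
  strata_levels = list(sex = list("female", "male")),
  units = list(age = "years", sbp = "mmHg", tc = "mg/dL", hdl = "mg/dL"),
  valid_ranges = list(age = list(40, 79), sbp = list(60, 300),
                      tc = list(80, 550), hdl = list(5, 200)),
  strata = list(
    female = list(
      terms = list(
        term("intercept", -12.823110),
        term("age", 0.106501),
        term("black", 0.432440),
        term("sbp", 0.017666),
        term("on_antihypertensive", 0.731678),
        term("sbp", -0.003647,
             condition = list(on_antihypertensive = TRUE)),
        term("diabetes", 0.943970),
        term("smoker", 1.009790),
        term("tc_hdl_ratio", 0.151318),
        term("age", -0.008580, condition = list(black = TRUE)),
        term("sbp", 0.006208, condition = list(black = TRUE)),
        term("on_antihypertensive", 0.152968,
             condition = list(black = TRUE)),
        term("sbp", -0.000173,
             condition = list(black = TRUE, on_antihypertensive = TRUE)),
        term("diabetes", 0.115232, condition = list(black = TRUE)),
        term("smoker", -0.092231, condition = list(black = TRUE)),
        term("tc_hdl_ratio", 0.070498, condition = list(black = TRUE))
      )
    ),
    male = list(
      terms = list(
        term("intercept", -11.679980),
        term("age", 0.064200),
        term("black", 0.482835),
        term("sbp", 0.038950),
        term("sbp", -0.000061, interact = "sbp"),
        term("on_antihypertensive", 2.055533),
        term("sbp", -0.014207,
             condition = list(on_antihypertensive = TRUE)),
        term("diabetes", 0.842209),
        term("smoker", 0.895589),
        term("tc_hdl_ratio", 0.193307),
        term("age", 0.000025, interact = "sbp"),
        term("sbp", 0.011609, condition = list(black = TRUE)),
        term("on_antihypertensive", -0.119621,
             condition = list(black = TRUE)),
        term("sbp", 0.004190,
             condition = list(black = TRUE, on_antihypertensive = TRUE)),
        term("age", -0.000199, interact = "sbp",
             condition = list(black = TRUE))
      )
    )
  )
)

write_set(pce, "pce2018_synthetic.json")

## ---- Globorisk-type laboratory equation, Brazil recalibration (synthetic) ----
# Age-interacted proportional-hazards relative risks recalibrated year by
# year against sex x age-band baseline annual event rates and mean
# risk-factor levels.  All numerical content (coefficients, Brazilian
# baseline rates, mean factor levels) is synthetic but epidemiologically
# plausible; TC is declared in mmol/L to exercise unit conversion.

bands <- lapply(seq(40, 80, by = 5), function(lo) list(lo, lo + 4))

globorisk <- list(
  model_id = "globorisk_lac",
  label = paste("Country-recalibrated laboratory cardiovascular risk",
                "equation, Globorisk form (synthetic stand-in)"),
  source = paste("Modeled on the laboratory-based, country-recalibrated",
                 "Globorisk methodology (fatal plus non-fatal events) for",
                 "Latin America and the Caribbean. Coefficients, baseline",
                 "rates and mean risk-factor levels are synthetic",
                 "stand-ins, not transcriptions; obtain the published",
                 "supplementary recalibration inputs before real-data use."),
  provenance = "synthetic",
  link = "globorisk_recalibrated",
  version = "laboratory",
  outcome = "fatal_plus_nonfatal_cvd",
  strata_by = list("sex"),
  strata_levels = list(sex = list("female", "male")),
  units = list(age = "years", sbp = "mmHg", tc = "mmol/L"),
  valid_ranges = list(age = list(40, 74), sbp = list(60, 300),
                      tc = list(2.07, 14.22)),
  strata = list(female = list(terms = list()),
                male = list(terms = list())),
  # log hazard-ratio per unit at age 60, with linear attenuation per year
  risk_factors = list(
    list(variable = "sbp", coef_at_60 = 0.0235, age_slope = -0.0002),
    list(variable = "tc", coef_at_60 = 0.1817, age_slope = -0.0012),
    list(variable = "diabetes", coef_at_60 = 0.615, age_slope = -0.010),
    list(variable = "smoker", coef_at_60 = 0.500, age_slope = -0.008)
  ),
  calibration = list(
    country = "BRA",
    age_bands = bands,
    female = list(
      baseline_annual_rate = list(0.0010, 0.0015, 0.0023, 0.0035, 0.0053,
                                  0.0080, 0.0120, 0.0180, 0.0270),
      mean_sbp = list(122, 125, 129, 133, 137, 141, 144, 147, 149),
      mean_tc = list(4.99, 5.12, 5.25, 5.35, 5.40, 5.40, 5.35, 5.28, 5.17),
      prev_smoker = list(0.18, 0.17, 0.16, 0.14, 0.12, 0.10, 0.08, 0.07,
                         0.06),
      prev_diabetes = list(0.06, 0.08, 0.10, 0.13, 0.16, 0.19, 0.21, 0.23,
                           0.24)
    ),
    male = list(
      baseline_annual_rate = list(0.0020, 0.0030, 0.0044, 0.0065, 0.0095,
                                  0.0138, 0.0200, 0.0290, 0.0420),
      mean_sbp = list(126, 128, 131, 134, 137, 140, 143, 146, 148),
      mean_tc = list(5.04, 5.12, 5.17, 5.20, 5.17, 5.12, 5.07, 4.99, 4.91),
      prev_smoker = list(0.25, 0.23, 0.21, 0.19, 0.17, 0.15, 0.13, 0.11,
                         0.09),
      prev_diabetes = list(0.07, 0.09, 0.11, 0.14, 0.17, 0.20, 0.22, 0.24,
                           0.25)
    )
  )
)

write_set(globorisk, "globorisk_lac_synthetic.json")

cat("wrote", length(list.files(out_dir)), "coefficient files to", out_dir,
    "\n")
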