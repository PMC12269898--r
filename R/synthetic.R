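# Seeded synthetic survey populations with the statistical structure the
# concordance analysis assumes: a Gaussian copula ties age, blood pressure,
# lipids and the categorical risk factors together; continuous marginals are
# shifted log-normals solved to match the target median and quartiles
# exactly; survey weights are log-normal; configurable contamination (missing
# fields, cardiovascular history, out-of-window ages) exercises every
# eligibility filter.

#' Fit a shifted log-normal to three quantiles
#'
#' Solves location, log-scale and shift so that the 25th, 50th and 75th
#' percentiles match exactly.  Requires right skew on the log scale
#' (`(q75-q50) > (q50-q25)`).
#'
#' @param quartiles Numeric `c(q25, q50, q75)`, strictly increasing.
#' @return List with `meanlog`, `sdlog`, `shift`.
#' @export
fit_shifted_lognormal <- function(quartiles) {
  q25 <- quartiles[1]; q50 <- quartiles[2]; q75 <- quartiles[3]
  stopifnot(q25 < q50, q50 < q75)
  r <- (q75 - q50) / (q50 - q25)
  if (r <= 1) {
    stop("quartiles are not right-skewed; a shifted log-normal needs ",
         "(q75 - q50) > (q50 - q25)", call. = FALSE)
  }
  a <- stats::qnorm(0.75)
  sdlog <- log(r) / a
  scale <- (q50 - q25) / (1 - 1 / r)
  list(meanlog = log(scale), sdlog = sdlog, shift = q50 - scale)
}

.q_shifted_lnorm <- function(u, fit) {
  fit$shift + stats::qlnorm(u, fit$meanlog, fit$sdlog)
}

.p_shifted_lnorm <- function(x, fit) {
  stats::plnorm(x - fit$shift, fit$meanlog, fit$sdlog)
}

# Map a uniform draw onto the marginal truncated to [lo, hi].
.q_trunc <- function(u, fit, lo, hi) {
  plo <- .p_shifted_lnorm(lo, fit)
  phi <- .p_shifted_lnorm(hi, fit)
  .q_shifted_lnorm(plo + u * (phi - plo), fit)
}

#' Synthetic population configuration
#'
#' Defaults encode the study conditions: the categorical marginals
#' (female 52.3%, black 48.8%, smokers 17.7%, antihypertensive use 23.4%,
#' diabetes 13.9%), age as a normal with mean 53.4 and SD 9.4 truncated to
#' 40-74 years, and total cholesterol / HDL / systolic blood pressure with
#' median (IQR) 191 (169-216) mg/dL, 44 (37-53) mg/dL and 128 (116-140.5)
#' mmHg.  Dependence is a Gaussian copula with a sparse default correlation
#' (age-SBP 0.3, TC-HDL 0.1, age-diabetes 0.2, all else 0).  SBP and TC are
#' truncated to the atypical-value bounds so the generator never produces an
#' atypical exclusion.
#'
#' @param n Number of records.
#' @param seed Integer RNG seed; the generator is byte-reproducible given
#'   `(n, seed)` and the remaining settings.
#' @param female,black,smoker,antihypertensive,diabetes Marginal shares.
#' @param age_mean,age_sd,age_range Parameters of the truncated-normal age
#'   marginal (years).
#' @param tc_quartiles,hdl_quartiles,sbp_quartiles Target `c(q25, q50, q75)`
#'   of the continuous marginals (mg/dL, mg/dL, mmHg).
#' @param correlations Named vector of copula correlations
#'   (`age_sbp`, `tc_hdl`, `age_diabetes`).
#' @param weight_meanlog,weight_sdlog Log-normal survey-weight parameters.
#' @param contamination List of shares: `missing` (records with one of
#'   SBP/TC/HDL blanked), `heart_disease` and `stroke` (prior-diagnosis
#'   flags), `age_out` (ages resampled outside the eligibility window).
#' @param sbp_bounds,tc_bounds Truncation bounds for SBP and TC (the
#'   atypical-value bounds); HDL is truncated to `hdl_bounds` for
#'   plausibility.
#' @param hdl_bounds Truncation bounds for HDL (mg/dL).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 2000, seed = 1,
                             female = 0.523,
                             age_mean = 53.4, age_sd = 9.4,
                             age_range = c(40, 74),
                             black = 0.488, smoker = 0.177,
                             antihypertensive = 0.234, diabetes = 0.139,
                             tc_quartiles = c(169, 191, 216),
                             hdl_quartiles = c(37, 44, 53),
                             sbp_quartiles = c(116, 128, 140.5),
                             correlations = c(age_sbp = 0.3, tc_hdl = 0.1,
                                              age_diabetes = 0.2),
                             weight_meanlog = log(1000), weight_sdlog = 0.5,
                             contamination = list(missing = 0.03,
                                                  heart_disease = 0.055,
                                                  stroke = 0.030,
                                                  age_out = 0.10),
                             sbp_bounds = c(70, 270),
                             tc_bounds = c(2.6, 13) * MGDL_PER_MMOLL,
                             hdl_bounds = c(15, 150)) {
  shares <- c(female = female, black = black, smoker = smoker,
              antihypertensive = antihypertensive, diabetes = diabetes,
              unlist(contamination))
  if (any(shares < 0 | shares > 1)) {
    stop("shares must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n > 0, age_range[1] < age_range[2])
  cfg <- as.list(environment())
  cfg$shares <- NULL
  cfg <- structure(cfg, class = "synthetic_config")
  # fail early on an invalid copula correlation matrix
  tryCatch(chol(.copula_sigma(cfg)),
           error = function(e) stop("copula correlation matrix is not ",
                                    "positive definite", call. = FALSE))
  cfg
}

# Copula variable order (fixed): age, sbp, tc, hdl, female, black, smoker,
# antihypertensive, diabetes.
.copula_sigma <- function(config) {
  s <- diag(9)
  nm <- c("age", "sbp", "tc", "hdl", "female", "black", "smoker",
          "antihyp", "diabetes")
  dimnames(s) <- list(nm, nm)
  rc <- config$correlations
  s["age", "sbp"] <- s["sbp", "age"] <- rc[["age_sbp"]]
  s["tc", "hdl"] <- s["hdl", "tc"] <- rc[["tc_hdl"]]
  s["age", "diabetes"] <- s["diabetes", "age"] <- rc[["age_diabetes"]]
  s
}

#' Generate a synthetic survey population
#'
#' Deterministic given the configuration (including its seed); the caller's
#' RNG state is saved and restored.  Returns canonical raw survey records
#' ready for [prepare_cohort()].
#'
#' @param config A [synthetic_config()].
#' @return Data.frame of raw survey records (one row per person).
#' @export
#' @examples
#' pop <- generate_population(synthetic_config(n = 500, seed = 42))
#' nrow(pop)
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  n <- config$n

  z <- MASS::mvrnorm(n, mu = rep(0, 9), Sigma = .copula_sigma(config))
  u <- stats::pnorm(z)

  # age: truncated normal via inverse CDF on the copula margin
  plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(plo + u[, 1] * (phi - plo),
                      config$age_mean, config$age_sd)

  sbp <- .q_trunc(u[, 2], fit_shifted_lognormal(config$sbp_quartiles),
                  config$sbp_bounds[1], config$sbp_bounds[2])
  tc <- .q_trunc(u[, 3], fit_shifted_lognormal(config$tc_quartiles),
                 config$tc_bounds[1], config$tc_bounds[2])
  hdl <- .q_trunc(u[, 4], fit_shifted_lognormal(config$hdl_quartiles),
                  config$hdl_bounds[1], config$hdl_bounds[2])

  female <- u[, 5] < config$female
  black <- u[, 6] < config$black
  smoker <- u[, 7] < config$smoker
  antihyp <- u[, 8] < config$antihypertensive
  diab <- u[, 9] < config$diabetes

  # categorical elaboration; every draw is a fixed-length runif so the RNG
  # stream (hence reproducibility) does not depend on the data
  aux <- matrix(stats::runif(6 * n), n, 6)

  skin_color <- ifelse(black,
                       ifelse(aux[, 1] < 0.7, "parda", "preta"),
                       ifelse(aux[, 1] < 0.9, "branca", "amarela"))
  smoking_response <- ifelse(smoker,
                             ifelse(aux[, 2] < 0.8, "sim, diariamente",
                                    "sim, menos que diariamente"),
                             ifelse(aux[, 2] < 0.4, "não, mas já fumou",
                                    "nunca fumou"))

  # hypertension diagnosis and the survey's skip pattern: the medication
  # question is only answered by people reporting the diagnosis
  hypertension_dx <- rep("no", n)
  use <- rep(NA_character_, n)
  hypertension_dx[antihyp] <- "yes"
  use[antihyp] <- "yes"
  na_idx <- which(!antihyp)
  cat_u <- aux[na_idx, 3]
  dx <- ifelse(cat_u < 0.10, "yes",
               ifelse(cat_u < 0.85, "no",
                      ifelse(cat_u < 0.95, "never-measured",
                             "only-in-pregnancy")))
  dx[dx == "only-in-pregnancy" & !female[na_idx]] <- "never-measured"
  hypertension_dx[na_idx] <- dx
  use[na_idx][dx == "yes"] <- "no"

  # diabetes: diagnosis categories and an HbA1c consistent with the target
  # share under the >= 6.5% rule
  diabetes_dx <- rep("no", n)
  diabetes_dx[diab] <- ifelse(aux[diab, 4] < 0.7, "yes",
                              ifelse(aux[diab, 4] < 0.9, "no",
                                     "never-measured"))
  diabetes_dx[!diab] <- ifelse(aux[!diab, 4] < 0.88, "no", "never-measured")
  hba1c <- rep(NA_real_, n)
  hba1c[diab] <- 6.5 + stats::rexp(sum(diab), rate = 1 / 1.2)
  hba1c[!diab] <- pmin(6.49, pmax(4.0, stats::rnorm(sum(!diab), 5.4, 0.45)))
  # a few diagnosed diabetics lack the assay; diabetes stays resolvable
  hba1c[diab & diabetes_dx == "yes" & aux[, 5] < 0.05] <- NA_real_

  heart_disease_dx <- aux[, 6] < config$contamination$heart_disease
  stroke_dx <- stats::runif(n) < config$contamination$stroke

  # out-of-window ages and missing measurements (filter contamination)
  age_u <- stats::runif(n)
  out <- age_u < config$contamination$age_out
  side <- stats::runif(n)
  age[out & side < 0.6] <- stats::runif(sum(out & side < 0.6), 18, 39.99)
  age[out & side >= 0.6] <- stats::runif(sum(out & side >= 0.6), 75, 90)

  miss_u <- stats::runif(n)
  miss <- miss_u < config$contamination$missing
  which_var <- sample.int(3, n, replace = TRUE)
  sbp[miss & which_var == 1] <- NA_real_
  tc[miss & which_var == 2] <- NA_real_
  hdl[miss & which_var == 3] <- NA_real_

  survey_weight <- stats::rlnorm(n, config$weight_meanlog, config$weight_sdlog)

  data.frame(sex = ifelse(female, "female", "male"),
             age = age,
             skin_color = skin_color,
             smoking_response = smoking_response,
             hypertension_dx = hypertension_dx,
             antihypertensive_use_2wk = use,
             diabetes_dx = diabetes_dx,
             hba1c = hba1c,
             heart_disease_dx = heart_disease_dx,
             stroke_dx = stroke_dx,
             sbp = sbp,
             tc = tc,
             hdl = hdl,
             survey_weight = survey_weight,
             stringsAsFactors = FALSE)
}

#' Simulate a population (convenience wrapper)
#'
#' @param n Number of records.
#' @param seed RNG seed.
#' @param ... Further arguments to [synthetic_config()].
#' @return Data.frame of raw survey records.
#' @export
simulate_population <- function(n = 2000, seed = 1, ...) {
  generate_population(synthetic_config(n = n, seed = seed, ...))
}
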