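# Generic evaluator for 10-year cardiovascular risk equations.
#
# A risk-factor profile is one row of a data.frame with columns
#   sex ("female"/"male"), age (years), sbp (mmHg), tc (mg/dL), hdl (mg/dL),
#   smoker, diabetes, on_antihypertensive, black (logicals).
# All functions are vectorized over rows.

.profile_fields <- c("sex", "age", "sbp", "tc", "hdl",
                     "smoker", "diabetes", "on_antihypertensive", "black")

.check_profiles <- function(profiles, coefs) {
  miss <- setdiff(.profile_fields, names(profiles))
  if (length(miss)) {
    stop("profiles lack required fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (v in names(coefs$valid_ranges)) {
    rng <- unlist(coefs$valid_ranges[[v]])
    x <- profiles[[v]]
    if (anyNA(x)) {
      stop("profiles contain missing '", v, "'; the eligibility stage must ",
           "remove incomplete records before scoring", call. = FALSE)
    }
    bad <- x < rng[1] | x > rng[2]
    if (any(bad)) {
      stop("variable '", v, "' outside the valid range [", rng[1], ", ",
           rng[2], "] for model ", coefs$model_id, " (first offending value: ",
           x[which(bad)[1]], ")", call. = FALSE)
    }
  }
  invisible(profiles)
}

.stratum_key <- function(profiles, coefs) {
  cols <- lapply(unlist(coefs$strata_by), function(f) {
    v <- profiles[[f]]
    if (is.logical(v)) tolower(as.character(v)) else as.character(v)
  })
  do.call(paste, c(cols, sep = "."))
}

# Value of one variable reference inside a term. Booleans become 0/1;
# "intercept" is the constant 1; "tc_hdl_ratio" is derived.
.term_variable <- function(profiles, var, transform) {
  x <- switch(var,
    intercept = rep(1, nrow(profiles)),
    tc_hdl_ratio = profiles$tc / profiles$hdl,
    {
      v <- profiles[[var]]
      if (is.null(v)) stop("unknown term variable '", var, "'", call. = FALSE)
      if (is.logical(v)) as.numeric(v) else v
    }
  )
  if (identical(transform, "natural_log")) log(x) else x
}

.eval_terms <- function(profiles, terms) {
  acc <- rep(0, nrow(profiles))
  for (tm in terms) {
    v <- .term_variable(profiles, tm$variable, tm$transform)
    if (!is.null(tm$interact)) {
      tr2 <- if (is.null(tm$interact_transform)) "identity" else tm$interact_transform
      v <- v * .term_variable(profiles, tm$interact, tr2)
    }
    if (!is.null(tm$condition)) {
      for (f in names(tm$condition)) {
        v <- v * as.numeric(profiles[[f]] == tm$condition[[f]])
      }
    }
    acc <- acc + tm$coef * v
  }
  acc
}

#' Linear predictor of a risk equation
#'
#' Evaluates L = sum of beta_i * transform_i(x_i) over the coefficient block
#' selected by each profile's stratum (e.g. sex).  Deterministic; out-of-range
#' inputs are rejected, not clamped.
#'
#' @param profiles Data.frame of risk-factor profiles (see package overview).
#' @param coefs A `coefficient_set`.
#' @return Numeric vector, one linear predictor per profile row.
#' @export
linear_predictor <- function(profiles, coefs) {
  stopifnot(inherits(coefs, "coefficient_set"))
  .check_profiles(profiles, coefs)
  key <- .stratum_key(profiles, coefs)
  unknown <- setdiff(unique(key), names(coefs$strata))
  if (length(unknown)) {
    stop("no coefficient block for stratum ", paste(unknown, collapse = ", "),
         " in model ", coefs$model_id, call. = FALSE)
  }
  lp <- rep(NA_real_, nrow(profiles))
  for (s in unique(key)) {
    idx <- key == s
    lp[idx] <- .eval_terms(profiles[idx, , drop = FALSE],
                           coefs$strata[[s]]$terms)
  }
  lp
}

#' Ten-year risk from a Cox-type baseline survival
#'
#' risk = 1 - S0^exp(L - Lbar), the standard conversion of a Cox linear
#' predictor to an absolute 10-year risk given the 10-year baseline survival
#' S0 and the cohort mean linear predictor Lbar.
#'
#' @param lp Linear predictor(s).
#' @param s0 Baseline 10-year survival fraction(s), each in (0,1).
#' @param mean_lp Cohort mean linear predictor(s).
#' @return Risk fraction(s) in (0,1).
#' @export
cox_ten_year_risk <- function(lp, s0, mean_lp) {
  if (any(s0 <= 0 | s0 >= 1)) {
    stop("baseline survival must lie strictly inside (0,1)", call. = FALSE)
  }
  1 - s0^exp(lp - mean_lp)
}

#' Ten-year risk from a logistic linear predictor
#'
#' @param lp Finite linear predictor(s).
#' @return Risk fraction(s) in (0,1), strictly increasing in `lp`.
#' @export
logistic_risk <- function(lp) {
  if (any(!is.finite(lp))) {
    stop("linear predictor must be finite", call. = FALSE)
  }
  stats::plogis(lp)
}

# Year-by-year recalibrated evaluation (Globorisk-style).  For each of the
# ten projection years the person is aged by one year, the sex x age-band
# baseline annual event rate is scaled by the person's relative risk versus
# the population-average risk-factor profile of that band, and the annual
# hazards are accumulated: risk = 1 - exp(-sum_t rate_t * RRratio_t).
.globorisk_risk <- function(profiles, coefs) {
  cal <- coefs$calibration
  bands <- do.call(rbind, lapply(cal$age_bands, unlist))
  lowers <- bands[, 1]
  rf <- coefs$risk_factors
  vars <- vapply(rf, `[[`, "", "variable")
  beta0 <- vapply(rf, `[[`, 0, "coef_at_60")
  slope <- vapply(rf, `[[`, 0, "age_slope")
  female <- profiles$sex == "female"
  cum <- rep(0, nrow(profiles))
  xmat <- vapply(vars, function(v) {
    x <- profiles[[v]]
    if (is.logical(x)) as.numeric(x) else x
  }, numeric(nrow(profiles)))
  xmat <- matrix(xmat, nrow = nrow(profiles))
  for (t in 0:9) {
    a <- floor(profiles$age) + t
    b <- findInterval(a, lowers)
    beta <- outer(a - 60, slope) + rep(beta0, each = nrow(profiles))
    lin_i <- rowSums(beta * xmat)
    lin_pop <- rep(0, nrow(profiles))
    rate <- numeric(nrow(profiles))
    for (s in c("female", "male")) {
      sel <- if (s == "female") female else !female
      if (!any(sel)) next
      blk <- cal[[s]]
      rate[sel] <- unlist(blk$baseline_annual_rate)[b[sel]]
      means <- vapply(vars, function(v) {
        key <- if (v %in% c("smoker", "diabetes")) paste0("prev_", v)
               else paste0("mean_", v)
        unlist(blk[[key]])[b[sel]]
      }, numeric(sum(sel)))
      means <- matrix(means, nrow = sum(sel))
      lin_pop[sel] <- rowSums(beta[sel, , drop = FALSE] * means)
    }
    cum <- cum + rate * exp(lin_i - lin_pop)
  }
  1 - exp(-cum)
}

#' Score profiles with a named risk equation
#'
#' Dispatches to the link declared by the model's coefficient set:
#' `cox_10yr` (Framingham-type), `logistic` (revised Pooled Cohort
#' Equations-type) or `globorisk_recalibrated` (country-recalibrated,
#' laboratory version, fatal plus non-fatal events).
#'
#' @param profiles Data.frame of risk-factor profiles.
#' @param model_id One of the registry's model ids; the packaged registry has
#'   `"framingham_gcvd"`, `"pce2018"` and `"globorisk_lac"`.
#' @param registry Named list of `coefficient_set` objects, as returned by
#'   [default_model_registry()].
#' @return Numeric vector of 10-year risk fractions, each in (0,1).
#' @export
#' @examples
#' p <- data.frame(sex = "female", age = 61, sbp = 124, tc = 180, hdl = 47,
#'                 smoker = TRUE, diabetes = FALSE,
#'                 on_antihypertensive = FALSE, black = FALSE)
#' risk_score(p, "framingham_gcvd")
risk_score <- function(profiles, model_id,
                       registry = default_model_registry()) {
  if (!model_id %in% names(registry)) {
    stop("unknown model_id '", model_id, "'; registry has: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  coefs <- registry[[model_id]]
  switch(coefs$link,
    cox_10yr = {
      lp <- linear_predictor(profiles, coefs)
      key <- .stratum_key(profiles, coefs)
      s0 <- vapply(coefs$strata, function(b) b$baseline$s0_10yr, 0)
      ml <- vapply(coefs$strata, function(b) b$baseline$mean_lp, 0)
      unname(cox_ten_year_risk(lp, s0[key], ml[key]))
    },
    logistic = logistic_risk(linear_predictor(profiles, coefs)),
    globorisk_recalibrated = {
      .check_profiles(profiles, coefs)
      .globorisk_risk(profiles, coefs)
    },
    stop("unhandled link '", coefs$link, "'", call. = FALSE)
  )
}

#' Score a cohort with several risk equations
#'
#' @param profiles Data.frame of risk-factor profiles.
#' @param models Character vector of model ids.
#' @param registry Model registry (see [default_model_registry()]).
#' @return Data.frame with one risk column per model, rows aligned with
#'   `profiles`.
#' @export
score_cohort <- function(profiles,
                         models = c("framingham_gcvd", "pce2018",
                                    "globorisk_lac"),
                         registry = default_model_registry()) {
  out <- lapply(models, function(m) risk_score(profiles, m, registry))
  stats::setNames(as.data.frame(out), models)
}
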