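reg <- default_model_registry()
model_ids <- c("framingham_gcvd", "pce2018", "globorisk_lac")

test_that("linear predictor handles trivial coefficient sets", {
  p <- one_profile()
  zero <- make_toy_set(list(toy_term("age", 0), toy_term("sbp", 0)))
  expect_equal(linear_predictor(p, zero), 0)

  one_term <- make_toy_set(list(toy_term("sbp", 2)))
  expect_equal(linear_predictor(one_profile(sbp = 120), one_term), 240)
})

test_that("engine matches a brute-force re-computation on toy sets", {
  set.seed(11)
  for (rep in 1:5) {
    terms_f <- list(
      toy_term("intercept", rnorm(1)),
      toy_term("age", rnorm(1)),
      toy_term("sbp", rnorm(1), "natural_log"),
      toy_term("tc_hdl_ratio", rnorm(1)),
      toy_term("sbp", rnorm(1), interact = "age"),
      toy_term("smoker", rnorm(1), condition = list(black = TRUE)),
      toy_term("sbp", rnorm(1),
               condition = list(on_antihypertensive = TRUE, black = FALSE))
    )
    terms_m <- list(
      toy_term("age", rnorm(1), "natural_log"),
      toy_term("hdl", rnorm(1), "natural_log", interact = "tc"),
      toy_term("diabetes", rnorm(1))
    )
    coefs <- make_toy_set(terms_f, terms_m)
    grid <- profile_grid()
    expect_equal(linear_predictor(grid, coefs), brute_force_lp(grid, coefs),
                 tolerance = 1e-12)
    risk <- logistic_risk(linear_predictor(grid, coefs))
    expect_equal(risk, 1 / (1 + exp(-brute_force_lp(grid, coefs))),
                 tolerance = 1e-12)
  }
})

test_that("cox ten-year risk follows 1 - S0^exp(L - Lbar)", {
  expect_equal(cox_ten_year_risk(2.5, 0.9, 2.5), 1 - 0.9)
  expect_lt(cox_ten_year_risk(0, 1 - 1e-12, 0), 1e-11)
  # L - Lbar = ln 2 doubles the exponent: 1 - 0.9^2 = 0.19
  expect_equal(cox_ten_year_risk(log(2), 0.9, 0), 0.19)
  expect_error(cox_ten_year_risk(1, 1.2, 0), "survival")
})

test_that("logistic link is correct and strictly increasing", {
  expect_equal(logistic_risk(0), 0.5)
  expect_equal(logistic_risk(log(3)), 0.75)
  expect_lt(logistic_risk(-40), 1e-15)
  expect_error(logistic_risk(Inf), "finite")
  lp <- seq(-8, 8, by = 0.25)
  expect_true(all(diff(logistic_risk(lp)) > 0))
})

test_that("all shipped models return risks strictly inside (0,1), deterministically", {
  grid <- profile_grid(age = c(41, 55, 74))
  for (m in model_ids) {
    r1 <- risk_score(grid, m, reg)
    r2 <- risk_score(grid, m, reg)
    expect_identical(r1, r2)
    expect_true(all(r1 > 0 & r1 < 1))
  }
})

test_that("smoking never lowers the risk under any model", {
  grid <- profile_grid(smoker = FALSE)
  for (m in model_ids) {
    r0 <- risk_score(grid, m, reg)
    grid2 <- grid
    grid2$smoker <- TRUE
    expect_true(all(risk_score(grid2, m, reg) >= r0))
  }
})

test_that("treated blood pressure carries at least the untreated risk (Framingham)", {
  grid <- profile_grid(on_antihypertensive = FALSE)
  r0 <- risk_score(grid, "framingham_gcvd", reg)
  grid$on_antihypertensive <- TRUE
  expect_true(all(risk_score(grid, "framingham_gcvd", reg) >= r0))
})

test_that("three models produce three generally different risks on one profile", {
  p <- one_profile(sex = "male", age = 60, sbp = 140, tc = 220, hdl = 40)
  risks <- vapply(model_ids, function(m) risk_score(p, m, reg), 0)
  expect_equal(length(unique(round(risks, 6))), 3L)
})

test_that("cholesterol unit declaration round-trips through conversion", {
  # rewrite the Framingham file declaring mmol/L (values scaled to match),
  # then score the same mg/dL profile: risks must agree to 1e-9
  path <- file.path(system.file("extdata", "coefficients",
                                package = "riskconcord"),
                    "framingham_gcvd.json")
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  f <- MGDL_PER_MMOLL
  for (v in c("tc", "hdl")) {
    doc$units[[v]] <- "mmol/L"
    doc$valid_ranges[[v]] <- lapply(doc$valid_ranges[[v]],
                                    function(b) b / f)
    for (s in names(doc$strata)) {
      doc$strata[[s]]$terms <- lapply(doc$strata[[s]]$terms, function(tm) {
        if (identical(tm$variable, v)) tm$coef <- tm$coef * f
        tm
      })
    }
  }
  doc$checksum <- NULL
  doc$checksum <- coefficient_checksum(doc)
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, tmp, auto_unbox = TRUE, digits = 10)
  converted <- load_coefficient_set(tmp)
  grid <- profile_grid()
  orig <- risk_score(grid, "framingham_gcvd", reg)
  alt <- cox_ten_year_risk(
    linear_predictor(grid, converted),
    c(female = 0.95012, male = 0.88936)[grid$sex],
    c(female = 26.1931, male = 23.9802)[grid$sex]
  )
  expect_equal(unname(alt), orig, tolerance = 1e-9)
})

test_that("out-of-range inputs are rejected with variable and bounds named", {
  p <- one_profile(age = 29)
  expect_error(risk_score(p, "framingham_gcvd", reg), "age.*30.*74")
  expect_error(risk_score(one_profile(sbp = 59), "pce2018", reg),
               "sbp.*60.*300")
  expect_error(risk_score(one_profile(age = 39), "globorisk_lac", reg),
               "age")
})

test_that("unknown models and missing strata raise configuration errors", {
  expect_error(risk_score(one_profile(), "who_2019", reg), "unknown model_id")
  half <- make_toy_set(list(toy_term("age", 0.1)))
  half$strata$male <- NULL
  expect_error(linear_predictor(one_profile(sex = "male"), half),
               "no coefficient block")
  expect_error(risk_score(one_profile(hdl = NA), "framingham_gcvd", reg),
               "missing")
})

test_that("a tampered coefficient file fails its checksum on load", {
  path <- file.path(system.file("extdata", "coefficients",
                                package = "riskconcord"),
                    "framingham_gcvd.json")
  txt <- readLines(path)
  tampered <- sub("2.32888", "2.42888", txt, fixed = TRUE)
  tmp <- tempfile(fileext = ".json")
  writeLines(tampered, tmp)
  expect_error(load_coefficient_set(tmp), "checksum mismatch")
})
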