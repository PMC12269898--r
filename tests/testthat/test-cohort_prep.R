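raw_record <- function(sex = "female", age = 50, skin_color = "branca",
                       smoking_response = "nunca fumou",
                       hypertension_dx = "no",
                       antihypertensive_use_2wk = NA_character_,
                       diabetes_dx = "no", hba1c = 5.4,
                       heart_disease_dx = FALSE, stroke_dx = FALSE,
                       sbp = 120, tc = 190, hdl = 45, survey_weight = 1) {
  data.frame(sex = sex, age = age, skin_color = skin_color,
             smoking_response = smoking_response,
             hypertension_dx = hypertension_dx,
             antihypertensive_use_2wk = antihypertensive_use_2wk,
             diabetes_dx = diabetes_dx, hba1c = hba1c,
             heart_disease_dx = heart_disease_dx, stroke_dx = stroke_dx,
             sbp = sbp, tc = tc, hdl = hdl, survey_weight = survey_weight,
             stringsAsFactors = FALSE)
}

test_that("skip-pattern missing antihypertensive answers are imputed as no", {
  cases <- rbind(
    raw_record(hypertension_dx = "never-measured"),
    raw_record(hypertension_dx = "only-in-pregnancy"),
    raw_record(hypertension_dx = "no"),
    raw_record(hypertension_dx = "yes",
               antihypertensive_use_2wk = "yes"),
    raw_record(hypertension_dx = "yes")  # diagnosed, truly unanswered
  )
  out <- impute_antihypertensive(cases)
  expect_equal(out$antihypertensive_use_2wk,
               c("no", "no", "no", "yes", NA))
  # idempotence
  expect_identical(impute_antihypertensive(out), out)
})

test_that("diabetes derivation applies never-measured-then-HbA1c in fixed order", {
  cases <- rbind(
    raw_record(diabetes_dx = "no", hba1c = 6.5),             # inclusive cut
    raw_record(diabetes_dx = "never-measured", hba1c = 6.4),
    raw_record(diabetes_dx = "never-measured", hba1c = 7.2), # order matters
    raw_record(diabetes_dx = "yes", hba1c = NA),
    raw_record(diabetes_dx = "no", hba1c = NA),
    raw_record(diabetes_dx = "never-measured", hba1c = NA)
  )
  out <- impute_diabetes(cases)
  expect_equal(out$diabetes, c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_identical(impute_diabetes(out), out)
})

test_that("history, smoking and race flags follow the survey coding", {
  cases <- rbind(
    raw_record(stroke_dx = TRUE),
    raw_record(heart_disease_dx = TRUE),
    raw_record(),
    raw_record(smoking_response = "sim, menos que diariamente"),
    raw_record(smoking_response = "sim, diariamente"),
    raw_record(skin_color = "parda"),
    raw_record(skin_color = "preta"),
    raw_record(skin_color = "amarela")
  )
  out <- derive_flags(cases)
  expect_equal(out$cvd_history[1:3], c(TRUE, TRUE, FALSE))
  expect_equal(out$smoker[3:5], c(FALSE, TRUE, TRUE))
  expect_equal(out$black[c(3, 6, 7, 8)], c(FALSE, TRUE, TRUE, FALSE))
})

test_that("eligibility applies age, joint completeness, history and atypical rules in order", {
  cases <- rbind(
    raw_record(age = 39),                       # below window
    raw_record(age = 74),                       # inclusive upper bound
    raw_record(hdl = NA),                       # joint completeness: HDL
                                                # missing excludes even though
                                                # one score ignores HDL
    raw_record(stroke_dx = TRUE),               # history
    raw_record(sbp = 370),                      # atypical SBP
    raw_record(tc = 60),                        # atypical TC
    raw_record(age = 40)                        # inclusive lower bound
  )
  prep <- prepare_cohort(cases)
  expect_equal(prep$tally$n_input, 7)
  expect_equal(unlist(prep$tally$counts),
               c(age = 1, completeness = 1, cvd_history = 1, atypical = 2))
  expect_equal(prep$tally$n_eligible, 2)
  expect_equal(prep$profiles$age, c(74, 40))
  expect_s3_class(prep$profiles, "data.frame")
  expect_named(prep$profiles,
               c("sex", "age", "sbp", "tc", "hdl", "smoker", "diabetes",
                 "on_antihypertensive", "black", "weight"))
})

test_that("the exclusion tally conserves counts on generated populations", {
  for (seed in c(3, 17, 99)) {
    pop <- simulate_population(n = 600, seed = seed)
    prep <- prepare_cohort(pop)
    expect_equal(prep$tally$n_input,
                 prep$tally$n_eligible + sum(unlist(prep$tally$counts)))
  }
})

test_that("an empty eligible set warns instead of failing", {
  cases <- rbind(raw_record(age = 20), raw_record(age = 90))
  expect_warning(prep <- prepare_cohort(cases), "no eligible records")
  expect_equal(prep$tally$n_eligible, 0)
  expect_equal(prep$tally$counts$age, 2)
})

test_that("survey CSV ingestion applies column mappings and validates weights", {
  pop <- simulate_population(n = 50, seed = 5)
  renamed <- pop
  names(renamed)[names(renamed) == "sbp"] <- "pressao_sistolica"
  names(renamed)[names(renamed) == "survey_weight"] <- "peso"
  f <- tempfile(fileext = ".csv")
  write.csv(renamed, f, row.names = FALSE)
  got <- read_survey_csv(f, mapping = c(pressao_sistolica = "sbp",
                                        peso = "survey_weight"))
  expect_true(all(c("sbp", "survey_weight") %in% names(got)))
  expect_equal(got$sbp, pop$sbp)

  bad <- pop
  bad$survey_weight[1] <- -2
  write.csv(bad, f, row.names = FALSE)
  expect_error(read_survey_csv(f), "positive")
  expect_error(read_survey_csv(f, mapping = c(sbp = "x")), "required columns")
})
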