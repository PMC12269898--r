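# Independent oracles used across the suite.  These deliberately avoid the
# package's evaluation paths: naive per-row loops, textbook formulas from
# integer counts, and literal spreadsheet-style arithmetic.

# Classical (unweighted) Gwet AC1 from a q x q integer count matrix.
classical_ac1 <- function(counts) {
  n <- sum(counts)
  q <- nrow(counts)
  pa <- sum(diag(counts)) / n
  pik <- (rowSums(counts) + colSums(counts)) / (2 * n)
  pe <- sum(pik * (1 - pik)) / (q - 1)
  (pa - pe) / (1 - pe)
}

# Cohen's kappa from a probability matrix.
cohen_kappa <- function(p) {
  p <- p / sum(p)
  pa <- sum(diag(p))
  pe <- sum(rowSums(p) * colSums(p))
  (pa - pe) / (1 - pe)
}

# All weak compositions of n into k non-negative parts (stars and bars),
# one composition per row.
weak_compositions <- function(n, k) {
  if (k == 1) return(matrix(n, 1, 1))
  bars <- utils::combn(n + k - 1, k - 1)
  if (is.null(dim(bars))) bars <- matrix(bars, nrow = k - 1)
  m <- ncol(bars)
  parts <- matrix(0L, m, k)
  prev <- rep(0L, m)
  for (j in seq_len(k - 1)) {
    parts[, j] <- bars[j, ] - prev - 1L
    prev <- bars[j, ]
  }
  parts[, k] <- n + k - 1L - prev
  parts
}

# Naive per-row re-computation of sum(beta * transform(x)) for a coefficient
# set: explicit loops, no vectorization, no shared code with the engine.
brute_force_lp <- function(profiles, coefs) {
  out <- numeric(nrow(profiles))
  for (i in seq_len(nrow(profiles))) {
    row <- profiles[i, , drop = FALSE]
    blk <- coefs$strata[[as.character(row$sex)]]
    acc <- 0
    for (tm in blk$terms) {
      val_of <- function(v, tr) {
        x <- if (v == "intercept") 1
        else if (v == "tc_hdl_ratio") row$tc / row$hdl
        else as.numeric(row[[v]])
        if (identical(tr, "natural_log")) log(x) else x
      }
      v <- val_of(tm$variable, tm$transform)
      if (!is.null(tm$interact)) {
        v <- v * val_of(tm$interact,
                        if (is.null(tm$interact_transform)) "identity"
                        else tm$interact_transform)
      }
      ok <- TRUE
      for (f in names(tm$condition)) {
        if (!identical(as.logical(row[[f]]), as.logical(tm$condition[[f]]))) {
          ok <- FALSE
        }
      }
      if (ok) acc <- acc + tm$coef * v
    }
    out[i] <- acc
  }
  out
}

# In-memory toy coefficient set (no file, no checksum needed).
make_toy_set <- function(terms_female, terms_male = terms_female,
                         link = "logistic",
                         baseline = list(s0_10yr = 0.9, mean_lp = 0)) {
  blk <- function(terms) {
    b <- list(terms = terms)
    if (link == "cox_10yr") b$baseline <- baseline
    b
  }
  structure(list(model_id = "toy", source = "in-memory test fixture",
                 link = link, strata_by = list("sex"),
                 strata_levels = list(sex = list("female", "male")),
                 units = list(), valid_ranges = list(),
                 strata = list(female = blk(terms_female),
                               male = blk(terms_male))),
            class = "coefficient_set")
}

toy_term <- function(variable, coef, transform = "identity",
                     interact = NULL, condition = NULL) {
  tm <- list(variable = variable, transform = transform, coef = coef)
  if (!is.null(interact)) tm$interact <- interact
  if (!is.null(condition)) tm$condition <- condition
  tm
}

# A factorial grid of valid profiles.
profile_grid <- function(age = c(45, 60, 74), sbp = c(100, 130, 170),
                         tc = c(150, 210, 300), hdl = c(30, 45, 70),
                         smoker = c(FALSE, TRUE), diabetes = c(FALSE, TRUE),
                         on_antihypertensive = c(FALSE, TRUE),
                         black = c(FALSE, TRUE),
                         sex = c("female", "male")) {
  expand.grid(sex = sex, age = age, sbp = sbp, tc = tc, hdl = hdl,
              smoker = smoker, diabetes = diabetes,
              on_antihypertensive = on_antihypertensive, black = black,
              stringsAsFactors = FALSE)
}

one_profile <- function(sex = "female", age = 61, sbp = 124, tc = 180,
                        hdl = 47, smoker = TRUE, diabetes = FALSE,
                        on_antihypertensive = FALSE, black = FALSE) {
  data.frame(sex = sex, age = age, sbp = sbp, tc = tc, hdl = hdl,
             smoker = smoker, diabetes = diabetes,
             on_antihypertensive = on_antihypertensive, black = black,
             stringsAsFactors = FALSE)
}
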