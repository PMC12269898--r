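# Between-score agreement: fold-ratio concordance of continuous risks and
# survey-weighted Gwet AC1 over guideline risk strata.

#' Classify a pair of risk estimates by fold ratio
#'
#' Two estimates are concordant when the larger is strictly less than `rho`
#' times the smaller (default 1.25, i.e. the log-scale Bland-Altman window
#' 0.8-1.25); otherwise the larger side is flagged.  A ratio of exactly
#' `rho` counts as discordant.
#'
#' @param r_a,r_b Positive risk vectors (fractions or percentages; the
#'   classification depends only on their ratio).
#' @param rho Fold threshold (> 1).
#' @return Factor with levels `concordant`, `a_higher`, `b_higher`.
#' @export
#' @examples
#' classify_pair(c(0.10, 0.10), c(0.10, 0.125))
classify_pair <- function(r_a, r_b, rho = 1.25) {
  if (length(r_a) != length(r_b)) {
    stop("risk vectors differ in length", call. = FALSE)
  }
  if (any(!is.finite(r_a) | !is.finite(r_b) | r_a <= 0 | r_b <= 0)) {
    stop("risks must be positive and finite", call. = FALSE)
  }
  stopifnot(rho > 1)
  ratio <- pmax(r_a, r_b) / pmin(r_a, r_b)
  out <- ifelse(ratio < rho, "concordant",
                ifelse(r_a > r_b, "a_higher", "b_higher"))
  factor(out, levels = c("concordant", "a_higher", "b_higher"))
}

#' Survey-weighted share of each classification
#'
#' @param classifications Factor as returned by [classify_pair()].
#' @param weights Positive survey weights, same length.
#' @return Named numeric vector of weighted proportions summing to 1.
#' @export
weighted_share <- function(classifications, weights) {
  if (length(classifications) != length(weights)) {
    stop("classifications and weights differ in length", call. = FALSE)
  }
  if (any(!is.finite(weights) | weights <= 0)) {
    stop("weights must be positive and finite", call. = FALSE)
  }
  tot <- sum(weights)
  vapply(levels(classifications),
         function(l) sum(weights[classifications == l]) / tot, 0)
}

#' Define an ordinal risk stratification scheme
#'
#' @param name Scheme name.
#' @param cuts Strictly increasing cut points in percent, each in (0,100);
#'   `q = length(cuts) + 1` ordinal categories result, lower bound inclusive.
#' @param labels Optional category labels (length `q`).
#' @return Object of class `stratification_scheme`.
#' @export
stratification_scheme <- function(name, cuts, labels = NULL) {
  cuts <- as.numeric(cuts)
  if (any(diff(cuts) <= 0) || any(cuts <= 0 | cuts >= 100)) {
    stop("cuts must be strictly increasing and inside (0,100)", call. = FALSE)
  }
  q <- length(cuts) + 1L
  if (is.null(labels)) {
    labels <- c(paste0("<", cuts[1], "%"),
                if (q > 2) paste0(utils::head(cuts, -1), "-<",
                                  utils::tail(cuts, -1), "%"),
                paste0(">=", utils::tail(cuts, 1), "%"))
  }
  stopifnot(length(labels) == q)
  structure(list(name = name, cuts = cuts, q = q, labels = labels),
            class = "stratification_scheme")
}

#' @export
print.stratification_scheme <- function(x, ...) {
  cat("<stratification_scheme> ", x$name, ": cuts at ",
      paste0(x$cuts, "%", collapse = ", "), " (", x$q, " categories)\n",
      sep = "")
  invisible(x)
}

#' Default stratification schemes
#'
#' The main scheme cuts at 10% and 20% (low / intermediate / high); the
#' sensitivity schemes are AHA/ACC 2018 (5, 7.5, 20), WHO (10, 20, 30) and
#' ESC/EAS 2019 for fatal plus non-fatal events (10, 15, 30 - the fatal-event
#' cut points 3/5/10 tripled).
#'
#' @return Named list of [stratification_scheme()] objects.
#' @export
default_schemes <- function() {
  list(
    main = stratification_scheme("main", c(10, 20),
                                 c("low", "intermediate", "high")),
    aha_acc = stratification_scheme("aha_acc", c(5, 7.5, 20)),
    who = stratification_scheme("who", c(10, 20, 30)),
    esc_eas = stratification_scheme("esc_eas", c(10, 15, 30))
  )
}

#' Map continuous risks to ordinal categories
#'
#' Category k holds risks with `100 * risk` in `[c_k, c_{k+1})`, lower bound
#' inclusive (so exactly 10% with cuts 10/20 is intermediate, exactly 20% is
#' high).
#'
#' @param risk Risk fractions in (0,1).
#' @param scheme A [stratification_scheme()].
#' @return Integer category indices in `1:q`.
#' @export
stratify <- function(risk, scheme) {
  stopifnot(inherits(scheme, "stratification_scheme"))
  if (any(!is.finite(risk) | risk <= 0 | risk >= 1)) {
    stop("risks must be fractions strictly inside (0,1)", call. = FALSE)
  }
  findInterval(100 * risk, scheme$cuts) + 1L
}

#' Build a weighted contingency table of two category vectors
#'
#' Cell (a,b) receives the normalized weight mass of records classified `a`
#' by the first score and `b` by the second.
#'
#' @param cats_a,cats_b Integer categories in `1:q`.
#' @param weights Positive weights.
#' @param q Number of categories.
#' @return Object of class `weighted_contingency`: list with the `q x q`
#'   probability matrix `p` (summing to 1), its marginals `row` and `col`,
#'   and `q`.
#' @export
build_contingency <- function(cats_a, cats_b, weights, q) {
  if (length(cats_a) != length(cats_b) ||
      length(cats_a) != length(weights)) {
    stop("category and weight vectors differ in length", call. = FALSE)
  }
  if (any(cats_a < 1 | cats_a > q | cats_b < 1 | cats_b > q)) {
    stop("categories outside 1..q", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  idx <- (cats_b - 1L) * q + cats_a
  p <- matrix(vapply(seq_len(q * q),
                     function(k) sum(weights[idx == k]), 0), q, q)
  p <- p / sum(p)
  structure(list(p = p, row = rowSums(p), col = colSums(p), q = q),
            class = "weighted_contingency")
}

#' Gwet's first-order agreement coefficient (AC1)
#'
#' AC1 = (Pa - Pe) / (1 - Pe) with Pa the diagonal mass, pi_k the average of
#' the two marginal shares of category k, and
#' Pe = sum_k pi_k (1 - pi_k) / (q - 1).  Chance correction built from
#' average category prevalences makes AC1 resistant to the kappa prevalence
#' paradox.  Adjacent categories are fully discordant (no ordinal
#' weighting).
#'
#' @param table A `weighted_contingency`, or a plain non-negative `q x q`
#'   matrix of masses (normalized internally).
#' @return AC1 in `[-1, 1]`.
#' @export
gwet_ac1 <- function(table) {
  if (is.matrix(table)) {
    table <- structure(list(p = table / sum(table),
                            row = rowSums(table) / sum(table),
                            col = colSums(table) / sum(table),
                            q = nrow(table)),
                       class = "weighted_contingency")
  }
  stopifnot(inherits(table, "weighted_contingency"), table$q >= 2)
  pa <- sum(diag(table$p))
  pik <- (table$row + table$col) / 2
  pe <- sum(pik * (1 - pik)) / (table$q - 1)
  if (1 - pe < 1e-12) {
    stop("degenerate table: chance agreement is 1, AC1 undefined",
         call. = FALSE)
  }
  (pa - pe) / (1 - pe)
}

#' Weighted quantile (left-continuous inverse CDF)
#'
#' Returns the lowest value whose cumulative normalized weight reaches `p`.
#' With `type = "interpolate"`, linearly interpolates the weighted CDF
#' between successive order statistics instead.
#'
#' @param values Numeric vector.
#' @param weights Positive weights, same length.
#' @param p Probabilities in `[0, 1]` (vectorized).
#' @param type `"lower"` (default, no interpolation) or `"interpolate"`.
#' @return Quantile(s).
#' @export
weighted_quantile <- function(values, weights, p,
                              type = c("lower", "interpolate")) {
  type <- match.arg(type)
  if (!length(values)) stop("empty input", call. = FALSE)
  if (length(values) != length(weights)) {
    stop("values and weights differ in length", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  stopifnot(all(p >= 0 & p <= 1))
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  if (type == "lower") {
    vapply(p, function(pp) v[which(cw >= pp)[1]], 0)
  } else {
    vapply(p, function(pp) stats::approx(c(0, cw), c(v[1], v), xout = pp,
                                         ties = "ordered")$y, 0)
  }
}

#' Weighted median and interquartile range
#'
#' @inheritParams weighted_quantile
#' @return Named vector `c(q25, median, q75)`.
#' @export
weighted_iqr <- function(values, weights, type = "lower") {
  q <- weighted_quantile(values, weights, c(0.25, 0.5, 0.75), type = type)
  stats::setNames(q, c("q25", "median", "q75"))
}

#' Agreement between two scores' risks
#'
#' Computes the fold-ratio concordance breakdown plus, per stratification
#' scheme, the observed weighted agreement Pa and Gwet's AC1.  Point
#' estimates only: without the survey's cluster variable no design-based
#' variance is possible.
#'
#' @param r_a,r_b Risk fractions from the two scores.
#' @param weights Positive survey weights.
#' @param rho Fold threshold (see [classify_pair()]).
#' @param schemes List of [stratification_scheme()]s.
#' @param pair Identifier string for reporting.
#' @return Object of class `agreement_result`: list with `pair`, `rho`,
#'   `shares` (concordant / a_higher / b_higher) and `by_scheme`, each
#'   element holding `pa`, `ac1` and the weighted contingency `table`.
#' @export
agreement_pair <- function(r_a, r_b, weights, rho = 1.25,
                           schemes = default_schemes(), pair = "a_vs_b") {
  cls <- classify_pair(r_a, r_b, rho)
  shares <- weighted_share(cls, weights)
  by_scheme <- lapply(schemes, function(sch) {
    tab <- build_contingency(stratify(r_a, sch), stratify(r_b, sch),
                             weights, sch$q)
    list(pa = sum(diag(tab$p)), ac1 = gwet_ac1(tab), table = tab)
  })
  structure(list(pair = pair, rho = rho, shares = shares,
                 by_scheme = by_scheme),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result> ", x$pair, " (fold threshold ", x$rho, ")\n",
      sep = "")
  cat(sprintf("  concordant %.1f%% | first higher %.1f%% | second higher %.1f%%\n",
              100 * x$shares["concordant"], 100 * x$shares["a_higher"],
              100 * x$shares["b_higher"]))
  for (s in names(x$by_scheme)) {
    cat(sprintf("  scheme %-8s Pa = %.3f, AC1 = %.3f\n", s,
                x$by_scheme[[s]]$pa, x$by_scheme[[s]]$ac1))
  }
  invisible(x)
}
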