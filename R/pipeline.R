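# End-to-end orchestration: ingest -> prepare -> score with the three
# equations -> agreement for every score pair under every stratification
# scheme -> report.

.default_models <- c("framingham_gcvd", "pce2018", "globorisk_lac")

#' Weighted cohort summary
#'
#' Weighted median and IQR of each score's continuous risk plus, per
#' stratification scheme, the weighted share of the population in each
#' stratum.  Per the study's weighting rule, absolute frequencies are
#' unweighted and every other statistic is weighted.
#'
#' @param risks Data.frame of risks (one column per score).
#' @param weights Positive survey weights.
#' @param schemes List of [stratification_scheme()]s.
#' @return List with `n` (unweighted count), `median_iqr` (per score, in
#'   percent) and `strata_shares` (per scheme, per score, weighted shares).
#' @export
summarize_cohort <- function(risks, weights, schemes = default_schemes()) {
  med <- lapply(risks, function(r) 100 * weighted_iqr(r, weights))
  shares <- lapply(schemes, function(sch) {
    lapply(risks, function(r) {
      cat_ <- stratify(r, sch)
      s <- vapply(seq_len(sch$q),
                  function(k) sum(weights[cat_ == k]) / sum(weights), 0)
      stats::setNames(s, sch$labels)
    })
  })
  list(n = nrow(risks), median_iqr = med, strata_shares = shares)
}

#' Agreement for every pair of scores
#'
#' @param risks Data.frame of risks, one column per score (at least two).
#' @param weights Positive survey weights.
#' @param rho Fold threshold for the continuous concordance.
#' @param schemes List of stratification schemes.
#' @return Named list of [agreement_pair()] results, one per unordered pair,
#'   named `"<a>_vs_<b>"`.
#' @export
compute_agreement <- function(risks, weights, rho = 1.25,
                              schemes = default_schemes()) {
  models <- names(risks)
  stopifnot(length(models) >= 2)
  pairs <- utils::combn(models, 2, simplify = FALSE)
  out <- lapply(pairs, function(pr) {
    agreement_pair(risks[[pr[1]]], risks[[pr[2]]], weights, rho = rho,
                   schemes = schemes,
                   pair = paste(pr[1], "vs", pr[2], sep = "_"))
  })
  stats::setNames(out, vapply(out, `[[`, "", "pair"))
}

.round1 <- function(x) round(100 * x, 1)

.agreement_report <- function(agreement) {
  lapply(agreement, function(ar) {
    list(
      pair = ar$pair,
      fold_threshold = ar$rho,
      shares_pct = as.list(.round1(ar$shares)),
      by_scheme = lapply(ar$by_scheme, function(s) {
        list(pa_pct = .round1(s$pa), ac1 = round(s$ac1, 3),
             table = s$table$p)
      }),
      machine = list(shares = as.list(ar$shares),
                     by_scheme = lapply(ar$by_scheme, function(s) {
                       list(pa = s$pa, ac1 = s$ac1)
                     }))
    )
  })
}

#' Run the full concordance pipeline
#'
#' Ingests raw survey records (a data.frame or a CSV path), prepares the
#' cohort (imputation, flags, eligibility with a full exclusion tally),
#' scores everyone with the three equations, summarizes the weighted risk
#' distributions, and computes fold-ratio concordance and stratified Gwet
#' AC1 for every score pair under every scheme.  Optionally writes a JSON
#' report, a JSON exclusion tally and a per-person risk/category CSV into
#' `out_dir`.  Deterministic: rerunning on the same input reproduces the
#' report bit for bit.
#'
#' @param input Data.frame of raw survey records, or a CSV path.
#' @param config A [prep_config()].
#' @param models Model ids to score with.
#' @param registry Model registry.
#' @param schemes Stratification schemes (default: main 10/20 plus the
#'   AHA/ACC, WHO and ESC/EAS sensitivity schemes).
#' @param rho Fold threshold.
#' @param out_dir Optional output directory (created if needed).
#' @param mapping Optional column mapping for CSV input
#'   (see [read_survey_csv()]).
#' @param verbose Emit one structured log line per stage.
#' @return Object of class `concordance_report`: list with `tally`,
#'   `profiles`, `risks`, `summary`, `agreement` and `report` (the
#'   JSON-ready list, percentages rounded to one decimal with raw values in
#'   a `machine` section).
#' @export
#' @examples
#' pop <- simulate_population(n = 400, seed = 7)
#' res <- run_concordance(pop, verbose = FALSE)
#' res$summary$median_iqr$framingham_gcvd
run_concordance <- function(input, config = prep_config(),
                            models = .default_models,
                            registry = default_model_registry(),
                            schemes = default_schemes(), rho = 1.25,
                            out_dir = NULL, mapping = NULL, verbose = TRUE) {
  records <- if (is.character(input)) read_survey_csv(input, mapping) else input
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage=ingest n_in=%d", nrow(records))

  prep <- prepare_cohort(records, config)
  profiles <- prep$profiles
  say("stage=prepare n_in=%d n_out=%d excluded_age=%d excluded_completeness=%d excluded_cvd=%d excluded_atypical=%d",
      prep$tally$n_input, prep$tally$n_eligible,
      prep$tally$counts$age, prep$tally$counts$completeness,
      prep$tally$counts$cvd_history, prep$tally$counts$atypical)

  if (nrow(profiles) == 0L) {
    warning("empty eligible set; returning tally-only report", call. = FALSE)
    report <- list(tally = prep$tally, warning = "empty eligible set")
    return(structure(list(tally = prep$tally, profiles = profiles,
                          risks = NULL, summary = NULL, agreement = NULL,
                          report = report),
                     class = "concordance_report"))
  }

  risks <- score_cohort(profiles, models, registry)
  say("stage=score n=%d models=%s", nrow(risks),
      paste(models, collapse = ","))

  summary <- summarize_cohort(risks, profiles$weight, schemes)
  agreement <- compute_agreement(risks, profiles$weight, rho, schemes)
  say("stage=agree pairs=%d schemes=%d", length(agreement), length(schemes))

  report <- list(
    n_eligible = prep$tally$n_eligible,
    exclusion_tally = prep$tally[c("n_input", "counts", "n_eligible")],
    risk_median_iqr_pct = lapply(summary$median_iqr,
                                 function(x) as.list(round(x, 1))),
    strata_shares_pct = lapply(summary$strata_shares, function(sch) {
      lapply(sch, function(x) as.list(.round1(x)))
    }),
    agreement = .agreement_report(agreement),
    machine = list(
      risk_median_iqr = summary$median_iqr,
      strata_shares = summary$strata_shares
    )
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(prep$tally[c("n_input", "counts", "n_eligible")],
                         file.path(out_dir, "exclusion_tally.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    per_person <- cbind(profiles, risks)
    for (sch in schemes) {
      for (m in models) {
        per_person[[paste0(m, "_", sch$name)]] <-
          sch$labels[stratify(risks[[m]], sch)]
      }
    }
    utils::write.csv(per_person,
                     file.path(out_dir, "person_risks.csv"),
                     row.names = FALSE)
    say("stage=write out_dir=%s", out_dir)
  }

  structure(list(tally = prep$tally, profiles = profiles, risks = risks,
                 summary = summary, agreement = agreement, report = report),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("<concordance_report>\n")
  print(x$tally)
  if (!is.null(x$summary)) {
    cat("  weighted median risk (IQR), %:\n")
    for (m in names(x$summary$median_iqr)) {
      q <- x$summary$median_iqr[[m]]
      cat(sprintf("    %-16s %.1f (%.1f-%.1f)\n", m, q["median"],
                  q["q25"], q["q75"]))
    }
    for (ar in x$agreement) print(ar)
  }
  invisible(x)
}
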