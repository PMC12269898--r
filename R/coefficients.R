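# Declarative risk-equation descriptions ("coefficient sets") loaded from JSON.
#
# A coefficient set is data, not code: it names a link function, the profile
# fields that select a stratum, the terms of the linear predictor (variable,
# transform, optional interaction partner, optional boolean conditions), the
# per-stratum baseline quantities, per-variable validity bounds and declared
# units.  The evaluator in risk_models.R is generic over this description.

#' Conversion factor between cholesterol units
#'
#' Total and HDL cholesterol in mmol/L are converted to the package's
#' canonical mg/dL by multiplying by this factor.
#' @export
MGDL_PER_MMOLL <- 38.67

# Variables that carry a cholesterol unit; everything else is unit-fixed
# (mmHg, years, unitless booleans/ratios).
.CHOL_VARS <- c("tc", "hdl")

#' Canonical JSON checksum of a coefficient file payload
#'
#' The md5 checksum stored in each coefficient file covers the whole parsed
#' document except the `checksum` field itself, serialized back to canonical
#' (unpretty, auto-unboxed) JSON. `load_coefficient_set()` recomputes it on
#' load and refuses a file whose substance has drifted from its recorded
#' checksum.
#'
#' @param x A parsed coefficient document (nested list).
#' @return A length-1 character md5 string.
#' @export
coefficient_checksum <- function(x) {
  x$checksum <- NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

.known_links <- c("cox_10yr", "logistic", "globorisk_recalibrated")
.known_transforms <- c("identity", "natural_log")

#' Load and validate a coefficient set from a JSON file
#'
#' Reads one risk-equation description, verifies its checksum and internal
#' consistency, and converts any variable declared in mmol/L to the canonical
#' mg/dL (bounds and calibration means are multiplied by
#' [MGDL_PER_MMOLL]; coefficients multiplying that variable are divided,
#' once per appearance of the variable in a term).
#'
#' @param path Path to a JSON coefficient file.
#' @return An object of class `coefficient_set`.
#' @export
load_coefficient_set <- function(path) {
  if (!file.exists(path)) {
    stop("coefficient file not found: ", path, call. = FALSE)
  }
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$checksum)) {
    stop("coefficient file ", basename(path), " has no checksum field",
         call. = FALSE)
  }
  got <- coefficient_checksum(x)
  if (!identical(got, x$checksum)) {
    stop("checksum mismatch in ", basename(path),
         ": recorded ", x$checksum, ", recomputed ", got,
         "; the file's substance has been altered", call. = FALSE)
  }
  x <- .convert_units(x)
  obj <- structure(x, class = "coefficient_set")
  validate_coefficient_set(obj)
  obj
}

.convert_units <- function(x) {
  units <- x$units
  if (is.null(units)) return(x)
  for (v in intersect(names(units), .CHOL_VARS)) {
    if (identical(units[[v]], "mmol/L")) {
      f <- MGDL_PER_MMOLL
      if (!is.null(x$valid_ranges[[v]])) {
        x$valid_ranges[[v]] <- lapply(x$valid_ranges[[v]], function(b) b * f)
      }
      for (s in names(x$strata)) {
        x$strata[[s]]$terms <- lapply(x$strata[[s]]$terms, function(tm) {
          k <- sum(identical(tm$variable, v), identical(tm$interact, v))
          if (k > 0) tm$coef <- tm$coef / f^k
          tm
        })
      }
      x$risk_factors <- lapply(x$risk_factors, function(rf) {
        if (identical(rf$variable, v)) {
          rf$coef_at_60 <- rf$coef_at_60 / f
          rf$age_slope <- rf$age_slope / f
        }
        rf
      })
      if (!is.null(x$calibration)) {
        key <- paste0("mean_", v)
        for (s in c("female", "male")) {
          if (!is.null(x$calibration[[s]][[key]])) {
            x$calibration[[s]][[key]] <-
              lapply(x$calibration[[s]][[key]], function(m) m * f)
          }
        }
      }
      units[[v]] <- "mg/dL"
    }
  }
  x$units <- units
  x
}

#' Validate a coefficient set
#'
#' Checks structural invariants: known link and transforms, a complete
#' coefficient block for every declared stratum level combination, baseline
#' survival inside (0,1) for Cox-type equations, and (for recalibrated
#' equations) non-negative baseline rates over contiguous, non-overlapping
#' age bands.
#'
#' @param x A `coefficient_set`.
#' @return `x`, invisibly; errors describe the first violated invariant.
#' @export
validate_coefficient_set <- function(x) {
  stopifnot(inherits(x, "coefficient_set"))
  if (is.null(x$model_id) || !nzchar(x$model_id)) {
    stop("coefficient set has no model_id", call. = FALSE)
  }
  if (is.null(x$source)) {
    stop("coefficient set ", x$model_id, " has no source citation",
         call. = FALSE)
  }
  if (!x$link %in% .known_links) {
    stop("unknown link '", x$link, "' in model ", x$model_id, call. = FALSE)
  }
  levels <- x$strata_levels
  combos <- do.call(
    paste,
    c(expand.grid(lapply(levels, unlist), stringsAsFactors = FALSE), sep = ".")
  )
  missing <- setdiff(combos, names(x$strata))
  if (length(missing)) {
    stop("model ", x$model_id, " is missing coefficient blocks for strata: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (s in names(x$strata)) {
    blk <- x$strata[[s]]
    for (tm in blk$terms) {
      if (!tm$transform %in% .known_transforms) {
        stop("unknown transform '", tm$transform, "' in model ", x$model_id,
             ", stratum ", s, call. = FALSE)
      }
      if (!is.numeric(tm$coef) || !is.finite(tm$coef)) {
        stop("non-finite coefficient in model ", x$model_id, ", stratum ", s,
             call. = FALSE)
      }
    }
    if (identical(x$link, "cox_10yr")) {
      s0 <- blk$baseline$s0_10yr
      if (is.null(s0) || s0 <= 0 || s0 >= 1) {
        stop("baseline 10-year survival must lie in (0,1); model ",
             x$model_id, ", stratum ", s, call. = FALSE)
      }
      if (is.null(blk$baseline$mean_lp)) {
        stop("cox_10yr stratum ", s, " lacks a mean linear predictor",
             call. = FALSE)
      }
    }
  }
  for (rng in x$valid_ranges) {
    rng <- unlist(rng)
    if (length(rng) != 2 || rng[1] >= rng[2]) {
      stop("valid_ranges entries must be increasing pairs; model ",
           x$model_id, call. = FALSE)
    }
  }
  if (identical(x$link, "globorisk_recalibrated")) {
    .validate_calibration(x)
  }
  invisible(x)
}

.validate_calibration <- function(x) {
  cal <- x$calibration
  if (is.null(cal)) {
    stop("recalibrated model ", x$model_id, " has no calibration block",
         call. = FALSE)
  }
  bands <- do.call(rbind, lapply(cal$age_bands, unlist))
  if (any(bands[, 1] > bands[, 2])) {
    stop("malformed age band in model ", x$model_id, call. = FALSE)
  }
  if (nrow(bands) > 1 &&
      any(bands[-1, 1] != bands[-nrow(bands), 2] + 1)) {
    stop("age bands must be contiguous and non-overlapping; model ",
         x$model_id, call. = FALSE)
  }
  nb <- nrow(bands)
  for (s in c("female", "male")) {
    blk <- cal[[s]]
    if (is.null(blk)) {
      stop("calibration lacks a ", s, " block; model ", x$model_id,
           call. = FALSE)
    }
    rate <- unlist(blk$baseline_annual_rate)
    if (length(rate) != nb || any(rate < 0)) {
      stop("baseline annual rates must be non-negative, one per age band; ",
           "model ", x$model_id, ", ", s, call. = FALSE)
    }
  }
  invisible(x)
}

#' Load the packaged model registry
#'
#' Loads every coefficient file in a directory (by default the package's
#' `extdata/coefficients`) and returns them keyed by `model_id`.  The
#' packaged registry holds `framingham_gcvd`, `pce2018` and `globorisk_lac`.
#'
#' @param dir Directory of JSON coefficient files; override to supply an
#'   alternative registry.
#' @return Named list of `coefficient_set` objects.
#' @export
#' @examples
#' reg <- default_model_registry()
#' names(reg)
default_model_registry <- function(dir = system.file("extdata", "coefficients",
                                                     package = "riskconcord")) {
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no coefficient files found in ", dir, call. = FALSE)
  sets <- lapply(files, load_coefficient_set)
  stats::setNames(sets, vapply(sets, `[[`, "", "model_id"))
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat("<coefficient_set> ", x$model_id, "\n", sep = "")
  cat("  link:    ", x$link, "\n", sep = "")
  cat("  strata:  ", paste(names(x$strata), collapse = ", "), "\n", sep = "")
  if (!is.null(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  cat("  source:  ", x$source, "\n", sep = "")
  invisible(x)
}
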