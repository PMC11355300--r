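#' Load the packaged study fixtures
#'
#' The package ships the published AIDA study tables as delimited-text
#' fixtures: participant and geometric-parameter summary statistics, the
#' Pearson correlation table, the pairwise decision-tree cut-off table, the
#' per-class performance/confusion-matrix table, the feature-importance
#' rankings, and the three per-patient prediction tables (AIDA classes 0, 3
#' and 4) with zone labels, asynclitism type, repetition counts and the
#' actual and per-algorithm predicted binary outcomes.
#'
#' The loader validates internal consistency before returning: expanded
#' prediction counts of 68 / 50 / 31 per class (149 in total over 86
#' distinct patients), and zone quadruples consistent with each class
#' (class 0 all green, class 3 exactly one green, class 4 none green).
#'
#' @return An object of class `aida_fixtures`: a list with elements
#'   `participant_summary`, `geometry_summary`, `correlations`, `cutoffs`,
#'   `performance`, `importance` and `predictions` (a list with elements
#'   `class0`, `class3`, `class4`).
#' @examples
#' fx <- load_fixtures()
#' subset(fx$geometry_summary, parameter == "ad_mm")
#' sum(fx$predictions$class3$n_predictions)  # 50
#' @export
load_fixtures <- function() {
  read_fixture <- function(file) {
    path <- system.file("extdata", file, package = "aidalabor", mustWork = FALSE)
    if (!nzchar(path)) stop("fixture file missing from package: ", file)
    df <- tryCatch(
      read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
      error = function(e) stop("corrupted fixture file ", file, ": ",
                               conditionMessage(e)))
    df
  }
  fx <- list(
    participant_summary = read_fixture("participant_summary.csv"),
    geometry_summary = read_fixture("geometry_summary.csv"),
    correlations = read_fixture("correlations.csv"),
    cutoffs = read_fixture("cutoffs.csv"),
    performance = read_fixture("performance_by_class.csv"),
    importance = read_fixture("importance_rankings.csv"),
    predictions = list(
      class0 = read_fixture("predictions_class0.csv"),
      class3 = read_fixture("predictions_class3.csv"),
      class4 = read_fixture("predictions_class4.csv")
    )
  )
  fx$predictions <- lapply(fx$predictions, function(df) {
    df$patient_id <- as.character(df$patient_id)
    df
  })
  class(fx) <- "aida_fixtures"
  validate_fixtures(fx)
  fx
}

validate_fixtures <- function(fx) {
  expected <- c(class0 = 68L, class3 = 50L, class4 = 31L)
  klass <- c(class0 = 0L, class3 = 3L, class4 = 4L)
  for (nm in names(expected)) {
    df <- fx$predictions[[nm]]
    need <- c("n_predictions", "patient_id", "asynclitism_type",
              "actual_outcome", "zone_ad", "zone_aop", "zone_mla", "zone_hsd",
              "pred_svm", "pred_rf", "pred_mlp")
    if (!all(need %in% names(df))) {
      stop("prediction fixture ", nm, " is missing columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    }
    if (sum(df$n_predictions) != expected[[nm]]) {
      stop("prediction fixture ", nm, " has ", sum(df$n_predictions),
           " expanded predictions, expected ", expected[[nm]])
    }
    zones <- df[, c("zone_ad", "zone_aop", "zone_hsd", "zone_mla")]
    n_green <- rowSums(zones == "GREEN")
    ok <- switch(nm,
                 class0 = all(n_green == 4),
                 class3 = all(n_green == 1),
                 class4 = all(n_green == 0))
    if (!ok) stop("prediction fixture ", nm,
                  " has zone quadruples inconsistent with AIDA class ",
                  klass[[nm]])
  }
  ids <- unlist(lapply(fx$predictions, `[[`, "patient_id"))
  if (length(unique(ids)) != 86L) {
    stop("prediction fixtures contain ", length(unique(ids)),
         " distinct patients, expected 86")
  }
  for (nm in names(expected)) {
    perf <- fx$performance[fx$performance$aida_class == klass[[nm]], ]
    tot <- perf$tp + perf$fp + perf$fn + perf$tn
    if (!all(tot == expected[[nm]])) {
      stop("performance fixture totals for class ", klass[[nm]],
           " do not equal the expanded prediction count ", expected[[nm]])
    }
  }
  invisible(fx)
}

COHORT_REQUIRED <- c("patient_id", "ad_mm", "aop_deg", "hsd_mm", "mla_deg",
                     "asynclitism_type", "delivery_outcome", "apgar1", "apgar5")
COHORT_OPTIONAL <- c("age_years", "gestational_age_weeks", "bmi",
                     "neonatal_weight_g")

#' Validate a cohort of patient records
#'
#' Checks the column schema and per-row invariants: non-negative distances,
#' angles in (0, 360), Apgar scores in 0..10, and enumerated
#' asynclitism-type and delivery-outcome values. Errors name the offending
#' row and field.
#'
#' @param cohort data frame of patient records.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(COHORT_REQUIRED, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  fail <- function(rows, field, why) {
    stop("invalid ", field, " at row(s) ",
         paste(utils::head(rows, 5), collapse = ", "), ": ", why)
  }
  check_range <- function(field, lo, hi, lo_open = FALSE, hi_open = FALSE) {
    v <- cohort[[field]]
    bad <- which(!is.finite(v) |
                   (if (lo_open) v <= lo else v < lo) |
                   (if (hi_open) v >= hi else v > hi))
    if (length(bad)) fail(bad, field, paste0("must be in ",
      if (lo_open) "(" else "[", lo, ", ", hi, if (hi_open) ")" else "]"))
  }
  check_range("ad_mm", 0, Inf)
  check_range("hsd_mm", 0, Inf)
  check_range("aop_deg", 0, 360, lo_open = TRUE, hi_open = TRUE)
  check_range("mla_deg", 0, 360, lo_open = TRUE, hi_open = TRUE)
  check_range("apgar1", 0, 10)
  check_range("apgar5", 0, 10)
  bad <- which(!cohort$asynclitism_type %in% c("anterior", "posterior"))
  if (length(bad)) fail(bad, "asynclitism_type",
                        "must be 'anterior' or 'posterior'")
  bad <- which(!cohort$delivery_outcome %in% OUTCOME_LEVELS)
  if (length(bad)) fail(bad, "delivery_outcome", paste(
    "must be one of", paste(OUTCOME_LEVELS, collapse = ", ")))
  invisible(cohort)
}

#' Read a cohort from a delimited text file
#'
#' Expects a comma-separated file with a header row, `.` decimal point and
#' the documented column names (`patient_id`, `ad_mm`, `aop_deg`, `hsd_mm`,
#' `mla_deg`, `asynclitism_type`, `delivery_outcome`, `apgar1`, `apgar5`,
#' plus optional demographics). Rows are validated and returned in file
#' order.
#'
#' @param path file path.
#' @return validated cohort data frame.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df)) df$patient_id <- as.character(df$patient_id)
  validate_cohort(df)
  df
}

#' Write a cohort to a delimited text file
#'
#' Comma-separated, UTF-8, `.` decimal; a round-trip through
#' [read_cohort()] reproduces the records exactly.
#'
#' @param cohort validated cohort data frame (may have zero rows, giving a
#'   header-only file).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (nrow(cohort)) validate_cohort(cohort)
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
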