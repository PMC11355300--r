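#' Confusion matrix over prediction records, cesarean delivery positive
#'
#' Counts true/false positives/negatives over prediction records, with the
#' intrapartum cesarean (ICD) label as the positive class. With
#' `expand_by_repetitions` (the default, matching the published totals)
#' each record is weighted by its `n_predictions` repetition count.
#'
#' @param records prediction-record data frame with columns
#'   `actual_outcome`, `pred_<algorithm>`, `n_predictions` and (for class
#'   filtering) `aida_class`.
#' @param algorithm which algorithm's predictions to score, e.g. `"rf"`.
#' @param aida_class optional class filter (0..4); NULL scores all rows.
#' @param expand_by_repetitions weight rows by `n_predictions`.
#' @return object of class `confusion_matrix`: named integer vector
#'   `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(records, algorithm, aida_class = NULL,
                             expand_by_repetitions = TRUE) {
  col <- paste0("pred_", algorithm)
  if (!col %in% names(records)) {
    stop("records carry no predictions for algorithm '", algorithm, "'")
  }
  if (!is.null(aida_class)) {
    records <- records[records$aida_class == aida_class, , drop = FALSE]
  }
  if (nrow(records) == 0) {
    warning("empty prediction selection; returning a zero matrix",
            call. = FALSE)
    return(structure(c(tp = 0L, fp = 0L, fn = 0L, tn = 0L),
                     class = "confusion_matrix"))
  }
  w <- if (expand_by_repetitions) records$n_predictions else
    rep(1L, nrow(records))
  actual <- as.character(binary_outcome(records$actual_outcome))
  pred <- as.character(binary_outcome(records[[col]]))
  cm <- c(
    tp = sum(w[actual == "ICD" & pred == "ICD"]),
    fp = sum(w[actual == "NOICD" & pred == "ICD"]),
    fn = sum(w[actual == "ICD" & pred == "NOICD"]),
    tn = sum(w[actual == "NOICD" & pred == "NOICD"]))
  structure(as.integer(cm), names = names(cm), class = "confusion_matrix")
}

#' Six classification metrics with the undefined-as-NA convention
#'
#' Accuracy, positive predictive value, negative predictive value, recall
#' (sensitivity), specificity and F1, each `NA` exactly when its defining
#' denominator is zero. F1 is `NA` when PPV or recall is `NA`, or when
#' `PPV + recall = 0` -- the convention of the published per-class table,
#' where e.g. all-negative classes have PPV printed as 0.00 but F1 as NA.
#'
#' @param cm a [confusion_counts()] result, or a named vector with
#'   elements `tp`, `fp`, `fn`, `tn` (total must be positive).
#' @return named numeric vector `accuracy`, `ppv`, `npv`, `recall`,
#'   `specificity`, `f1` (entries in \[0, 1\] or NA).
#' @examples
#' classification_metrics(c(tp = 44, fp = 4, fn = 0, tn = 2))
#' @export
classification_metrics <- function(cm) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  tp <- cm[["tp"]]; fp <- cm[["fp"]]; fn <- cm[["fn"]]; tn <- cm[["tn"]]
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  total <- tp + fp + fn + tn
  if (total == 0) stop("empty confusion matrix: metrics undefined")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- ratio(tp, tp + fp)
  recall <- ratio(tp, tp + fn)
  f1 <- if (is.na(ppv) || is.na(recall) || ppv + recall == 0) NA_real_ else
    2 * ppv * recall / (ppv + recall)
  c(accuracy = (tp + tn) / total,
    ppv = ppv,
    npv = ratio(tn, tn + fn),
    recall = recall,
    specificity = ratio(tn, tn + fp),
    f1 = f1)
}

METRIC_NAMES <- c("accuracy", "ppv", "npv", "recall", "specificity", "f1")

#' Recompute the published per-class performance table from the prediction fixtures
#'
#' For each of the nine (AIDA class, algorithm) pairs, builds the confusion
#' matrix from the packaged per-patient prediction tables (expanded by
#' repetition count, ICD positive), computes the six metrics, and compares
#' both counts and metrics against the packaged published performance
#' table at its printed precision (metrics rounded to 4 decimals; NA cells
#' must match the NA convention exactly).
#'
#' @param fixtures an [load_fixtures()] fixture set.
#' @return data frame with one row per (class, algorithm): computed counts
#'   and metrics, published values (`published_` prefix) and logical
#'   `counts_match` / `metrics_match` columns. Any mismatch is also
#'   reported in the `"mismatches"` attribute as a structured diff.
#' @export
reproduce_performance_table <- function(fixtures = load_fixtures()) {
  perf <- fixtures$performance
  rows <- list()
  mism <- list()
  for (i in seq_len(nrow(perf))) {
    cls <- perf$aida_class[i]
    alg <- perf$algorithm[i]
    fx <- fixtures$predictions[[paste0("class", cls)]]
    cm <- confusion_counts(fx, alg, expand_by_repetitions = TRUE)
    met <- classification_metrics(cm)
    pub_counts <- unlist(perf[i, c("tp", "fp", "fn", "tn")])
    pub_met <- unlist(perf[i, METRIC_NAMES])
    counts_match <- all(cm == pub_counts)
    same <- function(a, b) {
      (is.na(a) && is.na(b)) ||
        (!is.na(a) && !is.na(b) && abs(round(a, 4) - b) < 1e-9)
    }
    met_match <- all(mapply(same, met[METRIC_NAMES], pub_met))
    if (!counts_match || !met_match) {
      mism[[length(mism) + 1]] <- list(
        aida_class = cls, algorithm = alg,
        computed_counts = cm, published_counts = pub_counts,
        computed_metrics = met, published_metrics = pub_met)
    }
    row <- data.frame(aida_class = cls, algorithm = alg, t(as.integer(cm)))
    names(row)[3:6] <- c("tp", "fp", "fn", "tn")
    row <- cbind(row, t(met),
                 setNames(as.data.frame(t(pub_met)),
                          paste0("published_", METRIC_NAMES)),
                 counts_match = counts_match, metrics_match = met_match)
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mismatches") <- mism
  out
}

#' Per-patient agreement view of prediction records
#'
#' Reproduces the layout of the published per-patient tables: rows grouped
#' by AIDA class and asynclitism type, with one agreement flag per
#' algorithm (`TRUE` when the prediction matches the actual binary
#' outcome).
#'
#' @param records prediction-record data frame (fixture tables or
#'   [run_harness()] records).
#' @param algorithms algorithms to flag (default the `pred_*` columns
#'   present).
#' @return data frame with the record columns plus `agree_<algorithm>`
#'   logical flags, ordered by class then asynclitism type.
#' @export
agreement_view <- function(records, algorithms = NULL) {
  if (is.null(algorithms)) {
    algorithms <- sub("^pred_", "", grep("^pred_", names(records),
                                         value = TRUE))
  }
  out <- records
  actual <- as.character(binary_outcome(records$actual_outcome))
  for (alg in algorithms) {
    out[[paste0("agree_", alg)]] <-
      as.character(binary_outcome(records[[paste0("pred_", alg)]])) == actual
  }
  ord <- order(
    if ("aida_class" %in% names(out)) out$aida_class else rep(0, nrow(out)),
    out$asynclitism_type)
  out <- out[ord, ]
  rownames(out) <- NULL
  out
}
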