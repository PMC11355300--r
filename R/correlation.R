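#' Pearson correlation with a t-distribution p-value
#'
#' Sample Pearson coefficient with the standard two-sided p-value from the
#' exact t transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3; both non-constant.
#' @return list with `pc`, `p` and `n`.
#' @export
pearson_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (sd(x) == 0 || sd(y) == 0) {
    stop("undefined correlation: constant series")
  }
  ct <- cor.test(x, y, method = "pearson")
  list(pc = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation strength band of a Pearson coefficient
#'
#' Bands on the absolute coefficient: \[0, 0.20) very weak, \[0.20, 0.40)
#' weak, \[0.40, 0.60) moderate, \[0.60, 0.80) strong, \[0.80, 1\] very
#' strong. Boundaries are half-open so that 0.18 is "very weak" and -0.2
#' "weak", matching the published table's labelling.
#'
#' @param pc Pearson coefficient(s) in \[-1, 1\].
#' @return character vector of band labels.
#' @export
strength_label <- function(pc) {
  stopifnot(all(abs(pc) <= 1 + 1e-12))
  bands <- c("very weak", "weak", "moderate", "strong", "very strong")
  idx <- pmin(findInterval(abs(pc), c(0, 0.2, 0.4, 0.6, 0.8)), 5L)
  bands[idx]
}

#' Significance stars for a p-value
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, otherwise the
#' empty string; thresholds are strict, so p = 0.05 exactly earns no star.
#' A p-value of exactly 0 (double underflow at extreme sample sizes) earns
#' three stars.
#'
#' @param p p-value(s) in \[0, 1\].
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Pearson correlation report in the published table layout
#'
#' One row per requested variable pair with the coefficient, strength band,
#' p-value and significance stars. The default pairs are the six reported
#' by the study: the two Apgar scores with each other, and asynclitism
#' degree against angle of progression, head-symphysis distance, midline
#' angle and both Apgar scores.
#'
#' @param cohort cohort data frame containing the requested variables.
#' @param pairs list of length-2 character vectors of column names.
#' @return data frame with columns `var1`, `var2`, `pc`, `strength`, `p`,
#'   `stars`, `n`.
#' @export
correlation_report <- function(cohort, pairs = NULL) {
  if (is.null(pairs)) {
    pairs <- list(c("apgar1", "apgar5"),
                  c("aop_deg", "ad_mm"),
                  c("hsd_mm", "ad_mm"),
                  c("mla_deg", "ad_mm"),
                  c("apgar1", "ad_mm"),
                  c("apgar5", "ad_mm"))
  }
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2)
    if (!all(pr %in% names(cohort))) {
      stop("cohort lacks variable(s): ",
           paste(setdiff(pr, names(cohort)), collapse = ", "))
    }
    ct <- pearson_test(cohort[[pr[1]]], cohort[[pr[2]]])
    data.frame(var1 = pr[1], var2 = pr[2], pc = ct$pc,
               strength = strength_label(ct$pc), p = ct$p,
               stars = significance_stars(ct$p), n = ct$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
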