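# Shared fixtures built in code. The large reference cohort is generated
# once per test run and memoised; 10,000 patients keeps Monte-Carlo error
# on means near sd/100 and on correlations near 0.01.

.cache <- new.env(parent = emptyenv())

big_cohort <- function() {
  if (is.null(.cache$big)) {
    .cache$big <- generate_cohort(default_cohort_model(), n = 10000, seed = 20260928)
  }
  .cache$big
}

fixtures <- function() {
  if (is.null(.cache$fx)) .cache$fx <- load_fixtures()
  .cache$fx
}

# Minimal hand-written two-patient cohort for I/O and validation tests.
tiny_cohort <- function() {
  data.frame(
    patient_id = c("P1", "P2"),
    ad_mm = c(40, 75),
    aop_deg = c(120, 150),
    hsd_mm = c(12, 25),
    mla_deg = c(30, 60),
    asynclitism_type = c("anterior", "posterior"),
    delivery_outcome = c("spontaneous", "ICD"),
    apgar1 = c(8L, 6L),
    apgar5 = c(9L, 8L),
    stringsAsFactors = FALSE)
}

# Cohort with a hard deterministic outcome rule on asynclitism degree,
# used for cut-off recovery and separability checks.
hard_rule_cohort <- function(n = 135, seed = 7, threshold = 70) {
  co <- generate_cohort(default_cohort_model(), n = n, seed = seed)
  co$delivery_outcome <- ifelse(co$ad_mm >= threshold, "ICD", "spontaneous")
  co
}

# Independent brute-force oracle for single splits: enumerate every
# midpoint candidate and recompute the weighted Gini decrease directly.
oracle_best_split <- function(values, labels) {
  gini <- function(l) {
    p <- mean(l == "ICD")
    1 - p^2 - (1 - p)^2
  }
  sv <- sort(unique(values))
  if (length(sv) < 2) return(list(threshold = NA_real_, gain = 0))
  cands <- (sv[-length(sv)] + sv[-1]) / 2
  gains <- vapply(cands, function(thr) {
    l <- labels[values < thr]
    r <- labels[values >= thr]
    gini(labels) - (length(l) * gini(l) + length(r) * gini(r)) / length(values)
  }, numeric(1))
  best <- which(gains > max(gains) - 1e-12)[1]  # ties toward smallest
  list(threshold = cands[best], gain = max(gains, 0))
}

# Independent metric oracle: expand a confusion matrix into individual
# predictions and recompute each metric by counting.
oracle_metrics <- function(tp, fp, fn, tn) {
  actual <- c(rep("ICD", tp), rep("NOICD", fp), rep("ICD", fn), rep("NOICD", tn))
  pred <- c(rep("ICD", tp), rep("ICD", fp), rep("NOICD", fn), rep("NOICD", tn))
  rat <- function(num, den) if (den == 0) NA_real_ else num / den
  ppv <- rat(sum(actual == "ICD" & pred == "ICD"), sum(pred == "ICD"))
  rec <- rat(sum(actual == "ICD" & pred == "ICD"), sum(actual == "ICD"))
  c(accuracy = mean(actual == pred),
    ppv = ppv,
    npv = rat(sum(actual == "NOICD" & pred == "NOICD"), sum(pred == "NOICD")),
    recall = rec,
    specificity = rat(sum(actual == "NOICD" & pred == "NOICD"),
                      sum(actual == "NOICD")),
    f1 = if (is.na(ppv) || is.na(rec) || ppv + rec == 0) NA_real_ else
      2 * ppv * rec / (ppv + rec))
}
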