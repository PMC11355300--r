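#' Default synthetic-cohort model matched to the published study cohort
#'
#' Builds a `cohort_model` whose truncated-normal marginals reproduce the
#' published per-variable minimum, maximum, mean and SD, whose Gaussian
#' copula carries the published pairwise Pearson correlations (AD-AoP 0.36,
#' AD-HSD 0.18, AD-MLA 0.14, Apgar1-Apgar5 0.8, AD-Apgar1 -0.2, AD-Apgar5
#' -0.19; unreported pairs default to 0), whose anterior-asynclitism
#' fraction is 50/135, and whose logistic outcome model in the count of
#' non-green zones gives an intrapartum-cesarean probability of about 0.02
#' in AIDA class 0 and 0.98 in class 4. Positive (cesarean) outcomes are
#' split ICD : ICD-after-failure at the study's 56:22 ratio and negative
#' outcomes OVD : spontaneous at 31:26.
#'
#' Each marginal's latent mean/SD is moment-matched so that the
#' *truncated* distribution has the published mean and SD (truncation
#' otherwise shifts the mean, by more than 1 mm for asynclitism degree).
#'
#' @param icd_class0,icd_class4 target cesarean probabilities at AIDA
#'   classes 0 and 4; the logistic intercept and per-class slope are solved
#'   from these two anchors.
#' @return object of class `cohort_model`.
#' @examples
#' m <- default_cohort_model()
#' m$marginals$ad_mm[c("mean", "sd", "lower", "upper")]
#' m$correlations[["ad_mm:aop_deg"]]
#' @export
default_cohort_model <- function(icd_class0 = 0.02, icd_class4 = 0.98) {
  stopifnot(icd_class0 > 0, icd_class4 < 1, icd_class0 < icd_class4)
  marg <- list(
    ad_mm   = list(mean = 60.18, sd = 18.866, lower = 4, upper = 95),
    aop_deg = list(mean = 122.75, sd = 27.454, lower = 72, upper = 192),
    hsd_mm  = list(mean = 21.47, sd = 9.265, lower = 10, upper = 51),
    mla_deg = list(mean = 62.59, sd = 14.986, lower = 26, upper = 90),
    age_years = list(mean = 31.62, sd = 5.28, lower = 18, upper = 48),
    gestational_age_weeks = list(mean = 40.16, sd = 1.02, lower = 37, upper = 42.5),
    bmi = list(mean = 27.52, sd = 2.95, lower = 18, upper = 40),
    neonatal_weight_g = list(mean = 3926.68, sd = 309.66, lower = 2500, upper = 5000)
  )
  marg <- lapply(marg, function(m) {
    cal <- calibrate_tnorm(m$mean, m$sd, m$lower, m$upper)
    m$latent_mean <- cal$mean
    m$latent_sd <- cal$sd
    m
  })
  intercept <- qlogis(icd_class0)
  slope <- (qlogis(icd_class4) - qlogis(icd_class0)) / 4
  model <- list(
    marginals = marg,
    correlations = c(
      "ad_mm:aop_deg" = 0.36,
      "ad_mm:hsd_mm" = 0.18,
      "ad_mm:mla_deg" = 0.14,
      "apgar1:apgar5" = 0.8,
      "ad_mm:apgar1" = -0.2,
      "ad_mm:apgar5" = -0.19),
    apgar = list(mean1 = 6.65, sd1 = 1.22, mean5 = 8.74, sd5 = 1.12),
    anterior_fraction = 50 / 135,
    outcome = list(
      intercept = intercept,
      slope = slope,
      icd_split = c(ICD = 56, ICD_after_failure = 22),
      noicd_split = c(OVD = 31, spontaneous = 26))
  )
  class(model) <- "cohort_model"
  model
}

# Correlation between two named variables under the model (0 if unreported).
model_correlation <- function(model, a, b) {
  r <- model$correlations
  key1 <- paste(a, b, sep = ":")
  key2 <- paste(b, a, sep = ":")
  if (key1 %in% names(r)) unname(r[[key1]])
  else if (key2 %in% names(r)) unname(r[[key2]])
  else 0
}

geometry_corr_matrix <- function(model) {
  p <- GEOMETRY_PARAMS
  R <- diag(length(p))
  dimnames(R) <- list(p, p)
  for (i in seq_along(p)) for (j in seq_along(p)) {
    if (i != j) R[i, j] <- model_correlation(model, p[i], p[j])
  }
  repair_correlation(R)
}

#' Sample the four geometric parameters from the cohort model
#'
#' Draws from a Gaussian copula with the model's pairwise correlation
#' matrix (repaired by eigenvalue clipping if not positive semi-definite,
#' with a warning); each margin is mapped through the inverse CDF of its
#' calibrated truncated normal, so every value falls inside the published
#' range and the copula's rank structure is preserved exactly.
#'
#' @param model a [default_cohort_model()]-style `cohort_model`.
#' @param n number of patients (>= 1).
#' @param seed integer seed; the same seed reproduces the draw exactly.
#' @return data frame with columns `ad_mm`, `aop_deg`, `hsd_mm`, `mla_deg`.
#' @export
sample_geometry <- function(model, n, seed = 1) {
  stopifnot(n >= 1)
  R <- geometry_corr_matrix(model)
  L <- chol(R)
  set.seed(seed)
  Z <- matrix(rnorm(n * ncol(R)), n) %*% L
  out <- as.data.frame(lapply(seq_along(GEOMETRY_PARAMS), function(j) {
    m <- model$marginals[[GEOMETRY_PARAMS[j]]]
    qtnorm(pnorm(Z[, j]), m$latent_mean, m$latent_sd, m$lower, m$upper)
  }))
  names(out) <- GEOMETRY_PARAMS
  out
}

#' Latent copula score of observed values under a model marginal
#'
#' Maps observed measurements back to the standard-normal (latent) scale of
#' the Gaussian copula; correlations configured in the model are recovered
#' on this scale.
#'
#' @param x numeric vector of observed values.
#' @param model `cohort_model`.
#' @param variable marginal name, e.g. `"ad_mm"`.
#' @return numeric vector of standard-normal scores.
#' @export
latent_scores <- function(x, model, variable) {
  m <- model$marginals[[variable]]
  if (is.null(m)) stop("no marginal named ", variable, " in the model")
  p <- ptnorm(x, m$latent_mean, m$latent_sd, m$lower, m$upper)
  qnorm(pmin(pmax(p, 1e-12), 1 - 1e-12))
}

#' Sample Apgar scores correlated with asynclitism degree
#'
#' Draws (Apgar 1 min, Apgar 5 min) pairs from a bivariate normal with the
#' model's means/SDs and correlation (default 0.8 between the two scores),
#' conditioned on each patient's asynclitism degree through the configured
#' AD-Apgar correlations (-0.2 and -0.19 by default). Scores are rounded to
#' integers and clipped to 0..10 unless `round = FALSE`, which returns the
#' continuous pre-rounding scores.
#'
#' @param model `cohort_model`.
#' @param ad numeric vector of asynclitism degrees (mm).
#' @param seed integer seed.
#' @param round round and clip to the 0..10 integer scale (default TRUE).
#' @return data frame with columns `apgar1`, `apgar5`.
#' @export
sample_apgar <- function(model, ad, seed = 1, round = TRUE) {
  n <- length(ad)
  z_ad <- latent_scores(ad, model, "ad_mm")
  r1 <- model_correlation(model, "ad_mm", "apgar1")
  r5 <- model_correlation(model, "ad_mm", "apgar5")
  r15 <- model_correlation(model, "apgar1", "apgar5")
  # conditional distribution of (z1, z5) given z_ad under the 3x3 latent
  # correlation matrix [[1, r1, r5], [r1, 1, r15], [r5, r15, 1]]
  cond_cov <- matrix(c(1 - r1^2, r15 - r1 * r5,
                       r15 - r1 * r5, 1 - r5^2), 2)
  cond_cov <- (cond_cov + t(cond_cov)) / 2
  e <- eigen(cond_cov, symmetric = TRUE)
  if (min(e$values) < 0) {
    warning("AD-Apgar correlation triple is not positive semi-definite; ",
            "repaired by eigenvalue clipping", call. = FALSE)
    e$values <- pmax(e$values, 1e-8)
  }
  A <- e$vectors %*% diag(sqrt(e$values)) %*% t(e$vectors)
  set.seed(seed)
  E <- matrix(rnorm(2 * n), n) %*% A
  z1 <- r1 * z_ad + E[, 1]
  z5 <- r5 * z_ad + E[, 2]
  ap <- model$apgar
  s1 <- ap$mean1 + ap$sd1 * z1
  s5 <- ap$mean5 + ap$sd5 * z5
  if (round) {
    s1 <- pmin(pmax(round(s1), 0), 10)
    s5 <- pmin(pmax(round(s5), 0), 10)
  }
  data.frame(apgar1 = s1, apgar5 = s5)
}

#' Assign delivery outcomes from zone profiles
#'
#' Draws the binary cesarean (ICD) vs non-cesarean outcome from a logistic
#' model in the AIDA class (the count of non-green zones), then splits
#' positives into ICD vs ICD-after-failure at the model's 56:22 ratio and
#' negatives into operative-vaginal vs spontaneous at 31:26.
#'
#' @param model `cohort_model`.
#' @param geometry data frame with the four geometric parameter columns.
#' @param scheme zone scheme used to count non-green parameters.
#' @param seed integer seed.
#' @return factor of outcomes with levels `ICD`, `ICD_after_failure`,
#'   `OVD`, `spontaneous`.
#' @export
assign_outcomes <- function(model, geometry, scheme = default_zone_scheme(),
                            seed = 1) {
  prof <- zone_profile(geometry, scheme, warn_outside_evidence = FALSE)
  om <- model$outcome
  p_icd <- plogis(om$intercept + om$slope * prof$aida_class)
  set.seed(seed)
  n <- nrow(geometry)
  is_icd <- runif(n) < p_icd
  p_fail <- om$icd_split[["ICD_after_failure"]] / sum(om$icd_split)
  p_ovd <- om$noicd_split[["OVD"]] / sum(om$noicd_split)
  sub <- runif(n)
  out <- ifelse(is_icd,
                ifelse(sub < p_fail, "ICD_after_failure", "ICD"),
                ifelse(sub < p_ovd, "OVD", "spontaneous"))
  factor(out, levels = OUTCOME_LEVELS)
}

#' Generate a complete synthetic labor cohort
#'
#' Composes the geometry, Apgar, outcome and demographic samplers plus
#' anterior/posterior assignment into validated patient records. One root
#' seed is split into named substreams (geometry, apgar, outcome,
#' asynclitism type, demographics), so adding a sampler never perturbs
#' earlier streams; the same seed reproduces the cohort exactly.
#'
#' @param model `cohort_model` (default [default_cohort_model()]).
#' @param n cohort size (default 135, the study size).
#' @param seed integer root seed.
#' @param scheme zone scheme passed to [assign_outcomes()].
#' @return validated cohort data frame with patient ids `S0001`, ...
#' @examples
#' cohort <- generate_cohort(n = 20, seed = 1)
#' table(binary_outcome(cohort$delivery_outcome))
#' @export
generate_cohort <- function(model = default_cohort_model(), n = 135, seed = 1,
                            scheme = default_zone_scheme()) {
  stopifnot(n >= 1)
  ss <- substream_seeds(seed, 5)
  geometry <- sample_geometry(model, n, seed = ss[1])
  apgar <- sample_apgar(model, geometry$ad_mm, seed = ss[2])
  outcome <- assign_outcomes(model, geometry, scheme, seed = ss[3])
  set.seed(ss[4])
  type <- ifelse(runif(n) < model$anterior_fraction, "anterior", "posterior")
  set.seed(ss[5])
  demo <- as.data.frame(lapply(
    c("age_years", "gestational_age_weeks", "bmi", "neonatal_weight_g"),
    function(v) {
      m <- model$marginals[[v]]
      qtnorm(runif(n), m$latent_mean, m$latent_sd, m$lower, m$upper)
    }))
  names(demo) <- c("age_years", "gestational_age_weeks", "bmi",
                   "neonatal_weight_g")
  cohort <- cbind(
    data.frame(patient_id = sprintf("S%04d", seq_len(n))),
    geometry,
    data.frame(asynclitism_type = type,
               delivery_outcome = as.character(outcome)),
    apgar, demo)
  validate_cohort(cohort)
  cohort
}
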