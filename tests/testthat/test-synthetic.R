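test_that("default model carries the published cohort statistics", {
  m <- default_cohort_model()
  ad <- m$marginals$ad_mm
  expect_equal(c(ad$mean, ad$sd, ad$lower, ad$upper),
               c(60.18, 18.866, 4, 95))
  expect_equal(unname(m$correlations[["ad_mm:aop_deg"]]), 0.36)
  expect_equal(m$anterior_fraction, 50 / 135)
  # truncated latent marginals really have the published moments
  for (v in names(m$marginals)) {
    mm <- m$marginals[[v]]
    mo <- aidalabor:::tnorm_moments(mm$latent_mean, mm$latent_sd,
                                    mm$lower, mm$upper)
    expect_equal(unname(mo["mean"]), mm$mean, tolerance = 1e-4, label = v)
    expect_equal(unname(mo["sd"]), mm$sd, tolerance = 1e-4, label = v)
  }
})

test_that("samplers are deterministic under a fixed seed", {
  m <- default_cohort_model()
  expect_identical(sample_geometry(m, 50, seed = 3),
                   sample_geometry(m, 50, seed = 3))
  expect_identical(generate_cohort(m, 40, seed = 9),
                   generate_cohort(m, 40, seed = 9))
  expect_false(identical(generate_cohort(m, 40, seed = 9),
                         generate_cohort(m, 40, seed = 10)))
})

test_that("geometry marginals stay in bounds and recover their moments", {
  m <- default_cohort_model()
  co <- big_cohort()
  n <- nrow(co)
  for (v in c("ad_mm", "aop_deg", "hsd_mm", "mla_deg")) {
    mm <- m$marginals[[v]]
    expect_true(all(co[[v]] >= mm$lower & co[[v]] <= mm$upper), info = v)
    se <- mm$sd / sqrt(n)
    expect_lt(abs(mean(co[[v]]) - mm$mean), 3 * se, label = v)
  }
})

test_that("the copula recovers configured correlations on the latent scale", {
  m <- default_cohort_model()
  co <- big_cohort()
  z <- sapply(c("ad_mm", "aop_deg", "hsd_mm", "mla_deg"),
              function(v) latent_scores(co[[v]], m, v))
  expect_lt(abs(cor(z[, "ad_mm"], z[, "aop_deg"]) - 0.36), 0.05)
  expect_lt(abs(cor(z[, "ad_mm"], z[, "hsd_mm"]) - 0.18), 0.05)
  expect_lt(abs(cor(z[, "ad_mm"], z[, "mla_deg"]) - 0.14), 0.05)
  # unreported pairs default to independence
  expect_lt(abs(cor(z[, "aop_deg"], z[, "hsd_mm"])), 0.05)
})

test_that("a zero-correlation model gives independent marginals", {
  m <- default_cohort_model()
  m$correlations[] <- 0
  g <- sample_geometry(m, 4000, seed = 2)
  cors <- cor(g)
  off <- cors[upper.tri(cors)]
  expect_true(all(abs(off) < 3 / sqrt(4000)))
})

test_that("Apgar pairs carry the configured correlation and stay on scale", {
  m <- default_cohort_model()
  co <- big_cohort()
  cont <- sample_apgar(m, co$ad_mm, seed = 5, round = FALSE)
  expect_lt(abs(cor(cont$apgar1, cont$apgar5) - 0.8), 0.05)
  expect_lt(abs(cor(cont$apgar1, latent_scores(co$ad_mm, m, "ad_mm")) + 0.2),
            0.05)
  rounded <- sample_apgar(m, co$ad_mm, seed = 5)
  expect_true(all(rounded$apgar1 %in% 0:10))
  expect_true(all(rounded$apgar5 %in% 0:10))
  expect_true(all(rounded$apgar1 == round(rounded$apgar1)))

  # with AD correlations zeroed the scores are independent of AD
  m0 <- default_cohort_model()
  m0$correlations[["ad_mm:apgar1"]] <- 0
  m0$correlations[["ad_mm:apgar5"]] <- 0
  c0 <- sample_apgar(m0, co$ad_mm[1:5000], seed = 5, round = FALSE)
  expect_lt(abs(cor(c0$apgar1, co$ad_mm[1:5000])), 0.05)
})

test_that("outcome risk rises with AIDA class and splits at the study ratios", {
  m <- default_cohort_model()
  co <- big_cohort()
  prof <- zone_profile(co, warn_outside_evidence = FALSE)
  icd <- binary_outcome(co$delivery_outcome) == "ICD"
  p_by_class <- tapply(icd, prof$aida_class, mean)
  expect_true(all(diff(p_by_class) >= 0))
  expect_lt(p_by_class[["0"]], 0.05)
  expect_gt(p_by_class[["4"]], 0.95)

  # positives split ICD : ICD-after-failure near 56:22
  pos <- co$delivery_outcome[icd]
  frac_fail <- mean(pos == "ICD_after_failure")
  expect_lt(abs(frac_fail - 22 / 78), 0.03)
  neg <- co$delivery_outcome[!icd]
  expect_lt(abs(mean(neg == "OVD") - 31 / 57), 0.03)

  # zero slope removes the class gradient
  m0 <- default_cohort_model()
  m0$outcome$slope <- 0
  m0$outcome$intercept <- qlogis(0.5)
  out0 <- assign_outcomes(m0, co[1:5000, ], seed = 4)
  icd0 <- binary_outcome(out0) == "ICD"
  p0 <- tapply(icd0, prof$aida_class[1:5000], mean)
  expect_true(max(abs(p0 - 0.5)) < 0.1)
})

test_that("generate_cohort composes valid study-sized cohorts", {
  co <- generate_cohort(n = 135, seed = 1)
  expect_equal(nrow(co), 135)
  expect_silent(validate_cohort(co))
  expect_equal(co$patient_id[1:3], c("S0001", "S0002", "S0003"))
  big <- big_cohort()
  expect_lt(abs(mean(big$ad_mm) - 60.18), 0.6)
  expect_lt(abs(mean(big$asynclitism_type == "anterior") - 50 / 135), 0.02)
})

test_that("a non-PSD correlation target is repaired with a warning", {
  m <- default_cohort_model()
  m$correlations[["ad_mm:aop_deg"]] <- 0.9
  m$correlations[["ad_mm:hsd_mm"]] <- 0.9
  m$correlations[["aop_deg:hsd_mm"]] <- -0.9
  expect_warning(g <- sample_geometry(m, 100, seed = 1),
                 "positive semi-definite")
  expect_equal(nrow(g), 100)
})
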