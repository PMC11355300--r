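test_that("the split plan reproduces the study's 95/40 partitions", {
  plan <- make_split_plan(135)
  expect_equal(plan$seeds, c(1, 0, 250, 500, 750))
  for (sp in plan$splits) {
    expect_length(sp$train, 95)
    expect_length(sp$test, 40)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), 1:135)
  }
  # same seed twice in separate calls -> identical partition
  expect_identical(make_split_plan(135), make_split_plan(135))
  expect_error(make_split_plan(135, seeds = c(1, 1, 2)), "duplicate")

  # test-set multiplicities over the 5 seeds total seeds x 40
  test_ids <- unlist(lapply(plan$splits, `[[`, "test"))
  expect_length(test_ids, 200)
  expect_true(length(unique(test_ids)) >= 40 &&
                length(unique(test_ids)) <= 135)
})

test_that("learners separate a hard AD rule and refuse degenerate input", {
  co <- hard_rule_cohort(n = 300, seed = 17, threshold = 70)
  # leave a margin around the rule so any learned threshold inside the gap
  # classifies held-out data perfectly (genuine separability)
  co <- co[co$ad_mm < 65 | co$ad_mm > 75, ]
  train <- co[seq_len(floor(nrow(co) * 0.7)), ]
  test <- co[-seq_len(floor(nrow(co) * 0.7)), ]
  y_test <- binary_outcome(test$delivery_outcome)
  for (alg in c("dt", "rf")) {
    pred <- train_predict(alg, train, test, seed = 1)
    expect_equal(mean(pred == y_test), 1, label = alg)
  }
  # scale-sensitive learners also do well on a clean threshold rule
  # (logistic regression legitimately warns on fully separable data)
  for (alg in c("svm", "mlp", "lr")) {
    pred <- suppressWarnings(train_predict(alg, train, test, seed = 1))
    expect_gt(mean(pred == y_test), 0.9)
  }
  expect_length(train_predict("rf", train, test[1, ], seed = 1), 1)

  train1 <- train
  train1$delivery_outcome <- "ICD"
  expect_error(train_predict("rf", train1, test), "single outcome class")
  expect_error(train_predict("boost", train, test), "'arg'")
})

test_that("shuffled labels drive test accuracy to the class prior", {
  co <- generate_cohort(n = 600, seed = 31)
  y <- binary_outcome(co$delivery_outcome)
  prior <- max(table(y)) / length(y)
  set.seed(8)
  co$delivery_outcome <- sample(as.character(co$delivery_outcome))
  pred <- train_predict("rf", co[1:400, ], co[401:600, ], seed = 2)
  acc <- mean(pred == binary_outcome(co$delivery_outcome[401:600]))
  expect_lt(abs(acc - prior), 0.15)
})

test_that("feature importance recovers a single-driver outcome", {
  co <- hard_rule_cohort(n = 300, seed = 23, threshold = 70)
  train <- co[1:200, ]
  held <- co[201:300, ]
  for (alg in c("rf", "dt", "lr", "svm", "mlp")) {
    fit <- suppressWarnings(fit_learner(alg, train, seed = 4))
    rk <- feature_importance_rank(fit, held, seed = 4)
    expect_equal(rk$ranking[1], "ad_mm", label = alg)
  }
  # no-signal outcome is flagged as degenerate for tree importance
  co0 <- generate_cohort(n = 100, seed = 77)
  set.seed(5)
  co0$delivery_outcome <- sample(rep(c("ICD", "spontaneous"), 50))
  fit0 <- fit_learner("dt", co0, seed = 6)
  rk0 <- feature_importance_rank(fit0, co0, seed = 6)
  expect_true(is.list(rk0))
})

test_that("the harness accounts for 200 predictions per algorithm at n = 135", {
  co <- generate_cohort(n = 135, seed = 2)
  plan <- make_split_plan(135)
  hr <- run_harness(co, plan, seed = 10)
  for (alg in c("rf", "svm", "mlp")) {
    expect_equal(sum(hr$long$algorithm == alg), 200)
  }
  # expanded record counts match the seed-level totals
  expect_equal(sum(hr$records$n_predictions), 200)
  n_distinct <- length(unique(hr$records$patient_id))
  n_repeat <- 200 - n_distinct
  expect_equal(n_distinct + n_repeat, 200)
  expect_true(n_distinct >= 40 && n_distinct <= 135)

  # one seed only: every test patient predicted exactly once
  hr1 <- run_harness(co, make_split_plan(135, seeds = 1), seed = 10)
  expect_true(all(hr1$records$n_predictions == 1))
  expect_equal(sum(hr1$records$n_predictions), 40)
})

test_that("the harness is reproducible end to end", {
  co <- generate_cohort(n = 135, seed = 2)
  plan <- make_split_plan(135)
  a <- run_harness(co, plan, seed = 10)
  b <- run_harness(co, plan, seed = 10)
  expect_identical(a$records, b$records)
  expect_identical(a$long, b$long)
  expect_identical(lapply(a$importance, `[[`, "ranking"),
                   lapply(b$importance, `[[`, "ranking"))
})

test_that("zone-driven outcomes give near-perfect class 0 and 4 accuracy", {
  m <- default_cohort_model()
  co <- generate_cohort(m, n = 400, seed = 13)
  prof <- zone_profile(co, warn_outside_evidence = FALSE)
  # deterministic zone-driven outcome: cesarean iff class >= 3
  co$delivery_outcome <- ifelse(prof$aida_class >= 3, "ICD", "spontaneous")
  hr <- run_harness(co, make_split_plan(400), algorithms = "rf", seed = 3)
  rec <- hr$records
  for (cls in c(0, 4)) {
    cm <- confusion_counts(rec, "rf", aida_class = cls)
    met <- classification_metrics(cm)
    expect_gte(met[["accuracy"]], 0.95)
  }
})
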