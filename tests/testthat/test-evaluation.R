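test_that("confusion matrices from the fixtures match the published counts", {
  fx <- fixtures()
  expect_equal(unclass(confusion_counts(fx$predictions$class3, "rf")),
               c(tp = 44L, fp = 4L, fn = 0L, tn = 2L),
               ignore_attr = "class")
  expect_equal(unclass(confusion_counts(fx$predictions$class0, "svm")),
               c(tp = 0L, fp = 1L, fn = 0L, tn = 67L),
               ignore_attr = "class")
  expect_equal(unclass(confusion_counts(fx$predictions$class4, "mlp")),
               c(tp = 30L, fp = 0L, fn = 1L, tn = 0L),
               ignore_attr = "class")
  # without repetition expansion each patient row counts once
  cm_unexp <- confusion_counts(fx$predictions$class3, "svm",
                               expand_by_repetitions = FALSE)
  expect_equal(sum(cm_unexp), 31)  # 31 table rows (30 patients, one split row)
  expect_warning(confusion_counts(fx$predictions$class3, "rf",
                                  aida_class = 2), "empty")
})

test_that("metrics reproduce the published headline values and NA cells", {
  m <- classification_metrics(c(tp = 44, fp = 4, fn = 0, tn = 2))
  expect_equal(round(m[["accuracy"]], 4), 0.92)
  expect_equal(round(m[["ppv"]], 4), 0.9167)
  expect_equal(m[["npv"]], 1)
  expect_equal(m[["recall"]], 1)
  expect_equal(round(m[["specificity"]], 4), 0.3333)
  expect_equal(round(m[["f1"]], 4), 0.9565)

  m0 <- classification_metrics(c(tp = 0, fp = 0, fn = 0, tn = 68))
  expect_equal(m0[["accuracy"]], 1)
  expect_equal(m0[["npv"]], 1)
  expect_equal(m0[["specificity"]], 1)
  expect_true(is.na(m0[["ppv"]]))
  expect_true(is.na(m0[["recall"]]))
  expect_true(is.na(m0[["f1"]]))

  # ppv defined but zero, recall undefined -> f1 undefined
  ms <- classification_metrics(c(tp = 0, fp = 1, fn = 0, tn = 67))
  expect_equal(ms[["ppv"]], 0)
  expect_true(is.na(ms[["recall"]]))
  expect_true(is.na(ms[["f1"]]))

  m4 <- classification_metrics(c(tp = 30, fp = 0, fn = 1, tn = 0))
  expect_equal(round(m4[["accuracy"]], 4), 0.9677)
  expect_equal(round(m4[["f1"]], 4), 0.9836)

  expect_error(classification_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)),
               "empty")
})

test_that("metrics agree with the enumeration oracle on small matrices", {
  set.seed(11)
  for (rep in 1:80) {
    cm <- as.integer(stats::rmultinom(1, sample(1:30, 1), rep(0.25, 4)))
    names(cm) <- c("tp", "fp", "fn", "tn")
    if (sum(cm) == 0) next
    got <- classification_metrics(cm)
    want <- oracle_metrics(cm[["tp"]], cm[["fp"]], cm[["fn"]], cm[["tn"]])
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("accuracy is invariant to swapping the positive class", {
  set.seed(12)
  for (rep in 1:20) {
    cm <- as.integer(stats::rmultinom(1, 40, rep(0.25, 4))) + 1L
    names(cm) <- c("tp", "fp", "fn", "tn")
    sw <- cm[c("tn", "fn", "fp", "tp")]
    names(sw) <- c("tp", "fp", "fn", "tn")
    expect_equal(classification_metrics(cm)[["accuracy"]],
                 classification_metrics(sw)[["accuracy"]])
  }
})

test_that("the full published performance table is reproduced 9 for 9", {
  tab <- reproduce_performance_table(fixtures())
  expect_equal(nrow(tab), 9)
  expect_true(all(tab$counts_match))
  expect_true(all(tab$metrics_match))
  expect_length(attr(tab, "mismatches"), 0)
  # NA convention: 14 NA cells among the printed metrics (3 per
  # all-negative class 0 RF/MLP row, 2 for class 0 SVM, 1 for class 3 SVM,
  # 2 per all-positive class 4 RF/SVM row, 1 for class 4 MLP)
  pub <- tab[, paste0("published_", c("accuracy", "ppv", "npv", "recall",
                                      "specificity", "f1"))]
  expect_equal(sum(is.na(pub)), 14)
  # and each computed NA coincides with a published NA
  comp <- tab[, c("accuracy", "ppv", "npv", "recall", "specificity", "f1")]
  expect_equal(is.na(comp), is.na(pub), ignore_attr = TRUE)
})

test_that("agreement views flag the published disagreements", {
  fx <- fixtures()
  v0 <- agreement_view(fx$predictions$class0)
  expect_equal(sum(!v0$agree_svm), 1)
  expect_equal(v0$patient_id[!v0$agree_svm], "40")
  expect_equal(sum(!v0$agree_rf) + sum(!v0$agree_mlp), 0)

  v4 <- agreement_view(fx$predictions$class4)
  expect_equal(sum(!v4$agree_mlp), 1)
  expect_equal(v4$patient_id[!v4$agree_mlp], "78")
  expect_equal(sum(!v4$agree_svm) + sum(!v4$agree_rf), 0)

  # all-correct input carries no disagreement flags
  rec <- fx$predictions$class4
  rec$pred_mlp <- rec$actual_outcome
  v <- agreement_view(rec)
  expect_true(all(v$agree_svm & v$agree_rf & v$agree_mlp))
})
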