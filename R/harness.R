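HARNESS_ALGORITHMS <- c("rf", "svm", "mlp", "dt", "lr")

#' Seeded 70-30 train/test split plan
#'
#' Builds one reproducible simple random partition per seed. The default
#' seed list (1, 0, 250, 500, 750) and train fraction 0.70 mirror the
#' study's five samples; at n = 135 each split has 95 training and 40 test
#' patients. Splits are unstratified.
#'
#' @param n cohort size (>= 2).
#' @param seeds integer seeds, one partition each; duplicates are an error.
#' @param train_fraction fraction assigned to training, in (0, 1); train
#'   size is `floor(train_fraction * n + 0.5)`.
#' @return object of class `split_plan`: list with `n`, `seeds`,
#'   `train_fraction` and `splits` (per seed, sorted `train` and `test`
#'   index vectors).
#' @export
make_split_plan <- function(n, seeds = c(1, 0, 250, 500, 750),
                            train_fraction = 0.7) {
  stopifnot(n >= 2, train_fraction > 0, train_fraction < 1)
  if (anyDuplicated(seeds)) stop("duplicate seeds in split plan")
  n_train <- floor(train_fraction * n + 0.5)
  if (n_train < 1 || n_train >= n) stop("degenerate train/test sizes")
  splits <- lapply(seeds, function(s) {
    set.seed(s)
    train <- sort(sample.int(n, n_train))
    list(train = train, test = setdiff(seq_len(n), train))
  })
  names(splits) <- paste0("seed_", seeds)
  structure(list(n = n, seeds = seeds, train_fraction = train_fraction,
                 splits = splits),
            class = "split_plan")
}

default_hyper <- function(algorithm) {
  switch(algorithm,
    rf = list(ntree = 100),
    svm = list(cost = 1, gamma = 0.25),
    mlp = list(size = 8, decay = 1e-4, maxit = 500),
    dt = list(),
    lr = list(),
    stop("unknown algorithm: ", algorithm))
}

feature_matrix <- function(records) {
  stopifnot(all(GEOMETRY_PARAMS %in% names(records)))
  as.matrix(records[, GEOMETRY_PARAMS])
}

#' Fit one learner on a training cohort
#'
#' Supported learners: random forest (`rf`, 100 trees), RBF-kernel support
#' vector machine (`svm`, cost 1), single-hidden-layer multi-layer
#' perceptron (`mlp`, 8 units, fixed iteration cap, no early stopping),
#' classification tree (`dt`) and logistic regression (`lr`). Features are
#' the four geometric parameters only; they enter tree learners raw and are
#' z-scored (train-fitted) for the scale-sensitive SVM and MLP. Fits are
#' deterministic given `seed`.
#'
#' @param algorithm one of `"rf"`, `"svm"`, `"mlp"`, `"dt"`, `"lr"`.
#' @param train training cohort (must contain both outcome classes).
#' @param hyper named list overriding the defaults above.
#' @param seed integer seed for learner-internal randomness.
#' @return object of class `aida_fit`.
#' @export
fit_learner <- function(algorithm, train, hyper = list(), seed = 1) {
  algorithm <- match.arg(algorithm, HARNESS_ALGORITHMS)
  hp <- utils::modifyList(default_hyper(algorithm), hyper)
  x <- feature_matrix(train)
  y <- binary_outcome(train$delivery_outcome)
  if (length(unique(y)) < 2) {
    stop("training set contains a single outcome class")
  }
  center <- colMeans(x)
  scale_ <- apply(x, 2, sd)
  scale_[scale_ == 0] <- 1
  xs <- scale(x, center, scale_)
  set.seed(seed)
  model <- switch(algorithm,
    rf = randomForest::randomForest(x, y, ntree = hp$ntree),
    svm = e1071::svm(xs, y, kernel = "radial", cost = hp$cost,
                     gamma = hp$gamma, scale = FALSE),
    mlp = nnet::nnet(xs, as.numeric(y == "ICD"), size = hp$size,
                     decay = hp$decay, maxit = hp$maxit,
                     entropy = TRUE, trace = FALSE),
    dt = rpart::rpart(y ~ ., data = data.frame(y = y, x),
                      method = "class"),
    lr = glm(y ~ ., data = data.frame(y = y, xs), family = binomial())
  )
  structure(list(algorithm = algorithm, model = model, center = center,
                 scale = scale_, feature_sd = apply(x, 2, sd), hyper = hp),
            class = "aida_fit")
}

#' Predict binary outcomes with a fitted learner
#'
#' @param object an [fit_learner()] fit.
#' @param newdata cohort data frame.
#' @param ... unused.
#' @return factor of `ICD` / `NOICD` labels, one per row of `newdata`.
#' @export
predict.aida_fit <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  xs <- scale(x, object$center, object$scale)
  lab <- switch(object$algorithm,
    rf = as.character(predict(object$model, x)),
    svm = as.character(predict(object$model, xs)),
    mlp = ifelse(predict(object$model, xs) >= 0.5, "ICD", "NOICD"),
    dt = as.character(predict(object$model, data.frame(x), type = "class")),
    lr = ifelse(predict(object$model, data.frame(xs),
                        type = "response") >= 0.5, "ICD", "NOICD")
  )
  factor(lab, levels = BINARY_LEVELS)
}

#' Train on one cohort and predict another
#'
#' Convenience wrapper around [fit_learner()] + [predict.aida_fit()].
#'
#' @inheritParams fit_learner
#' @param test cohort to predict.
#' @return factor of predicted labels, one per test record.
#' @export
train_predict <- function(algorithm, train, test, hyper = list(), seed = 1) {
  fit <- fit_learner(algorithm, train, hyper = hyper, seed = seed)
  predict(fit, test)
}

#' Rank the four geometric parameters by importance for a fitted learner
#'
#' Tree learners use impurity importance, logistic regression the absolute
#' standardized coefficients, and SVM/MLP permutation importance (accuracy
#' drop when one feature is permuted) measured on held-out data.
#'
#' @param fit an [fit_learner()] fit.
#' @param newdata held-out cohort; required for `svm`/`mlp`.
#' @param seed seed for the permutations.
#' @param n_perm permutation repeats per feature (default 20).
#' @return list with `ranking` (feature names, most important first) and
#'   `importance` (named scores). Near-zero total importance (no signal) is
#'   flagged with attribute `degenerate`.
#' @export
feature_importance_rank <- function(fit, newdata = NULL, seed = 1,
                                    n_perm = 20) {
  stopifnot(inherits(fit, "aida_fit"))
  imp <- switch(fit$algorithm,
    rf = {
      m <- randomForest::importance(fit$model)[, "MeanDecreaseGini"]
      m[GEOMETRY_PARAMS]
    },
    dt = {
      v <- fit$model$variable.importance
      out <- setNames(numeric(4), GEOMETRY_PARAMS)
      out[names(v)[names(v) %in% GEOMETRY_PARAMS]] <-
        v[names(v) %in% GEOMETRY_PARAMS]
      out
    },
    lr = {
      # coefficients are already on the z-scored scale
      co <- coef(fit$model)[-1]
      abs(setNames(co[paste0(GEOMETRY_PARAMS)], GEOMETRY_PARAMS))
    },
    {
      if (is.null(newdata)) {
        stop("permutation importance for ", fit$algorithm,
             " needs held-out data")
      }
      y <- binary_outcome(newdata$delivery_outcome)
      base <- mean(predict(fit, newdata) == y)
      set.seed(seed)
      drops <- sapply(GEOMETRY_PARAMS, function(f) {
        mean(replicate(n_perm, {
          perm <- newdata
          perm[[f]] <- sample(perm[[f]])
          base - mean(predict(fit, perm) == y)
        }))
      })
      drops
    })
  imp[is.na(imp)] <- 0
  ranking <- names(sort(imp, decreasing = TRUE))
  out <- list(ranking = ranking, importance = imp)
  attr(out, "degenerate") <- sum(abs(imp)) < 1e-8
  out
}

#' Run the full seeded prediction harness
#'
#' For every (seed, algorithm) pair, fits the learner on the seed's
#' training split and predicts its test split; collects seed-level
#' predictions, aggregates them into per-patient prediction records (one
#' row per patient and distinct prediction pattern, with `n_predictions`
#' counting how many splits produced it, so the expanded total equals
#' seeds x test-set size per algorithm), attaches each patient's zone
#' profile, AIDA class and binary actual outcome, and ranks feature
#' importances per algorithm on the first seed's held-out split.
#'
#' @param cohort validated cohort data frame.
#' @param plan a [make_split_plan()] plan for `nrow(cohort)`.
#' @param algorithms algorithms to run (default `rf`, `svm`, `mlp`).
#' @param hyper named list of per-algorithm hyperparameter overrides, e.g.
#'   `list(rf = list(ntree = 200))`.
#' @param scheme zone scheme for the attached profiles.
#' @param seed root seed for learner-internal randomness (split membership
#'   is governed solely by the plan's seeds).
#' @return object of class `harness_result`: list with `long` (seed-level
#'   predictions), `records` (aggregated prediction records), `importance`
#'   (per algorithm) and `plan`.
#' @export
run_harness <- function(cohort, plan = make_split_plan(nrow(cohort)),
                        algorithms = c("rf", "svm", "mlp"),
                        hyper = list(), scheme = default_zone_scheme(),
                        seed = 1) {
  validate_cohort(cohort)
  stopifnot(plan$n == nrow(cohort))
  algorithms <- match.arg(algorithms, HARNESS_ALGORITHMS, several.ok = TRUE)
  fit_seeds <- matrix(
    substream_seeds(seed, length(plan$seeds) * length(algorithms)),
    nrow = length(plan$seeds))
  long <- list()
  for (si in seq_along(plan$seeds)) {
    sp <- plan$splits[[si]]
    train <- cohort[sp$train, , drop = FALSE]
    test <- cohort[sp$test, , drop = FALSE]
    for (ai in seq_along(algorithms)) {
      alg <- algorithms[ai]
      pred <- train_predict(alg, train, test,
                            hyper = hyper[[alg]] %||% list(),
                            seed = fit_seeds[si, ai])
      long[[length(long) + 1]] <- data.frame(
        split_seed = plan$seeds[si],
        algorithm = alg,
        patient_id = test$patient_id,
        actual_outcome = as.character(binary_outcome(test$delivery_outcome)),
        predicted = as.character(pred),
        stringsAsFactors = FALSE)
    }
  }
  long <- do.call(rbind, long)
  records <- aggregate_predictions(long, cohort, algorithms, scheme)
  importance <- lapply(setNames(algorithms, algorithms), function(alg) {
    sp <- plan$splits[[1]]
    fit <- fit_learner(alg, cohort[sp$train, , drop = FALSE],
                       hyper = hyper[[alg]] %||% list(),
                       seed = fit_seeds[1, match(alg, algorithms)])
    feature_importance_rank(fit, cohort[sp$test, , drop = FALSE], seed = seed)
  })
  structure(list(long = long, records = records, importance = importance,
                 plan = plan),
            class = "harness_result")
}

# Collapse seed-level predictions into per-patient prediction records:
# one row per (patient, prediction pattern across algorithms), counting
# how many splits produced that pattern.
aggregate_predictions <- function(long, cohort, algorithms, scheme) {
  wide <- NULL
  for (alg in algorithms) {
    sub <- long[long$algorithm == alg,
                c("split_seed", "patient_id", "actual_outcome", "predicted")]
    names(sub)[names(sub) == "predicted"] <- paste0("pred_", alg)
    wide <- if (is.null(wide)) sub else
      merge(wide, sub, by = c("split_seed", "patient_id", "actual_outcome"),
            sort = FALSE)
  }
  pred_cols <- paste0("pred_", algorithms)
  agg <- aggregate(list(n_predictions = rep(1L, nrow(wide))),
                   by = c(wide[c("patient_id", "actual_outcome")],
                          wide[pred_cols]),
                   FUN = sum)
  prof <- zone_profile(cohort, scheme, warn_outside_evidence = FALSE)
  meta <- cbind(cohort[, c("patient_id", "asynclitism_type")],
                prof[, c("zone_ad", "zone_aop", "zone_mla", "zone_hsd",
                         "aida_class")])
  out <- merge(agg, meta, by = "patient_id", sort = FALSE)
  out <- out[order(out$aida_class, out$asynclitism_type, out$patient_id), ]
  rownames(out) <- NULL
  cols <- c("n_predictions", "patient_id", "asynclitism_type",
            "actual_outcome", "zone_ad", "zone_aop", "zone_mla", "zone_hsd",
            "aida_class", pred_cols)
  out[, cols]
}
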