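#' Gini impurity of a binary ICD/NOICD label multiset
#'
#' For an ICD fraction p the impurity is `1 - p^2 - (1 - p)^2`, ranging
#' from 0 (pure node) to 0.5 (even split).
#'
#' @param labels non-empty vector of `"ICD"` / `"NOICD"` labels.
#' @return impurity in \[0, 0.5\].
#' @export
gini_impurity <- function(labels) {
  if (length(labels) == 0) stop("gini impurity of an empty label set is undefined")
  labels <- as.character(labels)
  stopifnot(all(labels %in% BINARY_LEVELS))
  p <- mean(labels == "ICD")
  1 - p^2 - (1 - p)^2
}

#' Best single split of one feature against the binary outcome
#'
#' Candidate thresholds are the midpoints of consecutive distinct sorted
#' feature values (so every chosen threshold lies strictly between observed
#' data points, giving the `x.5` character of the published cut-offs). The
#' candidate maximizing the weighted Gini impurity decrease is returned;
#' ties break toward the smallest threshold.
#'
#' @param values numeric feature values.
#' @param labels matching `"ICD"` / `"NOICD"` labels.
#' @return list with `threshold` (NA when all values are identical) and
#'   `gain` (weighted impurity decrease).
#' @examples
#' best_split(c(60, 80), c("NOICD", "ICD"))$threshold  # 70
#' @export
best_split <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2)
  labels <- as.character(labels)
  sv <- sort(unique(values))
  if (length(sv) < 2) return(list(threshold = NA_real_, gain = 0))
  candidates <- (sv[-length(sv)] + sv[-1]) / 2
  parent <- gini_impurity(labels)
  n <- length(values)
  best <- list(threshold = candidates[1], gain = -Inf)
  for (thr in candidates) {
    left <- values < thr
    child <- (sum(left) / n) * gini_impurity(labels[left]) +
      (sum(!left) / n) * gini_impurity(labels[!left])
    gain <- parent - child
    if (gain > best$gain + 1e-12) best <- list(threshold = thr, gain = gain)
  }
  best$gain <- max(best$gain, 0)
  best
}

# Recursive CART growth on a small feature matrix. Deterministic: no
# randomness, feature ties break toward the first column, threshold ties
# toward the smallest candidate. Leaves are labelled by majority vote
# (ties toward ICD, the positive class).
grow_tree <- function(X, labels, max_depth = 2, min_leaf = 1, depth = 0) {
  labels <- as.character(labels)
  n <- length(labels)
  p_icd <- mean(labels == "ICD")
  leaf <- list(leaf = TRUE, n = n, p_icd = p_icd,
               label = if (p_icd >= 0.5) "ICD" else "NOICD")
  if (depth >= max_depth || n < 2 * min_leaf ||
      p_icd == 0 || p_icd == 1) {
    return(leaf)
  }
  best <- NULL
  for (f in names(X)) {
    if (length(unique(X[[f]])) < 2) next
    s <- best_split(X[[f]], labels)
    if (is.na(s$threshold) || s$gain <= 1e-12) next
    left <- X[[f]] < s$threshold
    if (sum(left) < min_leaf || sum(!left) < min_leaf) next
    if (is.null(best) || s$gain > best$gain + 1e-12) {
      best <- list(feature = f, threshold = s$threshold, gain = s$gain)
    }
  }
  if (is.null(best)) return(leaf)
  left <- X[[best$feature]] < best$threshold
  list(leaf = FALSE, feature = best$feature, threshold = best$threshold,
       gain = best$gain, n = n, p_icd = p_icd,
       left = grow_tree(X[left, , drop = FALSE], labels[left],
                        max_depth, min_leaf, depth + 1),
       right = grow_tree(X[!left, , drop = FALSE], labels[!left],
                         max_depth, min_leaf, depth + 1))
}

predict_tree <- function(node, X) {
  if (node$leaf) return(rep(node$label, nrow(X)))
  left <- X[[node$feature]] < node$threshold
  out <- character(nrow(X))
  out[left] <- predict_tree(node$left, X[left, , drop = FALSE])
  out[!left] <- predict_tree(node$right, X[!left, , drop = FALSE])
  out
}

collect_splits <- function(node) {
  if (node$leaf) return(NULL)
  here <- data.frame(
    feature = node$feature,
    threshold = node$threshold,
    # the side with the higher cesarean fraction carries the ICD direction
    direction = if (node$right$p_icd >= node$left$p_icd) ">=" else "<",
    predicted = "ICD",
    gain = node$gain,
    stringsAsFactors = FALSE)
  rbind(here, collect_splits(node$left), collect_splits(node$right))
}

PAIR_FEATURES <- list(
  "AD-AoP" = c("ad_mm", "aop_deg"),
  "AD-HSD" = c("ad_mm", "hsd_mm"),
  "AD-MLA" = c("ad_mm", "mla_deg")
)

#' Derive ICD decision thresholds for a parameter pair with a shallow CART
#'
#' Reproduces the cut-off derivation procedure: a depth-limited
#' classification tree (Gini criterion, midpoint candidate thresholds,
#' minimum leaf size 1, no pruning, deterministic tie-breaks) is grown on
#' the two features of a pair -- AD with AoP, HSD or MLA -- against the
#' binary cesarean outcome, and each split's threshold is reported with the
#' direction pointing toward the cesarean-majority side. The published
#' thresholds themselves came from the unreleased raw cohort and ship as
#' fixtures; this function proves the procedure on any cohort.
#'
#' @param cohort cohort data frame containing both outcome classes.
#' @param pair `"AD-AoP"`, `"AD-HSD"` or `"AD-MLA"`.
#' @param max_depth maximum tree depth (default 2; the published AD-AoP
#'   rule, AD >= 67 with AoP >= 144.5 or < 101.5, needs depth 2).
#' @return object of class `pair_cutoffs`: list with `pair`, `cutoffs`
#'   (data frame feature/threshold/direction/gain, empty when no split
#'   gains) and the fitted `tree`.
#' @export
derive_pair_cutoffs <- function(cohort, pair = names(PAIR_FEATURES),
                                max_depth = 2) {
  pair <- match.arg(pair)
  stopifnot(max_depth >= 1)
  y <- binary_outcome(cohort$delivery_outcome)
  if (length(unique(y)) < 2) {
    stop("no split target: cohort contains a single outcome class")
  }
  X <- cohort[, PAIR_FEATURES[[pair]], drop = FALSE]
  tree <- grow_tree(X, y, max_depth = max_depth, min_leaf = 1)
  cuts <- collect_splits(tree)
  if (is.null(cuts)) {
    cuts <- data.frame(feature = character(), threshold = numeric(),
                       direction = character(), predicted = character(),
                       gain = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(pair = pair, cutoffs = cuts, tree = tree),
            class = "pair_cutoffs")
}

#' @export
print.pair_cutoffs <- function(x, ...) {
  cat("Pairwise decision-tree cut-offs for", x$pair, "\n")
  if (!nrow(x$cutoffs)) {
    cat("  (no split with positive impurity decrease)\n")
  } else {
    print(x$cutoffs, row.names = FALSE)
  }
  invisible(x)
}
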