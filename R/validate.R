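# k-fold cross-validated prediction of one target node, with confusion
# matrix, accuracy and ROC. The structure is learned once on the full data
# and held fixed; only the CPTs are refit inside each fold.

#' Seeded stratified fold assignment
#'
#' Partitions `n` rows into `k` disjoint folds. With `labels`, rows of each
#' class are dealt round-robin after a seeded shuffle, so per-fold class
#' proportions stay within one row of the global ones.
#'
#' @param n row count.
#' @param k fold count, `2 <= k <= n`.
#' @param labels optional stratification factor of length `n`.
#' @param seed integer seed.
#' @return Object of class `"fold_plan"`: integer fold index per row.
#' @examples
#' table(make_folds(122, 10, seed = 1)$fold)
#' @export
make_folds <- function(n, k = 10, labels = NULL, seed = 1L) {
  if (k < 2 || k > n) stop("need 2 <= k <= n")
  set.seed(seed)
  fold <- integer(n)
  groups <- if (is.null(labels)) list(seq_len(n))
            else split(seq_len(n), labels)
  offset <- 0L
  for (g in groups) {
    g <- sample(g)
    fold[g] <- (seq_along(g) + offset - 1L) %% k + 1L
    offset <- offset + length(g)   # stagger so small folds rotate across classes
  }
  structure(list(fold = fold, k = as.integer(k), seed = as.integer(seed),
                 stratified = !is.null(labels)), class = "fold_plan")
}

#' Accuracy from a confusion matrix
#'
#' @param cm square count matrix, actual in rows, predicted in columns.
#' @return List with `percent` (100 * trace / total) and `rounded` (nearest
#'   whole percent).
#' @examples
#' accuracy_from_confusion(matrix(c(34, 11, 10, 67), 2))  # 83%
#' @export
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  pct <- 100 * sum(diag(cm)) / total
  list(percent = pct, rounded = round(pct))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC with midrank tie handling. For targets with three or more
#' states a prevalence-weighted one-vs-rest average is returned.
#'
#' @param scores numeric score for the positive class (binary labels), or a
#'   matrix of per-state posterior probabilities (multi-state labels).
#' @param labels actual classes; for binary use, the positive class is the
#'   last factor level (the highest-valued state).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.factor(labels)
  lev <- levels(droplevels(labels))
  if (length(lev) < 2) stop("both classes must be present")
  if (is.matrix(scores) && length(lev) > 2) {
    w <- as.numeric(table(droplevels(labels))[lev]) / length(labels)
    aucs <- vapply(lev, function(cl)
      auc_binary(scores[, cl], labels == cl), 0)
    return(sum(w * aucs))
  }
  if (is.matrix(scores)) scores <- scores[, lev[length(lev)]]
  auc_binary(scores, labels == lev[length(lev)])
}

auc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)            # midranks
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validate prediction of a target node
#'
#' For each fold, CPTs are refit on the training rows over the fixed
#' structure; each test row's target posterior is computed given all other
#' variables as hard evidence, the maximum-posterior state is the prediction,
#' and results are pooled into a confusion matrix, overall and per-fold
#' accuracy, and AUC (positive state = highest-valued state for binary
#' targets, prevalence-weighted one-vs-rest otherwise).
#'
#' @param data data frame of factors.
#' @param structure a [bbn_dag()] learned on the full data (or a fitted
#'   `"bbn"`, whose structure is reused).
#' @param target target node id.
#' @param plan a [make_folds()] plan; defaults to stratified 10-fold.
#' @param k,seed used to build the default plan.
#' @param pseudocount CPT smoothing during refits.
#' @return Object of class `"bbn_cv"`: `confusion`, `accuracy` (percent),
#'   `auc`, `fold_accuracy`, `predicted`, `posterior`, `plan`.
#' @export
cross_validate <- function(data, structure, target, plan = NULL, k = 10,
                           seed = 1L, pseudocount = 1) {
  stopifnot(target %in% names(data))
  if (nlevels(data[[target]]) < 2) stop("target must have at least 2 states")
  if (inherits(structure, "bbn"))
    structure <- bbn_dag(structure$nodes, arcs(structure))
  if (is.null(plan)) plan <- make_folds(nrow(data), k, data[[target]], seed)
  lev <- levels(data[[target]])
  post <- matrix(NA_real_, nrow(data), length(lev),
                 dimnames = list(NULL, lev))
  for (f in seq_len(plan$k)) {
    test <- which(plan$fold == f)
    net <- fit_cpts(structure, data[-test, , drop = FALSE], pseudocount)
    others <- setdiff(names(data), target)
    for (i in test) {
      ev <- evidence(hard = vapply(data[i, others, drop = FALSE],
                                   as.character, ""))
      post[i, ] <- infer(net, ev, target)[[target]]
    }
  }
  predicted <- factor(lev[max.col(post, ties.method = "first")],
                      levels = lev, ordered = TRUE)
  confusion <- table(actual = data[[target]], predicted = predicted)
  acc <- accuracy_from_confusion(confusion)
  fold_acc <- vapply(seq_len(plan$k), function(f) {
    idx <- plan$fold == f
    mean(as.character(predicted[idx]) == as.character(data[[target]][idx]))
  }, 0)
  auc <- roc_auc(post, data[[target]])
  structure(list(confusion = confusion, accuracy = acc$percent,
                 accuracy_rounded = acc$rounded, auc = auc,
                 fold_accuracy = fold_acc, predicted = predicted,
                 posterior = post, target = target, plan = plan),
            class = "bbn_cv")
}

#' @export
print.bbn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation of %s\n", x$plan$k, x$target))
  cat(sprintf("  accuracy: %.1f%%   AUC: %.3f\n", x$accuracy, x$auc))
  cat("  confusion (actual x predicted):\n")
  print(x$confusion)
  invisible(x)
}
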