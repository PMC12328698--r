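#' Elastic-net prefilter of panel candidates
#'
#' Fits an elastic-net-penalized logistic regression (`alpha = 0.5`) over a
#' descending lambda path with k-fold cross-validation scored by AUC, and
#' returns the proteins with non-zero coefficients at the AUC-optimal
#' lambda (`lambda.min`). Missing abundances are median-imputed per protein
#' before fitting. Fold assignment is a deterministic function of the seed.
#'
#' @param x Log2-scale `AbundanceMatrix` restricted (by the caller) to the
#'   candidate proteins, e.g. the DAPs of a contrast.
#' @param labels Binary factor/vector parallel to the samples; the second
#'   level (or `positive`) is the positive class.
#' @param alpha Elastic-net mixing parameter.
#' @param folds Number of CV folds.
#' @param seed Integer seed for fold assignment.
#' @param positive Optional positive-class label.
#' @return Character vector of selected protein ids (class
#'   `"empty_selection"` error condition when the optimal model is
#'   intercept-only).
#' @export
lasso_prefilter <- function(x, labels, alpha = 0.5, folds = 5, seed = 1L,
                            positive = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"))
  y <- binarize_labels(labels, positive)
  if (length(unique(y)) < 2) stop("labels contain a single class")
  if (min(table(y)) < folds) stop("each class must have >= folds members")
  feat <- impute_median(t(x$values))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  foldid <- stratified_folds(y, folds)
  cv <- glmnet::cv.glmnet(feat, y, family = "binomial", alpha = alpha,
                          type.measure = "auc", foldid = foldid)
  beta <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1, 1]
  sel <- names(beta)[beta != 0]
  if (length(sel) == 0) {
    stop(structure(class = c("empty_selection", "error", "condition"),
                   list(message = "elastic net selected no proteins",
                        call = sys.call(-1))))
  }
  sel
}

binarize_labels <- function(labels, positive = NULL) {
  f <- as.factor(labels)
  if (nlevels(f) != 2) stop("labels must have exactly 2 classes")
  if (is.null(positive)) positive <- levels(f)[2]
  as.integer(f == positive)
}

# Deterministic stratified fold ids: within each class, shuffle then deal
# round-robin so folds are balanced.
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    foldid[idx] <- rep_len(seq_len(k), length(idx))
  }
  foldid
}

impute_median <- function(feat) {
  for (j in seq_len(ncol(feat))) {
    v <- feat[, j]
    if (anyNA(v)) feat[is.na(v), j] <- stats::median(v, na.rm = TRUE)
  }
  feat
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC: the fraction of positive/negative pairs
#' in which the positive scores higher, with ties credited one half. Equals
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric decision values, higher = more positive.
#' @param labels Binary labels (0/1, logical, or 2-level factor).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  y <- if (is.factor(labels)) binarize_labels(labels) else as.integer(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame `threshold`, `fpr`, `tpr`, stepping through the
#'   distinct score values from most to least stringent.
#' @export
roc_points <- function(scores, labels) {
  y <- if (is.factor(labels)) binarize_labels(labels) else as.integer(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & y == 0) / n0, 0),
    tpr = vapply(thr, function(t) sum(scores >= t & y == 1) / n1, 0))
}

#' Train a linear SVM scorer
#'
#' Standardizes the training features (zero-variance features are dropped
#' with a warning), fits a C-classification SVM (linear kernel, cost 1 by
#' default; RBF available) and returns a deterministic decision function
#' oriented so that larger values indicate the positive class.
#'
#' @param feat Samples-by-features numeric matrix (complete).
#' @param labels Binary labels.
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost SVM cost parameter.
#' @param positive Optional positive-class label.
#' @return A function `f(newdata)` returning decision values; selected
#'   feature names in attribute `"features"`.
#' @export
train_classifier <- function(feat, labels, kernel = c("linear", "rbf"),
                             cost = 1, positive = NULL) {
  kernel <- match.arg(kernel)
  y <- binarize_labels(labels, positive)
  if (min(table(y)) < 2) stop("need >= 2 samples per class")
  feat <- as.matrix(feat)
  mu <- colMeans(feat)
  sd_ <- apply(feat, 2, stats::sd)
  keep <- sd_ > 0
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(feat)[!keep], collapse = ", "))
    if (!any(keep)) stop("all features have zero variance")
  }
  z <- sweep(sweep(feat[, keep, drop = FALSE], 2, mu[keep]), 2,
             sd_[keep], "/")
  kern <- if (kernel == "linear") kernlab::vanilladot() else "rbfdot"
  fit <- kernlab::ksvm(z, factor(y, levels = c(0, 1)), type = "C-svc",
                       kernel = kern, C = cost, scaled = FALSE,
                       prob.model = FALSE)
  dv_train <- kernlab::predict(fit, z, type = "decision")[, 1]
  flip <- mean(dv_train[y == 1]) < mean(dv_train[y == 0])
  scorer <- function(newdata) {
    newdata <- as.matrix(newdata)[, colnames(z), drop = FALSE]
    zn <- sweep(sweep(newdata, 2, mu[keep]), 2, sd_[keep], "/")
    dv <- kernlab::predict(fit, zn, type = "decision")[, 1]
    if (flip) -dv else dv
  }
  attr(scorer, "features") <- colnames(z)
  scorer
}

#' Stepwise SVM forward selection of a protein panel
#'
#' Builds a minimal panel distinguishing two classes from a candidate pool
#' (typically the elastic-net prefilter output):
#' \enumerate{
#'   \item One stratified 80/20 train/test split, fixed by `seed`, shared
#'     by every model of the search.
#'   \item Each candidate is evaluated alone (train on the training split,
#'     AUC on the test split); the best seeds the panel. Remaining
#'     candidates are considered in descending single-protein test AUC
#'     (ties broken lexicographically).
#'   \item Greedy growth: each remaining candidate is tentatively added and
#'     kept only if the test AUC strictly increases; passes repeat until no
#'     addition helps.
#'   \item Tolerance growth: the best remaining candidate is added while
#'     the resulting AUC stays within `tol` (1 percentage point) of the
#'     maximum achieved, up to `cap` proteins, enlarging the panel without
#'     penalizing performance.
#' }
#' Missing abundances are imputed with training-split medians.
#'
#' @param x Log2-scale `AbundanceMatrix`.
#' @param labels Binary labels parallel to samples.
#' @param candidates Candidate protein ids (non-empty, present in `x`).
#' @param split Training fraction.
#' @param tol Absolute AUC tolerance for the growth phase.
#' @param cap Maximum panel size.
#' @param seed Integer seed fixing the split.
#' @param kernel,cost Passed to [train_classifier()].
#' @param positive Optional positive-class label.
#' @return A `PanelModel` list: `proteins` (ordered, 1..cap), `auc_test`,
#'   `roc`, `sensitivity`, `specificity`, `confusion`, `candidate_pool`,
#'   `split` (train/test sample ids), `seed`.
#' @export
stepwise_svm_panel <- function(x, labels, candidates, split = 0.8,
                               tol = 0.01, cap = 5, seed = 1L,
                               kernel = "linear", cost = 1,
                               positive = NULL) {
  stopifnot(inherits(x, "AbundanceMatrix"), length(candidates) >= 1,
            all(candidates %in% protein_ids(x)))
  y <- binarize_labels(labels, positive)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  sp <- stratified_split(y, split)
  if (length(unique(y[sp$test])) < 2 || length(unique(y[sp$train])) < 2) {
    stop("degenerate split: a side lacks a class")
  }
  feat_all <- t(x$values[candidates, , drop = FALSE])
  colnames(feat_all) <- candidates
  # impute with training-split medians only (no test leakage)
  med <- apply(feat_all[sp$train, , drop = FALSE], 2, stats::median,
               na.rm = TRUE)
  for (j in seq_len(ncol(feat_all))) {
    v <- feat_all[, j]
    if (anyNA(v)) feat_all[is.na(v), j] <- med[j]
  }

  panel_auc <- function(panel) {
    f_tr <- feat_all[sp$train, panel, drop = FALSE]
    f_te <- feat_all[sp$test, panel, drop = FALSE]
    scorer <- suppressWarnings(
      train_classifier(f_tr, y[sp$train], kernel = kernel, cost = cost))
    roc_auc(scorer(f_te), y[sp$test])
  }

  single <- vapply(candidates, function(p) panel_auc(p), 0)
  ord <- candidates[order(-single, candidates)]
  panel <- ord[1]
  best_auc <- single[[panel]]
  remaining <- setdiff(ord, panel)

  # Phase 2: keep additions only on strict AUC increase, repeat to fixpoint
  repeat {
    added <- FALSE
    for (p in remaining) {
      if (length(panel) >= cap) break
      auc_try <- panel_auc(c(panel, p))
      if (auc_try > best_auc) {
        panel <- c(panel, p)
        best_auc <- auc_try
        added <- TRUE
      }
    }
    remaining <- setdiff(remaining, panel)
    if (!added || length(panel) >= cap || length(remaining) == 0) break
  }

  # Phase 3: grow within tolerance of the maximum, never past the cap
  max_auc <- best_auc
  while (length(panel) < cap && length(remaining) > 0) {
    aucs_try <- vapply(remaining, function(p) panel_auc(c(panel, p)), 0)
    best_i <- order(-aucs_try, remaining)[1]
    if (aucs_try[best_i] >= max_auc - tol) {
      panel <- c(panel, remaining[best_i])
      max_auc <- max(max_auc, aucs_try[best_i])
      remaining <- remaining[-best_i]
    } else break
  }

  final <- evaluate_panel_internal(panel, feat_all, y, sp)
  structure(list(proteins = panel, auc_test = final$auc, roc = final$roc,
                 sensitivity = final$sensitivity,
                 specificity = final$specificity,
                 confusion = final$confusion,
                 candidate_pool = candidates,
                 split = sp, seed = seed),
            class = "PanelModel")
}

stratified_split <- function(y, split) {
  train <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    n_tr <- max(1, min(length(idx) - 1, round(split * length(idx))))
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(y), train))
}

evaluate_panel_internal <- function(panel, feat_all, y, sp,
                                    kernel = "linear", cost = 1) {
  f_tr <- feat_all[sp$train, panel, drop = FALSE]
  f_te <- feat_all[sp$test, panel, drop = FALSE]
  scorer <- suppressWarnings(
    train_classifier(f_tr, y[sp$train], kernel = kernel, cost = cost))
  dv <- scorer(f_te)
  y_te <- y[sp$test]
  pred <- as.integer(dv > 0)
  tp <- sum(pred == 1 & y_te == 1); fn <- sum(pred == 0 & y_te == 1)
  tn <- sum(pred == 0 & y_te == 0); fp <- sum(pred == 1 & y_te == 0)
  list(auc = roc_auc(dv, y_te), roc = roc_points(dv, y_te),
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       confusion = c(tp = tp, fp = fp, tn = tn, fn = fn))
}

#' Re-evaluate a fitted panel
#'
#' Retrains the panel SVM on the stored training split and reports test
#' metrics: AUC, ROC points, sensitivity/specificity and confusion counts
#' at decision threshold 0.
#'
#' @param panel A `PanelModel`.
#' @param x The `AbundanceMatrix` used to build it.
#' @param labels Binary labels parallel to samples.
#' @param positive Optional positive-class label.
#' @return List `auc`, `roc`, `sensitivity`, `specificity`, `confusion`.
#' @export
evaluate_panel <- function(panel, x, labels, positive = NULL) {
  stopifnot(inherits(panel, "PanelModel"))
  missing <- setdiff(panel$proteins, protein_ids(x))
  if (length(missing)) stop("panel protein(s) absent from matrix: ",
                            paste(missing, collapse = ", "))
  y <- binarize_labels(labels, positive)
  feat_all <- t(x$values[panel$proteins, , drop = FALSE])
  med <- apply(feat_all[panel$split$train, , drop = FALSE], 2,
               stats::median, na.rm = TRUE)
  for (j in seq_len(ncol(feat_all))) {
    v <- feat_all[, j]
    if (anyNA(v)) feat_all[is.na(v), j] <- med[j]
  }
  evaluate_panel_internal(panel$proteins, feat_all, y, panel$split)
}

#' @export
print.PanelModel <- function(x, ...) {
  cat("PanelModel:", paste(x$proteins, collapse = " + "), "\n")
  cat(sprintf("  test AUC %.3f | sens %.3f | spec %.3f\n",
              x$auc_test, x$sensitivity, x$specificity))
  invisible(x)
}
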