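#' Train a linear discriminant classifier
#'
#' Two-class Fisher discriminant with pooled within-class covariance and
#' empirical priors. The decision rule is `sign(w'x + b)`, positive meaning
#' the positive class (schizophrenia by default).
#'
#' @param features Subjects x d numeric matrix (a vector is taken as d = 1).
#' @param labels Class label per subject (two levels).
#' @param positive Label treated as the positive class
#'   (default "schizophrenia").
#' @param ridge Relative ridge added to the pooled covariance diagonal when
#'   it is not positive definite (default 1e-8).
#' @return Object of class `lda_model`: `weights`, `bias`, `priors`,
#'   `pooled_cov`, `positive`, `negative`.
#' @export
lda_train <- function(features, labels, positive = "schizophrenia",
                      ridge = 1e-8) {
  X <- as.matrix(features)
  if (!is.numeric(X)) stop("features must be numeric")
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("exactly two classes required in training data")
  if (!positive %in% lev) positive <- lev[1]
  negative <- setdiff(lev, positive)
  if (min(table(labels)) < 2)
    stop("each class needs at least 2 training members")
  Xp <- X[labels == positive, , drop = FALSE]
  Xn <- X[labels == negative, , drop = FALSE]
  mp <- colMeans(Xp); mn <- colMeans(Xn)
  n1 <- nrow(Xp); n0 <- nrow(Xn)
  Sw <- ((n1 - 1) * stats::cov(Xp) + (n0 - 1) * stats::cov(Xn)) / (n1 + n0 - 2)
  Sw <- as.matrix(Sw)
  ok <- tryCatch({ chol(Sw); TRUE }, error = function(e) FALSE)
  if (!ok)
    Sw <- Sw + diag(ridge * max(mean(diag(Sw)), 1e-12), ncol(Sw))
  w <- solve(Sw, mp - mn)
  b <- -sum(w * (mp + mn)) / 2 + log(n1 / n0)
  structure(list(weights = w, bias = b,
                 priors = c(stats::setNames(n1, positive),
                            stats::setNames(n0, negative)) / (n1 + n0),
                 pooled_cov = Sw, positive = positive, negative = negative),
            class = "lda_model")
}

#' Predict from a linear discriminant model
#'
#' @param object An `lda_model`.
#' @param newdata Subjects x d matrix or vector of features.
#' @param type `"class"` for labels, `"score"` for the discriminant value
#'   `w'x + b` (positive favours the positive class).
#' @param ... Unused.
#' @return Character vector of labels or numeric scores.
#' @export
predict.lda_model <- function(object, newdata, type = c("class", "score"),
                              ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$weights)) X <- t(X)
  score <- drop(X %*% object$weights) + object$bias
  if (type == "score") return(score)
  ifelse(score > 0, object$positive, object$negative)
}

# stratified fold assignment: within each class, shuffled indices are dealt
# round-robin over k folds, so per-fold class counts differ by at most one
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- sample(which(labels == lev))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated stratified k-fold cross-validated accuracy
#'
#' Repeats a stratified random k-fold split; per repeat, accuracy is pooled
#' over the held-out folds (correct / total across all subjects), giving one
#' number per repeat. The distribution over repeats is summarized by its
#' median and 25th/75th percentiles (linear-interpolation quantiles). ROC
#' curves are computed both from the out-of-fold discriminant scores of the
#' first repeat (cross-validated) and from an in-sample fit on all subjects.
#'
#' @param features Subjects x d matrix or vector of features, or a fold-wise
#'   feature extractor: a `function(train_idx, test_idx)` returning
#'   `list(train = , test = )` feature matrices. An extractor lets
#'   feature construction (e.g. projecting onto a group signature) be
#'   re-estimated inside each training fold, so held-out subjects never
#'   influence their own features.
#' @param labels Class label per subject.
#' @param k Number of folds (default 2).
#' @param repeats Number of repeats (default 100).
#' @param seed Integer seed making the whole procedure deterministic.
#' @param positive Positive class label (default "schizophrenia").
#' @return Object of class `classification_result`: `accuracies` (length
#'   `repeats`), `median`, `q25`, `q75`, `roc` and `auc` (cross-validated
#'   scores), `roc_insample` and `auc_insample`, `cv_scores`,
#'   `positive_label`, `k`, `repeats`, `seed`, `n_resampled_folds`.
#' @export
repeated_kfold_accuracy <- function(features, labels, k = 2, repeats = 100,
                                    seed = 1, positive = "schizophrenia") {
  extractor <- if (is.function(features)) features else {
    X <- as.matrix(features)
    function(tr, te) list(train = X[tr, , drop = FALSE],
                          test = X[te, , drop = FALSE])
  }
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2) stop("`k` must be at least 2")
  if (k > min(table(labels)))
    stop("`k` exceeds the smallest class size")
  set.seed(as.integer(seed))
  acc <- numeric(repeats)
  cv_scores <- NULL
  n_resampled <- 0L
  for (rep_i in seq_len(repeats)) {
    for (attempt in 1:100) {
      fold <- stratified_folds(labels, k)
      ok <- all(vapply(seq_len(k), function(f)
        min(table(labels[fold != f])) >= 2, logical(1)))
      if (ok) break
      n_resampled <- n_resampled + 1L
    }
    if (!ok) stop("could not draw folds with >= 2 training members per class")
    correct <- 0L
    scores <- numeric(n)
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      fx <- extractor(tr, te)
      fit <- lda_train(fx$train, labels[tr], positive = positive)
      pred <- predict(fit, fx$test, type = "class")
      correct <- correct + sum(pred == labels[te])
      scores[te] <- predict(fit, fx$test, type = "score")
    }
    acc[rep_i] <- correct / n
    if (rep_i == 1L) cv_scores <- scores
  }
  roc_cv <- roc_auc(cv_scores, labels, positive = positive)
  all_idx <- seq_len(n)
  fx_all <- extractor(all_idx, all_idx)
  fit_all <- lda_train(fx_all$train, labels, positive = positive)
  in_scores <- predict(fit_all, fx_all$test, type = "score")
  roc_in <- roc_auc(in_scores, labels, positive = positive)
  qs <- stats::quantile(acc, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  structure(list(accuracies = acc, median = qs[2], q25 = qs[1], q75 = qs[3],
                 roc = roc_cv$curve, auc = roc_cv$auc,
                 roc_insample = roc_in$curve, auc_insample = roc_in$auc,
                 cv_scores = cv_scores, positive_label = positive,
                 k = k, repeats = repeats, seed = seed,
                 n_resampled_folds = n_resampled),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "repeated %d-fold CV (%d repeats): median accuracy %.3f [%.3f, %.3f], AUC %.3f\n",
    x$k, x$repeats, x$median, x$q25, x$q75, x$auc))
  invisible(x)
}

#' ROC curve and AUC
#'
#' ROC points from the sorted unique score thresholds and the area under the
#' curve by the Mann-Whitney convention (tied scores contribute half), so
#' the AUC equals `U / (n_pos * n_neg)` from the rank-sum statistic.
#'
#' @param scores Per-subject discriminant scores (higher = more positive).
#' @param labels Class label per subject.
#' @param positive Positive class label (default "schizophrenia").
#' @return List: `curve` (data.frame threshold/fpr/tpr, from (0,0) to
#'   (1,1)), `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "schizophrenia") {
  labels <- as.character(labels)
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (length(unique(scores)) == 1L) {
    warning("constant scores: AUC set to 0.5")
    curve <- data.frame(threshold = c(Inf, unique(scores)),
                        fpr = c(0, 1), tpr = c(0, 1))
    return(list(curve = curve, auc = 0.5))
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n0, numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  rk <- rank(scores, ties.method = "average")
  auc <- (sum(rk[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  list(curve = curve, auc = auc)
}
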