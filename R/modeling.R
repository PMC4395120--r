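# Classification stage: column standardization, PCA to 25 components, and
# three classifiers (kNN with deterministic tie-breaking, Gaussian naive
# Bayes via e1071, and LDA with a small ridge on the pooled covariance so
# degenerate designs do not abort) evaluated under leave-one-out
# cross-validation. "strict" leakage handling refits standardization + PCA
# inside every fold; "paper" mode fits them once on all rows, mirroring the
# classical single-fit workflow.

standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(mu = mu, sd = sdv)
}
standardize_apply <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$sd, "/")

#' Reduce a feature matrix to principal-component scores
#'
#' Columns are standardized (zero mean, unit variance) and projected onto
#' the leading principal components, ordered by non-increasing explained
#' variance.
#'
#' @param x numeric matrix or data.frame of features (rows = epochs).
#' @param n_components number of components to keep (default 25); must be
#'   at most `min(nrow - 1, ncol)`.
#' @param scale standardize columns first (default `TRUE`).
#' @return object of class `pca_reduction`: `scores`
#'   (`nrow x n_components`), `rotation`, `explained_variance`,
#'   `center`/`scale` used, and `project(newdata)` via [predict()].
#' @export
reduce_dimensions <- function(x, n_components = 25, scale = TRUE) {
  x <- as.matrix(x)
  if (n_components < 1 || n_components > min(nrow(x) - 1, ncol(x)))
    stop_invalid_argument("`n_components` must lie in [1, min(rows - 1, cols)]")
  st <- if (scale) standardize_fit(x) else
    list(mu = rep(0, ncol(x)), sd = rep(1, ncol(x)))
  xs <- standardize_apply(x, st)
  pc <- prcomp(xs, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  structure(
    list(scores = pc$x[, seq_len(k), drop = FALSE],
         rotation = pc$rotation[, seq_len(k), drop = FALSE],
         explained_variance = pc$sdev^2,
         standardize = st, pca_center = pc$center,
         n_components = k),
    class = "pca_reduction")
}

#' @export
predict.pca_reduction <- function(object, newdata, ...) {
  nd <- standardize_apply(as.matrix(newdata), object$standardize)
  sweep(nd, 2, object$pca_center) %*% object$rotation
}

#' @export
print.pca_reduction <- function(x, ...) {
  ev <- x$explained_variance
  cat(sprintf("<pca_reduction> %d components, %.1f%% variance retained\n",
              x$n_components, 100 * sum(ev[seq_len(x$n_components)]) / sum(ev)))
  invisible(x)
}

# --- classifiers -----------------------------------------------------------

# kNN with deterministic tie-breaking: majority vote among the k nearest;
# ties broken by the larger summed inverse distance, then lexicographic
# class order.
knn_predict <- function(train, cl, test, k) {
  train <- as.matrix(train); test <- as.matrix(test)
  k <- min(k, nrow(train))
  cl <- as.character(cl)
  classes <- sort(unique(cl))
  tr2 <- rowSums(train^2)
  te2 <- rowSums(test^2)
  d2 <- outer(te2, tr2, "+") - 2 * test %*% t(train)
  d2[d2 < 0] <- 0
  apply(d2, 1, function(drow) {
    nn <- order(drow)[seq_len(k)]
    votes <- table(factor(cl[nn], levels = classes))
    top <- names(votes)[votes == max(votes)]
    if (length(top) == 1) return(top)
    inv <- vapply(top, function(cc) {
      idx <- nn[cl[nn] == cc]
      sum(1 / pmax(sqrt(drow[idx]), 1e-12))
    }, numeric(1))
    top[order(-inv, top)][1]
  })
}

# LDA with a small ridge on the pooled within-class covariance
lda_fit <- function(x, cl, ridge = 1e-6) {
  x <- as.matrix(x)
  cl <- factor(cl)
  classes <- levels(cl)
  p <- ncol(x)
  mus <- t(vapply(classes, function(cc)
    colMeans(x[cl == cc, , drop = FALSE]), numeric(p)))
  S <- matrix(0, p, p)
  for (cc in classes) {
    xc <- sweep(x[cl == cc, , drop = FALSE], 2, mus[cc, ])
    S <- S + crossprod(xc)
  }
  S <- S / max(1, nrow(x) - length(classes))
  lam <- ridge * max(mean(diag(S)), 1)
  S <- S + diag(lam, p)
  Sinv <- solve(S)
  priors <- as.numeric(table(cl)) / length(cl)
  list(classes = classes, mus = mus, Sinv = Sinv, log_priors = log(priors))
}

lda_predict <- function(fit, test) {
  test <- as.matrix(test)
  disc <- sapply(seq_along(fit$classes), function(j) {
    mu <- fit$mus[j, ]
    drop(test %*% (fit$Sinv %*% mu)) - 0.5 * drop(mu %*% fit$Sinv %*% mu) +
      fit$log_priors[j]
  })
  disc <- matrix(disc, nrow = nrow(test))
  fit$classes[apply(disc, 1, which.max)]
}

nb_predict <- function(train, cl, test) {
  df <- as.data.frame(train)
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  fit <- e1071::naiveBayes(df, factor(cl))
  td <- as.data.frame(as.matrix(test))
  colnames(td) <- colnames(df)
  as.character(predict(fit, td))
}

fit_predict <- function(classifier, train, cl, test, k) {
  switch(classifier,
    knn = knn_predict(train, cl, test, k),
    naive_bayes = nb_predict(train, cl, test),
    lda = lda_predict(lda_fit(train, cl), test),
    stop_invalid_argument(sprintf("unknown classifier '%s'", classifier)))
}

cv_result <- function(classifier, actual, predicted, ...) {
  actual <- as.character(actual); predicted <- as.character(predicted)
  lev <- sort(unique(actual))
  confusion <- table(actual = factor(actual, lev),
                     predicted = factor(predicted, lev))
  structure(
    c(list(classifier = classifier, predicted = predicted, actual = actual,
           confusion = confusion,
           accuracy = sum(diag(confusion)) / sum(confusion)),
      list(...)),
    class = "archepsy_cv")
}

#' @export
print.archepsy_cv <- function(x, ...) {
  cat(sprintf("<cv result> %s: accuracy %.1f%% (%d/%d)\n", x$classifier,
              100 * x$accuracy, sum(diag(x$confusion)), sum(x$confusion)))
  print(x$confusion)
  invisible(x)
}

#' Leave-one-out cross-validated classification
#'
#' Each row is predicted by a model fitted on all remaining rows. With
#' `leakage = "strict"` (default) column standardization and PCA are refit
#' inside every fold on the training rows only; `leakage = "paper"` fits
#' them once on the full matrix before cross-validation, mirroring the
#' classical single-fit workflow at the cost of mild information leakage.
#'
#' @param x numeric matrix/data.frame of features (rows = epochs).
#' @param labels class label per row (>= 2 classes, >= 2 rows per class).
#' @param classifier `"knn"`, `"naive_bayes"` or `"lda"`.
#' @param k neighbors for kNN (default 20; must be < rows - 1).
#' @param n_components principal components to keep before classification;
#'   `NULL` disables the standardization + PCA step.
#' @param leakage `"strict"` or `"paper"` (see above).
#' @return an `archepsy_cv` object: per-row predictions, the confusion
#'   matrix (rows = actual, columns = predicted) and overall accuracy
#'   (`trace / sum`).
#' @export
loocv_classify <- function(x, labels,
                           classifier = c("knn", "naive_bayes", "lda"),
                           k = 20, n_components = 25,
                           leakage = c("strict", "paper")) {
  classifier <- match.arg(classifier)
  leakage <- match.arg(leakage)
  x <- as.matrix(x)
  labels <- as.character(labels)
  n <- nrow(x)
  if (length(labels) != n) stop_invalid_argument("labels must match rows")
  if (length(unique(labels)) < 2) stop_invalid_design("need at least 2 classes")
  if (min(table(labels)) < 2)
    stop_invalid_design("every class needs at least 2 samples")
  if (classifier == "knn" && k >= n - 1)
    stop_invalid_argument("`k` must be smaller than rows - 1")

  use_pca <- !is.null(n_components)
  if (use_pca && n_components > min(n - 2, ncol(x)))
    stop_invalid_argument("`n_components` too large for LOOCV folds")

  if (use_pca && leakage == "paper") {
    red <- reduce_dimensions(x, n_components)
    x <- red$scores
    use_pca <- FALSE
  }
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- x[-i, , drop = FALSE]
    te <- x[i, , drop = FALSE]
    if (use_pca) {
      red <- reduce_dimensions(tr, n_components)
      tr <- red$scores
      te <- predict(red, te)
    }
    pred[i] <- fit_predict(classifier, tr, labels[-i], te, k)
  }
  cv_result(classifier, labels, pred, k = if (classifier == "knn") k else NULL,
            n_components = n_components, leakage = leakage)
}

#' Classify states from SAM reports
#'
#' Leave-one-out LDA on the three introspective dimensions (arousal,
#' valence, dominance); no dimension reduction is applied.
#'
#' @param sam numeric matrix/data.frame with 3 columns.
#' @param labels class label per row.
#' @return an `archepsy_cv` object.
#' @export
sam_classify <- function(sam, labels) {
  sam <- as.matrix(sam)
  if (ncol(sam) != 3) stop_invalid_argument("SAM matrix must have 3 columns")
  if (any(sam < 1 | sam > 9)) stop_invalid_argument("SAM values must lie in [1, 9]")
  loocv_classify(sam, labels, classifier = "lda", n_components = NULL)
}
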