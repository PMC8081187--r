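#' Fisher linear discriminant for two classes
#'
#' Closed-form LDA: pooled within-class covariance, weight vector
#' `w = S_pooled^-1 (mu_1 - mu_0)` and bias placing the decision boundary
#' at the midpoint of the projected means (shifted by the log prior ratio;
#' priors equal by default). If the pooled covariance is singular, a small
#' identity shrinkage is applied with a warning. Fitting is deterministic.
#'
#' @param x Numeric feature matrix (or data frame / feature tibble — any
#'   non-numeric columns such as `id` and `label` are dropped).
#' @param labels Two-class factor or character vector, one per row.
#' @param priors Class priors, in the order of `sort(unique(labels))`.
#' @return An `lda_model` with `means`, `pooled_cov`, `priors`, `w`,
#'   `bias` and `classes`.
#' @export
fit_lda <- function(x, labels, priors = c(0.5, 0.5)) {
  x <- feature_matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("LDA here is two-class; got a different class count")
  n0 <- sum(labels == classes[1]); n1 <- sum(labels == classes[2])
  if (min(n0, n1) < 2) abort("each class needs at least 2 samples")
  x0 <- x[labels == classes[1], , drop = FALSE]
  x1 <- x[labels == classes[2], , drop = FALSE]
  mu0 <- colMeans(x0); mu1 <- colMeans(x1)
  sp <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) / (n0 + n1 - 2)
  w <- tryCatch(solve(sp, mu1 - mu0), error = function(e) NULL)
  if (is.null(w) || rcond_sym(sp) < 1e-12) {
    warn("singular pooled covariance: applying identity shrinkage")
    sp <- 0.95 * sp + 0.05 * diag(mean(diag(sp)) + 1e-12, ncol(sp))
    w <- solve(sp, mu1 - mu0)
  }
  bias <- sum(w * (mu0 + mu1)) / 2 - log(priors[2] / priors[1])
  structure(
    list(means = rbind(mu0, mu1), pooled_cov = sp, priors = priors,
         w = w, bias = bias, classes = classes),
    class = "lda_model"
  )
}

rcond_sym <- function(s) {
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (max(ev) <= 0) 0 else max(min(ev), 0) / max(ev)
}

feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- as.matrix(x[vapply(x, is.numeric, TRUE) &
                       !(names(x) %in% c("id"))])
  }
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  x
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  x <- feature_matrix(newdata)
  score <- drop(x %*% object$w)
  factor(ifelse(score > object$bias, object$classes[2], object$classes[1]),
         levels = object$classes)
}

#' RBF-kernel support vector classifier
#'
#' Soft-margin SVM with a radial basis kernel at cost `C = 0.4` (the
#' operating point used alongside LDA in this pipeline). `gamma` defaults
#' to `1 / (d * mean feature variance)`. Fitting has no internal
#' randomness. This is a thin wrapper around [e1071::svm()].
#'
#' @inheritParams fit_lda
#' @param C Soft-margin cost.
#' @param gamma Kernel width; `NULL` for the default above.
#' @return An `svm_model` wrapping the e1071 fit.
#' @export
fit_svm_rbf <- function(x, labels, C = 0.4, gamma = NULL) {
  x <- feature_matrix(x)
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) abort("SVM needs two classes; got one")
  if (is.null(gamma)) {
    v <- mean(apply(x, 2, stats::var))
    gamma <- 1 / (ncol(x) * max(v, 1e-12))
  }
  fit <- e1071::svm(x, labels, type = "C-classification", kernel = "radial",
                    cost = C, gamma = gamma, scale = FALSE)
  structure(list(fit = fit, classes = levels(labels), C = C, gamma = gamma),
            class = "svm_model")
}

#' @export
predict.svm_model <- function(object, newdata, ...) {
  predict(object$fit, feature_matrix(newdata))
}

fit_classifier <- function(kind, x, labels) {
  switch(kind,
         lda = fit_lda(x, labels),
         svm = fit_svm_rbf(x, labels),
         abort(paste0("unknown classifier '", kind, "'")))
}

# Stratified fold assignment on stable epoch ids: within each class, epochs
# are taken in id order and folds assigned by a seeded shuffle, so the
# assignment (and hence the CV accuracy) does not depend on epoch order.
stratified_folds <- function(labels, ids, k, seed) {
  fold <- integer(length(labels))
  withr::with_seed(as.integer(seed), {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[order(ids[idx])]
      if (length(idx) < k) {
        abort(paste0("class '", cl, "' has ", length(idx),
                     " epochs, fewer than k = ", k, " folds"))
      }
      fold[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
    }
  })
  fold
}

#' Cross-validated CSP + classifier accuracy
#'
#' Stratified k-fold cross-validation of the full decoding pipeline on a
#' two-class epoch set. Inside every training fold the CSP filters (and
#' the classifier) are re-fit from scratch, so no information from the
#' held-out fold leaks into the spatial filters; the per-epoch band
#' filtering applied beforehand has no data-dependent parameters and is
#' therefore fold-safe.
#'
#' @param epochs An [epoch_set()] containing exactly two label classes
#'   (subset with [filter_epochs()] first if needed).
#' @param m CSP filters per extreme.
#' @param classifier `"lda"` or `"svm"`.
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param window Optional post-onset time window in ms `c(from, to)` to
#'   crop the epochs to before decoding.
#' @param shrinkage Covariance shrinkage, as in [class_covariance()].
#' @param keep_models Keep the per-fold CSP/classifier fits (for audits).
#' @return A `cv_report`: per-fold accuracies, `mean`, `sd`, fold seed and
#'   per-class epoch counts.
#' @export
crossval <- function(epochs, m = 3, classifier = c("lda", "svm"), k = 10,
                     seed = 1, window = NULL, shrinkage = "auto",
                     keep_models = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  classifier <- match.arg(classifier)
  if (!is.null(window)) epochs <- filter_epochs(epochs, window = window)
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2) {
    abort(paste0("cross-validation needs exactly 2 classes, got ",
                 length(classes)))
  }
  fold <- stratified_folds(epochs$labels, epochs$ids, k, seed)
  models <- if (keep_models) vector("list", k) else NULL
  acc <- numeric(k)
  n_test <- integer(k)
  for (f in seq_len(k)) {
    train <- filter_epochs(epochs, idx = which(fold != f))
    test <- filter_epochs(epochs, idx = which(fold == f))
    csp <- fit_csp(filter_epochs(train, labels = classes[1]),
                   filter_epochs(train, labels = classes[2]),
                   m = m, shrinkage = shrinkage)
    ftr <- csp_features(csp, train)
    fte <- csp_features(csp, test)
    clf <- fit_classifier(classifier, ftr, ftr$label)
    pred <- predict(clf, fte)
    acc[f] <- mean(as.character(pred) == fte$label)
    n_test[f] <- nrow(fte)
    if (keep_models) models[[f]] <- list(csp = csp, classifier = clf)
  }
  structure(
    list(folds = tibble(fold = seq_len(k), n_test = n_test, accuracy = acc),
         mean = mean(acc), sd = stats::sd(acc), k = k, seed = seed,
         classes = classes,
         n_per_class = table(epochs$labels), classifier = classifier,
         m = m, models = models),
    class = "cv_report"
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report> ", x$k, "-fold ", toupper(x$classifier),
      " on CSP(m=", x$m, ") features: accuracy ",
      sprintf("%.3f +/- %.3f", x$mean, x$sd), "\n", sep = "")
  invisible(x)
}

#' Sliding-window decoding accuracy
#'
#' Emulates real-time evaluation: the epochs are restricted to successive
#' post-onset windows (500 ms long, advanced in 100 ms steps by default)
#' and the cross-validated pipeline accuracy is recomputed per window.
#' A 0-1000 ms epoch with the defaults yields 6 windows starting at
#' 0, 100, ..., 500 ms.
#'
#' @inheritParams crossval
#' @param win Window length in ms.
#' @param step Step between window starts in ms.
#' @param start_min First window start in ms (post-onset by default).
#' @return A `sliding_window_report` tibble: `window_start`, `window_end`,
#'   `accuracy`, `sd`.
#' @export
sliding_window_eval <- function(epochs, win = 500, step = 100,
                                start_min = 0, m = 3, classifier = "lda",
                                k = 10, seed = 1, shrinkage = "auto") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (win > epochs$tmax - start_min) {
    abort("`win` exceeds the available post-onset epoch span")
  }
  starts <- seq(start_min, epochs$tmax - win, by = step)
  rows <- purrr::map(starts, function(s) {
    cv <- crossval(epochs, m = m, classifier = classifier, k = k,
                   seed = seed, window = c(s, s + win), shrinkage = shrinkage)
    tibble(window_start = s, window_end = s + win,
           accuracy = cv$mean, sd = cv$sd)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "win") <- win
  attr(out, "step") <- step
  class(out) <- c("sliding_window_report", class(out))
  out
}
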