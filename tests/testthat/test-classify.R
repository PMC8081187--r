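gaussian_features <- function(n_per_class, d = 2, sep = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per_class * d, -sep / 2), ncol = d),
               matrix(rnorm(n_per_class * d, sep / 2), ncol = d))
    list(x = x, labels = rep(c("a", "b"), each = n_per_class))
  })
}

test_that("LDA reproduces its closed-form geometry", {
  # well-separated clouds: perfect training accuracy
  g <- gaussian_features(30, sep = 8, seed = 1)
  fit <- fit_lda(g$x, g$labels)
  expect_equal(mean(predict(fit, g$x) == g$labels), 1)
  # 1-D symmetric classes: threshold at 0
  g1 <- list(x = matrix(c(rnorm(50, -1), rnorm(50, 1))),
             labels = rep(c("a", "b"), each = 50))
  withr::with_seed(2, g1$x <- matrix(c(rnorm(200, -1), rnorm(200, 1))))
  g1$labels <- rep(c("a", "b"), each = 200)
  fit1 <- fit_lda(g1$x, g1$labels)
  expect_lt(abs(fit1$bias / fit1$w), 0.2) # threshold near 0
  expect_equal(unname(predict(fit1, matrix(c(-3, 3)))), factor(c("a", "b")))
  expect_error(fit_lda(g$x, rep("a", nrow(g$x))), "class")
})

test_that("LDA matches the reference implementation's predictions", {
  g <- gaussian_features(40, d = 3, sep = 1.5, seed = 3)
  mine <- fit_lda(g$x, g$labels)
  ref <- MASS::lda(g$x, grouping = g$labels)
  test_x <- gaussian_features(25, d = 3, sep = 1.5, seed = 4)$x
  expect_equal(as.character(predict(mine, test_x)),
               as.character(predict(ref, test_x)$class))
})

test_that("degenerate feature covariance falls back to shrinkage", {
  withr::local_seed(5)
  x <- cbind(rnorm(20), 0) # constant second feature
  labels <- rep(c("a", "b"), 10)
  expect_warning(fit <- fit_lda(x, labels), "shrinkage")
  expect_true(all(is.finite(fit$w)))
})

test_that("the RBF-SVM is deterministic and competitive on separable data", {
  g <- gaussian_features(25, sep = 6, seed = 6)
  s1 <- fit_svm_rbf(g$x, g$labels)
  s2 <- fit_svm_rbf(g$x, g$labels)
  grid <- gaussian_features(30, sep = 6, seed = 7)$x
  expect_identical(predict(s1, grid), predict(s2, grid))
  expect_gte(mean(predict(s1, g$x) == g$labels), 0.95)
  expect_error(fit_svm_rbf(g$x, rep("a", nrow(g$x))), "two classes")
})

test_that("cross-validation is stratified, seeded and order-invariant", {
  eps <- planted_band_epochs(n_per_class = 15, seed = 8)
  cv <- crossval(eps, k = 5, seed = 3)
  expect_equal(sum(cv$folds$n_test), 30)
  expect_true(all(abs(cv$folds$n_test - 6) <= 1))
  # same seed, permuted epoch order: identical result
  perm <- withr::with_seed(9, sample(30))
  eps2 <- filter_epochs(eps, idx = perm)
  cv2 <- crossval(eps2, k = 5, seed = 3)
  expect_equal(cv$mean, cv2$mean)
  expect_error(crossval(eps, k = 16, seed = 1), "fewer than")
  # leave-pair-out boundary: k equal to the per-class count still runs
  cvb <- crossval(eps, k = 15, seed = 1)
  expect_true(is.finite(cvb$mean))
})

test_that("training-fold models never see held-out epochs", {
  eps <- planted_band_epochs(n_per_class = 10, seed = 10)
  cv <- crossval(eps, k = 5, seed = 4, keep_models = TRUE)
  # corrupt the *data* of the epochs held out in fold 1; the model whose
  # test set they form must be bit-identical (it trained without them),
  # while other folds (which train on them) must change
  fold <- tactileP300:::stratified_folds(eps$labels, eps$ids, 5, 4)
  eps_cor <- eps
  eps_cor$data[fold == 1, , ] <- 5 * eps_cor$data[fold == 1, , ] + 1
  cv_cor <- crossval(eps_cor, k = 5, seed = 4, keep_models = TRUE)
  expect_identical(cv$models[[1]]$csp$W, cv_cor$models[[1]]$csp$W)
  expect_identical(cv$models[[1]]$classifier$w, cv_cor$models[[1]]$classifier$w)
  expect_false(identical(cv$models[[2]]$csp$W, cv_cor$models[[2]]$csp$W))
})

test_that("accuracy is chance for exchangeable classes and grows with effect size", {
  # identical class distributions: CV accuracy within the 99% binomial band
  null_eps <- planted_band_epochs(n_per_class = 20, amp = 0, seed = 12)
  cv0 <- crossval(null_eps, k = 5, seed = 5)
  half <- stats::qnorm(0.995) * sqrt(0.25 / 40)
  expect_lt(abs(cv0$mean - 0.5), half + 1e-9)
  # monotone in the planted amplitude at three grid points
  acc <- vapply(c(0, 1.5, 4), function(a) {
    crossval(planted_band_epochs(n_per_class = 15, amp = a, seed = 13),
             k = 5, seed = 6)$mean
  }, 0)
  expect_true(all(diff(acc) >= 0))
})

test_that("sliding windows tile the epoch and find the informative span", {
  eps <- planted_band_epochs(n_per_class = 12, interval = c(300, 800),
                             seed = 14)
  sw <- sliding_window_eval(eps, win = 500, step = 100, k = 4, seed = 7)
  expect_equal(sw$window_start, seq(0, 500, by = 100)) # 6 windows
  expect_equal(sw$window_end, sw$window_start + 500)
  # accuracy peaks for (shorter) windows overlapping 300-800 ms
  sw3 <- sliding_window_eval(eps, win = 300, step = 100, k = 4, seed = 7)
  overlap <- pmin(sw3$window_end, 800) - pmax(sw3$window_start, 300)
  expect_gt(min(sw3$accuracy[overlap >= 300]),
            max(sw3$accuracy[overlap <= 0]))
  expect_error(sliding_window_eval(eps, win = 2000), "span")
})

test_that("sliding windows on null data stay near chance", {
  eps <- planted_band_epochs(n_per_class = 12, amp = 0, seed = 15)
  sw <- sliding_window_eval(eps, win = 500, step = 250, k = 4, seed = 8)
  expect_lt(max(abs(sw$accuracy - 0.5)), 0.25)
  expect_lt(abs(mean(sw$accuracy) - 0.5), 0.12)
})
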