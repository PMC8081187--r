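test_that("class covariances are trace-normalized averages", {
  toy <- toy_csp_epochs()
  ca <- class_covariance(toy$a, shrinkage = 0)
  expect_equal(sum(diag(ca)), 1)
  expect_equal(unclass(ca), t(unclass(ca)), ignore_attr = TRUE)
  # identical epochs: average equals the single-epoch normalized covariance
  e1 <- toy$a$data[1, , ]
  e1 <- e1 - rowMeans(e1)
  c1 <- tcrossprod(e1) / (ncol(e1) - 1)
  expect_equal(unclass(ca), c1 / sum(diag(c1)), ignore_attr = TRUE,
               tolerance = 1e-12)
  # white independent channels approach identity / N
  withr::local_seed(5)
  n_ch <- 4; n_ep <- 12; t_len <- 10000
  arr <- array(rnorm(n_ep * n_ch * t_len), c(n_ep, n_ch, t_len))
  eps <- epoch_set(arr, 1000, 0, (t_len - 1), rep("w", n_ep),
                   paste0("ch", 1:n_ch))
  cw <- class_covariance(eps, shrinkage = 0)
  expect_lt(max(abs(unclass(cw) - diag(1 / n_ch, n_ch))), 0.01)
})

test_that("the two-channel toy solves in closed form", {
  toy <- toy_csp_epochs()
  fit <- fit_csp(toy$a, toy$b, m = 1, shrinkage = 0)
  expect_equal(fit$eigenvalues, c(0.8, 0.2), tolerance = 1e-8)
  # filters align with the coordinate axes
  wn <- abs(fit$W / sqrt(rowSums(fit$W^2)))
  expect_equal(sort(apply(wn, 1, max)), c(1, 1), tolerance = 1e-8)
  # whitening identity: W Sa W' + W Sb W' = I
  sa <- tactileP300:::unclass_cov(class_covariance(toy$a, shrinkage = 0))
  sb <- tactileP300:::unclass_cov(class_covariance(toy$b, shrinkage = 0))
  ident <- fit$W %*% sa %*% t(fit$W) + fit$W %*% sb %*% t(fit$W)
  expect_lt(max(abs(ident - diag(2))), 1e-6)
})

test_that("equal class covariances give no discriminative structure", {
  s <- random_spd(3, seed = 1)
  fit <- tactileP300:::csp_from_cov(s, s, m = 1)
  expect_equal(fit$eigenvalues, rep(0.5, 3), tolerance = 1e-10)
})

test_that("the eigen route matches a brute-force oracle for small N", {
  for (n in 2:4) {
    sa <- random_spd(n, seed = n)
    sb <- random_spd(n, seed = n + 10)
    fit <- tactileP300:::csp_from_cov(sa, sb, m = 1)
    oracle <- csp_oracle(sa, sb)
    expect_equal(fit$eigenvalues, oracle$eigenvalues, tolerance = 1e-8)
    # filters match up to sign
    for (j in seq_len(n)) {
      agree <- min(max(abs(fit$W[j, ] - oracle$W[j, ])),
                   max(abs(fit$W[j, ] + oracle$W[j, ])))
      expect_lt(agree, 1e-8)
    }
    # projected class covariances are diagonal and sum to the identity
    pa <- fit$W %*% sa %*% t(fit$W) / 1 # scaled by composite whitening
    pb <- fit$W %*% sb %*% t(fit$W)
    expect_lt(max(abs((pa + pb) - diag(n))), 1e-6)
    expect_lt(max(abs(pa - diag(diag(pa)))), 1e-6)
    expect_lt(max(abs(pb - diag(diag(pb)))), 1e-6)
    # eigenvalue pairing symmetry: lambda_j(A,B) = 1 - lambda_{N+1-j}(B,A)
    fit_rev <- tactileP300:::csp_from_cov(sb, sa, m = 1)
    expect_equal(fit$eigenvalues, 1 - rev(fit_rev$eigenvalues),
                 tolerance = 1e-8)
  }
})

test_that("log-variance features obey their closed forms", {
  toy <- toy_csp_epochs()
  fit <- fit_csp(toy$a, toy$b, m = 1, shrinkage = 0)
  # an epoch whose projected rows have equal variance -> both features log(1/2)
  w <- fit$W[fit$selected_idx, ]
  e <- solve(w) %*% rbind(sin(2 * pi * 3 * (1:120) / 120),
                               cos(2 * pi * 5 * (1:120) / 120))
  f <- csp_features(fit, e)
  expect_equal(unname(unlist(f[, c("csp_1", "csp_2")])), rep(log(1 / 2), 2),
               tolerance = 1e-8)
  # scale invariance
  f2 <- csp_features(fit, 7.3 * e)
  expect_equal(f[, -(1:2)], f2[, -(1:2)], tolerance = 1e-12)
  # features are logs of proportions, hence <= 0
  fa <- csp_features(fit, toy$a)
  expect_true(all(as.matrix(fa[, -(1:2)]) <= 1e-12))
  # the toy classes separate linearly with positive margin
  fb <- csp_features(fit, toy$b)
  expect_gt(min(fa$csp_1) - max(fb$csp_1), 0)
})

test_that("guard rails reject impossible inputs", {
  toy <- toy_csp_epochs()
  expect_error(fit_csp(toy$a, toy$b, m = 2), "2m")
  sa <- random_spd(3, seed = 2)
  expect_error(tactileP300:::csp_from_cov(sa, diag(c(1, -1, 1)), m = 1),
               "positive")
  fit <- fit_csp(toy$a, toy$b, m = 1, shrinkage = 0)
  zero_epoch <- matrix(0, 2, 50)
  expect_error(csp_features(fit, zero_epoch), "zero projected variance")
})

test_that("a planted lateralized source is recovered as an extreme pattern", {
  run <- recovery_run()
  eb <- bandpass(run$post, 4, 20)
  fit <- fit_csp(filter_epochs(eb, labels = "left_attended"),
                 filter_epochs(eb, labels = "right_attended"), m = 3)
  truth <- run$sim$truth
  ext <- fit$patterns[, fit$selected_idx, drop = FALSE]
  best <- max(apply(ext, 2, function(a) {
    max(abs(stats::cor(a, truth$lateral_topography_right)),
        abs(stats::cor(a, truth$lateral_topography_left)))
  }))
  expect_gte(best, 0.9)
})
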