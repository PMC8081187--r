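#' Average normalized class covariance
#'
#' Per epoch, the channel covariance of the centred epoch is computed and
#' trace-normalized (so every trial contributes equally regardless of its
#' broadband power), then averaged over the epochs of the class. An
#' optional Ledoit-Wolf-style shrinkage toward a scaled identity
#' stabilizes the estimate when channels outnumber what the trial count
#' supports (30 channels vs ~1,000-sample epochs); `"auto"` picks the
#' shrinkage intensity from the across-trial dispersion of the per-epoch
#' covariances, `0` disables it. The result always has unit trace.
#'
#' @param epochs An [epoch_set()].
#' @param label Optional label to subset the epochs first.
#' @param shrinkage `"auto"`, or a fixed value in `[0, 1]`.
#' @return A symmetric positive semi-definite matrix with unit trace;
#'   attributes `n_epochs` and `shrinkage`.
#' @export
class_covariance <- function(epochs, label = NULL, shrinkage = "auto") {
  stopifnot(inherits(epochs, "epoch_set"))
  if (!is.null(label)) epochs <- filter_epochs(epochs, labels = label)
  n_ep <- dim(epochs$data)[1]
  if (n_ep < 2) abort("class covariance needs at least 2 epochs")
  n_ch <- dim(epochs$data)[2]
  covs <- array(0, dim = c(n_ch, n_ch, n_ep))
  for (i in seq_len(n_ep)) {
    e <- epochs$data[i, , ]
    e <- e - rowMeans(e)
    c_i <- tcrossprod(e) / (ncol(e) - 1)
    tr <- sum(diag(c_i))
    if (tr <= 0) abort(paste0("epoch ", i, " has zero variance"))
    covs[, , i] <- c_i / tr
  }
  cbar <- apply(covs, c(1, 2), mean)

  gamma <- shrinkage
  if (identical(shrinkage, "auto")) {
    # across-trial analogue of the Ledoit-Wolf intensity: variance of the
    # mean estimate over squared distance from the shrinkage target
    num <- mean(apply(covs, 3, function(ci) sum((ci - cbar)^2))) / n_ep
    target <- diag(sum(diag(cbar)) / n_ch, n_ch)
    den <- sum((cbar - target)^2)
    gamma <- if (den <= 0) 0 else min(1, max(0, num / den))
  }
  if (gamma > 0) {
    cbar <- (1 - gamma) * cbar + gamma * diag(sum(diag(cbar)) / n_ch, n_ch)
  }
  if (min(eigen(cbar, symmetric = TRUE, only.values = TRUE)$values) < 1e-12) {
    warn("class covariance is numerically rank-deficient despite shrinkage")
  }
  structure(cbar, n_epochs = n_ep, shrinkage = gamma)
}

# CSP from two covariance matrices: whiten the composite, rotate by the
# eigenvectors of the whitened class-A covariance. Equivalent to the
# generalized eigenproblem  cov_a w = lambda (cov_a + cov_b) w.
csp_from_cov <- function(cov_a, cov_b, m) {
  n <- nrow(cov_a)
  if (!isTRUE(all.equal(cov_a, t(cov_a), tolerance = 1e-8)) ||
      !isTRUE(all.equal(cov_b, t(cov_b), tolerance = 1e-8))) {
    abort("covariance matrices must be symmetric")
  }
  if (m < 1 || 2 * m > n) abort("need 1 <= m and 2m <= channel count")
  for (s in list(cov_a, cov_b)) {
    if (min(eigen(s, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
      abort("covariance input is not positive semi-definite")
    }
  }
  comp <- cov_a + cov_b
  eg <- eigen((comp + t(comp)) / 2, symmetric = TRUE)
  if (min(eg$values) <= 1e-12 * max(eg$values)) {
    abort("composite covariance is not positive definite")
  }
  p <- diag(1 / sqrt(eg$values), n) %*% t(eg$vectors)
  s_a <- p %*% cov_a %*% t(p)
  es <- eigen((s_a + t(s_a)) / 2, symmetric = TRUE) # eigenvalues descending
  w <- t(es$vectors) %*% p # rows are spatial filters
  lambda <- pmin(pmax(es$values, 0), 1)
  patterns <- solve(w) # columns are scalp patterns

  # sign convention: largest-magnitude pattern coefficient positive,
  # ties broken toward the lowest channel index
  for (j in seq_len(n)) {
    aj <- patterns[, j]
    k <- which(abs(aj) == max(abs(aj)))[1]
    if (aj[k] < 0) {
      patterns[, j] <- -aj
      w[j, ] <- -w[j, ]
    }
  }
  structure(
    list(W = w, eigenvalues = lambda,
         selected_idx = c(seq_len(m), (n - m + 1):n),
         patterns = patterns, n_channels = n, m = m,
         cov_a = cov_a, cov_b = cov_b),
    class = "csp_model"
  )
}

#' Fit Common Spatial Pattern filters
#'
#' Simultaneously diagonalizes the two class covariance matrices: the
#' composite covariance is whitened and rotated by the eigenvectors of the
#' whitened class-A covariance, which solves the generalized eigenproblem
#' `cov_A w = lambda (cov_A + cov_B) w`. Rows of the projection matrix `W`
#' are spatial filters ordered by the class-A variance ratio `lambda`
#' (descending, in `[0, 1]`); the columns of `W^-1` are the corresponding
#' scalp patterns. The `m` filters from each end of the spectrum — the
#' directions with the most extreme between-class variance ratios — are
#' selected for feature extraction.
#'
#' @param epochs_a,epochs_b [epoch_set()]s of the two classes (at least 2
#'   epochs each, same channels).
#' @param m Filters selected per extreme (feature dimension `2m`).
#' @param shrinkage Covariance shrinkage, as in [class_covariance()].
#' @return A `csp_model`: projection matrix `W`, `eigenvalues`,
#'   `selected_idx`, `patterns`, the class covariances and `m`.
#' @export
fit_csp <- function(epochs_a, epochs_b, m = 3, shrinkage = "auto") {
  stopifnot(inherits(epochs_a, "epoch_set"), inherits(epochs_b, "epoch_set"))
  if (!identical(epochs_a$channel_names, epochs_b$channel_names)) {
    abort("the two classes must share the same channels")
  }
  cov_a <- class_covariance(epochs_a, shrinkage = shrinkage)
  cov_b <- class_covariance(epochs_b, shrinkage = shrinkage)
  model <- csp_from_cov(unclass_cov(cov_a), unclass_cov(cov_b), m)
  model$channel_names <- epochs_a$channel_names
  model$classes <- c(epochs_a$labels[1], epochs_b$labels[1])
  model$shrinkage <- c(attr(cov_a, "shrinkage"), attr(cov_b, "shrinkage"))
  model
}

unclass_cov <- function(x) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @export
print.csp_model <- function(x, ...) {
  cat("<csp_model> ", x$n_channels, " channels, m = ", x$m,
      " (", 2 * x$m, " filters selected)\n", sep = "")
  cat("  extreme eigenvalues:",
      paste(signif(x$eigenvalues[x$selected_idx], 3), collapse = ", "), "\n")
  invisible(x)
}

#' Log-variance CSP features
#'
#' Projects each epoch through the selected spatial filters,
#' `Z = W_sel E`, and returns the log of each projected row's variance
#' share, `x_p = log(var(Z_p) / sum_i var(Z_i))` over the `2m` selected
#' rows. Features are scale-invariant (multiplying an epoch by any
#' positive constant leaves them unchanged) and each component is <= 0,
#' being the log of a proportion.
#'
#' @param model A [fit_csp()] result.
#' @param epochs An [epoch_set()] (or a single channels x samples matrix).
#' @return A tibble with one row per epoch: `id`, `label` and feature
#'   columns `csp_1 .. csp_2m`.
#' @export
csp_features <- function(model, epochs) {
  stopifnot(inherits(model, "csp_model"))
  if (is.matrix(epochs)) {
    epochs <- epoch_set(array(epochs, dim = c(1, dim(epochs))), fs = 1,
                        tmin = 0, tmax = (ncol(epochs) - 1) * 1000,
                        labels = NA_character_,
                        channel_names = rownames(epochs) %||%
                          paste0("ch", seq_len(nrow(epochs))))
  }
  if (dim(epochs$data)[2] != model$n_channels) {
    abort("epoch channel count does not match the model")
  }
  w_sel <- model$W[model$selected_idx, , drop = FALSE]
  n_ep <- dim(epochs$data)[1]
  feats <- matrix(0, n_ep, nrow(w_sel))
  for (i in seq_len(n_ep)) {
    z <- w_sel %*% epochs$data[i, , ]
    v <- apply(z, 1, stats::var)
    total <- sum(v)
    if (total <= 0) abort(paste0("epoch ", i, " has zero projected variance"))
    feats[i, ] <- log(v / total)
  }
  colnames(feats) <- paste0("csp_", seq_len(ncol(feats)))
  dplyr::bind_cols(tibble(id = epochs$ids, label = epochs$labels),
                   as_tibble(feats))
}
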