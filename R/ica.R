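# Deflationary FastICA (tanh contrast) after PCA whitening.
#
# Components are extracted one at a time. ICA can only identify
# non-Gaussian directions: in an exactly Gaussian subspace the FastICA
# fixed point update is pure sampling noise and no direction is any more
# "independent" than another. When a component fails to converge we
# therefore treat the remaining (orthogonal) subspace as the unstructured
# residual and complete the basis with it unrotated, which is an equally
# valid decomposition of that subspace. `strict = TRUE` turns this
# situation into an error carrying iteration diagnostics instead.
fastica_unmix <- function(x, n_components = NULL, max_iter = 200,
                          tol = 1e-4, seed = 1, strict = FALSE) {
  n_ch <- nrow(x)
  center <- rowMeans(x)
  xc <- x - center
  cv <- tcrossprod(xc) / (ncol(xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  rank <- sum(eg$values > 1e-10 * eg$values[1])
  if (is.null(n_components)) n_components <- rank # previously-removed components stay out
  p <- n_components
  if (p > rank) {
    abort(paste0("data have numerical rank ", rank,
                 "; reduce `n_components` (requested ", p, ")"))
  }
  K <- diag(1 / sqrt(eg$values[seq_len(p)]), p) %*%
    t(eg$vectors[, seq_len(p), drop = FALSE])
  z <- K %*% xc
  n <- ncol(z)

  W <- matrix(0, p, p)
  iters <- integer(p)
  n_conv <- 0L
  starts <- withr::with_seed(as.integer(seed), matrix(rnorm(p * p), p))
  for (j in seq_len(p)) {
    w <- starts[j, ]
    deflate <- function(v) {
      if (n_conv > 0) {
        wp <- W[seq_len(n_conv), , drop = FALSE]
        v <- v - drop(t(wp) %*% (wp %*% v))
      }
      v / sqrt(sum(v^2))
    }
    w <- deflate(w)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      wz <- drop(w %*% z)
      g <- tanh(wz)
      w_new <- drop(z %*% g) / n - mean(1 - g^2) * w
      if (!all(is.finite(w_new))) {
        abort(paste0("FastICA numerical failure at component ", j,
                     ", iteration ", it))
      }
      w_new <- deflate(w_new)
      d <- abs(1 - abs(sum(w_new * w)))
      w <- w_new
      if (d < tol) { converged <- TRUE; break }
    }
    iters[j] <- it
    if (!converged) {
      if (strict) {
        abort(paste0("FastICA did not converge for component ", j, " after ",
                     max_iter, " iterations (last change ", signif(d, 3),
                     ", tolerance ", tol, "); components 1..", n_conv,
                     " had converged"))
      }
      break
    }
    n_conv <- j
    W[j, ] <- w
  }
  if (n_conv < p) {
    # orthonormal complement of the converged rows, unrotated
    basis <- if (n_conv == 0) diag(p) else
      qr.Q(qr(t(W[seq_len(n_conv), , drop = FALSE])), complete = TRUE)
    W[(n_conv + 1):p, ] <- t(basis[, (n_conv + 1):p, drop = FALSE])
  }
  unmixing <- W %*% K # components x channels, applied to centred data
  mixing <- MASS::ginv(unmixing) # channels x components
  list(unmixing = unmixing, mixing = mixing, center = center,
       iterations = iters, n_converged = n_conv)
}

#' Remove ocular artifact components by ICA
#'
#' Decomposes the recording into maximally independent components
#' (deflationary FastICA with a tanh contrast after whitening) and removes
#' components that look like eye activity under a two-threshold rule:
#' (a) the squared component topography is concentrated on the frontal
#' channels (fraction at least `frontal_frac`), and (b) the component's
#' spectral energy is concentrated below `low_band` Hz (fraction at least
#' `low_frac`). Both conditions must hold. This automates the usual expert
#' screening of blink components, which sit frontally and live in the
#' low-frequency bands. The recording is reconstructed without the flagged
#' components.
#'
#' Directions in which the data are Gaussian are not identifiable by ICA;
#' once component extraction stops converging, the remaining subspace is
#' kept as its unrotated principal axes (see `strict_convergence` to make
#' this an error instead). Blink components are strongly non-Gaussian and
#' are extracted first, so this does not affect artifact screening.
#'
#' @param recording A [continuous_recording()] at least `min_duration`
#'   seconds long (shorter recordings give unstable unmixing).
#' @param n_components Number of components (default: all channels).
#' @param frontal_channels Channels counted as frontal for rule (a).
#' @param low_band Upper edge (Hz) of the "low-frequency" range of rule (b).
#' @param frontal_frac,low_frac The two thresholds. The low-frequency
#'   default (0.75) is set well above the fraction a 1/f background puts
#'   below 3 Hz (~0.45-0.65 per component); planted blink components sit
#'   at 0.9+.
#' @param decimate Estimate the unmixing on every k-th sample (the cleanup
#'   itself always runs at full rate).
#' @param max_iter,tol FastICA iteration controls.
#' @param seed Seed for the random starts.
#' @param min_duration Minimum recording length in seconds.
#' @param strict_convergence Error (with iteration diagnostics) if any
#'   requested component fails to converge.
#' @return The cleaned recording, with attribute `"eog"`: a list holding
#'   `flagged` (component indices), `frontal_fraction`, `lowfreq_fraction`,
#'   `iterations` and `n_converged`.
#' @export
remove_eog <- function(recording, n_components = NULL,
                       frontal_channels = c("Fp1", "Fp2", "F3", "F4", "F7", "F8"),
                       low_band = 3, frontal_frac = 0.6, low_frac = 0.75,
                       decimate = 4, max_iter = 200, tol = 1e-4, seed = 1,
                       min_duration = 30, strict_convergence = FALSE) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (ncol(recording$data) / recording$fs < min_duration) {
    abort(paste0("recording shorter than ", min_duration,
                 " s: too little data for a stable unmixing"))
  }
  frontal_idx <- match(frontal_channels, recording$channel_names)
  frontal_idx <- frontal_idx[!is.na(frontal_idx)]
  if (length(frontal_idx) == 0) abort("none of `frontal_channels` is present")

  est_data <- recording$data[, seq(1, ncol(recording$data), by = decimate),
                             drop = FALSE]
  dec <- fastica_unmix(est_data, n_components, max_iter, tol, seed,
                       strict = strict_convergence)

  center <- rowMeans(recording$data)
  xc <- recording$data - center
  s <- dec$unmixing %*% xc
  a <- dec$mixing
  n_comp <- nrow(s)

  ffrac <- vapply(seq_len(n_comp), function(j) {
    sum(a[frontal_idx, j]^2) / sum(a[, j]^2)
  }, 0)
  lfrac <- vapply(seq_len(n_comp), function(j) {
    p <- welch_psd(s[j, seq(1, ncol(s), by = decimate)],
                   fs = recording$fs / decimate)
    sum(p$psd[p$freq <= low_band]) / sum(p$psd)
  }, 0)
  flagged <- which(ffrac >= frontal_frac & lfrac >= low_frac)

  if (length(flagged) > 0) {
    keep <- setdiff(seq_len(n_comp), flagged)
    xc <- a[, keep, drop = FALSE] %*% s[keep, , drop = FALSE]
    inform(paste0("remove_eog: removed ", length(flagged),
                  " component(s): ", paste(flagged, collapse = ", ")))
  } else if (n_comp < nrow(recording$data)) {
    xc <- a %*% s
  }
  recording$data <- xc + center
  attr(recording, "eog") <- list(flagged = flagged,
                                 frontal_fraction = ffrac,
                                 lowfreq_fraction = lfrac,
                                 iterations = dec$iterations,
                                 n_converged = dec$n_converged)
  recording
}
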