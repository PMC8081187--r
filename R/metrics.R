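#' Bits per decision (Wolpaw formula)
#'
#' `B = log2(N) + P log2(P) + (1 - P) log2((1 - P) / (N - 1))` for an
#' N-choice decision classified correctly with probability P, with the
#' continuity convention `0 * log 0 = 0` at the endpoints. B runs from 0
#' at chance (`P = 1/N`) to `log2(N)` at perfect accuracy and is strictly
#' increasing in P in between; at N = 2 it equals one minus the binary
#' entropy of P.
#'
#' @param P Probability of accurate classification, in `[1/N, 1]`
#'   (vectorized).
#' @param N Number of command categories (>= 2).
#' @return Bits per decision.
#' @examples
#' bits_per_trial(0.95, 2)
#' @export
bits_per_trial <- function(P, N = 2) {
  if (N < 2) abort("`N` must be at least 2")
  if (any(P < 1 / N - 1e-12) || any(P > 1 + 1e-12)) {
    abort(paste0("`P` must lie in [1/N, 1] = [", signif(1 / N, 4), ", 1]"))
  }
  P <- pmin(pmax(P, 1 / N), 1)
  plogp <- ifelse(P > 0, P * log2(P), 0)
  qlogq <- ifelse(P < 1, (1 - P) * log2((1 - P) / (N - 1)), 0)
  log2(N) + plogp + qlogq
}

#' Information transfer rate
#'
#' `ITR = B * M` bits per minute, where B is [bits_per_trial()] and M the
#' number of decisions per minute. The protocol's default M is 9.5238
#' (one 3.15 s trial per decision).
#'
#' @inheritParams bits_per_trial
#' @param M Decisions per minute (> 0).
#' @return ITR in bits/min (full precision; round for presentation).
#' @examples
#' round(itr(1.0, 2, 9.5238), 2) # 9.52
#' round(itr(0.895, 2, 9.5238), 2) # 4.91
#' @export
itr <- function(P, N = 2, M = 9.5238) {
  if (any(M <= 0)) abort("`M` must be > 0")
  bits_per_trial(P, N) * M
}

#' Grand-average ERP
#'
#' Mean and standard error across epochs per channel and time point, with
#' the positive peak searched in a latency window (250-450 ms by default,
#' around the expected P300 latency).
#'
#' @param epochs An [epoch_set()].
#' @param label Optional condition label to average (default: all epochs).
#' @param channels Optional channel subset.
#' @param peak_window Latency search window in ms.
#' @return An `erp_summary`: `avg` and `se` matrices (channels x times),
#'   `times`, `channels`, `n`, and a `peaks` tibble (`channel`,
#'   `peak_amplitude`, `peak_latency_ms`).
#' @export
grand_average <- function(epochs, label = NULL, channels = NULL,
                          peak_window = c(250, 450)) {
  stopifnot(inherits(epochs, "epoch_set"))
  sub <- filter_epochs(epochs, labels = label, channels = channels)
  n <- dim(sub$data)[1]
  if (n < 1) abort("no epochs of the requested condition")
  avg <- apply(sub$data, c(2, 3), mean)
  se <- if (n > 1) apply(sub$data, c(2, 3), stats::sd) / sqrt(n) else avg * 0
  times <- epoch_times(sub)
  widx <- which(times >= peak_window[1] & times <= peak_window[2])
  if (length(widx) == 0) abort("`peak_window` lies outside the epoch")
  peaks <- purrr::map(seq_along(sub$channel_names), function(ch) {
    j <- widx[which.max(avg[ch, widx])]
    tibble(channel = sub$channel_names[ch], peak_amplitude = avg[ch, j],
           peak_latency_ms = times[j])
  })
  structure(
    list(avg = avg, se = se, times = times, channels = sub$channel_names,
         n = n, label = label %||% "all", peaks = dplyr::bind_rows(peaks)),
    class = "erp_summary"
  )
}

#' @export
print.erp_summary <- function(x, ...) {
  cat("<erp_summary> '", x$label, "': n = ", x$n, ", ",
      length(x$channels), " channels, ", length(x$times), " time points\n",
      sep = "")
  invisible(x)
}

#' Paired two-sided t test
#'
#' Classical closed form on the pairwise differences:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom.
#' Identical vectors (all differences zero) give `t = 0`, `p = 1`; a
#' non-zero constant shift has zero-variance differences, which is a
#' degenerate input and raises an error rather than returning an infinite
#' statistic.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 2.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`.
#' @examples
#' paired_compare(c(2, 3, 5), c(1, 2, 3)) # t = 4, p ~ 0.057
#' @export
paired_compare <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    abort("paired comparison needs equal-length vectors of length >= 2")
  }
  d <- values_a - values_b
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    if (all(d == 0)) {
      return(tibble(statistic = 0, df = n - 1, p_value = 1, mean_diff = 0))
    }
    abort("degenerate input: the pairwise differences have zero variance")
  }
  t_stat <- mean(d) / (s / sqrt(n))
  tibble(statistic = t_stat, df = n - 1,
         p_value = 2 * pt(-abs(t_stat), n - 1), mean_diff = mean(d))
}
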