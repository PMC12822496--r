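#' Weighted maximum-likelihood estimate of a normal distribution
#'
#' Weighted mean and ML (denominator sum-of-weights) standard deviation, as
#' used in the EM M-step.
#'
#' @param values numeric vector.
#' @param weights non-negative weights, same length; must not all be zero.
#' @return named numeric vector `c(mean, sd)`.
#' @examples
#' weighted_normal_mle(c(1, 2, 3), c(1, 1, 1))  # mean 2, sd sqrt(2/3)
#' @export
weighted_normal_mle <- function(values, weights = rep(1, length(values))) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  W <- sum(weights)
  if (W <= 0) stop("all weights are zero")
  m <- sum(weights * values) / W
  v <- sum(weights * (values - m)^2) / W
  if (v <= 0) stop("degenerate component: zero weighted variance")
  c(mean = m, sd = sqrt(v))
}

#' Weighted maximum-likelihood estimate of a gamma distribution
#'
#' Solves the weighted gamma ML score equation
#' \deqn{\log k - \psi(k) = \log \bar A - \bar L}
#' where \eqn{\bar A} is the weighted arithmetic mean and \eqn{\bar L} the
#' weighted mean log, with \eqn{\psi} the digamma function; the rate is then
#' \eqn{k / \bar A}.  A Newton iteration on \eqn{k} (derivative
#' \eqn{1/k - \psi'(k)}) is started from the standard closed-form
#' approximation and falls back to guaranteed bracketing if a step leaves
#' the positive half-line.  Near-equal values (score statistic below
#' 1e-12) would send the shape to infinity; the shape is then capped at
#' 1e6 with a warning.
#'
#' @param values strictly positive numeric vector.
#' @param weights non-negative weights, not all zero.
#' @param tol convergence tolerance on the score (default 1e-10).
#' @param max_iter Newton iteration cap.
#' @return named numeric vector `c(shape, rate)`.
#' @examples
#' set.seed(1)
#' weighted_gamma_mle(rgamma(5000, shape = 2, rate = 1))
#' @export
weighted_gamma_mle <- function(values, weights = rep(1, length(values)),
                               tol = 1e-10, max_iter = 200L) {
  stopifnot(length(values) == length(weights), all(weights >= 0))
  if (any(values <= 0)) stop("gamma MLE requires strictly positive values")
  W <- sum(weights)
  if (W <= 0) stop("all weights are zero")
  A <- sum(weights * values) / W
  L <- sum(weights * log(values)) / W
  s <- log(A) - L  # >= 0 by Jensen; 0 only for constant values
  if (!is.finite(s) || s < 1e-12) {
    warning("values (effectively) constant: gamma shape capped at 1e6")
    k <- 1e6
    return(c(shape = k, rate = k / A))
  }
  # Minka/Choi-Wette starting value
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  score <- function(k) log(k) - digamma(k) - s
  # score is strictly decreasing in k; maintain a bracket lo < root < hi
  lo <- NA_real_; hi <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    f <- score(k)
    if (abs(f) < tol) { converged <- TRUE; break }
    if (f > 0) lo <- if (is.na(lo)) k else max(lo, k)
    else hi <- if (is.na(hi)) k else min(hi, k)
    k_new <- k - f / (1 / k - trigamma(k))
    bad <- !is.finite(k_new) || k_new <= 0 ||
      (!is.na(lo) && k_new <= lo) || (!is.na(hi) && k_new >= hi)
    if (bad)
      k_new <- if (!is.na(lo) && !is.na(hi)) sqrt(lo * hi)
               else if (f > 0) k * 2 else k / 2
    k <- k_new
    if (k > 1e6) { k <- 1e6; break }
  }
  if (!converged && abs(score(k)) > 1e-6 && k < 1e6)
    warning("gamma MLE Newton iteration did not fully converge")
  if (k >= 1e6) warning("gamma shape capped at 1e6")
  c(shape = k, rate = k / A)
}
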