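# Closed-form noise theory: the density/CDF of the threshold-minus-distance
# noise difference, the indicator flip probability, and the posterior-error
# bounds that follow from it.

check_b <- function(b) {
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0) {
    stop_invalid("`b` must be a single positive Laplace scale")
  }
  invisible(b)
}

#' Density of the noise difference Z = Lap(b) - Lap(2b)
#'
#' The accept/reject comparison of ABCDP depends on the noise only through
#' `Z = m - nu`, the threshold noise minus the distance noise. Its density
#' is the even function
#' \deqn{f_Z(z) = \frac{1}{6b}\left[2 e^{-|z|/(2b)} - e^{-|z|/b}\right].}
#'
#' @param z Numeric vector of evaluation points.
#' @param b Positive scale of the threshold noise.
#' @return Density values, strictly positive.
#' @export
#' @examples
#' noise_diff_pdf(0, 1)  # 1/6
noise_diff_pdf <- function(z, b) {
  check_b(b)
  (2 * exp(-abs(z) / (2 * b)) - exp(-abs(z) / b)) / (6 * b)
}

#' Upper tail of the noise difference
#'
#' `G_b(a) = P(Z >= a) = (1/6) * [4 exp(-a/(2b)) - exp(-a/b)]` for
#' `a >= 0`. Strictly decreasing from `G_b(0) = 1/2` to 0; this is the
#' function through which all flip probabilities and error bounds are
#' expressed.
#'
#' @param a Nonnegative numeric vector.
#' @inheritParams noise_diff_pdf
#' @return Tail probabilities in (0, 1/2].
#' @export
#' @examples
#' flip_tail_G(0, 1)  # 0.5
flip_tail_G <- function(a, b) {
  check_b(b)
  if (any(a < 0)) stop_invalid("`a` must be nonnegative")
  (4 * exp(-a / (2 * b)) - exp(-a / b)) / 6
}

#' CDF of the noise difference
#'
#' `F_Z(a) = H(a) + (1 - 2 H(a)) * G_b(|a|)` with the Heaviside convention
#' `H(0) = 1` (at `a = 0` both conventions give 1/2, so the choice is
#' observationally irrelevant; it is fixed for determinism).
#'
#' @param a Numeric vector.
#' @inheritParams noise_diff_pdf
#' @return Probabilities in \[0, 1\], with `F_Z(-a) = 1 - F_Z(a)`.
#' @export
noise_diff_cdf <- function(a, b) {
  check_b(b)
  H <- as.numeric(a >= 0)
  H + (1 - 2 * H) * flip_tail_G(abs(a), b)
}

#' Probability that ABCDP flips a rejection-ABC indicator
#'
#' At a step with raw distance `rho_t`, the private indicator differs from
#' the non-private one with probability `G_b(|rho_t - epsilon_abc|)`,
#' regardless of which side of the threshold the distance falls on. The
#' probability is 1/2 exactly at the threshold and decays exponentially in
#' the gap at rate `1/(2b)`.
#'
#' With `b = 0` (the non-private sentinel) the flip probability is 0 by
#' convention: the noise-free mechanism never flips.
#'
#' @param rho_t Nonnegative raw distance(s); vectorized.
#' @param epsilon_abc The ABC threshold.
#' @param b Nonnegative Laplace scale of the threshold noise.
#' @return Flip probabilities in \[0, 1/2\].
#' @export
#' @examples
#' flip_probability(0.2, 0.2, b = 0.1)  # 0.5 at the threshold
flip_probability <- function(rho_t, epsilon_abc, b) {
  if (any(rho_t < 0)) stop_invalid("`rho_t` must be nonnegative")
  if (identical(b, 0) || isTRUE(b == 0)) return(rep(0, length(rho_t)))
  flip_tail_G(abs(rho_t - epsilon_abc), b)
}

#' Bound on the expected posterior-expectation error
#'
#' The expected L2 distance between the private and non-private posterior
#' expectations of a function `f` over the same stream is at most
#' \deqn{\frac{2 K_T}{c'} \sum_t G_b(|\rho_t - \epsilon_{abc}|),}
#' where `K_T = max_t ||f(theta_t)||_2` and `c'` is the non-private
#' acceptance count. Monotone non-decreasing in `b`: more noise, larger
#' worst-case error.
#'
#' @param rho Vector of raw distances over the stream.
#' @param epsilon_abc The ABC threshold.
#' @param K_T Maximum L2 norm of `f(theta_t)` over the stream (finite).
#' @param c_prime Non-private acceptance count (at least 1).
#' @inheritParams noise_diff_pdf
#' @return The nonnegative bound.
#' @export
expected_error_bound <- function(rho, epsilon_abc, K_T, c_prime, b) {
  c_prime <- check_count(c_prime, "c_prime")
  if (!is.finite(K_T) || K_T < 0) stop_invalid("`K_T` must be finite and >= 0")
  if (K_T == 0) return(0)
  (2 * K_T / c_prime) * sum(flip_tail_G(abs(rho - epsilon_abc), b))
}

#' Tail bound on the posterior-expectation error
#'
#' For any `a > 0`, the probability that the private/non-private gap is at
#' most `a` is at least
#' \deqn{1 - \frac{4 K_T}{3 a c'} \sum_t e^{-|\rho_t - \epsilon_{abc}| / (2b)}.}
#' The bound may be negative, in which case it is vacuous (any probability
#' satisfies it); it is returned as-is with a `"vacuous"` attribute set.
#'
#' @param a Positive error level.
#' @inheritParams expected_error_bound
#' @return The bound (possibly negative), with attribute `vacuous`.
#' @export
error_tail_bound <- function(a, rho, epsilon_abc, K_T, c_prime, b) {
  check_positive_scalar(a, "a")
  c_prime <- check_count(c_prime, "c_prime")
  if (!is.finite(K_T) || K_T < 0) stop_invalid("`K_T` must be finite and >= 0")
  check_b(b)
  val <- 1 - (4 * K_T / (3 * a * c_prime)) *
    sum(exp(-abs(rho - epsilon_abc) / (2 * b)))
  structure(val, vacuous = val < 0)
}
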