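# Privacy accounting: distance sensitivity, budget <-> Laplace-scale
# calibration, and the two noise draws of the mechanism.

#' Sensitivity of the MMD distance
#'
#' With a kernel uniformly bounded by `B_k`, replacing one record of an
#' N-point private dataset changes the (root) MMD distance to any pseudo
#' dataset by at most `2 * sqrt(B_k) / N`. This is the global sensitivity
#' to which the Laplace noise is calibrated.
#'
#' @param N Size of the private dataset (number of records).
#' @param B_k Uniform kernel bound (1 for the Gaussian kernel).
#' @return `2 * sqrt(B_k) / N`.
#' @export
#' @examples
#' mmd_sensitivity(10)     # 0.2
#' mmd_sensitivity(5000)   # 4e-4
mmd_sensitivity <- function(N, B_k = 1) {
  N <- check_count(N, "N")
  check_positive_scalar(B_k, "B_k")
  2 * sqrt(B_k) / N
}

#' Laplace scale from a total privacy budget
#'
#' Releasing up to `c` above-threshold answers over the stream costs
#' `epsilon_total = (c + 1) * delta_rho / b` when the noisy threshold is
#' drawn once (`resample = FALSE`) and `2 * c * delta_rho / b` when it is
#' redrawn after every acceptance (`resample = TRUE`). This solves for the
#' threshold-noise scale `b`; the distance noise uses scale `2 b`.
#' `epsilon_total = Inf` is the supported non-private sentinel and maps to
#' `b = 0` (no noise).
#'
#' @param epsilon_total Total privacy budget (positive, possibly `Inf`).
#' @param c Target number of released acceptances.
#' @param delta_rho Sensitivity of the distance.
#' @param resample Whether the noisy threshold is redrawn after each
#'   acceptance.
#' @return The nonnegative Laplace scale `b`.
#' @seealso [budget_of_noise_scale()] for the inverse map.
#' @export
#' @examples
#' noise_scale(1, c = 5, delta_rho = 0.2)                    # 1.2
#' noise_scale(Inf, c = 5, delta_rho = 0.2)                  # 0
noise_scale <- function(epsilon_total, c, delta_rho, resample = FALSE) {
  check_positive_scalar(epsilon_total, "epsilon_total", allow_inf = TRUE)
  c <- check_count(c, "c")
  check_positive_scalar(delta_rho, "delta_rho")
  if (is.infinite(epsilon_total)) return(0)
  if (resample) 2 * c * delta_rho / epsilon_total
  else (c + 1) * delta_rho / epsilon_total
}

#' Total privacy budget implied by a Laplace scale
#'
#' Inverse of [noise_scale()]: the total budget spent by a run using
#' threshold-noise scale `b`, releasing at most `c` acceptances.
#'
#' @param b Positive Laplace scale of the threshold noise.
#' @inheritParams noise_scale
#' @return The positive total budget `epsilon_total`.
#' @export
#' @examples
#' budget_of_noise_scale(1.2, c = 5, delta_rho = 0.2)  # 1
budget_of_noise_scale <- function(b, c, delta_rho, resample = FALSE) {
  check_positive_scalar(b, "b")
  c <- check_count(c, "c")
  check_positive_scalar(delta_rho, "delta_rho")
  if (resample) 2 * c * delta_rho / b else (c + 1) * delta_rho / b
}

#' Draw zero-mean Laplace noise
#'
#' Inverse-CDF sampling from the caller's RNG stream, so draws are
#' reproducible under `set.seed()`. A scale of exactly 0 returns exact
#' zeros, which makes the non-private reduction (`epsilon_total = Inf`)
#' noise-free rather than approximately so.
#'
#' @param n Number of draws.
#' @param scale Nonnegative Laplace scale; variance is `2 * scale^2`.
#' @return Numeric vector of `n` draws.
#' @export
#' @examples
#' set.seed(1); draw_laplace(3, 1)
#' draw_laplace(3, 0)  # exact zeros
draw_laplace <- function(n, scale) {
  if (!is.numeric(scale) || length(scale) != 1L || is.na(scale) || scale < 0) {
    stop_invalid("`scale` must be a single nonnegative number")
  }
  if (scale == 0) return(rep(0, n))
  u <- runif(n, -0.5, 0.5)
  -scale * sign(u) * log1p(-2 * abs(u))
}

#' Privacy budget for an ABCDP run
#'
#' Bundles the total budget, the acceptance cap, the resampling mode and
#' the distance sensitivity, and derives the Laplace scale `b` via
#' [noise_scale()].
#'
#' @inheritParams noise_scale
#' @return An object of class `abcdp_budget` with fields `epsilon_total`,
#'   `c`, `resample`, `delta_rho` and `noise_scale_b`.
#' @export
#' @examples
#' privacy_budget(1, c = 5, delta_rho = mmd_sensitivity(5000))
privacy_budget <- function(epsilon_total, c, delta_rho, resample = FALSE) {
  b <- noise_scale(epsilon_total, c, delta_rho, resample)
  structure(
    list(epsilon_total = epsilon_total, c = check_count(c, "c"),
         resample = isTRUE(resample), delta_rho = delta_rho,
         noise_scale_b = b),
    class = "abcdp_budget"
  )
}

#' @export
print.abcdp_budget <- function(x, ...) {
  cat("ABCDP privacy budget\n")
  cat("  epsilon_total:", format(x$epsilon_total),
      if (is.infinite(x$epsilon_total)) "(non-private)", "\n")
  cat("  acceptance cap c:", x$c,
      "; resample threshold:", x$resample, "\n")
  cat("  sensitivity delta_rho:", format(x$delta_rho), "\n")
  cat("  Laplace scale b:", format(x$noise_scale_b),
      "(distance noise scale 2b)\n")
  invisible(x)
}
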