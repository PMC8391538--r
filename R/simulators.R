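# Self-contained generative models: the five-component uniform-mixture toy
# model, the cubic outbreak-count model with Gaussian priors, and the lazy
# seeded pair stream that feeds the ABC engines.

#' Ground-truth mixing proportions of the toy mixture model
#'
#' The five-component mixing vector used as the recovery target in the
#' mixture experiments.
#'
#' @return The 5-vector `c(0.25, 0.04, 0.33, 0.04, 0.34)`.
#' @export
mixture_theta_star <- function() c(0.25, 0.04, 0.33, 0.04, 0.34)

#' Sample from the flat Dirichlet prior on the 5-simplex
#'
#' Draws from Dirichlet(1, 1, 1, 1, 1) — the uniform distribution over
#' mixing-proportion vectors — via normalized unit-rate Gamma variates.
#'
#' @param n Number of draws.
#' @return A 5-vector for `n = 1`, otherwise an `n` x 5 matrix with unit
#'   row sums.
#' @export
#' @examples
#' set.seed(1); sum(sample_simplex_prior())  # 1
sample_simplex_prior <- function(n = 1) {
  g <- matrix(rgamma(5 * n, shape = 1), nrow = n)
  theta <- g / rowSums(g)
  if (n == 1) theta[1, ] else theta
}

#' Sample from the five-component uniform mixture
#'
#' The toy likelihood: component i has support \[i - 1, i), so a draw picks
#' a component from `Multinomial(theta)` and then a uniform point within
#' its unit bin. Sampling is deliberately two-stage (component, then
#' position) for exactness and testability of the bin occupancy.
#'
#' @param theta Mixing proportions on the 5-simplex.
#' @param n Number of points.
#' @return An `n` x 1 dataset of points in \[0, 5).
#' @export
#' @examples
#' set.seed(1)
#' range(sample_mixture_data(mixture_theta_star(), 100))
sample_mixture_data <- function(theta, n) {
  if (length(theta) != 5L || any(theta < 0) ||
      abs(sum(theta) - 1) > 1e-8) {
    stop_invalid("`theta` must be a nonnegative 5-vector summing to 1")
  }
  n <- check_count(n, "n")
  comp <- sample.int(5L, n, replace = TRUE, prob = theta)
  matrix(comp - 1 + runif(n), ncol = 1L)
}

#' Evaluate the cubic outbreak-trend curve
#'
#' `y(t) = a3 + a2 * t + a1 * t^2 + a0 * t^3` with the coefficient vector
#' supplied in the order `c(a0, a1, a2, a3)` — cubic term first, intercept
#' last.
#'
#' @param a Numeric 4-vector `c(a0, a1, a2, a3)`.
#' @param t_grid Numeric vector of time points.
#' @return The curve values on `t_grid`.
#' @export
#' @examples
#' polynomial_curve(c(0, 0, 0, 7), 1:5)  # constant 7
polynomial_curve <- function(a, t_grid) {
  if (length(a) != 4L || !all(is.finite(a))) {
    stop_invalid("`a` must be a finite 4-vector c(a0, a1, a2, a3)")
  }
  a[4] + a[3] * t_grid + a[2] * t_grid^2 + a[1] * t_grid^3
}

#' Synthetic daily outbreak counts (stand-in data)
#'
#' Generates a short series of daily case counts from a noisy cubic trend:
#' `count_i = max(0, round(y(t_i) + N(0, noise_sd^2)))` on days
#' `t_i = 1..n_days`. This is a synthetic emulation of an early-epidemic
#' daily-count series (18 days by default, matching the size regime where
#' privacy is hardest); it is generated in-package so all analyses run
#' offline.
#'
#' @param a_true True coefficient vector `c(a0, a1, a2, a3)`; the default
#'   traces a plausible early-outbreak rise from a handful of cases to a
#'   few hundred per day.
#' @param n_days Number of days (default 18).
#' @param noise_sd Standard deviation of the additive Gaussian count noise
#'   before rounding (default 10 cases).
#' @return A data frame with columns `day` and `count`; the `count` column
#'   is the N = `n_days` dataset (one day's count per record).
#' @export
#' @examples
#' set.seed(1); synthetic_outbreak_counts()
synthetic_outbreak_counts <- function(a_true = c(0.06, -0.4, 5, 0),
                                      n_days = 18, noise_sd = 10) {
  n_days <- check_count(n_days, "n_days")
  if (noise_sd < 0) stop_invalid("`noise_sd` must be nonnegative")
  t_grid <- seq_len(n_days)
  y <- polynomial_curve(a_true, t_grid)
  noise <- if (noise_sd > 0) rnorm(n_days, 0, noise_sd) else 0
  data.frame(day = t_grid, count = pmax(0, round(y + noise)))
}

#' Generate a lazy, seeded stream of parameter/pseudo-data pairs
#'
#' Produces the public simulation stream consumed by the ABC engines:
#' `n_pairs` i.i.d. pairs, where pair t draws `theta_t` from
#' `prior_sampler()` and a pseudo dataset from `data_sampler(theta_t)`.
#' Each pair has its own derived seed, so the stream is (a) reproducible —
#' the same master seed gives bit-identical pairs — and (b) lazy — pairs
#' are simulated only when requested, so ABCDP's early stop skips the
#' simulation of unvisited steps.
#'
#' @param prior_sampler Function of no arguments returning a parameter
#'   vector.
#' @param data_sampler Function of a parameter vector returning a dataset.
#' @param n_pairs Stream length T.
#' @param seed Master seed for the stream.
#' @return An object of class `abcdp_stream` with fields `size` and
#'   `get(t)`; `get(t)` returns `list(theta, data, index = t)`.
#' @export
#' @examples
#' s <- generate_pair_stream(function() runif(1),
#'                           function(th) matrix(rnorm(5, th), ncol = 1),
#'                           n_pairs = 10, seed = 42)
#' s$get(3)$index  # 3
generate_pair_stream <- function(prior_sampler, data_sampler, n_pairs,
                                 seed) {
  n_pairs <- check_count(n_pairs, "n_pairs")
  pair_seeds <- with_preserved_seed(seed,
                                    sample.int(2147483646L, n_pairs))
  get <- function(t) {
    t <- check_count(t, "t")
    if (t > n_pairs) stop_invalid("stream index out of range")
    with_preserved_seed(pair_seeds[t], {
      theta <- prior_sampler()
      list(theta = theta, data = data_sampler(theta), index = t)
    })
  }
  structure(list(size = n_pairs, get = get, seed = seed),
            class = "abcdp_stream")
}

#' @export
print.abcdp_stream <- function(x, ...) {
  cat("Lazy simulation stream:", x$size, "pair(s)",
      if (!is.null(x$seed)) paste0("(seed ", x$seed, ")"), "\n")
  invisible(x)
}

#' Pair stream for the uniform-mixture toy model
#'
#' Convenience wrapper: flat Dirichlet prior over mixing proportions,
#' pseudo datasets of `n_per_dataset` mixture draws each.
#'
#' @param n_pairs Stream length T.
#' @param n_per_dataset Points per pseudo dataset.
#' @param seed Master seed.
#' @return An `abcdp_stream`.
#' @export
mixture_pair_stream <- function(n_pairs, n_per_dataset, seed) {
  generate_pair_stream(
    prior_sampler = function() sample_simplex_prior(),
    data_sampler = function(theta) sample_mixture_data(theta, n_per_dataset),
    n_pairs = n_pairs, seed = seed
  )
}

#' Pair stream for the cubic outbreak-count model
#'
#' Standard-normal priors on all four polynomial coefficients; each pseudo
#' dataset is the noise-free cubic curve evaluated on days `1..n_days`,
#' floored at zero and rounded to counts (the stochasticity of the model
#' lives in the prior over coefficients).
#'
#' @param n_pairs Stream length T.
#' @param n_days Days per pseudo series (default 18).
#' @param seed Master seed.
#' @return An `abcdp_stream`.
#' @export
polynomial_pair_stream <- function(n_pairs, n_days = 18, seed) {
  t_grid <- seq_len(n_days)
  generate_pair_stream(
    prior_sampler = function() rnorm(4),
    data_sampler = function(a) {
      matrix(pmax(0, round(polynomial_curve(a, t_grid))), ncol = 1L)
    },
    n_pairs = n_pairs, seed = seed
  )
}
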