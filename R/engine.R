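# The c-sample ABCDP engine (sparse-vector accept/reject over a simulated
# stream) and the non-private rejection-ABC baseline.

# Normalize stream input: either an abcdp_stream (lazy, from
# generate_pair_stream) or a plain list of list(theta=, data=) pairs.
as_pair_stream <- function(pairs) {
  if (inherits(pairs, "abcdp_stream")) return(pairs)
  if (is.list(pairs) && length(pairs) >= 1L &&
      all(vapply(pairs, function(p) is.list(p) && !is.null(p$theta) &&
                   !is.null(p$data), logical(1)))) {
    force(pairs)
    return(structure(
      list(size = length(pairs),
           get = function(t) {
             p <- pairs[[t]]
             list(theta = p$theta, data = p$data, index = t)
           }),
      class = "abcdp_stream"))
  }
  stop_invalid("`pairs` must be an abcdp_stream or a nonempty list of ",
               "list(theta = , data = ) pairs")
}

# Core sparse-vector loop, shared by run_abcdp() and svt_indicators().
# get_rho(t) must return the (already clipped) raw distance at step t;
# distances are computed lazily so the early stop skips unneeded simulation.
#
# Noise draw order (fixed for reproducibility): one threshold draw before
# the loop; one distance draw per iteration; on each acceptance, if
# resample, the threshold is redrawn immediately.
svt_core <- function(get_rho, n_steps, epsilon_abc, b, c, resample) {
  indicators <- integer(n_steps)
  raw <- noisy <- thresholds <- numeric(n_steps)
  eps_hat <- epsilon_abc + draw_laplace(1, b)
  count <- 0L
  t_stop <- n_steps
  for (t in seq_len(n_steps)) {
    rho_t <- get_rho(t)
    rho_hat <- rho_t + draw_laplace(1, 2 * b)
    raw[t] <- rho_t
    noisy[t] <- rho_hat
    thresholds[t] <- eps_hat
    if (rho_hat <= eps_hat) {
      indicators[t] <- 1L
      count <- count + 1L
      if (resample) eps_hat <- epsilon_abc + draw_laplace(1, b)
    }
    if (count >= c) {
      t_stop <- t
      break
    }
  }
  keep <- seq_len(t_stop)
  list(indicators = indicators[keep], raw_distances = raw[keep],
       noisy_distances = noisy[keep], noisy_thresholds = thresholds[keep],
       count = count, termination_step = t_stop)
}

new_trace <- function(core, theta = NULL, private, epsilon_abc, b = 0,
                      c_target = NA_integer_, stream_size) {
  structure(
    list(indicators = core$indicators,
         accepted_indices = which(core$indicators == 1L),
         count = core$count,
         termination_step = core$termination_step,
         stream_size = stream_size,
         raw_distances = core$raw_distances,
         noisy_distances = if (private) core$noisy_distances,
         noisy_thresholds = if (private) core$noisy_thresholds,
         theta = theta,
         private = private,
         epsilon_abc = epsilon_abc,
         noise_scale_b = b,
         c_target = c_target),
    class = "abcdp_trace"
  )
}

#' @export
print.abcdp_trace <- function(x, ...) {
  cat(if (x$private) "ABCDP" else "Rejection ABC", "trace:",
      x$count, "acceptance(s) in", x$termination_step, "of",
      x$stream_size, "steps\n")
  cat("  epsilon_abc:", format(x$epsilon_abc), "\n")
  if (x$private) {
    cat("  Laplace scale b:", format(x$noise_scale_b),
        "; acceptance cap c:", x$c_target, "\n")
    if (x$count < x$c_target) {
      cat("  note: stream exhausted before reaching c (shortfall run)\n")
    }
    cat("  releasable output: indicators and accepted parameters only;\n",
        "  recorded distances are diagnostics, not part of the DP release\n")
  }
  invisible(x)
}

#' Sparse-vector indicators over a sequence of distances
#'
#' The mechanism core of ABCDP, operating on precomputed (clipped)
#' distances: a noisy threshold `epsilon_abc + Lap(b)` is drawn once (and
#' redrawn after each acceptance when `resample`); each distance is
#' perturbed with `Lap(2b)` noise and an indicator `1[noisy distance <=
#' noisy threshold]` is emitted; the loop stops after `c` acceptances.
#' Useful for theory checks and for replaying noise on a fixed stream;
#' [run_abcdp()] adds distance computation on top of this loop.
#'
#' @param rho Numeric vector of nonnegative raw distances, in stream order.
#' @param epsilon_abc The ABC similarity threshold.
#' @param b Nonnegative Laplace scale of the threshold noise (distance
#'   noise has scale `2 * b`); 0 gives the noise-free rule.
#' @param c Acceptance cap (default `Inf`: run the whole sequence).
#' @param resample Whether to redraw the threshold after each acceptance.
#' @return An `abcdp_trace` (without parameter values).
#' @export
#' @examples
#' set.seed(1)
#' svt_indicators(c(0.1, 0.5, 0.02), epsilon_abc = 0.2, b = 0.05)
svt_indicators <- function(rho, epsilon_abc, b, c = Inf, resample = FALSE) {
  stopifnot(is.numeric(rho), length(rho) >= 1L, all(is.finite(rho)))
  core <- svt_core(function(t) rho[t], length(rho), epsilon_abc, b, c,
                   resample)
  new_trace(core, private = TRUE, epsilon_abc = epsilon_abc, b = b,
            c_target = if (is.finite(c)) as.integer(c) else NA_integer_,
            stream_size = length(rho))
}

#' Run the c-sample ABCDP algorithm
#'
#' Streams through parameter/pseudo-data pairs, computes the (clipped)
#' distance of each pseudo dataset to the private observations, and
#' releases differentially private accept/reject indicators via the
#' sparse vector technique: both the ABC threshold and every distance are
#' perturbed with Laplace noise calibrated by the budget, and the run
#' terminates once `c` acceptances have been released (or the stream is
#' exhausted — a valid shortfall: the claimed budget remains an upper
#' bound on the privacy loss).
#'
#' The returned trace records raw and noisy distances for diagnostics and
#' theory checks; these are internal quantities, not part of the private
#' release, which consists of the indicators (and hence the accepted
#' parameters) only.
#'
#' @param observed The private dataset (see [as_dataset()]).
#' @param pairs A pair stream from [generate_pair_stream()] or a list of
#'   `list(theta = , data = )` pairs.
#' @param epsilon_abc The ABC similarity threshold.
#' @param budget A [privacy_budget()]; `epsilon_total = Inf` reduces the
#'   algorithm to (early-stopping) non-private rejection ABC.
#' @param distance A [distance_spec()]; a `"median"` bandwidth must be
#'   resolved against pseudo-data beforehand.
#' @return An `abcdp_trace` with parameter values of all visited steps.
#' @seealso [run_rejection_abc()], [svt_indicators()], [posterior_mean()]
#' @export
run_abcdp <- function(observed, pairs, epsilon_abc, budget, distance) {
  stopifnot(inherits(budget, "abcdp_budget"),
            inherits(distance, "abcdp_distance"))
  stream <- as_pair_stream(pairs)
  observed <- as_dataset(observed)
  rho_fun <- make_distance_fun(distance, observed)
  thetas <- vector("list", stream$size)
  get_rho <- function(t) {
    pair <- stream$get(t)
    thetas[[t]] <<- pair$theta
    rho_fun(pair$data)
  }
  core <- svt_core(get_rho, stream$size, epsilon_abc,
                   budget$noise_scale_b, budget$c, budget$resample)
  theta <- do.call(rbind, thetas[seq_len(core$termination_step)])
  new_trace(core, theta = theta, private = TRUE,
            epsilon_abc = epsilon_abc, b = budget$noise_scale_b,
            c_target = budget$c, stream_size = stream$size)
}

#' Run non-private rejection ABC
#'
#' The classical baseline: accept step t iff the raw distance is at most
#' `epsilon_abc`. Always runs the full stream (no early stop), so private
#' and non-private runs can be compared over the same number of
#' iterations. Deterministic given the stream and observations.
#'
#' @inheritParams run_abcdp
#' @return An `abcdp_trace` with `private = FALSE`.
#' @export
run_rejection_abc <- function(observed, pairs, epsilon_abc, distance) {
  stopifnot(inherits(distance, "abcdp_distance"))
  stream <- as_pair_stream(pairs)
  observed <- as_dataset(observed)
  rho_fun <- make_distance_fun(distance, observed)
  n <- stream$size
  rho <- numeric(n)
  thetas <- vector("list", n)
  for (t in seq_len(n)) {
    pair <- stream$get(t)
    thetas[[t]] <- pair$theta
    rho[t] <- rho_fun(pair$data)
  }
  indicators <- as.integer(rho <= epsilon_abc)
  core <- list(indicators = indicators, raw_distances = rho,
               noisy_distances = NULL, noisy_thresholds = NULL,
               count = sum(indicators), termination_step = n)
  new_trace(core, theta = do.call(rbind, thetas), private = FALSE,
            epsilon_abc = epsilon_abc, stream_size = n)
}

#' ABC posterior expectation from a trace
#'
#' The Monte-Carlo posterior expectation of `f(theta)` over accepted
#' samples, `(1/count) * sum_t f(theta_t) * indicator_t`. With the default
#' identity `f` this is the ABC posterior-mean estimate of the parameter.
#'
#' @param trace An `abcdp_trace`.
#' @param f Function of a single parameter vector; must return a fixed-
#'   length numeric vector. Default: identity.
#' @param thetas Optional list or matrix (rows = steps) of parameter
#'   values for the steps covered by the trace; defaults to the values
#'   recorded in the trace.
#' @return The posterior expectation vector.
#' @export
posterior_mean <- function(trace, f = identity, thetas = NULL) {
  stopifnot(inherits(trace, "abcdp_trace"))
  if (trace$count < 1L) {
    stop_invalid("no accepted samples in the trace; the posterior ",
                 "expectation is undefined (requires at least one ",
                 "acceptance)")
  }
  if (is.null(thetas)) thetas <- trace$theta
  if (is.null(thetas)) {
    stop_invalid("the trace records no parameter values; supply `thetas`")
  }
  if (is.matrix(thetas)) {
    thetas <- lapply(seq_len(nrow(thetas)), function(i) thetas[i, ])
  }
  idx <- trace$accepted_indices
  vals <- lapply(thetas[idx], f)
  Reduce(`+`, vals) / trace$count
}
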