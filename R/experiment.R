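# Experiment runners: configuration handling, the simulate -> baseline ->
# ABCDP -> summaries pipeline, result serialization, and the flip-probability
# table.

default_config <- function() {
  list(
    model = "mixture",
    epsilon_total = Inf,
    epsilon_abc = 0.05,
    c = 10,
    T = 1000,
    n = 1000,
    resample = FALSE,       # FALSE, TRUE, or "both"
    seed = 1,
    theta_star = mixture_theta_star(),
    a_true = c(0.06, -0.4, 5, 0),
    noise_sd = 10,
    n_days = 18,
    distance = list(kind = "mmd", bandwidth = "median", clip = NULL,
                    weights = 1, delta_rho = "auto"),
    observed_csv = NULL
  )
}

#' Build a validated run configuration
#'
#' Merges user settings over the defaults and validates them. The
#' configuration is serialized verbatim into every results bundle so a run
#' can be replayed from its own output.
#'
#' @param ... Named settings overriding the defaults: `model` (`"mixture"`,
#'   `"polynomial"` or `"external-csv"`), `epsilon_total` (number, `Inf`,
#'   or the string `"inf"`), `epsilon_abc`, `c`, `T` (stream length), `n`
#'   (points per dataset, mixture model), `resample` (logical or
#'   `"both"`), `seed`, `distance` (list with `kind`, `bandwidth`
#'   (`"median"` or a number), `clip`, `weights`, `delta_rho` (`"auto"` or
#'   a number)), plus model-specific fields `theta_star`, `a_true`,
#'   `noise_sd`, `n_days`, `observed_csv`.
#' @return A validated config list of class `abcdp_config`.
#' @export
#' @examples
#' run_config(model = "mixture", epsilon_total = 1, c = 10, T = 200, n = 100)
run_config <- function(...) {
  cfg <- utils::modifyList(default_config(), list(...))
  validate_config(cfg)
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [run_config()].
#' @return A validated config list.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

validate_config <- function(cfg) {
  fail <- function(field, msg) {
    stop_invalid("invalid config at `", field, "`: ", msg)
  }
  if (!cfg$model %in% c("mixture", "polynomial", "external-csv")) {
    fail("model", "must be one of mixture, polynomial, external-csv")
  }
  if (identical(cfg$epsilon_total, "inf")) cfg$epsilon_total <- Inf
  if (!is.numeric(cfg$epsilon_total) || cfg$epsilon_total <= 0) {
    fail("epsilon_total", "must be a positive number or \"inf\"")
  }
  if (!is.numeric(cfg$epsilon_abc) || length(cfg$epsilon_abc) != 1L) {
    fail("epsilon_abc", "must be a single number")
  }
  cfg$c <- tryCatch(check_count(cfg$c, "c"),
                    error = function(e) fail("c", conditionMessage(e)))
  cfg$T <- tryCatch(check_count(cfg$T, "T"),
                    error = function(e) fail("T", conditionMessage(e)))
  if (!(isTRUE(cfg$resample) || isFALSE(cfg$resample) ||
        identical(cfg$resample, "both"))) {
    fail("resample", "must be TRUE, FALSE or \"both\"")
  }
  d <- cfg$distance
  if (!d$kind %in% c("mmd", "weighted_l2")) {
    fail("distance.kind", "must be mmd or weighted_l2")
  }
  if (d$kind == "weighted_l2" && identical(d$delta_rho, "auto")) {
    fail("distance.delta_rho",
         "must be numeric for weighted_l2 (no derivable sensitivity)")
  }
  structure(cfg, class = "abcdp_config")
}

# Build a distance_spec from the config's distance block (bandwidth still
# possibly "median"; resolved later against pseudo-data).
config_distance_spec <- function(cfg, bandwidth = NULL) {
  d <- cfg$distance
  if (d$kind == "mmd") {
    bw <- if (!is.null(bandwidth)) bandwidth else d$bandwidth
    distance_spec("mmd", kernel = kernel_spec(bw), clip = d$clip,
                  sensitivity = d$delta_rho)
  } else {
    distance_spec("weighted_l2", weights = d$weights, clip = d$clip,
                  sensitivity = d$delta_rho)
  }
}

build_observed <- function(cfg) {
  switch(cfg$model,
    mixture = sample_mixture_data(cfg$theta_star, cfg$n),
    polynomial = as_dataset(
      synthetic_outbreak_counts(cfg$a_true, cfg$n_days, cfg$noise_sd)$count),
    `external-csv` = {
      if (is.null(cfg$observed_csv)) {
        stop_invalid("invalid config at `observed_csv`: required for ",
                     "model external-csv")
      }
      as_dataset(utils::read.csv(cfg$observed_csv))
    })
}

build_stream <- function(cfg, seed) {
  switch(cfg$model,
    mixture = mixture_pair_stream(cfg$T, cfg$n, seed),
    polynomial = polynomial_pair_stream(cfg$T, cfg$n_days, seed),
    `external-csv` = NULL)
}

#' Run a full ABCDP experiment
#'
#' Executes the whole pipeline for one configuration: simulate the
#' observed data and the public pair stream, resolve the kernel bandwidth
#' on pseudo-data (median heuristic), run the non-private rejection-ABC
#' baseline and ABCDP (one or both threshold-resampling modes) over the
#' same stream, and compute posterior summaries, theory bounds and the
#' privacy accounting. Optionally writes a results bundle to disk.
#'
#' Seeds are derived from `config$seed` by a fixed counter scheme
#' (observed data, stream, then one noise seed per private mode), so a
#' bundle can be replayed bit-identically from its embedded config.
#'
#' @param config An `abcdp_config` from [run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional directory; if given, writes `results.json`
#'   (privacy-safe release: indicators, accepted parameters, accounting),
#'   `accepted_theta_<mode>.csv` and `config.yaml`.
#' @param pairs Optional pre-built pair stream (required for
#'   `model = "external-csv"`).
#' @return A results bundle (class `abcdp_results`): config, traces,
#'   posterior summaries, theory bounds, accounting.
#' @export
#' @examples
#' res <- run_experiment(run_config(T = 50, n = 50, c = 5,
#'                                  epsilon_total = 1, seed = 7))
#' res$accounting
run_experiment <- function(config, out_dir = NULL, pairs = NULL) {
  stopifnot(inherits(config, "abcdp_config"))
  cfg <- config
  seed_obs <- derive_seed(cfg$seed, 1L)
  seed_stream <- derive_seed(cfg$seed, 2L)

  observed <- with_preserved_seed(seed_obs, build_observed(cfg))
  stream <- if (!is.null(pairs)) as_pair_stream(pairs) else
    build_stream(cfg, seed_stream)
  if (is.null(stream)) {
    stop_invalid("model external-csv requires a `pairs` stream")
  }

  # Bandwidth from pseudo-data only (no privacy cost): pool the first few
  # pseudo datasets, capped at 1000 points.
  dspec <- cfg$distance
  if (dspec$kind == "mmd" && identical(dspec$bandwidth, "median")) {
    n_pool <- min(20L, stream$size)
    pool <- lapply(seq_len(n_pool), function(t) stream$get(t)$data)
    bw <- median_heuristic_bandwidth(pool, subsample_seed = seed_stream)
  } else {
    bw <- dspec$bandwidth
  }
  distance <- config_distance_spec(cfg, bandwidth = bw)
  delta_rho <- resolve_sensitivity(distance, nrow(observed))

  # Baseline pass computes every raw distance once; the private runs replay
  # noise over the same distances (the algorithm's accept rule depends on
  # the data only through them).
  baseline <- run_rejection_abc(observed, stream, cfg$epsilon_abc, distance)
  truth <- switch(cfg$model, mixture = cfg$theta_star,
                  polynomial = cfg$a_true, NULL)

  modes <- if (identical(cfg$resample, "both")) c(FALSE, TRUE) else
    cfg$resample
  private <- list()
  for (i in seq_along(modes)) {
    rs <- modes[i]
    budget <- privacy_budget(cfg$epsilon_total, cfg$c, delta_rho,
                             resample = rs)
    noise_seed <- derive_seed(cfg$seed, 2L + i)
    trace <- with_preserved_seed(noise_seed,
      svt_indicators(baseline$raw_distances, cfg$epsilon_abc,
                     budget$noise_scale_b, c = budget$c, resample = rs))
    trace$theta <- baseline$theta
    mode_res <- summarize_mode(trace, baseline, budget, cfg, truth)
    private[[if (rs) "resample_true" else "resample_false"]] <- mode_res
  }

  baseline_summary <- list(
    count = baseline$count,
    posterior_mean = if (baseline$count >= 1) posterior_mean(baseline),
    mse = if (baseline$count >= 1 && !is.null(truth)) {
      mean((posterior_mean(baseline) - truth)^2)
    }
  )

  bundle <- structure(
    list(config = cfg, observed_n = nrow(observed), bandwidth = bw,
         delta_rho = delta_rho, baseline = baseline_summary,
         baseline_trace = baseline, private = private),
    class = "abcdp_results")
  if (!is.null(out_dir)) write_results(bundle, out_dir)
  bundle
}

summarize_mode <- function(trace, baseline, budget, cfg, truth) {
  accepted <- trace$theta[trace$accepted_indices, , drop = FALSE]
  pm <- if (trace$count >= 1) posterior_mean(trace) else NULL
  norms <- sqrt(rowSums(baseline$theta^2))
  theory <- if (budget$noise_scale_b > 0 && baseline$count >= 1) {
    list(expected_error_bound = expected_error_bound(
      baseline$raw_distances, cfg$epsilon_abc, K_T = max(norms),
      c_prime = baseline$count, b = budget$noise_scale_b))
  }
  list(
    trace = trace,
    accepted_theta = accepted,
    posterior_mean = pm,
    mse = if (!is.null(pm) && !is.null(truth)) mean((pm - truth)^2),
    no_acceptances = trace$count == 0L,
    shortfall = trace$count < budget$c,
    theory = theory,
    accounting = list(
      epsilon_total_claimed = budget$epsilon_total,
      noise_scale_b = budget$noise_scale_b,
      delta_rho = budget$delta_rho,
      resample = budget$resample,
      c_target = budget$c,
      acceptances_released = trace$count,
      termination_step = trace$termination_step
    )
  )
}

#' @export
print.abcdp_results <- function(x, ...) {
  cat("ABCDP experiment (model:", x$config$model, ", seed:",
      x$config$seed, ")\n")
  cat("  baseline rejection ABC:", x$baseline$count, "acceptance(s)\n")
  for (nm in names(x$private)) {
    acc <- x$private[[nm]]$accounting
    cat("  ", nm, ": ", acc$acceptances_released, " acceptance(s), ",
        "epsilon_total = ", format(acc$epsilon_total_claimed),
        ", b = ", format(acc$noise_scale_b), "\n", sep = "")
  }
  invisible(x)
}

# Privacy-safe serialization: the JSON release contains the indicators,
# accepted parameters and accounting; raw/noisy distances stay in the
# in-memory trace only.
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  release <- list(
    config = unclass(bundle$config),
    bandwidth = bundle$bandwidth,
    delta_rho = bundle$delta_rho,
    baseline = bundle$baseline,
    private = lapply(bundle$private, function(m) {
      list(indicators = m$trace$indicators,
           accepted_theta = m$accepted_theta,
           posterior_mean = m$posterior_mean,
           mse = m$mse,
           no_acceptances = m$no_acceptances,
           accounting = m$accounting)
    })
  )
  jsonlite::write_json(release, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  for (nm in names(bundle$private)) {
    acc <- bundle$private[[nm]]$accepted_theta
    if (!is.null(acc) && nrow(acc) > 0) {
      utils::write.csv(as.data.frame(acc),
                       file.path(out_dir, paste0("accepted_theta_", nm,
                                                 ".csv")),
                       row.names = FALSE)
    }
  }
  cfg_out <- unclass(bundle$config)
  cfg_out$epsilon_total <- if (is.infinite(cfg_out$epsilon_total)) "inf"
    else cfg_out$epsilon_total
  cfg_out$distance <- lapply(cfg_out$distance,
                             function(v) if (is.null(v)) NULL else v)
  yaml::write_yaml(cfg_out, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Flip-probability table over a privacy-design grid
#'
#' For each combination of dataset size N, acceptance cap c and total
#' budget, derives the Laplace scale from the budget calibration (with the
#' MMD sensitivity `2 * sqrt(B_k) / N`) and evaluates the closed-form flip
#' probability at each supplied distance value. This is the design table a
#' data owner consults to choose c for a given N and budget: it shows how
#' likely each released indicator is to differ from the non-private one.
#'
#' @param N_grid Dataset sizes.
#' @param c_grid Acceptance caps.
#' @param eps_total_grid Total budgets (may include `Inf`).
#' @param rho Distance values at which to evaluate the flip probability.
#' @param epsilon_abc ABC threshold (default 0.2).
#' @param B_k Kernel bound (default 1).
#' @param resample Threshold-resampling mode for the calibration.
#' @return A data frame with columns `N`, `c`, `epsilon_total`, `b`,
#'   `rho`, `flip_prob`.
#' @export
#' @examples
#' flip_prob_table(10, 10, c(1, 10), rho = c(0.1, 0.5))
flip_prob_table <- function(N_grid, c_grid, eps_total_grid, rho,
                            epsilon_abc = 0.2, B_k = 1, resample = FALSE) {
  stopifnot(length(N_grid) >= 1, length(c_grid) >= 1,
            length(eps_total_grid) >= 1, length(rho) >= 1)
  grid <- expand.grid(N = N_grid, c = c_grid,
                      epsilon_total = eps_total_grid,
                      rho = rho, KEEP.OUT.ATTRS = FALSE)
  grid$b <- mapply(function(N, cc, eps) {
    noise_scale(eps, cc, mmd_sensitivity(N, B_k), resample)
  }, grid$N, grid$c, grid$epsilon_total)
  grid$flip_prob <- mapply(function(r, b) flip_probability(r, epsilon_abc, b),
                           grid$rho, grid$b)
  grid[, c("N", "c", "epsilon_total", "b", "rho", "flip_prob")]
}
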