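small_cfg <- function(...) {
  run_config(model = "mixture", T = 60, n = 60, c = 3,
             epsilon_abc = 0.25, seed = 17, ...)
}

test_that("config validation reports the offending field", {
  expect_error(run_config(model = "nope"), "`model`")
  expect_error(run_config(epsilon_total = -1), "`epsilon_total`")
  expect_error(run_config(c = 0.5), "`c`")
  expect_error(run_config(resample = "sometimes"), "`resample`")
  expect_error(run_config(distance = list(kind = "weighted_l2",
                                          delta_rho = "auto")),
               "delta_rho")
  cfg <- run_config(epsilon_total = "inf")
  expect_identical(cfg$epsilon_total, Inf)
})

test_that("YAML configs round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("model: mixture", "epsilon_total: 2.5", "epsilon_abc: 0.1",
               "c: 4", "T: 30", "n: 20", "seed: 5"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "abcdp_config")
  expect_equal(cfg$epsilon_total, 2.5)
  expect_equal(cfg$T, 30L)
  expect_equal(cfg$c, 4L)
})

test_that("infinite budget makes the private run reproduce the baseline", {
  res <- run_experiment(small_cfg(epsilon_total = Inf, resample = "both"))
  for (mode in res$private) {
    expect_identical(mode$accounting$noise_scale_b, 0)
    k <- mode$trace$termination_step
    expect_identical(mode$trace$indicators,
                     res$baseline_trace$indicators[seq_len(k)])
    if (!mode$no_acceptances && mode$accounting$acceptances_released ==
        res$baseline$count) {
      expect_equal(mode$posterior_mean, res$baseline$posterior_mean)
    }
  }
})

test_that("a results bundle replays bit-identically from its config", {
  res1 <- run_experiment(small_cfg(epsilon_total = 1))
  res2 <- run_experiment(res1$config)
  expect_identical(res1$private$resample_false$trace$indicators,
                   res2$private$resample_false$trace$indicators)
  expect_equal(res1$baseline_trace$raw_distances,
               res2$baseline_trace$raw_distances)
  expect_equal(res1$bandwidth, res2$bandwidth)
})

test_that("results are serialized without raw distances", {
  out <- withr::local_tempdir()
  res <- run_experiment(small_cfg(epsilon_total = 1), out_dir = out)
  expect_true(file.exists(file.path(out, "results.json")))
  expect_true(file.exists(file.path(out, "config.yaml")))
  released <- jsonlite::read_json(file.path(out, "results.json"))
  expect_null(released$private$resample_false$raw_distances)
  expect_false(grepl("raw_distances",
                     paste(readLines(file.path(out, "results.json")),
                           collapse = "")))
  acc <- released$private$resample_false$accounting
  expect_equal(acc$acceptances_released,
               res$private$resample_false$trace$count)
  # accepted parameters CSV matches the release
  csv <- file.path(out, "accepted_theta_resample_false.csv")
  if (res$private$resample_false$trace$count > 0) {
    expect_equal(nrow(utils::read.csv(csv)),
                 res$private$resample_false$trace$count)
  }
  # the embedded config replays: same indicators
  cfg2 <- read_run_config(file.path(out, "config.yaml"))
  res2 <- run_experiment(cfg2)
  expect_identical(res$private$resample_false$trace$indicators,
                   res2$private$resample_false$trace$indicators)
})

test_that("accounting matches the closed-form budget for the mode run", {
  res <- run_experiment(small_cfg(epsilon_total = 2, resample = "both"))
  dr <- res$delta_rho
  expect_equal(dr, mmd_sensitivity(60))
  accF <- res$private$resample_false$accounting
  accT <- res$private$resample_true$accounting
  expect_equal(accF$noise_scale_b, noise_scale(2, 3, dr, resample = FALSE))
  expect_equal(accT$noise_scale_b, noise_scale(2, 3, dr, resample = TRUE))
  expect_equal(budget_of_noise_scale(accF$noise_scale_b, 3, dr, FALSE), 2)
})

test_that("polynomial model runs end to end with explicit sensitivity", {
  cfg <- run_config(model = "polynomial", T = 80, c = 2, epsilon_total = 1,
                    epsilon_abc = 150, seed = 4,
                    distance = list(kind = "weighted_l2", bandwidth = NULL,
                                    clip = 200, weights = 1,
                                    delta_rho = 200))
  res <- run_experiment(cfg)
  expect_equal(res$observed_n, 18)
  expect_equal(res$delta_rho, 200)
  expect_s3_class(res$baseline_trace, "abcdp_trace")
})

test_that("flip-probability table is plumbing over the closed forms", {
  set.seed(70)
  rho <- runif(10)
  tab <- flip_prob_table(N_grid = c(10, 1000), c_grid = c(1, 10),
                         eps_total_grid = c(0.5, Inf), rho = rho,
                         epsilon_abc = 0.2)
  expect_equal(nrow(tab), 2 * 2 * 2 * 10)
  # table values equal direct calls
  for (i in sample(nrow(tab), 10)) {
    b <- noise_scale(tab$epsilon_total[i], tab$c[i],
                     mmd_sensitivity(tab$N[i]))
    expect_equal(tab$b[i], b)
    expect_equal(tab$flip_prob[i], flip_probability(tab$rho[i], 0.2, b))
  }
  # infinite budget: zero flips
  expect_true(all(tab$flip_prob[is.infinite(tab$epsilon_total)] == 0))
  # larger N at fixed (c, eps): stochastically fewer flips
  m10 <- mean(tab$flip_prob[tab$N == 10 & is.finite(tab$epsilon_total)])
  m1000 <- mean(tab$flip_prob[tab$N == 1000 & is.finite(tab$epsilon_total)])
  expect_lt(m1000, m10)
})
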