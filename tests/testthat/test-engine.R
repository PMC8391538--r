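make_toy_stream <- function(n_pairs, n_points = 30, seed = 1) {
  generate_pair_stream(
    prior_sampler = function() runif(1, 0, 3),
    data_sampler = function(th) matrix(rnorm(n_points, mean = th), ncol = 1),
    n_pairs = n_pairs, seed = seed
  )
}

test_that("rejection ABC equals a brute-force filter of the distance list", {
  set.seed(50)
  obs <- matrix(rnorm(30, 1.5), ncol = 1)
  stream <- make_toy_stream(25, seed = 2)
  spec <- distance_spec("mmd", kernel_spec(1))
  tr <- run_rejection_abc(obs, stream, 0.3, spec)
  rho <- vapply(1:25, function(t) {
    mmd_distance(obs, stream$get(t)$data, kernel_spec(1))
  }, numeric(1))
  expect_equal(tr$raw_distances, rho, tolerance = 1e-12)
  expect_identical(tr$indicators, as.integer(rho <= 0.3))
  expect_identical(tr$count, sum(rho <= 0.3))
  expect_identical(tr$termination_step, 25L)  # never early-stops
  # threshold above the MMD sup bound accepts everything; negative rejects all
  expect_true(all(run_rejection_abc(obs, stream, 2, spec)$indicators == 1L))
  expect_true(all(run_rejection_abc(obs, stream, -1, spec)$indicators == 0L))
})

test_that("zero-noise ABCDP reduces to rejection ABC up to its early stop", {
  spec <- distance_spec("mmd", kernel_spec(1))
  for (seed in 1:5) {
    set.seed(seed)
    obs <- matrix(rnorm(30, 1.5), ncol = 1)
    stream <- make_toy_stream(30, seed = seed + 100)
    base <- run_rejection_abc(obs, stream, 0.35, spec)
    budget <- privacy_budget(Inf, c = 3, delta_rho = mmd_sensitivity(30))
    priv <- run_abcdp(obs, stream, 0.35, budget, spec)
    k <- priv$termination_step
    expect_identical(priv$indicators, base$indicators[seq_len(k)])
    expect_equal(priv$raw_distances, base$raw_distances[seq_len(k)])
    expect_lte(priv$count, 3L)
  }
})

test_that("the acceptance cap triggers early termination, shortfalls are valid", {
  set.seed(51)
  # distances alternate below/above the threshold deterministically
  rho <- rep(c(0.01, 5), 10)
  tr <- svt_indicators(rho, epsilon_abc = 0.1, b = 0, c = 4)
  expect_identical(tr$count, 4L)
  expect_identical(tr$termination_step, 7L)  # 4th acceptance at step 7
  expect_identical(tr$accepted_indices, c(1L, 3L, 5L, 7L))
  # fewer sub-threshold steps than c: stream exhausted, run still valid
  tr2 <- svt_indicators(c(0.01, 5, 5), epsilon_abc = 0.1, b = 0, c = 4)
  expect_identical(tr2$count, 1L)
  expect_identical(tr2$termination_step, 3L)
})

test_that("acceptance count never exceeds c under noise", {
  set.seed(52)
  for (i in 1:30) {
    rho <- runif(50, 0, 0.4)
    cc <- sample(1:6, 1)
    tr <- svt_indicators(rho, epsilon_abc = 0.2, b = 0.1, c = cc,
                         resample = i %% 2 == 0)
    expect_lte(tr$count, cc)
    expect_identical(tr$count, sum(tr$indicators))
    expect_identical(tr$accepted_indices, which(tr$indicators == 1L))
  }
})

test_that("single-step flip frequency matches the closed-form probability", {
  # one fixed step: rho = 0.7, eps_abc = 0.2, b = 0.1; non-private
  # indicator is 0, so a flip is an acceptance
  set.seed(53)
  n_rep <- 5000
  flips <- vapply(seq_len(n_rep), function(i) {
    svt_indicators(0.7, epsilon_abc = 0.2, b = 0.1)$indicators[1] != 0L
  }, logical(1))
  p <- flip_probability(0.7, 0.2, 0.1)
  se <- sqrt(p * (1 - p) / n_rep)
  expect_lt(abs(mean(flips) - p), 3 * se)
})

test_that("posterior_mean averages f over accepted parameters", {
  rho <- c(0.5, 0.05, 0.5, 0.02)
  tr <- svt_indicators(rho, epsilon_abc = 0.1, b = 0)
  thetas <- matrix(1:8, ncol = 2, byrow = TRUE)
  expect_equal(posterior_mean(tr, thetas = thetas),
               colMeans(thetas[c(2, 4), ]))
  # single acceptance returns that parameter exactly
  tr1 <- svt_indicators(c(0.5, 0.02, 0.5), epsilon_abc = 0.1, b = 0)
  expect_equal(posterior_mean(tr1, thetas = thetas[1:3, ]), thetas[2, ])
  # all accepted: plain mean; and f is applied
  tr_all <- svt_indicators(rep(0.01, 4), epsilon_abc = 0.1, b = 0)
  expect_equal(posterior_mean(tr_all, thetas = thetas), colMeans(thetas))
  expect_equal(posterior_mean(tr_all, f = function(th) sum(th)^2,
                              thetas = thetas),
               mean(rowSums(thetas)^2))
  # no acceptances is an explicit error
  tr0 <- svt_indicators(rep(5, 3), epsilon_abc = 0.1, b = 0)
  expect_error(posterior_mean(tr0, thetas = thetas[1:3, ]), "accepted")
})

test_that("engine rejects malformed inputs", {
  spec <- distance_spec("mmd", kernel_spec(1))
  budget <- privacy_budget(1, c = 2, delta_rho = 0.1)
  expect_error(run_abcdp(matrix(1), list(), 0.1, budget, spec), "pairs")
  stream <- make_toy_stream(3)
  obs2d <- matrix(rnorm(10), ncol = 2)
  expect_error(run_abcdp(obs2d, stream, 0.1, budget, spec), "dimension")
  expect_error(svt_indicators(numeric(0), 0.1, 0.1), "rho")
})
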