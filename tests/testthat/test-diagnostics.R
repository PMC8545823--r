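test_that("test information and approximate SE follow sqrt(sigma2 / I)", {
  expect_equal(test_information(1, 1), diag(2))
  expect_equal(test_information(0.5, 2), 2 * test_information(0.5, 1))
  expect_equal(diag(test_information(0.087, 40)), rep(40 / 0.087, 2))
  expect_equal(diag(test_information(0.087, 40)), rep(459.77, 2),
               tolerance = 1e-4)
  expect_equal(approx_se(1, 1), 1)
  expect_equal(approx_se(0.087, 40), 0.0466, tolerance = 1e-3)
  # square-root law: quadrupling the test length halves the SE
  expect_equal(approx_se(0.3, 40), approx_se(0.3, 10) / 2)
  # algebraic identity se^2 * I = sigma2
  for (s2 in c(0.01, 0.087, 1.3)) {
    for (I in c(1, 10, 40)) {
      expect_equal(approx_se(s2, I)^2 * I, s2, tolerance = 1e-12)
    }
  }
  expect_error(test_information(0, 10), "positive")
  expect_error(approx_se(-1, 10), "positive")
})

test_that("reliability implements the true-score variance ratio", {
  theta <- cbind(c(-0.4, 0.1, 0.3), c(0.4, -0.1, -0.3))
  v <- apply(theta, 2, var)
  expect_equal(reliability(theta, error_var = 0)$rho, c(1, 1))
  expect_equal(reliability(theta, error_var = v)$rho, c(0, 0))
  # worked arithmetic: var 0.1156, error 0.01734 -> rho = 0.85
  scaled <- theta %*% diag(sqrt(0.1156 / v))
  out <- reliability(scaled, error_var = 0.01734)
  expect_equal(out$rho, c(0.85, 0.85), tolerance = 1e-10)
  # negative reliability is reported, not clipped
  expect_lt(reliability(theta, error_var = 2 * v[1])$rho[1], 0)
  expect_error(reliability(theta[1, , drop = FALSE], error_var = 0.1),
               "at least 2")
  expect_error(reliability(matrix(1, 3, 2), error_var = 0.1), "zero trait")
})

test_that("profile differentiation is the range of dimension totals", {
  expect_equal(differentiation(matrix(5, 4, 3)), 0)
  # printed trait vector of a low-differentiation respondent
  expect_equal(differentiation(matrix(c(-0.08, 0.16, -0.21, 0.13), 1, 4)), 0.37)
  expect_equal(differentiation(matrix(c(10, 30, 20, 30, 70, 40), 2, 3)), 70)
  # invariant to permuting items; equivariant under positive scaling
  set.seed(2)
  m <- matrix(rexp(20), 5, 4)
  expect_equal(differentiation(m[sample(5), ]), differentiation(m))
  expect_equal(differentiation(3.7 * m), 3.7 * differentiation(m))
})

test_that("the exceedance proportion counts ties as exceedances", {
  expect_equal(ppmc_pr(rep(2, 10), 2), 1)
  expect_equal(ppmc_pr(c(1, 2, 3, 4), 2.5), 0.5)
  # brute-force equivalence on random draws
  set.seed(6)
  reps <- rnorm(500)
  obs <- 0.3
  count <- 0
  for (v in reps) if (v >= obs) count <- count + 1
  expect_equal(ppmc_pr(reps, obs), count / 500)
})

test_that("posterior predictive checks are calibrated under the true model", {
  # data simulated from the model itself should rarely flag misfit
  inside <- 0
  for (r in 1:10) {
    sim <- simulate_lim(n_persons = 80, n_items = 6, seed = 100 + r)
    fit <- fit_lim(sim$data, sim$design, n_burnin = 300, n_draws = 450,
                   seed = r, max_theta_stored = 150)
    pp <- ppmc(fit, sim$data, sim$design, n_rep = 200, seed = r)
    expect_true(pp$pr >= 0 && pp$pr <= 1)
    # stored replicate list reproduces pr exactly
    expect_equal(pp$pr, mean(pp$replicated_stats >= pp$observed_stat))
    if (pp$pr >= 0.025 && pp$pr <= 0.975) inside <- inside + 1
  }
  expect_gte(inside, 9)
})

test_that("ppmc warns below 100 replicates and respects the draw budget", {
  sim <- simulate_lim(n_persons = 25, n_items = 4, seed = 55)
  fit <- fit_lim(sim$data, sim$design, n_burnin = 100, n_draws = 150,
                 seed = 1, max_theta_stored = 50)
  expect_warning(pp <- ppmc(fit, sim$data, sim$design, n_rep = 50, seed = 2),
                 "unstable")
  expect_equal(pp$n_rep, 50)
  expect_s3_class(autoplot(pp), "ggplot")
})
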