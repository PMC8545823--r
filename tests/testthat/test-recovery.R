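test_that("recovery metrics reproduce enumerated values", {
  # estimates identical to truth: everything zero
  est0 <- tibble::tibble(replication = 1:3, block = "delta", parameter = "d",
                         estimate = 1.5, truth = 1.5)
  m0 <- recovery_metrics(est0)
  expect_equal(m0$bias, 0)
  expect_equal(m0$rmse, 0)

  # single replication
  m1 <- recovery_metrics(tibble::tibble(
    replication = 1, block = "cov", parameter = "c",
    estimate = 1.1, truth = 1
  ))
  expect_equal(m1$bias, 0.1)
  expect_equal(m1$rmse, 0.1)
  expect_equal(m1$rel_bias, 0.1)
  expect_equal(m1$rel_abs_bias, 0.1)

  # two replications with opposite errors: bias cancels, RMSE does not
  m2 <- recovery_metrics(tibble::tibble(
    replication = 1:2, block = "theta", parameter = "t",
    estimate = c(1.1, 0.9), truth = 1
  ))
  expect_equal(m2$bias, 0)
  expect_equal(m2$rmse, 0.1)

  # RMSE >= |bias| on random instances
  set.seed(14)
  r <- tibble::tibble(replication = 1:20, block = "delta", parameter = "x",
                      estimate = rnorm(20), truth = rnorm(20))
  mr <- recovery_metrics(r)
  expect_gte(mr$rmse, abs(mr$bias))

  # near-zero truths are excluded from relative metrics and listed
  mz <- recovery_metrics(tibble::tibble(
    replication = 1, block = "cov", parameter = "z", estimate = 0.1, truth = 0
  ))
  expect_true(is.na(mz$rel_abs_bias))
  expect_equal(nrow(attr(mz, "excluded")), 1)

  expect_error(recovery_metrics(tibble::tibble(a = 1)), "needs columns")
})

test_that("a smoke recovery run is well-formed and deterministic", {
  cond <- tibble::tibble(n_items = 4, n_persons = 50, correlation = 0.5)
  rec <- run_recovery(cond, n_reps = 2, seed = 3,
                      n_burnin = 150, n_draws = 200)
  expect_s3_class(rec, "lim_recovery")
  expect_equal(rec$convergence$n_reps, 2)
  expect_true(all(c("bias", "rmse", "rel_abs_bias") %in% names(rec$metrics)))
  expect_true(all(c("delta", "theta", "sigma2", "cov") %in% rec$metrics$block))
  # covariance rows carry relative metrics
  cov_rows <- dplyr::filter(rec$metrics, block == "cov")
  expect_true(all(is.finite(cov_rows$rel_abs_bias)))
  expect_true(all(cov_rows$rmse >= abs(cov_rows$bias) - 1e-12))

  rec2 <- run_recovery(cond, n_reps = 2, seed = 3,
                       n_burnin = 150, n_draws = 200)
  expect_identical(rec$metrics$bias, rec2$metrics$bias)
  expect_identical(rec$replications$max_psr, rec2$replications$max_psr)
})

test_that("utility RMSE declines as the sample grows", {
  rmse_at <- function(n_persons) {
    cond <- tibble::tibble(n_items = 10, n_persons = n_persons,
                           correlation = 0.5)
    rec <- run_recovery(cond, n_reps = 3, seed = 19,
                        n_burnin = 600, n_draws = 800)
    mean(dplyr::filter(rec$metrics, block == "delta")$rmse)
  }
  r <- vapply(c(250, 500, 1000), rmse_at, numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("trait estimates shrink toward zero at extreme true values", {
  sim <- simulate_lim(n_persons = 300, n_items = 10, seed = 41)
  fit <- fit_lim(sim$data, sim$design, n_burnin = 400, n_draws = 600, seed = 12)
  th_true <- limcomp:::identify_params(sim$truth$theta_ipsative,
                                       sim$truth$delta, sim$design)$theta
  err <- as.vector(fit$estimates$theta - th_true)
  tru <- as.vector(th_true)
  hi <- tru >= quantile(tru, 0.9)
  lo <- tru <= quantile(tru, 0.1)
  expect_lt(mean(err[hi]), 0)   # high truths under-estimated
  expect_gt(mean(err[lo]), 0)   # low truths over-estimated
  # the bias-on-truth regression slope is negative (prior shrinkage)
  expect_lt(coef(lm(err ~ tru))[2], 0)
})
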