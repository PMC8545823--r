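# Desk-scale MCMC checks; chains are deliberately short, sized so that each
# block runs in seconds while still separating signal from noise.

test_that("fitting refuses degenerate problems", {
  sim <- simulate_lim(n_persons = 5, n_items = 3, n_dims = 2, seed = 1)
  d1 <- lim_design(tibble::tibble(item = 1, A = "a", B = "b"))
  expect_error(fit_lim(sim$data, d1), "not informative")
})

test_that("chains are bit-identical under the same seed and config", {
  sim <- simulate_lim(n_persons = 40, n_items = 4, seed = 21)
  f1 <- fit_lim(sim$data, sim$design, n_burnin = 100, n_draws = 150, seed = 5)
  f2 <- fit_lim(sim$data, sim$design, n_burnin = 100, n_draws = 150, seed = 5)
  expect_identical(f1$draws$delta, f2$draws$delta)
  expect_identical(f1$draws$sigma2, f2$draws$sigma2)
  expect_identical(f1$draws$theta, f2$draws$theta)
  f3 <- fit_lim(sim$data, sim$design, n_burnin = 100, n_draws = 150, seed = 6)
  expect_false(identical(f1$draws$delta, f3$draws$delta))
})

test_that("identification constraints hold exactly on every stored draw", {
  sim <- simulate_lim(n_persons = 50, n_items = 5, seed = 13)
  fit <- fit_lim(sim$data, sim$design, n_burnin = 200, n_draws = 200, seed = 2)
  d <- sim$design
  # per-dimension slot sums of every delta draw vanish
  for (ch in 1:2) {
    for (it in c(1, 100, 200)) {
      del <- fit$draws$delta[it, ch, ]
      ss <- limcomp:::delta_slot_sums(del, d)
      expect_true(all(abs(ss) < 1e-9))
    }
  }
  # every stored trait draw is ipsative
  sums <- apply(fit$draws$theta, c(1, 2, 3), sum)
  expect_true(all(abs(sums) < 1e-9))
  # point estimates inherit both constraints
  expect_true(all(abs(rowSums(fit$estimates$theta)) < 1e-9))
  expect_true(all(abs(limcomp:::delta_slot_sums(
    unname(fit$estimates$delta), d)) < 1e-9))
})

test_that("uninformative equal allocations center the posterior at zero", {
  d <- gen_design(6, 4)
  arr <- array(25, c(40, 6, 4))
  data <- make_composition(arr)
  fit <- fit_lim(data, d, n_burnin = 400, n_draws = 600, seed = 3)
  expect_true(all(abs(fit$estimates$theta) < 0.05))
  expect_true(all(abs(fit$estimates$delta) < 0.05))
})

test_that("the sigma2 full conditional matches the conjugate closed form", {
  sim <- simulate_lim(n_persons = 60, n_items = 6, seed = 17)
  y <- alr_transform(sim$data, sim$design)
  # fix theta and delta at the truth; only sigma2 is sampled
  fit <- fit_lim(y, sim$design, n_chains = 2, n_burnin = 50, n_draws = 1000,
                 seed = 4, project_delta = FALSE,
                 fix = list(theta = sim$truth$theta_ipsative,
                            delta = sim$truth$delta,
                            mu = rep(0, 3), cov = diag(3)))
  # closed form: InvGamma(1 + nIK/2, 1 + SSR/2)
  cells <- limcomp:::design_cells(sim$design)
  mu_cells <- limcomp:::lim_expected_cells(
    limcomp:::theta_free_of(sim$truth$theta_ipsative, sim$design),
    limcomp:::delta_vector(sim$truth$delta, sim$design), sim$design, cells)
  resid <- limcomp:::alr_cell_matrix(y) - mu_cells
  shape <- 1 + length(resid) / 2
  rate <- 1 + sum(resid^2) / 2
  closed_mean <- rate / (shape - 1)
  draws <- as.vector(fit$draws$sigma2)
  mc_se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - closed_mean), 3 * mc_se)
})

test_that("with wide priors and no noise the utilities reach least squares", {
  d <- gen_design(8, 4)
  delta_true <- gen_utilities(d, seed = 6)
  tr <- gen_traits(400, 0.5, 4, seed = 7)
  x <- gen_responses(tr$ipsative, delta_true, sigma2 = 0, design = d, seed = 8)
  y <- alr_transform(x, d)
  fit <- fit_lim(y, d, n_burnin = 200, n_draws = 400, seed = 9,
                 delta_prior_sd = 100, project_delta = FALSE,
                 fix = list(theta = tr$ipsative, sigma2 = 1e-4,
                            mu = rep(0, 3), cov = diag(3)))
  # oracle: minimum-norm least squares on the cell-mean equations
  cells <- limcomp:::design_cells(d)
  target <- as.vector(cells$M %*% limcomp:::delta_vector(delta_true, d))
  # compare fitted cell contrasts (identified combinations), not raw deltas
  est_cells <- as.vector(cells$M %*% unname(fit$estimates$delta[d$statements]))
  expect_lt(max(abs(est_cells - target)), 0.02)
})

test_that("a seeded recovery run tracks the generating utilities", {
  sim <- simulate_lim(n_persons = 500, n_items = 20, seed = 23, sigma2 = 0.087)
  fit <- fit_lim(sim$data, sim$design, n_burnin = 500, n_draws = 750, seed = 10)
  truth_id <- limcomp:::identify_params(sim$truth$theta_ipsative,
                                        sim$truth$delta, sim$design)
  d_true <- limcomp:::delta_vector(truth_id$delta, sim$design)
  d_est <- unname(fit$estimates$delta[sim$design$statements])
  expect_gte(cor(d_est, d_true), 0.95)
  expect_lt(abs(mean(d_est - d_true)), 0.05)
  expect_true(fit$converged)
})
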