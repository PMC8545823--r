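toy_params <- function(design, theta, delta, sigma2 = 1) {
  lim_params(theta = theta, delta = setNames(delta, design$statements),
             sigma2 = sigma2)
}

test_that("expected log ratios follow the trait/utility decomposition", {
  d3 <- gen_design(2, 3)
  # item with utilities [1.5, 0, 0] and a flat trait profile
  delta <- rep(0, length(d3$statements))
  delta[d3$slot_idx[1, ]] <- c(1.5, 0, 0)
  p <- toy_params(d3, matrix(0, 1, 3), delta)
  expect_equal(expected_log_ratio(c(0, 0, 0), 1, p, d3), c(1.5, 0))

  # all-zero parameters give all-zero expectations
  p0 <- toy_params(d3, matrix(0, 1, 3), rep(0, length(d3$statements)))
  expect_equal(expected_log_ratio(c(0, 0, 0), 2, p0, d3), c(0, 0))

  # D = 2 with equal utilities: expectation is the trait contrast
  d2 <- gen_design(2, 2)
  p2 <- toy_params(d2, matrix(c(1, -1), 1, 2), rep(0.3, length(d2$statements)))
  expect_equal(expected_log_ratio(c(1, -1), 1, p2, d2), 2)

  expect_error(expected_log_ratio(c(0.5, 0, 0), 1, p, d3), "sum to zero")
  expect_error(expected_log_ratio(c(0, 0, 0), "nope", p, d3), "unknown item")
})

test_that("person contrasts are item-free and item contrasts are sample-free", {
  set.seed(31)
  d <- gen_design(4, 4)
  S <- length(d$statements)
  theta_n <- c(0.5, -0.2, 0.1, -0.4)
  theta_m <- c(-0.3, 0.6, -0.2, -0.1)

  # test-free: person differences on one item are invariant to any utilities
  base <- NULL
  for (r in 1:100) {
    delta <- rnorm(S)
    p <- toy_params(d, rbind(theta_n, theta_m), delta)
    diff_nm <- expected_log_ratio(theta_n, 2, p, d) -
      expected_log_ratio(theta_m, 2, p, d)
    if (is.null(base)) base <- diff_nm
    expect_equal(diff_nm, base, tolerance = 1e-12)
  }

  # sample-free: item differences for one person are invariant to any traits
  delta <- rnorm(S)
  base <- NULL
  for (r in 1:100) {
    th <- rnorm(4)
    th <- th - mean(th)
    p <- toy_params(d, matrix(th, 1), delta)
    diff_ij <- expected_log_ratio(th, 1, p, d) - expected_log_ratio(th, 3, p, d)
    if (is.null(base)) base <- diff_ij
    expect_equal(diff_ij, base, tolerance = 1e-12)
  }
})

test_that("the log likelihood matches an independent normal-density oracle", {
  set.seed(5)
  d <- gen_design(3, 4)
  S <- length(d$statements)
  N <- 4
  theta <- matrix(rnorm(N * 4), N)
  theta <- theta - rowMeans(theta)
  delta <- rnorm(S, sd = 0.5)
  sigma2 <- 0.3
  p <- toy_params(d, theta, delta, sigma2)
  y <- array(rnorm(N * 3 * 3), c(N, 3, 3))
  class(y) <- "lim_alr"
  attr(y, "reference_dim") <- 4

  expect_equal(lim_log_likelihood(y, p, d),
               loglik_oracle(y, theta, delta, sigma2, d), tolerance = 1e-10)

  # a zero-residual term contributes -0.5 (log sigma2 + log 2 pi)
  d2 <- lim_design(tibble::tibble(item = 1:2, A = c("a1", "a2"), B = c("b1", "b2")))
  p2 <- lim_params(matrix(0, 1, 2), setNames(rep(0, 4), d2$statements), sigma2 = 0.4)
  y2 <- array(0, c(1, 2, 1))
  expect_equal(lim_log_likelihood(y2, p2, d2),
               2 * (-0.5 * (log(0.4) + log(2 * pi))), tolerance = 1e-12)

  # local independence: the total is the sum of per-item totals
  y_a <- y; y_a[, c(2, 3), ] <- 0
  y_b <- y; y_b[, c(1, 3), ] <- 0
  y_c <- y; y_c[, c(1, 2), ] <- 0
  zero_ll <- lim_log_likelihood(structure(array(0, dim(y)), class = "lim_alr"), p, d)
  expect_equal(
    lim_log_likelihood(y_a, p, d) + lim_log_likelihood(y_b, p, d) +
      lim_log_likelihood(y_c, p, d) - 2 * zero_ll,
    lim_log_likelihood(y, p, d), tolerance = 1e-9
  )

  expect_error(lim_params(theta, delta, sigma2 = -1), "positive")
})

test_that("noise-free data are best explained by the generating traits", {
  # 2 persons, D = 3, grid search over sum-zero trait rows
  d <- gen_design(2, 3)
  delta <- setNames(rnorm(length(d$statements), sd = 0.3), d$statements)
  set.seed(9)
  theta_true <- matrix(c(0.6, -0.2, -0.4, -0.4, 0.6, -0.2), 2, byrow = TRUE)
  y <- gen_responses(theta_true, delta, sigma2 = 0, design = d, seed = 1)
  yarr <- alr_transform(y, d)
  grid <- seq(-0.8, 0.8, by = 0.2)
  best <- -Inf; best_theta <- NULL
  for (a1 in grid) for (b1 in grid) for (a2 in grid) for (b2 in grid) {
    th <- rbind(c(a1, b1, -a1 - b1), c(a2, b2, -a2 - b2))
    ll <- lim_log_likelihood(yarr, lim_params(th, delta, sigma2 = 0.05), d)
    if (ll > best) { best <- ll; best_theta <- th }
  }
  expect_equal(best_theta, theta_true, tolerance = 1e-8)
})

test_that("the Thurstonian expectation nests the LIM and follows its slopes", {
  d <- gen_design(3, 3)
  S <- length(d$statements)
  delta <- rnorm(S, sd = 0.4)
  th <- c(0.3, -0.5, 0.2)
  lim_p <- toy_params(d, matrix(th, 1), delta)

  # beta = 1 and pair locations delta_k - delta_D reproduce the LIM exactly
  ref <- d$reference_dim
  ks <- setdiff(seq_len(3), ref)
  loc <- t(vapply(seq_len(3), function(i) {
    delta[d$slot_idx[i, ks]] - delta[d$slot_idx[i, ref]]
  }, numeric(2)))
  tmc_p <- tmc_params(matrix(th, 1), pair_location = loc,
                      slope = setNames(rep(1, S), d$statements), sigma2 = 1)
  for (i in 1:3) {
    expect_equal(tmc_expected_log_ratio(th, i, tmc_p, d),
                 expected_log_ratio(th, i, lim_p, d), tolerance = 1e-12)
  }

  # zero traits return the pair locations themselves
  expect_equal(tmc_expected_log_ratio(c(0, 0, 0), 2, tmc_p, d),
               unname(loc[2, ]))

  # slopes scale the trait contributions: beta [2, 1], theta [0.5, 0.5]
  d2 <- gen_design(2, 2)
  tmc_2 <- tmc_params(matrix(c(0.5, 0.5), 1),
                      pair_location = matrix(0, 2, 1),
                      slope = setNames(rep(c(2, 1), each = 2), d2$statements),
                      sigma2 = 1)
  # statement slopes: slot 1 of each item has slope 2, slot 2 slope 1
  expect_equal(tmc_expected_log_ratio(c(0.5, 0.5), 1, tmc_2, d2), 0.5)
})
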