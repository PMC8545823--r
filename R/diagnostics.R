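#' Fisher information and approximate standard error
#'
#' Under the LIM the second derivative of a person's log likelihood with
#' respect to any trait is `-I / sigma2` (test length I), so the test
#' information matrix is diagonal with entries `I / sigma2` - independent of
#' the trait and utility values - and the approximate standard error of a
#' trait estimate is `sqrt(sigma2 / I)`.
#'
#' @param sigma2 Positive log-ratio noise variance.
#' @param n_items Test length (number of items administered).
#' @param n_dims Size of the returned information matrix (default 2, the
#'   reference dimension plus one other, as the matrix is the same for every
#'   pair).
#' @return `test_information()`: a diagonal matrix with entries
#'   `n_items / sigma2`. `approx_se()`: the scalar `sqrt(sigma2 / n_items)`.
#' @examples
#' test_information(0.087, 40)
#' approx_se(0.087, 40)
#' @export
test_information <- function(sigma2, n_items, n_dims = 2) {
  if (!is.numeric(sigma2) || sigma2 <= 0) abort("`sigma2` must be positive")
  stopifnot(n_items >= 1)
  diag(n_items / sigma2, n_dims)
}

#' @rdname test_information
#' @export
approx_se <- function(sigma2, n_items) {
  if (!is.numeric(sigma2) || sigma2 <= 0) abort("`sigma2` must be positive")
  stopifnot(n_items >= 1)
  sqrt(sigma2 / n_items)
}

#' Reliability of trait estimates
#'
#' Classic true-score reliability per dimension:
#' `rho_d = (var(theta_hat_d) - error_var_d) / var(theta_hat_d)`, the share
#' of observed trait-estimate variance not attributable to estimation error.
#' A negative value (error variance exceeding observed variance) is reported
#' as is, never clipped.
#'
#' @param theta_hat Persons x D matrix of trait point estimates, or a
#'   `lim_fit` (whose posterior means and SDs are used).
#' @param error_var Per-dimension error variance: a length-D vector, a
#'   scalar recycled across dimensions, or `NULL` (allowed only with a
#'   `lim_fit`). For a fit, the default is the per-dimension mean squared
#'   posterior SD; `error = "fisher"` uses the constant `sigma2 / I` from
#'   the information function instead.
#' @param error For a `lim_fit`: `"posterior"` (default) or `"fisher"`.
#' @return A tibble of class `lim_reliability` with columns `dimension`,
#'   `trait_var`, `error_var`, `rho`.
#' @examples
#' theta <- cbind(rnorm(50, sd = 0.4), rnorm(50, sd = 0.4))
#' theta <- theta - rowMeans(theta)
#' reliability(theta, error_var = 0.01)
#' @export
reliability <- function(theta_hat, error_var = NULL,
                        error = c("posterior", "fisher")) {
  error <- match.arg(error)
  dims <- NULL
  if (inherits(theta_hat, "lim_fit")) {
    fit <- theta_hat
    theta_hat <- fit$estimates$theta
    dims <- fit$design$dim_names
    if (is.null(error_var)) {
      error_var <- if (error == "fisher") {
        rep(fit$estimates$sigma2 / fit$design$n_items, ncol(theta_hat))
      } else {
        colMeans(fit$estimates$theta_sd^2)
      }
    }
  }
  theta_hat <- as.matrix(theta_hat)
  if (nrow(theta_hat) < 2) abort("reliability needs at least 2 persons")
  if (is.null(error_var)) abort("`error_var` is required for a plain matrix")
  if (any(error_var < 0)) abort("`error_var` must be nonnegative")
  error_var <- rep(error_var, length.out = ncol(theta_hat))
  v <- apply(theta_hat, 2, var)
  if (any(v == 0)) abort("zero trait variance: reliability undefined")
  out <- tibble::tibble(
    dimension = dims %||% paste0("dim", seq_len(ncol(theta_hat))),
    trait_var = v,
    error_var = error_var,
    rho = (v - error_var) / v
  )
  class(out) <- c("lim_reliability", class(out))
  out
}

#' Profile differentiation of a person's scores
#'
#' Column-sums an I x D matrix of a person's observed scores over items and
#' returns the range (max minus min) of the D dimension totals: how strongly
#' the person's allocations separate the dimensions. A 1 x D matrix of trait
#' point estimates gives the range of the trait profile itself.
#'
#' @param person_scores An I x D numeric matrix (items x dimensions).
#' @return Nonnegative scalar.
#' @examples
#' differentiation(matrix(c(10, 20, 70, 30, 30, 40), 2, 3, byrow = TRUE))
#' @export
differentiation <- function(person_scores) {
  m <- as.matrix(person_scores)
  sums <- colSums(m)
  max(sums) - min(sums)
}

# sum of per-person differentiation over a persons x items x D score array
total_differentiation <- function(arr) {
  persum <- apply(arr, c(1, 3), sum)     # persons x D
  sum(apply(persum, 1, function(r) max(r) - min(r)))
}

#' Posterior predictive model checking
#'
#' For `T` evenly spaced posterior draws, generates a replicated dataset
#' from the fitted LIM (same design, same total), computes the discrepancy
#' statistic - the sum over persons of the profile differentiation of the
#' RAW scores - and reports `pr`, the proportion of replicated statistics at
#' least as large as the observed one. `pr` outside (0.025, 0.975) flags
#' misfit.
#'
#' @param fit A `lim_fit` from [fit_lim()].
#' @param observed The observed [composition_data()] (strictly positive
#'   scores).
#' @param design The [lim_design()] used for the fit.
#' @param n_rep Number of replicated datasets `T` (default 500, capped at
#'   the number of stored trait draws; below 100 a warning flags an
#'   unstable `pr`).
#' @param seed Seed for the replication noise.
#' @return A list of class `lim_ppmc`: `observed_stat`, `replicated_stats`,
#'   `pr`, `percentile` (of the observed statistic among replicates),
#'   `misfit`, `n_rep`, `seed`.
#' @export
ppmc <- function(fit, observed, design, n_rep = 500, seed = 1) {
  stopifnot(inherits(fit, "lim_fit"))
  th <- fit$draws$theta                      # kept x chains x N x D
  n_avail <- dim(th)[1] * dim(th)[2]
  if (n_rep > n_avail) n_rep <- n_avail
  if (n_rep < 100) warn("fewer than 100 replications: pr is unstable")
  obs_arr <- as_score_array(observed, design)
  total <- composition_total(observed)
  obs_stat <- total_differentiation(obs_arr)

  idx <- round(seq(1, n_avail, length.out = n_rep))
  set.seed(seed)
  cells <- design_cells(design)
  N <- dim(th)[3]
  rep_stats <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    i <- ((idx[r] - 1) %% dim(th)[1]) + 1
    ch <- ((idx[r] - 1) %/% dim(th)[1]) + 1
    theta_r <- th[i, ch, , ]
    k <- fit$theta_kept_idx[i]               # matching full-draw index
    delta_r <- fit$draws$delta[k, ch, ]
    sigma2_r <- fit$draws$sigma2[k, ch]
    tf <- theta_free_of(theta_r, design)
    mu_cells <- lim_expected_cells(tf, delta_r, design, cells)
    y_cells <- mu_cells + matrix(rnorm(length(mu_cells), sd = sqrt(sigma2_r)),
                                 nrow(mu_cells))
    y_rep <- cell_matrix_to_alr(y_cells, design)
    x_rep <- alr_inverse(y_rep, total = total, design = design)
    rep_stats[r] <- total_differentiation(x_rep)
  }
  pr <- ppmc_pr(rep_stats, obs_stat)
  structure(list(
    observed_stat = obs_stat, replicated_stats = rep_stats, pr = pr,
    percentile = 100 * mean(rep_stats < obs_stat),
    misfit = pr < 0.025 || pr > 0.975, n_rep = n_rep, seed = seed
  ), class = "lim_ppmc")
}

#' Posterior predictive exceedance proportion
#'
#' The share of replicated discrepancy statistics at least as large as the
#' observed one; ties count as exceedances.
#'
#' @param replicated Numeric vector of replicated statistics.
#' @param observed Observed statistic.
#' @return `mean(replicated >= observed)`.
#' @examples
#' ppmc_pr(c(1, 2, 3, 4), 2.5)
#' @export
ppmc_pr <- function(replicated, observed) {
  mean(replicated >= observed)
}

#' @export
print.lim_ppmc <- function(x, ...) {
  cat(sprintf(
    "<lim_ppmc> observed total differentiation %.2f at the %.1fth percentile of %d replicates; pr = %.3f (%s)\n",
    x$observed_stat, x$percentile, x$n_rep, x$pr,
    if (x$misfit) "misfit" else "acceptable fit"
  ))
  invisible(x)
}

#' @export
autoplot.lim_ppmc <- function(object, ...) {
  df <- tibble::tibble(stat = object$replicated_stats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_stat,
                        colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "sum of profile differentiation (replicated)",
      y = "count",
      title = sprintf("PPMC: observed at percentile %.1f, pr = %.3f",
                      object$percentile, object$pr)
    )
}
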