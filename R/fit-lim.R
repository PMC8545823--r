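# Blocked Gibbs sampler for the LIM posterior
#   P(theta, delta, sigma2, mu, Sigma | Y)
#     propto L(Y | theta, delta, sigma2) MVN(theta_free | mu, Sigma)
#            N(delta | 0, prior_sd^2) N(mu | 0, 1) IW(Sigma | I, D-1)
#            InvGamma(sigma2 | 1, 1)
# All full conditionals are conjugate (linear-Gaussian structure); each block
# is drawn exactly, so no proposal tuning is needed and acceptance is 1.

#' Fit the lognormal ipsative model by MCMC
#'
#' Samples the joint posterior of ipsative person traits, statement
#' utilities, log-ratio noise variance, and the population mean and
#' covariance of the free trait coordinates, using a blocked Gibbs sampler
#' with exact conjugate updates. Only the D-1 free trait coordinates are
#' sampled per person (the reference coordinate is minus their sum); after
#' every sweep the utilities are projected onto the per-dimension
#' slot-sum-zero identification constraint, with the compensating
#' likelihood-invariant shift applied to the traits and `mu`.
#'
#' @param data A [composition_data()] tibble of strictly positive scores, or
#'   a `lim_alr` array from [alr_transform()].
#' @param design The [lim_design()] describing the items.
#' @param n_chains Number of chains (default 2; at least 2 for PSR).
#' @param n_burnin Burn-in sweeps per chain (default 10000).
#' @param n_draws Retained sweeps per chain (default 10000).
#' @param thin Keep every `thin`-th retained sweep (default 1).
#' @param seed Integer seed; chain `c` runs from `seed + c - 1`. The same
#'   (seed, config, data) triple reproduces draws bit for bit.
#' @param psr_threshold Convergence is declared when every monitored
#'   potential scale reduction factor is below this value (default 1.1).
#' @param delta_prior_sd Prior standard deviation of the utilities
#'   (default 1, the standard-normal prior).
#' @param n_monitor_theta How many individual trait scalars join the
#'   monitored set for convergence (default 50, drawn reproducibly).
#' @param max_theta_stored Cap on stored trait draws per chain (default 400);
#'   point estimates and posterior SDs always use every post-burn-in sweep.
#' @param project_delta Apply the identification projection each sweep
#'   (default `TRUE`; only disable for conditional-distribution checks).
#' @param fix Optional named list pinning blocks at fixed values instead of
#'   sampling them: any of `theta` (persons x D), `delta`, `sigma2`, `mu`,
#'   `cov`. Used for conditional-distribution diagnostics.
#' @return A `lim_fit` object; see [tidy.lim_fit()], [glance.lim_fit()],
#'   [psr()], [ppmc()].
#' @examples
#' sim <- simulate_lim(n_persons = 30, n_items = 5, seed = 2)
#' fit <- fit_lim(sim$data, sim$design, n_burnin = 200, n_draws = 300,
#'                seed = 1)
#' glance(fit)
#' @export
fit_lim <- function(data, design, n_chains = 2, n_burnin = 10000,
                    n_draws = 10000, thin = 1, seed = 1,
                    psr_threshold = 1.1, delta_prior_sd = 1,
                    n_monitor_theta = 50, max_theta_stored = 400,
                    project_delta = TRUE, fix = list()) {
  if (design$n_items < 2 || design$n_dims < 2) {
    abort("model not informative: need at least 2 items and 2 dimensions")
  }
  stopifnot(n_chains >= 1, n_burnin >= 0, n_draws >= 1, thin >= 1)
  y <- if (inherits(data, "lim_alr")) data else alr_transform(data, design)
  if (dim(y)[2] != design$n_items || dim(y)[3] != design$n_dims - 1) {
    abort("log-ratio array does not conform to the linkage design")
  }
  Y <- alr_cell_matrix(y)
  persons <- dimnames(y)[[1]] %||% as.character(seq_len(nrow(Y)))

  cfg <- list(
    model = "lim", n_chains = n_chains, n_burnin = n_burnin,
    n_draws = n_draws, thin = thin, seed = seed,
    psr_threshold = psr_threshold, delta_prior_sd = delta_prior_sd,
    project_delta = project_delta
  )
  chains <- lapply(seq_len(n_chains), function(ch) {
    lim_gibbs_chain(Y, design, cfg, chain_seed = seed + ch - 1,
                    max_theta_stored = max_theta_stored, fix = fix)
  })
  finish_fit(chains, design, cfg, persons, y,
             n_monitor_theta = n_monitor_theta, model = "lim")
}

lim_gibbs_chain <- function(Y, design, cfg, chain_seed, max_theta_stored, fix) {
  set.seed(chain_seed)
  N <- nrow(Y)
  D <- design$n_dims
  K <- D - 1
  I <- design$n_items
  S <- length(design$statements)
  cells <- design_cells(design)
  nC <- cells$n_cells
  A <- contrast_matrix(D)
  AtA <- crossprod(A)
  Ainv <- diag(K) - matrix(1, K, K) / D
  M <- cells$M
  MtM <- crossprod(M)
  P0 <- diag(S) / cfg$delta_prior_sd^2
  ks <- cells$ks
  ref <- design$reference_dim
  kpos <- cells$kpos
  kcols <- lapply(seq_len(K), function(k) which(kpos == k))
  stmt_dim <- design$statement_dim

  # initial state: overdispersed around the prior
  Tm <- matrix(rnorm(N * K, sd = 0.5), N, K)
  delta <- rnorm(S, sd = 0.5)
  sigma2 <- stats::runif(1, 0.05, 1)
  mu <- rnorm(K, sd = 0.3)
  Sigma <- diag(K)
  if (!is.null(fix$theta)) Tm <- theta_free_of(fix$theta, design)
  if (!is.null(fix$delta)) delta <- delta_vector(fix$delta, design)
  if (!is.null(fix$sigma2)) sigma2 <- fix$sigma2
  if (!is.null(fix$mu)) mu <- fix$mu
  if (!is.null(fix$cov)) Sigma <- as.matrix(fix$cov)

  n_iter <- cfg$n_burnin + cfg$n_draws
  kept <- seq(cfg$n_burnin + cfg$thin, n_iter, by = cfg$thin)
  n_kept <- length(kept)
  theta_stride <- max(1L, ceiling(n_kept / max_theta_stored))
  theta_kept <- kept[seq(theta_stride, n_kept, by = theta_stride)]

  draw_delta <- matrix(NA_real_, n_kept, S)
  draw_sigma2 <- numeric(n_kept)
  draw_mu <- matrix(NA_real_, n_kept, K)
  draw_cov <- matrix(NA_real_, n_kept, K * K)
  draw_theta <- array(NA_real_, c(length(theta_kept), N, D))
  theta_sum <- matrix(0, N, D)
  theta_sumsq <- matrix(0, N, D)
  keep_i <- 0L
  keep_t <- 0L

  for (it in seq_len(n_iter)) {
    Sigma_inv <- chol2inv(chol(Sigma))

    # --- theta block (shared precision across persons) ---
    d_cell <- as.vector(M %*% delta)
    if (is.null(fix$theta)) {
      E1 <- Y - matrix(d_cell, N, nC, byrow = TRUE)
      Rmat <- matrix(0, N, K)
      for (k in seq_len(K)) {
        Rmat[, k] <- rowSums(E1[, kcols[[k]], drop = FALSE])
      }
      P <- Sigma_inv + (I / sigma2) * AtA
      Ru <- chol(P)
      rhs <- matrix(as.vector(Sigma_inv %*% mu), N, K, byrow = TRUE) +
        (Rmat %*% A) / sigma2
      Mean <- t(backsolve(Ru, forwardsolve(t(Ru), t(rhs))))
      Tm <- Mean + t(backsolve(Ru, matrix(rnorm(N * K), K, N)))
    }

    # --- delta block (joint over statements) ---
    TA <- Tm %*% A
    theta_part <- TA[, kpos, drop = FALSE]
    if (is.null(fix$delta)) {
      E2 <- Y - theta_part
      ebar <- colMeans(E2)
      Prec <- P0 + (N / sigma2) * MtM
      Rd <- chol(Prec)
      rhs_d <- (N / sigma2) * as.vector(crossprod(M, ebar))
      mean_d <- backsolve(Rd, forwardsolve(t(Rd), rhs_d))
      delta <- as.vector(mean_d + backsolve(Rd, rnorm(S)))
      d_cell <- as.vector(M %*% delta)
    }

    # residuals BEFORE projection; the projection + compensating trait/mu
    # shift leaves them unchanged (likelihood-invariant recentering)
    Resid <- Y - theta_part - matrix(d_cell, N, nC, byrow = TRUE)

    # --- identification projection ---
    if (cfg$project_delta && is.null(fix$delta)) {
      cdim <- delta_slot_sums(delta, design) / I
      delta <- delta - cdim[stmt_dim]
      if (is.null(fix$theta)) {
        v <- as.vector(Ainv %*% (cdim[ks] - cdim[ref]))
        Tm <- Tm + matrix(v, N, K, byrow = TRUE)
        if (is.null(fix$mu)) mu <- mu + v
      }
    }

    # --- sigma2 block ---
    if (is.null(fix$sigma2)) {
      shape <- 1 + N * nC / 2
      rate <- 1 + sum(Resid^2) / 2
      sigma2 <- 1 / rgamma(1, shape = shape, rate = rate)
    }

    # --- mu block ---
    if (is.null(fix$mu)) {
      Pmu <- diag(K) + N * Sigma_inv
      Rmu <- chol(Pmu)
      rhs_mu <- as.vector(Sigma_inv %*% colSums(Tm))
      mu <- as.vector(backsolve(Rmu, forwardsolve(t(Rmu), rhs_mu)) +
                        backsolve(Rmu, rnorm(K)))
    }

    # --- Sigma block ---
    if (is.null(fix$cov)) {
      Sc <- crossprod(Tm - matrix(mu, N, K, byrow = TRUE))
      Psi <- diag(K) + Sc
      W <- rWishart(1, df = (design$n_dims - 1) + N, Sigma = chol2inv(chol(Psi)))[, , 1]
      Sigma <- chol2inv(chol(W))
    }

    # --- bookkeeping ---
    if (it > cfg$n_burnin && (it - cfg$n_burnin) %% cfg$thin == 0) {
      keep_i <- keep_i + 1L
      draw_delta[keep_i, ] <- delta
      draw_sigma2[keep_i] <- sigma2
      draw_mu[keep_i, ] <- mu
      draw_cov[keep_i, ] <- as.vector(Sigma)
      theta_full <- matrix(0, N, D)
      theta_full[, ks] <- Tm
      theta_full[, ref] <- -rowSums(Tm)
      theta_sum <- theta_sum + theta_full
      theta_sumsq <- theta_sumsq + theta_full^2
      if (it %in% theta_kept) {
        keep_t <- keep_t + 1L
        draw_theta[keep_t, , ] <- theta_full
      }
    }
  }

  n_est <- keep_i
  list(
    delta = draw_delta, sigma2 = draw_sigma2, mu = draw_mu, cov = draw_cov,
    theta = draw_theta,
    theta_mean = theta_sum / n_est,
    theta_sd = sqrt(pmax(theta_sumsq / n_est - (theta_sum / n_est)^2, 0) *
                      n_est / max(n_est - 1, 1)),
    theta_kept_idx = seq(theta_stride, n_kept, by = theta_stride),
    acceptance = stats::setNames(1, "gibbs"), seed = chain_seed
  )
}

# Assemble chains into a lim_fit object with point estimates and PSR table.
finish_fit <- function(chains, design, cfg, persons, y, n_monitor_theta,
                       model, extra = list()) {
  n_chains <- length(chains)
  K <- design$n_dims - 1
  D <- design$n_dims
  S <- length(design$statements)
  n_kept <- length(chains[[1]]$sigma2)
  trait_dim <- ncol(chains[[1]]$mu)

  bind3 <- function(name) {
    m <- chains[[1]][[name]]
    out <- array(NA_real_, c(nrow(as.matrix(m)), n_chains, ncol(as.matrix(m))))
    for (ch in seq_len(n_chains)) out[, ch, ] <- as.matrix(chains[[ch]][[name]])
    out
  }
  draws <- list(
    delta = bind3("delta"),
    sigma2 = vapply(chains, `[[`, numeric(n_kept), "sigma2"),
    mu = bind3("mu"),
    cov = bind3("cov"),
    theta = {
      th1 <- chains[[1]]$theta
      arr <- array(NA_real_, c(dim(th1)[1], n_chains, dim(th1)[2], dim(th1)[3]))
      for (ch in seq_len(n_chains)) arr[, ch, , ] <- chains[[ch]]$theta
      arr
    }
  )
  dimnames(draws$delta)[[3]] <- design$statements
  if (is.matrix(draws$sigma2) == FALSE) draws$sigma2 <- matrix(draws$sigma2, n_kept, n_chains)

  est_delta <- apply(draws$delta, 3, mean)
  names(est_delta) <- design$statements
  est_sigma2 <- mean(draws$sigma2)
  est_mu <- apply(draws$mu, 3, mean)
  est_cov <- matrix(apply(draws$cov, 3, mean), trait_dim, trait_dim)
  theta_mean <- Reduce(`+`, lapply(chains, `[[`, "theta_mean")) / n_chains
  theta_sd <- sqrt(Reduce(`+`, lapply(chains, function(ch) ch$theta_sd^2)) / n_chains)
  rownames(theta_mean) <- rownames(theta_sd) <- persons

  # PSR over monitored scalars: all delta, sigma2, mu, cov entries, and a
  # reproducible subsample of individual trait scalars.
  mats <- list()
  stmt_block <- if (identical(model, "tmc")) "beta[" else "delta["
  for (s in seq_len(S)) {
    mats[[paste0(stmt_block, design$statements[s], "]")]] <- draws$delta[, , s]
  }
  mats[["sigma2"]] <- draws$sigma2
  for (k in seq_len(trait_dim)) mats[[paste0("mu[", k, "]")]] <- draws$mu[, , k]
  for (i in seq_len(trait_dim)) for (j in seq_len(trait_dim)) {
    if (j >= i) {
      mats[[sprintf("cov[%d,%d]", i, j)]] <-
        draws$cov[, , (j - 1) * trait_dim + i]
    }
  }
  n_theta_scalars <- dim(draws$theta)[3] * dim(draws$theta)[4]
  if (n_monitor_theta > 0 && dim(draws$theta)[1] >= 2) {
    # deterministic, evenly spread subsample of individual trait scalars
    pick <- unique(round(seq(1, n_theta_scalars,
                             length.out = min(n_monitor_theta, n_theta_scalars))))
    for (p in pick) {
      n_i <- dim(draws$theta)[3]
      row <- ((p - 1) %% n_i) + 1
      col <- ((p - 1) %/% n_i) + 1
      mats[[sprintf("theta[%s,%d]", persons[row], col)]] <- draws$theta[, , row, col]
    }
  }
  psr_tbl <- tibble::tibble(
    parameter = names(mats),
    psr = vapply(mats, psr_matrix, numeric(1), quiet = TRUE)
  )
  converged <- n_chains >= 2 && all(psr_tbl$psr < cfg$psr_threshold, na.rm = TRUE)

  structure(c(list(
    model = model,
    draws = draws,
    estimates = list(theta = theta_mean, theta_sd = theta_sd,
                     delta = est_delta, sigma2 = est_sigma2,
                     mu = est_mu, cov = est_cov),
    psr = psr_tbl, converged = converged,
    theta_kept_idx = chains[[1]]$theta_kept_idx,
    config = cfg, design = design, persons = persons,
    acceptance = lapply(chains, `[[`, "acceptance"),
    seeds = vapply(chains, `[[`, numeric(1), "seed"),
    y = y
  ), extra), class = "lim_fit")
}

#' @export
print.lim_fit <- function(x, ...) {
  cat(sprintf(
    "<lim_fit:%s> %d persons x %d items x %d dims; %d chains x %d draws\n",
    x$model, length(x$persons), x$design$n_items, x$design$n_dims,
    x$config$n_chains, x$config$n_draws
  ))
  cat(sprintf("  sigma2 = %.4f; max PSR = %.3f; converged: %s\n",
              x$estimates$sigma2, max(x$psr$psr), x$converged))
  invisible(x)
}
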