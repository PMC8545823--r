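# Sampler for the Thurstonian comparator (TMC): a two-parameter model with
# per-statement slopes and per-cell pairwise locations,
#   Y_k = loc_{i,k} + beta_k theta_k - beta_D theta_D + eps.
# Identification under MCMC is deliberately minimal scaffolding (lognormal
# slope priors, N(0,1) locations, unconstrained MVN traits): with equally
# keyed statements the model is weakly identified, and the resulting
# non-convergence is reported, never repaired.

#' Fit the Thurstonian comparator model by MCMC
#'
#' Samples pairwise statement locations, per-statement slopes
#' (lognormal(0, 0.5) prior), unconstrained multivariate-normal person
#' traits, the noise variance, and the trait covariance. Traits, locations,
#' the noise variance and the covariance use exact conjugate updates; slopes
#' use per-statement adaptive random-walk Metropolis on the log scale
#' (adaptation targets acceptance 0.2-0.5 and freezes after burn-in).
#'
#' With `fix_beta = TRUE` and `ipsative = TRUE` the model reduces to the
#' LIM with cell-level locations: slopes pinned at one and the sum-zero
#' trait constraint switched on.
#'
#' @inheritParams fit_lim
#' @param fix_beta Pin all slopes at 1 (default `FALSE`).
#' @param ipsative Impose the sum-zero trait constraint as in the LIM
#'   (default `FALSE`: traits are a free D-dimensional MVN with zero mean).
#' @return A `lim_fit` object with `model = "tmc"`; `estimates` additionally
#'   carries `pair_location` (item x (D-1)) and `slope` (per statement).
#' @export
fit_tmc <- function(data, design, n_chains = 2, n_burnin = 10000,
                    n_draws = 10000, thin = 1, seed = 1,
                    psr_threshold = 1.1, n_monitor_theta = 50,
                    max_theta_stored = 400, fix_beta = FALSE,
                    ipsative = FALSE) {
  if (design$n_items < 2 || design$n_dims < 2) {
    abort("model not informative: need at least 2 items and 2 dimensions")
  }
  y <- if (inherits(data, "lim_alr")) data else alr_transform(data, design)
  Y <- alr_cell_matrix(y)
  persons <- dimnames(y)[[1]] %||% as.character(seq_len(nrow(Y)))
  cfg <- list(
    model = "tmc", n_chains = n_chains, n_burnin = n_burnin,
    n_draws = n_draws, thin = thin, seed = seed,
    psr_threshold = psr_threshold, fix_beta = fix_beta, ipsative = ipsative
  )
  chains <- lapply(seq_len(n_chains), function(ch) {
    tmc_gibbs_chain(Y, design, cfg, chain_seed = seed + ch - 1,
                    max_theta_stored = max_theta_stored)
  })
  fit <- finish_fit(chains, design, cfg, persons, y,
                    n_monitor_theta = n_monitor_theta, model = "tmc")
  K <- design$n_dims - 1
  fit$estimates$pair_location <- matrix(
    apply(simplify2array(lapply(chains, function(ch) colMeans(ch$loc))), 1, mean),
    design$n_items, K, byrow = TRUE
  )
  fit$estimates$slope <- setNames(
    rowMeans(simplify2array(lapply(chains, function(ch) colMeans(ch$beta)))),
    design$statements
  )
  fit$draws$loc <- simplify2array(lapply(chains, `[[`, "loc"))
  fit$draws$beta <- simplify2array(lapply(chains, `[[`, "beta"))
  fit
}

tmc_gibbs_chain <- function(Y, design, cfg, chain_seed, max_theta_stored) {
  set.seed(chain_seed)
  N <- nrow(Y)
  D <- design$n_dims
  I <- design$n_items
  S <- length(design$statements)
  cells <- design_cells(design)
  nC <- cells$n_cells
  ref <- design$reference_dim
  ks <- cells$ks
  kpos <- cells$kpos
  A <- contrast_matrix(D)
  ipsative <- isTRUE(cfg$ipsative)
  Kdim <- if (ipsative) D - 1 else D         # dimension of the free trait block

  # statement of each cell's numerator and reference slot
  num_stmt <- design$slot_idx[cbind(cells$item, cells$dim_k)]
  ref_stmt <- design$slot_idx[cells$item, ref]
  cells_of_stmt <- lapply(seq_len(S), function(s) {
    list(num = which(num_stmt == s), ref = which(ref_stmt == s))
  })

  Tm <- matrix(rnorm(N * Kdim, sd = 0.5), N, Kdim)
  loc <- rnorm(nC, sd = 0.5)
  beta <- if (cfg$fix_beta) rep(1, S) else exp(rnorm(S, sd = 0.3))
  sigma2 <- stats::runif(1, 0.05, 1)
  Sigma <- diag(Kdim)
  log_step <- rep(log(0.2), S)
  acc <- rep(0, S)
  n_prop <- rep(0, S)

  # free-trait design matrix (cells x Kdim) for the current slopes
  build_B <- function(beta) {
    B <- matrix(0, nC, Kdim)
    if (ipsative) {
      # theta_k = t_k, theta_ref = -sum(t): coef on t_j is
      # beta_ref + beta_k * 1{j = k(cell)}
      for (c in seq_len(nC)) {
        B[c, ] <- beta[ref_stmt[c]]
        B[c, kpos[c]] <- B[c, kpos[c]] + beta[num_stmt[c]]
      }
    } else {
      for (c in seq_len(nC)) {
        B[c, match(cells$dim_k[c], seq_len(D))] <- beta[num_stmt[c]]
        B[c, ref] <- B[c, ref] - beta[ref_stmt[c]]
      }
    }
    B
  }
  B <- build_B(beta)

  n_iter <- cfg$n_burnin + cfg$n_draws
  kept <- seq(cfg$n_burnin + cfg$thin, n_iter, by = cfg$thin)
  n_kept <- length(kept)
  theta_stride <- max(1L, ceiling(n_kept / max_theta_stored))
  theta_kept <- kept[seq(theta_stride, n_kept, by = theta_stride)]

  draw_delta <- matrix(NA_real_, n_kept, S)   # slot reused for beta PSR block
  draw_sigma2 <- numeric(n_kept)
  draw_mu <- matrix(0, n_kept, Kdim)
  draw_cov <- matrix(NA_real_, n_kept, Kdim * Kdim)
  draw_loc <- matrix(NA_real_, n_kept, nC)
  draw_beta <- matrix(NA_real_, n_kept, S)
  draw_theta <- array(NA_real_, c(length(theta_kept), N, D))
  theta_sum <- matrix(0, N, D)
  theta_sumsq <- matrix(0, N, D)
  keep_i <- 0L
  keep_t <- 0L

  theta_full_of <- function(Tm) {
    if (!ipsative) return(Tm)
    th <- matrix(0, N, D)
    th[, ks] <- Tm
    th[, ref] <- -rowSums(Tm)
    th
  }

  for (it in seq_len(n_iter)) {
    Sigma_inv <- chol2inv(chol(Sigma))

    # --- traits (shared precision; prior mean zero) ---
    E1 <- Y - matrix(loc, N, nC, byrow = TRUE)
    P <- Sigma_inv + crossprod(B) / sigma2
    Ru <- chol(P)
    rhs <- (E1 %*% B) / sigma2
    Mean <- t(backsolve(Ru, forwardsolve(t(Ru), t(rhs))))
    Tm <- Mean + t(backsolve(Ru, matrix(rnorm(N * Kdim), Kdim, N)))
    theta_part <- Tm %*% t(B)                 # N x cells

    # --- locations (independent N(0,1) priors) ---
    E2 <- Y - theta_part
    prec_l <- 1 + N / sigma2
    mean_l <- (N / sigma2) * colMeans(E2) / prec_l
    loc <- mean_l + rnorm(nC) / sqrt(prec_l)
    Resid <- E2 - matrix(loc, N, nC, byrow = TRUE)

    # --- slopes: per-statement random-walk MH on the log scale ---
    if (!cfg$fix_beta) {
      theta_mat <- theta_full_of(Tm)
      for (s in seq_len(S)) {
        cs <- cells_of_stmt[[s]]
        cols <- c(cs$num, cs$ref)
        if (!length(cols)) next
        lb_new <- log(beta[s]) + exp(log_step[s]) * rnorm(1)
        b_new <- exp(lb_new)
        d_acc <- stats::dnorm(lb_new, 0, 0.5, log = TRUE) -
          stats::dnorm(log(beta[s]), 0, 0.5, log = TRUE)
        for (c in cs$num) {
          x <- theta_mat[, cells$dim_k[c]]
          r_old <- Resid[, c]
          r_new <- r_old - (b_new - beta[s]) * x
          d_acc <- d_acc + sum(r_old^2 - r_new^2) / (2 * sigma2)
        }
        for (c in cs$ref) {
          x <- -theta_mat[, ref]
          r_old <- Resid[, c]
          r_new <- r_old - (b_new - beta[s]) * x
          d_acc <- d_acc + sum(r_old^2 - r_new^2) / (2 * sigma2)
        }
        n_prop[s] <- n_prop[s] + 1
        if (log(stats::runif(1)) < d_acc) {
          # accept: update residuals for affected cells
          for (c in cs$num) {
            Resid[, c] <- Resid[, c] - (b_new - beta[s]) * theta_mat[, cells$dim_k[c]]
          }
          for (c in cs$ref) {
            Resid[, c] <- Resid[, c] + (b_new - beta[s]) * theta_mat[, ref]
          }
          beta[s] <- b_new
          acc[s] <- acc[s] + 1
        }
        if (it <= cfg$n_burnin) {
          rate <- acc[s] / n_prop[s]
          log_step[s] <- log_step[s] + (rate - 0.3) / sqrt(it)
        }
      }
      B <- build_B(beta)
      theta_part <- Tm %*% t(B)
      Resid <- Y - theta_part - matrix(loc, N, nC, byrow = TRUE)
    }

    # --- sigma2 ---
    shape <- 1 + N * nC / 2
    rate <- 1 + sum(Resid^2) / 2
    sigma2 <- 1 / rgamma(1, shape = shape, rate = rate)

    # --- trait covariance (zero-mean prior) ---
    Psi <- diag(Kdim) + crossprod(Tm)
    W <- rWishart(1, df = Kdim + N, Sigma = chol2inv(chol(Psi)))[, , 1]
    Sigma <- chol2inv(chol(W))

    if (it > cfg$n_burnin && (it - cfg$n_burnin) %% cfg$thin == 0) {
      keep_i <- keep_i + 1L
      draw_delta[keep_i, ] <- beta
      draw_sigma2[keep_i] <- sigma2
      draw_cov[keep_i, ] <- as.vector(Sigma)
      draw_loc[keep_i, ] <- loc
      draw_beta[keep_i, ] <- beta
      th <- theta_full_of(Tm)
      theta_sum <- theta_sum + th
      theta_sumsq <- theta_sumsq + th^2
      if (it %in% theta_kept) {
        keep_t <- keep_t + 1L
        draw_theta[keep_t, , ] <- th
      }
    }
  }

  n_est <- keep_i
  list(
    delta = draw_delta, sigma2 = draw_sigma2, mu = draw_mu, cov = draw_cov,
    theta = draw_theta, loc = draw_loc, beta = draw_beta,
    theta_mean = theta_sum / n_est,
    theta_sd = sqrt(pmax(theta_sumsq / n_est - (theta_sum / n_est)^2, 0) *
                      n_est / max(n_est - 1, 1)),
    theta_kept_idx = seq(theta_stride, n_kept, by = theta_stride),
    acceptance = c(slopes = if (all(n_prop == 0)) 1 else sum(acc) / sum(n_prop)),
    seed = chain_seed
  )
}
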