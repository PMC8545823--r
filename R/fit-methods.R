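#' Tidy a fitted model
#'
#' One row per scalar parameter with its posterior mean and posterior
#' standard deviation.
#'
#' @param x A `lim_fit`.
#' @param blocks Which parameter blocks to return (default all of
#'   `"theta"`, `"delta"`, `"sigma2"`, `"mu"`, `"cov"`; TMC fits also carry
#'   `"slope"` and `"pair_location"` point estimates under `delta`-like
#'   blocks).
#' @param ... Unused.
#' @return A tibble with columns `block`, `term`, `estimate`, `std.error`.
#' @export
tidy.lim_fit <- function(x, blocks = c("theta", "delta", "sigma2", "mu", "cov"),
                         ...) {
  out <- list()
  if ("theta" %in% blocks) {
    th <- x$estimates$theta
    sdm <- x$estimates$theta_sd
    out$theta <- tibble::tibble(
      block = "theta",
      term = paste0("theta[", rep(rownames(th), ncol(th)), ",",
                    rep(seq_len(ncol(th)), each = nrow(th)), "]"),
      estimate = as.vector(th),
      std.error = as.vector(sdm)
    )
  }
  if ("delta" %in% blocks) {
    lab <- if (identical(x$model, "tmc")) "beta[" else "delta["
    out$delta <- tibble::tibble(
      block = if (identical(x$model, "tmc")) "slope" else "delta",
      term = paste0(lab, names(x$estimates$delta), "]"),
      estimate = unname(x$estimates$delta),
      std.error = apply(x$draws$delta, 3, sd)
    )
  }
  if ("sigma2" %in% blocks) {
    out$sigma2 <- tibble::tibble(
      block = "sigma2", term = "sigma2",
      estimate = x$estimates$sigma2, std.error = sd(as.vector(x$draws$sigma2))
    )
  }
  if ("mu" %in% blocks) {
    out$mu <- tibble::tibble(
      block = "mu", term = paste0("mu[", seq_along(x$estimates$mu), "]"),
      estimate = x$estimates$mu, std.error = apply(x$draws$mu, 3, sd)
    )
  }
  if ("cov" %in% blocks) {
    cv <- x$estimates$cov
    kk <- nrow(cv)
    out$cov <- tibble::tibble(
      block = "cov",
      term = sprintf("cov[%d,%d]", rep(seq_len(kk), kk),
                     rep(seq_len(kk), each = kk)),
      estimate = as.vector(cv),
      std.error = apply(x$draws$cov, 3, sd)
    )
  }
  dplyr::bind_rows(out)
}

#' Glance at a fitted model
#'
#' @param x A `lim_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample sizes, chains/draws, posterior mean
#'   noise variance, the largest monitored PSR, and the convergence flag.
#' @export
glance.lim_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model,
    n_persons = length(x$persons),
    n_items = x$design$n_items,
    n_dims = x$design$n_dims,
    n_chains = x$config$n_chains,
    n_draws = x$config$n_draws,
    sigma2 = x$estimates$sigma2,
    max_psr = max(x$psr$psr, na.rm = TRUE),
    converged = x$converged
  )
}

#' Trace plot of monitored draws
#'
#' @param object A `lim_fit`.
#' @param pars Parameter block to trace: `"delta"` (default), `"sigma2"`,
#'   `"mu"` or `"cov"`.
#' @param max_pars Cap on traced scalars (default 12).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lim_fit <- function(object, pars = "delta", max_pars = 12, ...) {
  arr <- switch(pars,
    delta = object$draws$delta,
    mu = object$draws$mu,
    cov = object$draws$cov,
    sigma2 = array(object$draws$sigma2,
                   c(nrow(object$draws$sigma2), ncol(object$draws$sigma2), 1)),
    abort("unknown parameter block")
  )
  P <- min(dim(arr)[3], max_pars)
  df <- purrr::map_dfr(seq_len(P), function(p) {
    purrr::map_dfr(seq_len(dim(arr)[2]), function(ch) {
      tibble::tibble(
        parameter = paste0(pars, "[", p, "]"),
        chain = factor(ch),
        iteration = seq_len(dim(arr)[1]),
        value = arr[, ch, p]
      )
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "retained iteration", y = "draw")
}

#' Serialize posterior draws and a run manifest
#'
#' Writes one CSV per parameter block (columns `chain`, `iteration`,
#' `parameter`, `value`) plus `manifest.json` with the configuration, chain
#' seeds, acceptance rates and the PSR table.
#'
#' @param fit A `lim_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_draws <- function(fit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  blocks <- list(
    delta = fit$draws$delta, mu = fit$draws$mu, cov = fit$draws$cov,
    sigma2 = array(fit$draws$sigma2,
                   c(nrow(fit$draws$sigma2), ncol(fit$draws$sigma2), 1))
  )
  for (b in names(blocks)) {
    arr <- blocks[[b]]
    nm <- dimnames(arr)[[3]] %||% as.character(seq_len(dim(arr)[3]))
    df <- purrr::map_dfr(seq_len(dim(arr)[2]), function(ch) {
      tibble::tibble(
        chain = ch,
        iteration = rep(seq_len(dim(arr)[1]), dim(arr)[3]),
        parameter = rep(paste0(b, "[", nm, "]"), each = dim(arr)[1]),
        value = as.vector(arr[, ch, ])
      )
    })
    readr::write_csv(df, file.path(dir, paste0(b, ".csv")))
  }
  manifest <- list(
    package = "limcomp",
    version = as.character(utils::packageVersion("limcomp")),
    model = fit$model,
    config = fit$config,
    chain_seeds = fit$seeds,
    acceptance = fit$acceptance,
    converged = fit$converged,
    psr = fit$psr
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
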