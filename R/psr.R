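#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Computes the classic Gelman-Rubin ratio per scalar parameter:
#' `sqrt(V_hat / W)` with `W` the mean within-chain variance,
#' `B/n` the between-chain variance of the chain means, and
#' `V_hat = (n-1)/n W + B/n`. Values near 1 indicate that the chains have
#' mixed. A degenerate parameter (zero variance in every chain) returns 1
#' with a warning instead of 0/0.
#'
#' @param x A `lim_fit` object, or a numeric matrix with one column per
#'   chain (iterations x chains).
#' @param ... Unused.
#' @return For a fit: a tibble with columns `parameter` and `psr` over the
#'   monitored set (all utilities, `sigma2`, `mu`, covariance entries and a
#'   subsample of person traits). For a matrix: a single number.
#' @examples
#' psr(cbind(rnorm(100), rnorm(100)))
#' @export
psr <- function(x, ...) UseMethod("psr")

#' @export
psr.lim_fit <- function(x, ...) x$psr

#' @export
psr.matrix <- function(x, ...) psr_matrix(x, quiet = FALSE)

#' @export
psr.default <- function(x, ...) {
  abort("`psr()` needs a lim_fit or an iterations x chains matrix")
}

psr_matrix <- function(m, quiet = FALSE) {
  m <- as.matrix(m)
  n <- nrow(m)
  n_chains <- ncol(m)
  if (n_chains < 2) {
    if (quiet) return(NA_real_)
    abort("PSR needs at least 2 chains")
  }
  if (n < 2) {
    if (quiet) return(NA_real_)
    abort("PSR needs at least 2 draws per chain")
  }
  W <- mean(apply(m, 2, var))
  B_over_n <- var(colMeans(m))
  if (W == 0) {
    if (!quiet) warn("zero within-chain variance; PSR defined as 1")
    return(1)
  }
  v_hat <- (n - 1) / n * W + B_over_n
  sqrt(v_hat / W)
}

#' Has a fit converged?
#'
#' `TRUE` when every monitored PSR is below the fit's threshold (and at
#' least two chains were run).
#'
#' @param fit A `lim_fit`.
#' @return Logical scalar.
#' @export
declare_converged <- function(fit) {
  stopifnot(inherits(fit, "lim_fit"))
  isTRUE(fit$converged)
}
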