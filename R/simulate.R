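# Synthetic-data generation with the study's generative structure:
# ipsatized multivariate-normal traits, uniform item-centered statement
# utilities, Gaussian log-ratio noise mapped back to compositions.

#' The real-world inter-trait correlation matrix
#'
#' A published four-dimension empirical correlation matrix used as one of the
#' simulation conditions. The printed source is sign-inconsistent in one
#' off-diagonal pair, so the matrix is symmetrized from its lower triangle;
#' the result is positive definite.
#'
#' @return A 4 x 4 correlation matrix.
#' @export
real_world_corr <- function() {
  m <- diag(4)
  low <- c(-0.33, -0.43, -0.37, 0.30, 0.32, 0.27)
  m[lower.tri(m)] <- low
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

corr_matrix_of <- function(correlation, n_dims) {
  if (is.matrix(correlation)) {
    R <- correlation
  } else if (identical(correlation, "real-world") || identical(correlation, "real")) {
    R <- real_world_corr()
  } else if (is.numeric(correlation) && length(correlation) == 1) {
    R <- matrix(correlation, n_dims, n_dims)
    diag(R) <- 1
  } else {
    abort("`correlation` must be a scalar, a matrix, or \"real-world\"")
  }
  if (nrow(R) != n_dims) abort("correlation matrix does not match `n_dims`")
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("correlation matrix is not positive definite")
  }
  R
}

#' Generate statement utilities for a design
#'
#' Utilities are drawn independently from U(-1.2, 1.2), then centered within
#' each item so that every item's D slot utilities sum to zero (matching the
#' identification of generated tests).
#'
#' @param design A [lim_design()]. Statements shared between items receive
#'   one draw; the per-item centering is applied to the slot values, which is
#'   exact when statements are not shared (the simulation-study layout).
#' @param seed Integer seed.
#' @param range Half-width of the uniform distribution (default 1.2).
#' @return Named numeric vector of utilities over `design$statements`.
#' @export
gen_utilities <- function(design, seed = NULL, range = 1.2) {
  if (!is.null(seed)) set.seed(seed)
  delta <- stats::runif(length(design$statements), -range, range)
  # center within items via slot averages accumulated per statement
  adj <- numeric(length(delta))
  cnt <- numeric(length(delta))
  item_means <- rowMeans(matrix(delta[design$slot_idx], design$n_items))
  for (d in seq_len(design$n_dims)) {
    idx <- design$slot_idx[, d]
    adj[idx] <- adj[idx] + item_means
    cnt[idx] <- cnt[idx] + 1
  }
  delta <- delta - adj / pmax(cnt, 1)
  setNames(delta, design$statements)
}

#' Generate normative and ipsatized latent traits
#'
#' Persons are drawn from a multivariate normal with zero means, unit
#' standard deviations and the requested inter-trait correlations; the
#' ipsative truth subtracts each person's within-person mean, so ipsative
#' rows sum to zero exactly.
#'
#' @param n_persons Number of persons.
#' @param correlation Scalar correlation applied to all pairs, a full
#'   correlation matrix, or `"real-world"` for [real_world_corr()].
#' @param n_dims Number of dimensions (default 4).
#' @param seed Integer seed.
#' @return List with `normative` and `ipsative` (both persons x D matrices)
#'   and the correlation matrix used.
#' @export
gen_traits <- function(n_persons, correlation = 0.5, n_dims = 4, seed = NULL) {
  R <- corr_matrix_of(correlation, n_dims)
  if (!is.null(seed)) set.seed(seed)
  z <- matrix(rnorm(n_persons * n_dims), n_persons, n_dims)
  normative <- z %*% chol(R)
  ipsative <- normative - rowMeans(normative)
  list(normative = normative, ipsative = ipsative, corr = R)
}

#' Generate compositional responses from the LIM
#'
#' For each person and item the D-1 log ratios are the noise-free
#' expectations plus independent N(0, sigma2) errors; the inverse log-ratio
#' transform maps them to positive scores summing to `total`.
#'
#' @param theta_ipsative Persons x D matrix of ipsative traits.
#' @param delta Statement utilities (named as the design's statements).
#' @param sigma2 Log-ratio noise variance (default 0.087).
#' @param design A [lim_design()].
#' @param total Allocation total `C` (default 100).
#' @param seed Integer seed.
#' @return A [composition_data()] tibble.
#' @export
gen_responses <- function(theta_ipsative, delta, sigma2 = 0.087, design,
                          total = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(sigma2 >= 0)
  cells <- design_cells(design)
  tf <- theta_free_of(theta_ipsative, design)
  mu_cells <- lim_expected_cells(tf, delta_vector(delta, design), design, cells)
  N <- nrow(mu_cells)
  y_cells <- mu_cells + matrix(rnorm(N * cells$n_cells, sd = sqrt(sigma2)),
                               N, cells$n_cells)
  y <- cell_matrix_to_alr(y_cells, design, persons = sprintf("p%03d", seq_len(N)))
  arr <- alr_inverse(y, total = total, design = design)
  score_array_to_tbl(arr, total = total)
}

# inverse of alr_cell_matrix: persons x cells -> persons x items x (D-1)
cell_matrix_to_alr <- function(m, design, persons = NULL) {
  I <- design$n_items
  K <- design$n_dims - 1
  y <- array(NA_real_, c(nrow(m), I, K))
  for (i in seq_len(I)) y[, i, ] <- m[, (i - 1) * K + seq_len(K)]
  dimnames(y) <- list(
    persons %||% sprintf("p%03d", seq_len(nrow(m))),
    as.character(design$items[[1]]), NULL
  )
  structure(y, total = NULL, reference_dim = design$reference_dim,
            class = "lim_alr")
}

#' Simulate a complete LIM dataset
#'
#' One-stop generator for recovery studies: builds (or accepts) a design,
#' draws item-centered utilities, correlated ipsatized traits and noisy
#' responses, and returns the data together with the generating truth.
#'
#' @param n_persons Number of persons.
#' @param n_items Number of items (ignored when `design` is given).
#' @param n_dims Number of dimensions (default 4).
#' @param correlation Inter-trait correlation specification (see
#'   [gen_traits()]); default 0.5.
#' @param sigma2 Generating noise variance (default 0.087, an empirical
#'   log-ratio error-variance estimate for 100-point value items).
#' @param total Allocation total (default 100).
#' @param design Optional [lim_design()]; default [gen_design()] layout.
#' @param seed Integer seed controlling all draws.
#' @return List of class `lim_simulation`: `data` ([composition_data()]),
#'   `design`, and `truth` (list with `delta`, `theta_normative`,
#'   `theta_ipsative`, `sigma2`, `corr`).
#' @examples
#' sim <- simulate_lim(n_persons = 20, n_items = 5, seed = 7)
#' sim$data
#' @export
simulate_lim <- function(n_persons, n_items = 10, n_dims = 4,
                         correlation = 0.5, sigma2 = 0.087, total = 100,
                         design = NULL, seed = NULL) {
  if (is.null(design)) design <- gen_design(n_items, n_dims)
  if (!is.null(seed)) set.seed(seed)
  delta <- gen_utilities(design)
  traits <- gen_traits(n_persons, correlation, design$n_dims)
  data <- gen_responses(traits$ipsative, delta, sigma2, design, total)
  structure(
    list(data = data, design = design,
         truth = list(delta = delta, theta_normative = traits$normative,
                      theta_ipsative = traits$ipsative, sigma2 = sigma2,
                      corr = traits$corr)),
    class = "lim_simulation"
  )
}

#' @export
print.lim_simulation <- function(x, ...) {
  cat(sprintf(
    "<lim_simulation> %d persons x %d items x %d dimensions (sigma2 = %g)\n",
    nrow(x$truth$theta_ipsative), x$design$n_items, x$design$n_dims,
    x$truth$sigma2
  ))
  invisible(x)
}
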