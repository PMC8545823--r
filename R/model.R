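# Deterministic mathematics of the lognormal ipsative model (LIM) and the
# Thurstonian comparator (TMC).
#
# LIM:  Y_k = (theta_k + delta_{i,k}) - (theta_D + delta_{i,D}) + eps,
#       eps ~ N(0, sigma2), independently over the D-1 ratios of an item.
# TMC:  Y_k = loc_{i,k} + beta_{i,k} theta_k - beta_{i,D} theta_D + eps.

#' Parameter sets for the LIM and the TMC
#'
#' `lim_params()` bundles person traits, statement utilities, the log-ratio
#' noise variance and (optionally) the population mean and covariance of the
#' free trait coordinates. Traits are ipsative: each person's D values sum to
#' zero. Utilities are identified by a per-dimension slot-sum-zero constraint
#' over the items of the design (checked when `strict = TRUE`, as sampler
#' output always satisfies it; relaxed otherwise so that hypothetical single
#' items can be explored).
#'
#' @param theta Persons x D matrix of ipsative traits (rows sum to 0).
#' @param delta Named numeric vector of statement utilities (names = statement
#'   ids of the design) or an unnamed vector ordered as `design$statements`.
#' @param sigma2 Positive scalar noise variance of the log ratios.
#' @param mu Optional length D-1 population mean of the free trait block.
#' @param cov Optional (D-1) x (D-1) SPD population covariance.
#' @param strict Also enforce the per-dimension utility constraint.
#' @param design A [lim_design()] (needed when `strict = TRUE`).
#' @return A list of class `lim_params`.
#' @export
lim_params <- function(theta, delta, sigma2, mu = NULL, cov = NULL,
                       strict = FALSE, design = NULL) {
  theta <- as.matrix(theta)
  if (any(abs(rowSums(theta)) > 1e-9)) {
    abort("each person's trait row must sum to zero (ipsative constraint)")
  }
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("`sigma2` must be a positive scalar")
  }
  if (!is.null(cov)) check_spd(cov)
  if (strict) {
    if (is.null(design)) abort("`strict = TRUE` needs the linkage design")
    ss <- delta_slot_sums(delta_vector(delta, design), design)
    if (any(abs(ss) > 1e-9)) {
      abort("utilities must have zero slot-sum within every dimension")
    }
  }
  structure(list(theta = theta, delta = delta, sigma2 = sigma2,
                 mu = mu, cov = cov), class = "lim_params")
}

#' @param pair_location Item x (D-1) matrix (or per-cell vector) of pairwise
#'   locations relative to the reference statement.
#' @param slope Named numeric vector of statement slopes (discriminations).
#' @rdname lim_params
#' @export
tmc_params <- function(theta, pair_location, slope, sigma2,
                       mu = NULL, cov = NULL) {
  if (!is.numeric(sigma2) || length(sigma2) != 1 || sigma2 <= 0) {
    abort("`sigma2` must be a positive scalar")
  }
  if (!is.null(cov)) check_spd(cov)
  structure(list(theta = as.matrix(theta), pair_location = pair_location,
                 slope = slope, sigma2 = sigma2, mu = mu, cov = cov),
            class = "tmc_params")
}

check_spd <- function(m) {
  m <- as.matrix(m)
  if (!isSymmetric(unname(m), tol = 1e-8)) abort("covariance must be symmetric")
  if (any(eigen(m, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("covariance must be positive definite")
  }
  invisible(m)
}

# delta as a plain vector ordered like design$statements
delta_vector <- function(delta, design) {
  if (!is.null(names(delta))) {
    if (!all(design$statements %in% names(delta))) {
      abort("`delta` is missing utilities for some statements in the design")
    }
    delta <- delta[design$statements]
  }
  if (length(delta) != length(design$statements)) {
    abort("`delta` length does not match the number of statements")
  }
  unname(delta)
}

# per-dimension sums of delta over item slots (with repetition)
delta_slot_sums <- function(delta, design) {
  vapply(seq_len(design$n_dims), function(d) {
    sum(delta[design$slot_idx[, d]])
  }, numeric(1))
}

# Cell bookkeeping: the I*(D-1) (item, non-reference slot) pairs, in
# item-major order, plus the signed statement incidence matrix M such that
# the utility contrast of cell (i,k) is (M %*% delta)[cell].
design_cells <- function(design) {
  I <- design$n_items
  D <- design$n_dims
  ref <- design$reference_dim
  ks <- setdiff(seq_len(D), ref)
  item <- rep(seq_len(I), each = D - 1)
  kpos <- rep(seq_len(D - 1), times = I)       # ratio index within item
  dim_k <- ks[kpos]                            # dimension of the numerator slot
  S <- length(design$statements)
  M <- matrix(0, I * (D - 1), S)
  for (c in seq_along(item)) {
    M[c, design$slot_idx[item[c], dim_k[c]]] <- M[c, design$slot_idx[item[c], dim_k[c]]] + 1
    M[c, design$slot_idx[item[c], ref]] <- M[c, design$slot_idx[item[c], ref]] - 1
  }
  list(item = item, kpos = kpos, dim_k = dim_k, ks = ks, M = M,
       n_cells = I * (D - 1))
}

# Map (theta, delta) to the identified representative on the constraint
# manifold: utilities get per-dimension slot-sum zero, traits absorb the
# compensating likelihood-invariant shift. Expected log ratios are unchanged.
identify_params <- function(theta, delta, design) {
  delta <- delta_vector(delta, design)
  cdim <- delta_slot_sums(delta, design) / design$n_items
  delta_id <- delta - cdim[design$statement_dim]
  D <- design$n_dims
  ref <- design$reference_dim
  ks <- setdiff(seq_len(D), ref)
  Ainv <- diag(D - 1) - matrix(1, D - 1, D - 1) / D
  v <- as.vector(Ainv %*% (cdim[ks] - cdim[ref]))
  theta_id <- as.matrix(theta)
  theta_id[, ks] <- theta_id[, ks] + matrix(v, nrow(theta_id), D - 1, byrow = TRUE)
  theta_id[, ref] <- theta_id[, ref] - sum(v)
  list(theta = theta_id, delta = setNames(delta_id, design$statements))
}

# A maps free trait coordinates t = theta[, ks] to contrasts
# theta_k - theta_ref = t_k + sum(t): A = I + J.
contrast_matrix <- function(n_dims) {
  diag(n_dims - 1) + matrix(1, n_dims - 1, n_dims - 1)
}

# Expected log ratios for all persons and cells: N x n_cells matrix.
lim_expected_cells <- function(theta_free, delta, design, cells = design_cells(design)) {
  A <- contrast_matrix(design$n_dims)
  TA <- theta_free %*% A                              # N x (D-1) contrasts
  d_cell <- as.vector(cells$M %*% delta)              # cell utility contrasts
  TA[, cells$kpos, drop = FALSE] +
    matrix(d_cell, nrow(theta_free), cells$n_cells, byrow = TRUE)
}

theta_free_of <- function(theta, design) {
  ks <- setdiff(seq_len(design$n_dims), design$reference_dim)
  as.matrix(theta)[, ks, drop = FALSE]
}

#' Expected log ratios of one person on one item
#'
#' The noise-free expectation of the D-1 log ratios: component `k` equals
#' `(theta_k + delta_{slot k}) - (theta_D + delta_{slot D})` with `D` the
#' design's reference dimension.
#'
#' @param theta_row Length-D ipsative trait vector (sums to zero).
#' @param item Item identifier (as in the design) or index.
#' @param params A [lim_params()] (only `delta` is used).
#' @param design A [lim_design()].
#' @return Numeric vector of length D-1.
#' @examples
#' d <- gen_design(2, 3)
#' delta <- setNames(rep(0, 6), d$statements)
#' p <- lim_params(theta = matrix(0, 1, 3), delta = delta, sigma2 = 1)
#' expected_log_ratio(c(0, 0, 0), 1, p, d)
#' @export
expected_log_ratio <- function(theta_row, item, params, design) {
  i <- match_item(item, design)
  if (abs(sum(theta_row)) > 1e-9) abort("`theta_row` must sum to zero")
  delta <- delta_vector(params$delta, design)
  ref <- design$reference_dim
  ks <- setdiff(seq_len(design$n_dims), ref)
  unname((theta_row[ks] + delta[design$slot_idx[i, ks]]) -
           (theta_row[ref] + delta[design$slot_idx[i, ref]]))
}

#' Expected log ratios under the Thurstonian comparator
#'
#' Component `k` equals
#' `loc_{i,k} + beta_{slot k} * theta_k - beta_{slot D} * theta_D`.
#' With all slopes equal to one and pair locations equal to the LIM utility
#' contrasts this reduces exactly to [expected_log_ratio()].
#'
#' @param theta_row Length-D trait vector (unconstrained).
#' @inheritParams expected_log_ratio
#' @param params A [tmc_params()].
#' @return Numeric vector of length D-1.
#' @export
tmc_expected_log_ratio <- function(theta_row, item, params, design) {
  i <- match_item(item, design)
  ref <- design$reference_dim
  ks <- setdiff(seq_len(design$n_dims), ref)
  slope <- params$slope
  if (!is.null(names(slope))) slope <- slope[design$statements]
  loc <- params$pair_location
  loc_i <- if (is.matrix(loc)) loc[i, ] else
    loc[(i - 1) * (design$n_dims - 1) + seq_len(design$n_dims - 1)]
  b_k <- slope[design$slot_idx[i, ks]]
  b_ref <- slope[design$slot_idx[i, ref]]
  unname(loc_i + b_k * theta_row[ks] - b_ref * theta_row[ref])
}

match_item <- function(item, design) {
  ids <- design$items[[1]]
  i <- if (is.numeric(item) && !item %in% ids) item else match(item, ids)
  if (is.na(i) || i < 1 || i > design$n_items) {
    abort(sprintf("unknown item '%s'", as.character(item)))
  }
  as.integer(i)
}

#' Log likelihood of log-ratio data under the LIM
#'
#' Sums, over persons, items and the D-1 ratios, the normal log density of
#' the observed log ratio around its expectation with variance `sigma2`. The
#' ratios within an item are treated as independent.
#'
#' @param y A `lim_alr` array (persons x items x D-1), see [alr_transform()].
#' @param params A [lim_params()].
#' @param design A [lim_design()].
#' @return The scalar log likelihood.
#' @export
lim_log_likelihood <- function(y, params, design) {
  if (params$sigma2 <= 0) abort("`sigma2` must be positive")
  delta <- delta_vector(params$delta, design)
  cells <- design_cells(design)
  tf <- theta_free_of(params$theta, design)
  mu_cells <- lim_expected_cells(tf, delta, design, cells)
  ymat <- alr_cell_matrix(y)
  sum(stats::dnorm(ymat, mu_cells, sqrt(params$sigma2), log = TRUE))
}

# persons x cells matrix view of a persons x items x (D-1) array,
# cells in item-major (item, ratio) order to match design_cells().
alr_cell_matrix <- function(y) {
  N <- dim(y)[1]; I <- dim(y)[2]; K <- dim(y)[3]
  m <- matrix(0, N, I * K)
  for (i in seq_len(I)) {
    m[, (i - 1) * K + seq_len(K)] <- y[, i, ]
  }
  m
}
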