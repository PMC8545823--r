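#' Additive log-ratio transform of compositional responses
#'
#' Maps each D-part allocation to D-1 log ratios against the design's
#' reference slot: `Y_k = ln(X_k) - ln(X_D)`. All scores must be strictly
#' positive - impute zeros first (see [impute_zeros()]).
#'
#' @param x A [composition_data()] tibble (or a persons x items x D array).
#' @param design A [lim_design()] matching the data.
#' @return A persons x items x (D-1) numeric array of class `lim_alr`, with
#'   person and item ids as dimnames and the allocation total stored in the
#'   `total` attribute.
#' @examples
#' d <- gen_design(2, 3)
#' sim <- simulate_lim(n_persons = 3, design = d, sigma2 = 0.05, seed = 1)
#' y <- alr_transform(sim$data, d)
#' dim(y)
#' @export
alr_transform <- function(x, design) {
  arr <- if (is.array(x)) x else as_score_array(x, design)
  total <- if (is.array(x)) attr(x, "total") %||% 100 else composition_total(x)
  if (any(arr <= 0)) {
    bad <- which(arr <= 0, arr.ind = TRUE)[1, ]
    dn <- dimnames(arr)
    abort(sprintf(
      "unimputed zero/negative response for person '%s', item '%s' (slot %d); impute zeros before the log-ratio transform",
      dn[[1]][bad[1]], dn[[2]][bad[2]], bad[3]
    ))
  }
  D <- design$n_dims
  ref <- design$reference_dim
  ks <- setdiff(seq_len(D), ref)
  y <- log(arr[, , ks, drop = FALSE]) - rep(log(arr[, , ref]), times = D - 1)
  dim(y) <- c(dim(arr)[1:2], D - 1)
  dimnames(y) <- c(dimnames(arr)[1:2], list(NULL))
  structure(y, total = total, reference_dim = ref, class = "lim_alr")
}

#' Inverse additive log-ratio transform
#'
#' Reconstructs the D-part composition summing to `total` from D-1 log
#' ratios: the reference part is `C / (1 + sum(exp(Y)))` and part `k` is the
#' reference part times `exp(Y_k)`.
#'
#' @param y A persons x items x (D-1) array of finite log ratios (as produced
#'   by [alr_transform()]).
#' @param total The allocation total `C` (default: the array's `total`
#'   attribute, else 100).
#' @param design Optional [lim_design()]; if supplied, the reconstructed
#'   parts are placed back in the design's slot order around its reference
#'   dimension.
#' @return A persons x items x D array of positive scores; each (person,
#'   item) row sums to `total`.
#' @export
alr_inverse <- function(y, total = NULL, design = NULL) {
  if (!all(is.finite(y))) abort("log ratios must be finite")
  total <- total %||% attr(y, "total") %||% 100
  ref <- if (!is.null(design)) design$reference_dim else
    attr(y, "reference_dim") %||% (dim(y)[3] + 1L)
  D <- dim(y)[3] + 1L
  e <- exp(y)
  denom <- 1 + apply(e, c(1, 2), sum)
  ref_part <- total / denom
  arr <- array(NA_real_, c(dim(y)[1:2], D),
               dimnames = c(dimnames(y)[1:2], list(NULL)))
  ks <- setdiff(seq_len(D), ref)
  arr[, , ref] <- ref_part
  for (j in seq_along(ks)) arr[, , ks[j]] <- ref_part * e[, , j]
  attr(arr, "total") <- total
  arr
}

#' @export
print.lim_alr <- function(x, ...) {
  cat(sprintf(
    "<lim_alr> %d persons x %d items x %d log ratios (reference dimension %d)\n",
    dim(x)[1], dim(x)[2], dim(x)[3], attr(x, "reference_dim")
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
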