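# Independent oracles used across tests; deliberately naive implementations.

# Gelman-Rubin ratio computed directly from the textbook formula on a
# two-column matrix (iterations x chains).
gelman_rubin_oracle <- function(m) {
  n <- nrow(m)
  W <- mean(apply(m, 2, var))
  B_over_n <- var(colMeans(m))
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# brute-force LIM log likelihood: loop over persons/items/ratios with dnorm
loglik_oracle <- function(y, theta, delta, sigma2, design) {
  ref <- design$reference_dim
  ks <- setdiff(seq_len(design$n_dims), ref)
  total <- 0
  for (n in seq_len(dim(y)[1])) {
    for (i in seq_len(dim(y)[2])) {
      for (k in seq_along(ks)) {
        mu <- (theta[n, ks[k]] + delta[design$slot_idx[i, ks[k]]]) -
          (theta[n, ref] + delta[design$slot_idx[i, ref]])
        total <- total + dnorm(y[n, i, k], mu, sqrt(sigma2), log = TRUE)
      }
    }
  }
  total
}

# persons x items x D array -> composition tibble
make_composition <- function(arr, total = 100) {
  if (is.null(dimnames(arr)[[1]])) {
    dimnames(arr) <- list(paste0("p", seq_len(dim(arr)[1])),
                          as.character(seq_len(dim(arr)[2])), NULL)
  }
  dn <- dimnames(arr)
  grid <- expand.grid(slot = seq_len(dim(arr)[3]), item_id = dn[[2]],
                      person_id = dn[[1]], stringsAsFactors = FALSE)
  grid$score <- arr[cbind(match(grid$person_id, dn[[1]]),
                          match(grid$item_id, dn[[2]]), grid$slot)]
  composition_data(tibble::as_tibble(grid[, c(3, 2, 1, 4)]), total = total)
}
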