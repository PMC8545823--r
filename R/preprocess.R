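#' Screen raw compositional survey responses
#'
#' Removes two classes of unusable respondents before model fitting:
#' * constant allocation - persons who give the entire total `C` to the same
#'   slot position in every item (a nonsense pattern that carries no
#'   preference information), and
#' * rushed completion - persons whose total response time falls below a
#'   floor (default 300 seconds), when times are supplied.
#'
#' @param data A [composition_data()] tibble.
#' @param times Optional data frame with columns `person_id` and
#'   `response_seconds`.
#' @param min_response_seconds Exclusion floor on response time (default 300).
#' @param drop_constant_allocation Apply the constant-allocation rule
#'   (default `TRUE`).
#' @return A list of class `lim_screening` with elements `data` (the retained
#'   [composition_data()]) and `exclusions` (tibble `person_id`, `reason`).
#' @examples
#' d <- gen_design(3, 3)
#' sim <- simulate_lim(n_persons = 4, design = d, seed = 1)
#' screen_responses(sim$data)$exclusions
#' @export
screen_responses <- function(data, times = NULL, min_response_seconds = 300,
                             drop_constant_allocation = TRUE) {
  total <- composition_total(data)
  excl <- tibble::tibble(person_id = character(), reason = character())

  if (drop_constant_allocation) {
    full <- dplyr::filter(data, abs(.data$score - total) <= 1e-9 * total)
    const <- dplyr::summarise(
      dplyr::group_by(full, .data$person_id, .data$slot),
      n = dplyr::n(), .groups = "drop"
    )
    n_items <- dplyr::n_distinct(data$item_id)
    const <- dplyr::filter(const, .data$n == n_items)
    if (nrow(const)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        person_id = as.character(unique(const$person_id)),
        reason = "constant allocation"
      ))
    }
  }

  if (!is.null(times)) {
    fast <- dplyr::filter(times, .data$response_seconds < min_response_seconds)
    if (nrow(fast)) {
      excl <- dplyr::bind_rows(excl, tibble::tibble(
        person_id = as.character(fast$person_id),
        reason = sprintf("response time below %g s", min_response_seconds)
      ))
    }
  }

  excl <- dplyr::distinct(excl)
  kept <- dplyr::filter(data, !(as.character(.data$person_id) %in% excl$person_id))
  if (nrow(kept) == 0) {
    warn("screening removed every respondent")
    out <- kept
    attr(out, "total") <- total
    class(out) <- c("lim_composition", class(tibble::as_tibble(kept)))
  } else {
    out <- composition_data(kept, total = total)
  }
  structure(list(data = out, exclusions = excl), class = "lim_screening")
}

#' @export
print.lim_screening <- function(x, ...) {
  cat(sprintf(
    "<lim_screening> %d persons retained, %d excluded\n",
    dplyr::n_distinct(x$data$person_id), dplyr::n_distinct(x$exclusions$person_id)
  ))
  if (nrow(x$exclusions)) print(x$exclusions)
  invisible(x)
}

#' Multiplicative imputation of zero allocations
#'
#' Replaces every zero score with a small constant `kappa` and rescales the
#' nonzero scores of the same (person, item) block by `1 - m * kappa / C`
#' (with `m` that block's zero count), so the block still sums to the total
#' `C`. Blocks without zeros are untouched; rank order of the positive
#' scores is preserved. A zero fraction above 10% of all entries triggers a
#' warning, as the replacement distorts compositions beyond that load.
#'
#' @param data A [composition_data()] tibble with nonnegative scores.
#' @param kappa Imputation constant, `0 < kappa <` the smallest admissible
#'   nonzero response (default 0.5). A common alternative is 0.65 times the
#'   smallest possible response.
#' @return The imputed [composition_data()] tibble.
#' @examples
#' d <- tibble::tibble(person_id = "p1", item_id = "i1", slot = 1:4,
#'                     score = c(0, 50, 30, 20))
#' impute_zeros(composition_data(d), kappa = 0.5)$score
#' @export
impute_zeros <- function(data, kappa = 0.5) {
  total <- composition_total(data)
  min_pos <- min(data$score[data$score > 0], Inf)
  if (!is.numeric(kappa) || length(kappa) != 1 || kappa <= 0 || kappa >= min_pos) {
    abort("`kappa` must be positive and smaller than the smallest nonzero response")
  }
  zero_frac <- mean(data$score == 0)
  if (zero_frac > 0.10) {
    warn(sprintf(
      "%.1f%% of entries are zero; imputation is only well supported below 10%%",
      100 * zero_frac
    ))
  }
  out <- dplyr::mutate(
    dplyr::group_by(data, .data$person_id, .data$item_id),
    .m = sum(.data$score == 0),
    score = dplyr::if_else(
      .data$score == 0, .env$kappa,
      .data$score * (1 - .data$.m * .env$kappa / .env$total)
    )
  )
  out <- dplyr::select(dplyr::ungroup(out), -".m")
  composition_data(out, total = total, tol = 1e-9)
}
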