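#' Compositional response data
#'
#' Responses to compositional forced-choice items live in a long tibble with
#' one row per (person, item, slot): columns `person_id`, `item_id`,
#' `slot` (1..D, ordered as in the linkage design) and `score`. Every
#' (person, item) block must allocate the fixed total `C` across its D slots.
#' `composition_data()` validates such a table and tags it with the total.
#'
#' @param x A data frame with columns `person_id`, `item_id`, `slot`, `score`.
#' @param total The fixed allocation total `C` (default 100).
#' @param tol Relative tolerance on the per-item sum check (default 1e-6).
#' @return `x` as a tibble of class `lim_composition` carrying a `total`
#'   attribute.
#' @export
composition_data <- function(x, total = 100, tol = 1e-6) {
  x <- tibble::as_tibble(x)
  needed <- c("person_id", "item_id", "slot", "score")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(x$score)) || any(x$score < 0)) {
    abort("scores must be finite and nonnegative")
  }
  dup <- duplicated(x[, c("person_id", "item_id", "slot")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate (person, item, slot) row at line %d: person '%s', item '%s', slot %s",
      i, x$person_id[i], x$item_id[i], x$slot[i]
    ))
  }
  sums <- dplyr::summarise(
    dplyr::group_by(x, .data$person_id, .data$item_id),
    n_slots = dplyr::n(), total_obs = sum(.data$score), .groups = "drop"
  )
  n_slots <- unique(sums$n_slots)
  if (length(n_slots) != 1) {
    abort("every (person, item) must have the same number of slot rows")
  }
  bad <- which(abs(sums$total_obs - total) > tol * total)
  if (length(bad)) {
    b <- sums[bad[1], ]
    abort(sprintf(
      "item allocation does not sum to the declared total %g: person '%s', item '%s' sums to %g (%d offending blocks)",
      total, b$person_id, b$item_id, b$total_obs, length(bad)
    ))
  }
  attr(x, "total") <- total
  class(x) <- c("lim_composition", class(x))
  x
}

#' @export
print.lim_composition <- function(x, ...) {
  cat(sprintf(
    "<lim_composition> %d persons x %d items, total C = %g\n",
    dplyr::n_distinct(x$person_id), dplyr::n_distinct(x$item_id),
    attr(x, "total")
  ))
  NextMethod()
}

#' Total allocation constant of a composition table
#' @param x A `lim_composition` (or any data frame with a `total` attribute).
#' @return The constant `C`.
#' @export
composition_total <- function(x) {
  tot <- attr(x, "total")
  if (is.null(tot)) 100 else tot
}

# Long tibble -> persons x items x D array (and back). The array is the
# working representation for everything numeric; dimnames carry the ids.
as_score_array <- function(x, design = NULL) {
  persons <- unique(x$person_id)
  items <- unique(x$item_id)
  if (!is.null(design)) {
    items_design <- as.character(design$items[[1]])
    if (!setequal(as.character(items), items_design)) {
      abort("items in the data do not match the linkage design")
    }
    items <- items_design
  }
  slots <- sort(unique(x$slot))
  arr <- array(
    NA_real_, c(length(persons), length(items), length(slots)),
    dimnames = list(as.character(persons), as.character(items), NULL)
  )
  idx <- cbind(
    match(as.character(x$person_id), as.character(persons)),
    match(as.character(x$item_id), as.character(items)),
    match(x$slot, slots)
  )
  arr[idx] <- x$score
  if (anyNA(arr)) abort("incomplete (person, item, slot) grid in response data")
  arr
}

score_array_to_tbl <- function(arr, total = 100) {
  dn <- dimnames(arr)
  tbl <- tidyr::expand_grid(
    person_id = dn[[1]], item_id = dn[[2]], slot = seq_len(dim(arr)[3])
  )
  tbl$score <- arr[cbind(
    match(tbl$person_id, dn[[1]]), match(tbl$item_id, dn[[2]]), tbl$slot
  )]
  composition_data(tbl, total = total)
}

#' Read and write compositional response files
#'
#' The on-disk format is a long CSV with columns `person_id`, `item_id`,
#' `slot`, `score` and a leading comment line `# total=C` declaring the fixed
#' allocation total. `read_responses()` validates sums and duplicates on
#' load; `write_responses()` round-trips losslessly at full precision.
#'
#' @param path File path.
#' @return `read_responses()` returns a [composition_data()] tibble.
#' @export
read_responses <- function(path) {
  first <- readLines(path, n = 1)
  total <- 100
  if (grepl("^#\\s*total\\s*=", first)) {
    total <- as.numeric(sub("^#\\s*total\\s*=\\s*", "", first))
    if (!is.finite(total) || total <= 0) abort("unparseable '# total=' header")
  }
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           person_id = readr::col_character(),
                           item_id = readr::col_character(),
                           slot = readr::col_integer(),
                           score = readr::col_double()
                         ))
  composition_data(tbl, total = total)
}

#' @param x A [composition_data()] tibble.
#' @rdname read_responses
#' @export
write_responses <- function(x, path) {
  writeLines(sprintf("# total=%.15g", composition_total(x)), path)
  out <- tibble::as_tibble(x)
  out$score <- sprintf("%.15g", out$score)
  readr::write_csv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
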