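#' Linkage designs for compositional forced-choice tests
#'
#' A linkage design records, for each of `I` items, which statement occupies
#' each of the item's `D` slots, and which latent dimension every statement
#' measures. Within an item the slots are ordered by dimension, i.e. slot `d`
#' always carries the statement written for dimension `d`; the last slot
#' (dimension `D` by default) acts as the reference part of the additive
#' log-ratio transform. Statements may be shared between items - that is what
#' links the dimensions across the test.
#'
#' @param items A data frame with one row per item: an `item` column
#'   (identifier) followed by one column per dimension giving the statement
#'   identifier occupying that dimension's slot. Column order defines the
#'   dimension order.
#' @param reference_dim Integer index of the reference dimension used by the
#'   log-ratio transform. Defaults to the last dimension.
#'
#' @return An object of class `lim_design`: a list with elements
#'   `items` (tibble as supplied), `n_items`, `n_dims`, `dim_names`,
#'   `statements` (character vector of unique statement ids),
#'   `statement_dim` (named integer, statement -> dimension),
#'   `slot_idx` (I x D integer matrix indexing into `statements`), and
#'   `reference_dim`.
#'
#' @examples
#' d <- lim_design(tibble::tibble(
#'   item = 1:2, A = c("a1", "a2"), B = c("b1", "b2")
#' ))
#' d$n_dims
#' @export
lim_design <- function(items, reference_dim = NULL) {
  items <- tibble::as_tibble(items)
  if (ncol(items) < 3) {
    abort("a linkage design needs an item column plus at least two dimension columns")
  }
  if (anyDuplicated(items[[1]])) {
    abort("duplicated item identifiers in linkage design")
  }
  dim_names <- names(items)[-1]
  n_items <- nrow(items)
  n_dims <- length(dim_names)
  if (is.null(reference_dim)) reference_dim <- n_dims
  if (!reference_dim %in% seq_len(n_dims)) {
    abort("`reference_dim` must index one of the design's dimensions")
  }

  slot_chr <- as.matrix(items[, -1])
  mode(slot_chr) <- "character"
  statements <- unique(as.vector(slot_chr))
  statement_dim <- integer(0)
  for (d in seq_len(n_dims)) {
    for (s in unique(slot_chr[, d])) {
      if (s %in% names(statement_dim) && statement_dim[[s]] != d) {
        abort(sprintf("statement '%s' appears under two different dimensions", s))
      }
      statement_dim[[s]] <- d
    }
  }
  statement_dim <- statement_dim[statements]
  slot_idx <- matrix(match(slot_chr, statements), n_items, n_dims)

  structure(
    list(
      items = items,
      n_items = n_items,
      n_dims = n_dims,
      dim_names = dim_names,
      statements = statements,
      statement_dim = statement_dim,
      slot_idx = slot_idx,
      reference_dim = reference_dim
    ),
    class = "lim_design"
  )
}

#' @export
print.lim_design <- function(x, ...) {
  cat(sprintf(
    "<lim_design> %d items x %d dimensions (%s), %d statements, reference dimension %d\n",
    x$n_items, x$n_dims, paste(x$dim_names, collapse = ", "),
    length(x$statements), x$reference_dim
  ))
  invisible(x)
}

#' Generate the simulation-study linkage design
#'
#' Builds the layout used in recovery simulations: every item gets its own
#' `n_dims` fresh statements, one per dimension, so the design holds
#' `n_items * n_dims` distinct statements and no statement is shared.
#'
#' @param n_items Number of items (at least 2).
#' @param n_dims Number of dimensions (at least 2).
#' @return A [lim_design()].
#' @examples
#' gen_design(10, 4)
#' @export
gen_design <- function(n_items, n_dims = 4) {
  stopifnot(n_items >= 2, n_dims >= 2)
  cols <- lapply(seq_len(n_dims), function(d) {
    sprintf("s%02d_%02d", seq_len(n_items), d)
  })
  names(cols) <- sprintf("dim%d", seq_len(n_dims))
  lim_design(tibble::tibble(item = seq_len(n_items), !!!cols))
}

#' Read a linkage design from CSV
#'
#' The file must have an item-identifier column first, then one statement
#' column per dimension (the layout of a printed linkage table).
#'
#' @param path Path to the CSV file.
#' @param reference_dim Passed to [lim_design()].
#' @return A [lim_design()].
#' @export
read_design <- function(path, reference_dim = NULL) {
  tbl <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  lim_design(tbl, reference_dim = reference_dim)
}

#' The 40-item online value-test linkage design
#'
#' The partial linkage design of a four-dimension online value test
#' (Self-Transcendence, Conservation, Self-Enhancement, Openness to Change):
#' 40 compositional items drawing on 32 statements, each statement appearing
#' in exactly 5 items. Ships as a plain-text fixture with the package.
#'
#' @return A [lim_design()] with 40 items, 4 dimensions and 32 statements.
#' @examples
#' value_test_design()
#' @export
value_test_design <- function() {
  read_design(system.file("extdata", "value_test_design.csv", package = "limcomp"))
}
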