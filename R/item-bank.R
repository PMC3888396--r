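#' Item bank for a dichotomous questionnaire
#'
#' An item bank is the vector of item difficulties \eqn{\delta_j} (logit
#' scale) for a `J`-item dichotomous instrument.  Under the Rasch model the
#' probability that a subject with latent trait \eqn{\theta} endorses item
#' `j` is `plogis(theta - delta[j])`, so larger difficulties mean lower
#' endorsement rates at fixed \eqn{\theta}.
#'
#' @param difficulties Numeric vector of finite item difficulties, length
#'   `J >= 1`.
#'
#' @return An object of class `item_bank`: a numeric vector of difficulties.
#' @examples
#' item_bank(c(-0.97, -0.43, 0, 0.44, 0.98))
#' @export
item_bank <- function(difficulties) {
  difficulties <- as.numeric(difficulties)
  if (length(difficulties) < 1L) {
    abort("an item bank needs at least one item")
  }
  if (!all(is.finite(difficulties))) {
    abort("item difficulties must all be finite")
  }
  structure(difficulties, class = c("item_bank", "numeric"))
}

#' @export
print.item_bank <- function(x, ...) {
  cat("<item_bank> ", length(x), " dichotomous items\n", sep = "")
  cat("difficulties: ", paste(format(unclass(x)), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Canonical difficulty sets for 5- and 10-item questionnaires
#'
#' Two reference difficulty vectors placed at regular percentiles of a
#' standard normal latent trait, so that the instrument is neither too easy
#' nor too hard for the target population and the trait is measured with
#' similar precision over its range.
#'
#' @param j Number of items, 5 or 10.
#'
#' @return An [item_bank()].
#' @examples
#' canonical_difficulties(5)
#' @export
canonical_difficulties <- function(j) {
  if (j == 5) {
    item_bank(c(-0.97, -0.43, 0, 0.44, 0.98))
  } else if (j == 10) {
    item_bank(c(-1.33, -0.9, -0.6, -0.34, -0.11, 0.12, 0.36, 0.61, 0.92,
                1.34))
  } else {
    abort("canonical difficulty sets are defined for j = 5 or j = 10")
  }
}

#' Read item difficulties from a CSV or JSON file
#'
#' Accepts either a one-column CSV (with or without a header row) or a JSON
#' array of numbers.
#'
#' @param path Path to a `.csv` or `.json` file.
#'
#' @return An [item_bank()].
#' @export
read_difficulties <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::fromJSON(path)
    if (!is.numeric(vals)) abort("JSON difficulties file must be a numeric array")
    return(item_bank(vals))
  }
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(trimws(strsplit(first, ",")[[1]][1]))))
  tab <- readr::read_csv(path, col_names = has_header,
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_double()))
  if (ncol(tab) != 1L) abort("difficulties CSV must have exactly one column")
  item_bank(tab[[1]])
}
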