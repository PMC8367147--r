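#' Construct a polytomous item bank
#'
#' An item bank holds the calibrated partial credit model parameters shared
#' by calibration, adaptive testing and ground-truth scoring: for each item,
#' an identifier, its number of ordered response categories (>= 2) and the
#' `n_categories - 1` step thresholds (delta, in logits). Discrimination is
#' fixed at 1 for every item (the Rasch constraint).
#'
#' @param item_id character vector of unique item identifiers.
#' @param thresholds list of numeric vectors, one per item; item j has
#'   `length(thresholds[[j]]) + 1` response categories.
#' @return object of class `item_bank`.
#' @examples
#' b <- item_bank(c("i1", "i2"), list(c(-1, 0, 1), c(0, 0.5)))
#' n_categories(b)
#' @export
item_bank <- function(item_id, thresholds) {
  item_id <- as.character(item_id)
  if (anyDuplicated(item_id)) stop("item_id values must be unique")
  if (length(item_id) != length(thresholds))
    stop("item_id and thresholds must have the same length")
  thresholds <- lapply(thresholds, as.numeric)
  ok <- vapply(thresholds, function(d) length(d) >= 1L && all(is.finite(d)),
               logical(1))
  if (!all(ok)) stop("each item needs >= 1 finite threshold")
  names(thresholds) <- item_id
  structure(list(item_id = item_id, thresholds = thresholds),
            class = "item_bank")
}

#' Number of response categories per item
#' @param bank an `item_bank`.
#' @return named integer vector.
#' @export
n_categories <- function(bank) {
  stopifnot(inherits(bank, "item_bank"))
  vapply(bank$thresholds, function(d) length(d) + 1L, integer(1))
}

#' @export
length.item_bank <- function(x) length(x$item_id)

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("Item bank: %d items (partial credit model, discrimination 1)\n",
              length(x)))
  for (id in x$item_id) {
    cat(sprintf("  %-16s %d categories  delta = [%s]\n", id,
                length(x$thresholds[[id]]) + 1L,
                paste(sprintf("%.3f", x$thresholds[[id]]), collapse = ", ")))
  }
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  data.frame(item_id = x$item_id,
             n_categories = unname(n_categories(x)),
             thresholds = vapply(x$thresholds,
                                 function(d) paste(d, collapse = ";"),
                                 character(1)),
             row.names = NULL)
}

# subset a bank by item ids (internal)
bank_subset <- function(bank, ids) item_bank(ids, bank$thresholds[ids])

#' Serialize an item bank to JSON
#'
#' @param bank an `item_bank`.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  stopifnot(inherits(bank, "item_bank"))
  items <- lapply(bank$item_id, function(id) {
    list(item_id = id,
         n_categories = length(bank$thresholds[[id]]) + 1L,
         thresholds = as.numeric(bank$thresholds[[id]]))
  })
  jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an item bank from JSON
#' @param path file written by [write_item_bank()].
#' @return an `item_bank`.
#' @export
read_item_bank <- function(path) {
  items <- jsonlite::read_json(path)
  item_bank(vapply(items, `[[`, character(1), "item_id"),
            lapply(items, function(it) unlist(it$thresholds)))
}
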