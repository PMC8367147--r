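#' Read a response matrix from CSV
#'
#' The CSV must have a header of unique item ids and one row of integer
#' 0-based categories per person. If a bank is supplied, every cell is
#' range-checked against that item's category count.
#'
#' @param path CSV file.
#' @param bank optional [item_bank()] for validation.
#' @return integer matrix with item-id column names.
#' @export
read_response_csv <- function(path, bank = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!ncol(df)) stop("response CSV has no columns: ", path)
  if (anyDuplicated(colnames(df)))
    stop("duplicate item_ids in response CSV header")
  for (j in seq_along(df)) {
    x <- suppressWarnings(as.numeric(df[[j]]))
    bad <- which(is.na(x) | x != floor(x))
    if (length(bad))
      stop(sprintf("non-integer cell at row %d, column '%s'",
                   bad[1], colnames(df)[j]))
    df[[j]] <- x
  }
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (!is.null(bank)) {
    ncat <- n_categories(bank)
    for (id in colnames(m)) {
      if (!id %in% bank$item_id) stop("item not in bank: ", id)
      bad <- which(m[, id] < 0L | m[, id] > ncat[[id]] - 1L)
      if (length(bad))
        stop(sprintf("cell %d of item '%s' is %d, outside categories 0..%d",
                     bad[1], id, m[bad[1], id], ncat[[id]] - 1L))
    }
  }
  m
}

#' Write a response matrix to CSV
#' @param responses integer matrix with item-id column names.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_response_csv <- function(responses, path) {
  responses <- as_response_matrix(responses)
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

# provenance sidecar written next to every CLI output
write_provenance <- function(path, config, seed) {
  ver <- tryCatch(as.character(utils::packageVersion("promcat")),
                  error = function(e) NA_character_)
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  side <- list(config = config, seed = seed, package_version = ver,
               config_hash = sum(utf8ToInt(as.character(cfg_json)) *
                                   (seq_len(nchar(cfg_json)) %% 97 + 1)))
  jsonlite::write_json(side, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML or JSON
#'
#' The format is auto-detected: files parsing as JSON are read with
#' jsonlite, anything else with the YAML parser (YAML is a superset of
#' JSON in practice, so either works).
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  out <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
                  error = function(e) NULL)
  # literal true/false stay boolean, but YAML 1.1's y/n/yes/no shorthands
  # stay strings so that a key or value like "n" is not coerced
  strict_bool <- function(x)
    if (x %in% c("true", "True", "TRUE")) TRUE
    else if (x %in% c("false", "False", "FALSE")) FALSE
    else x
  if (is.null(out))
    out <- yaml::yaml.load(txt, handlers = list("bool#yes" = strict_bool,
                                                "bool#no" = strict_bool))
  if (!is.list(out)) stop("config must be a mapping: ", path)
  out
}
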