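#' Default clinical covariate specification
#'
#' Covariates emulating the clinician-reported data available alongside a
#' cleft-related quality-of-life scale: age, gender, cleft type,
#' laterality and planned future treatment. Each entry carries its kind
#' (`binary`, `categorical`, `continuous`) and an additive effect on the
#' latent trait in logits. Effects default to small values (<= 0.4
#' logits), reflecting clinical variables that are weak predictors of the
#' measured construct relative to item responses.
#'
#' @return list of covariate specifications (`name`, `kind`, `effect`,
#'   and `levels` for categorical kinds, `range` for continuous).
#' @export
default_covariates <- function() {
  list(
    list(name = "age", kind = "continuous", effect = 0.2, range = c(8, 29)),
    list(name = "gender", kind = "binary", effect = 0.1),
    list(name = "cleft_type", kind = "categorical", effect = 0.3,
         levels = c("CL", "CLA", "CLP", "CP")),
    list(name = "laterality", kind = "categorical", effect = 0.1,
         levels = c("left", "right", "bilateral")),
    list(name = "planned_treatment", kind = "binary", effect = 0.2)
  )
}

#' Configuration for a synthetic PROM cohort
#'
#' Defines the generating conditions for a synthetic polytomous scale and
#' cohort: a unidimensional latent trait, a Rasch-family (partial credit)
#' scale of `n_items` items with 3 or 4 ordered response categories, an
#' extra "overall appearance" rating outside the calibrated scale, and
#' clinical covariates weakly shifting the latent trait. The seed fully
#' determines every generated object.
#'
#' @param n_persons cohort size.
#' @param n_items number of scale items (default 8).
#' @param n_categories response categories per item, 3 or 4.
#' @param threshold_spread logit scale of item-location and category-step
#'   dispersion; 0 puts every threshold at 0.
#' @param covariates covariate specification list (see
#'   [default_covariates()]); each `effect` must be finite.
#' @param global_loading correlation strength (0..1) between the latent
#'   trait and the latent input of the overall-appearance item.
#' @param seed integer seed.
#' @return object of class `synth_config`.
#' @export
synth_config <- function(n_persons, n_items = 8L, n_categories = 4L,
                         threshold_spread = 1, covariates = default_covariates(),
                         global_loading = 0.7, seed = 1L) {
  n_persons <- as.integer(n_persons)
  n_items <- as.integer(n_items)
  n_categories <- as.integer(n_categories)
  if (n_persons < 1L) stop("n_persons must be positive")
  if (n_items < 1L) stop("n_items must be positive")
  if (!n_categories %in% c(3L, 4L))
    stop("n_categories must be 3 or 4")
  if (!is.finite(threshold_spread) || threshold_spread < 0)
    stop("threshold_spread must be a nonnegative number")
  if (!is.finite(global_loading) || global_loading < 0 || global_loading > 1)
    stop("global_loading must be in [0, 1]")
  effs <- vapply(covariates, `[[`, numeric(1), "effect")
  if (!all(is.finite(effs))) stop("covariate effects must be finite")
  structure(list(n_persons = n_persons, n_items = n_items,
                 n_categories = n_categories,
                 threshold_spread = threshold_spread,
                 covariates = covariates, global_loading = global_loading,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort config: %d persons, %d items x %d ",
                     "categories,\n  threshold spread %g, overall-item ",
                     "loading %g, %d covariates, seed %d\n"),
              x$n_persons, x$n_items, x$n_categories, x$threshold_spread,
              x$global_loading, length(x$covariates), x$seed))
  invisible(x)
}

# centered, ordered step offsets for K thresholds, scaled by the spread
step_offsets <- function(K, spread) spread * 0.8 * ((1:K) - (K + 1) / 2)

#' Generate a synthetic calibrated item bank
#'
#' Draws `n_items` partial credit items reproducibly from the configured
#' spread: item locations from N(0, spread^2) plus centered ordered
#' category-step offsets (also scaled by the spread), so `spread = 0`
#' puts every threshold at 0. Discrimination is 1 for every item.
#'
#' @param config a [synth_config()].
#' @return an [item_bank()] with items `item1..itemN` (zero-padded).
#' @export
generate_item_bank <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  K <- config$n_categories - 1L
  off <- step_offsets(K, config$threshold_spread)
  with_seed(config$seed, {
    loc <- stats::rnorm(config$n_items, 0, config$threshold_spread)
    item_bank(sprintf("item%02d", seq_len(config$n_items)),
              lapply(loc, function(l) l + off))
  })
}

#' Generate a synthetic cohort
#'
#' Person locations are standard normal shifted additively on the logit
#' scale by the covariate effects; scale responses are drawn from the
#' partial credit category distribution at each person's location; the
#' overall-appearance rating is a 4-category partial credit response to
#' `global_loading * theta + sqrt(1 - loading^2) * noise`, giving the
#' configured correlation strength with the trait. Responses are complete
#' by construction.
#'
#' @param config a [synth_config()].
#' @param bank the matching [item_bank()] from [generate_item_bank()].
#' @return object of class `cohort`: list with `theta` (true person
#'   locations), `responses` (persons x items integer matrix, categories
#'   `0..n_categories-1`), `covariates` (data frame), `global_item`
#'   (integer vector, 4 categories), `bank`, `config`.
#' @export
generate_cohort <- function(config, bank) {
  stopifnot(inherits(config, "synth_config"), inherits(bank, "item_bank"))
  if (length(bank) != config$n_items)
    stop("bank size does not match config n_items")
  if (!all(n_categories(bank) == config$n_categories))
    stop("bank category counts do not match config")
  n <- config$n_persons
  with_seed(config$seed + 500000L, {
    cov_draw <- draw_covariates(config$covariates, n)
    theta <- stats::rnorm(n) + cov_draw$shift
    responses <- draw_pcm_responses(theta, bank)
    lam <- config$global_loading
    gtheta <- lam * theta + sqrt(1 - lam^2) * stats::rnorm(n)
    gbank <- item_bank("overall_appearance",
                       list(step_offsets(3L, config$threshold_spread)))
    global_item <- drop(draw_pcm_responses(gtheta, gbank))
    structure(list(theta = theta, responses = responses,
                   covariates = cov_draw$table, global_item = global_item,
                   bank = bank, config = config),
              class = "cohort")
  })
}

# draw the covariate table and its additive latent-trait shift
draw_covariates <- function(spec, n) {
  shift <- numeric(n)
  cols <- list()
  for (cv in spec) {
    eff <- cv$effect
    if (cv$kind == "continuous") {
      rg <- cv$range %||% c(0, 1)
      x <- stats::runif(n, rg[1], rg[2])
      z <- (x - mean(rg)) / (diff(rg) / sqrt(12))   # standardized uniform
      shift <- shift + eff * z
      cols[[cv$name]] <- round(x, 1)
    } else if (cv$kind == "binary") {
      x <- stats::rbinom(n, 1L, 0.5)
      shift <- shift + eff * (x - 0.5)
      cols[[cv$name]] <- x
    } else if (cv$kind == "categorical") {
      lev <- cv$levels
      x <- sample(lev, n, replace = TRUE)
      lev_eff <- eff * seq(-0.5, 0.5, length.out = length(lev))
      shift <- shift + lev_eff[match(x, lev)]
      cols[[cv$name]] <- x
    } else stop("unknown covariate kind: ", cv$kind)
  }
  tab <- if (length(cols)) as.data.frame(cols, stringsAsFactors = FALSE)
         else data.frame(row.names = seq_len(n))
  list(table = tab, shift = shift)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d persons, %d scale items ",
                     "(%d categories) + overall-appearance item,\n  ",
                     "covariates: %s\n"),
              nrow(x$responses), ncol(x$responses), x$config$n_categories,
              paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

#' Write a cohort to plain-text files
#'
#' Writes `responses.csv` (header = item ids), `covariates.csv` (header =
#' covariate names plus the `overall_appearance` rating) and a JSON
#' sidecar `cohort.json` holding the true person locations, the
#' generating item bank and the seed.
#'
#' @param cohort a `cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(as.data.frame(cohort$responses),
                   file.path(dir, "responses.csv"), row.names = FALSE)
  cov <- cohort$covariates
  cov$overall_appearance <- cohort$global_item
  utils::write.csv(cov, file.path(dir, "covariates.csv"), row.names = FALSE)
  side <- list(seed = cohort$config$seed,
               n_persons = cohort$config$n_persons,
               n_items = cohort$config$n_items,
               n_categories = cohort$config$n_categories,
               threshold_spread = cohort$config$threshold_spread,
               global_loading = cohort$config$global_loading,
               theta = cohort$theta,
               bank = lapply(cohort$bank$item_id, function(id)
                 list(item_id = id,
                      thresholds = as.numeric(cohort$bank$thresholds[[id]]))))
  jsonlite::write_json(side, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing `responses.csv`, `covariates.csv`,
#'   `cohort.json`.
#' @return a `cohort` (with its `config` rebuilt from the sidecar,
#'   covariate spec defaulted).
#' @export
read_cohort <- function(dir) {
  responses <- read_response_csv(file.path(dir, "responses.csv"))
  cov <- utils::read.csv(file.path(dir, "covariates.csv"),
                         stringsAsFactors = FALSE)
  side <- jsonlite::read_json(file.path(dir, "cohort.json"))
  global_item <- as.integer(cov$overall_appearance)
  cov$overall_appearance <- NULL
  bank <- item_bank(vapply(side$bank, `[[`, character(1), "item_id"),
                    lapply(side$bank, function(it) unlist(it$thresholds)))
  config <- synth_config(n_persons = side$n_persons, n_items = side$n_items,
                         n_categories = side$n_categories,
                         threshold_spread = side$threshold_spread,
                         global_loading = side$global_loading,
                         seed = side$seed)
  structure(list(theta = unlist(side$theta), responses = responses,
                 covariates = cov, global_item = global_item,
                 bank = bank, config = config),
            class = "cohort")
}
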