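#' Initialize an adaptive-testing posterior state
#'
#' A `cat_state` carries the running (unnormalized, log-scale) posterior of
#' one respondent over the quadrature nodes, the ordered record of
#' administered (item, response) pairs, and precomputed category-probability
#' tables for every bank item at the nodes.
#'
#' @param bank an [item_bank()] of candidate items.
#' @param grid a [quad_grid()].
#' @return object of class `cat_state`.
#' @export
cat_state_init <- function(bank, grid = quad_grid()) {
  stopifnot(inherits(bank, "item_bank"))
  grid <- as_quad_grid(grid)
  structure(list(bank = bank, grid = grid,
                 probs = bank_grid_probs(bank, grid),
                 logpost = log(grid$weights),
                 administered = list()),
            class = "cat_state")
}

#' @export
print.cat_state <- function(x, ...) {
  got <- vapply(x$administered, function(a)
    sprintf("%s=%d", a$item_id, a$response), character(1))
  p <- cat_posterior(x)
  cat(sprintf("CAT state: %d/%d items administered [%s]\n  theta_hat %.3f, se %.3f\n",
              length(x$administered), length(x$bank),
              paste(got, collapse = ", "), p$mean, p$sd))
  invisible(x)
}

administered_ids <- function(state)
  vapply(state$administered, `[[`, character(1), "item_id")

# normalized posterior with mean/sd
cat_posterior <- function(state) {
  w <- exp(state$logpost - max(state$logpost))
  w <- w / sum(w)
  m1 <- sum(w * state$grid$nodes)
  m2 <- sum(w * state$grid$nodes^2)
  list(weights = w, mean = m1, sd = sqrt(max(m2 - m1^2, 0)))
}

# core MEPV computation on a normalized posterior (weights over nodes)
epv_from_weights <- function(w, nodes, P) {
  epv <- 0
  for (k in seq_len(ncol(P))) {
    joint <- w * P[, k]
    pk <- sum(joint)
    if (pk <= 0) next
    m1 <- sum(joint * nodes) / pk
    m2 <- sum(joint * nodes^2) / pk
    epv <- epv + pk * max(m2 - m1^2, 0)
  }
  epv
}

#' Expected posterior variance of a candidate item
#'
#' The minimum expected posterior variance (MEPV) item-selection criterion:
#' for a candidate item, the posterior-predictive category probabilities
#' under the current posterior weight the latent-trait posterior variances
#' that each possible response would produce,
#' `sum_k P(X=k | data) * Var(theta | data, X=k)`.
#'
#' @param state a `cat_state`.
#' @param item_id a bank item not yet administered.
#' @return scalar expected posterior variance (logits squared).
#' @export
expected_posterior_variance <- function(state, item_id) {
  stopifnot(inherits(state, "cat_state"))
  if (!item_id %in% state$bank$item_id) stop("unknown item: ", item_id)
  if (item_id %in% administered_ids(state))
    stop("item already administered: ", item_id)
  p <- cat_posterior(state)
  epv_from_weights(p$weights, state$grid$nodes, state$probs[[item_id]])
}

#' Select the next item by minimum expected posterior variance
#'
#' Returns the unadministered item whose administration minimizes the
#' expected posterior variance; ties break to the lexicographically
#' smallest item id so that sessions are fully deterministic. Applied to a
#' fresh state this same rule picks the first item (the item expected to be
#' most informative in the prior population).
#'
#' @param state a `cat_state`.
#' @return an item id.
#' @export
select_next_item <- function(state) {
  stopifnot(inherits(state, "cat_state"))
  cand <- setdiff(state$bank$item_id, administered_ids(state))
  if (!length(cand)) stop("item bank exhausted")
  cand <- sort(cand)
  p <- cat_posterior(state)
  best <- cand[1L]
  best_v <- Inf
  for (id in cand) {
    v <- epv_from_weights(p$weights, state$grid$nodes, state$probs[[id]])
    if (v < best_v) {
      best_v <- v
      best <- id
    }
  }
  best
}

#' Record a response and update the posterior
#'
#' @param state a `cat_state`.
#' @param item_id the administered item.
#' @param response 0-based category.
#' @return the updated `cat_state`.
#' @export
cat_update <- function(state, item_id, response) {
  stopifnot(inherits(state, "cat_state"))
  if (item_id %in% administered_ids(state))
    stop("item already administered: ", item_id)
  P <- state$probs[[item_id]]
  if (is.null(P)) stop("unknown item: ", item_id)
  response <- as.integer(response)
  if (is.na(response) || response < 0L || response > ncol(P) - 1L)
    stop(sprintf("response category out of range for item '%s'", item_id))
  state$logpost <- state$logpost + log(P[, response + 1L])
  state$administered <- c(state$administered,
                          list(list(item_id = item_id, response = response)))
  state
}

#' Simulate one fixed-length adaptive assessment
#'
#' Runs a computerized adaptive test against a simulated respondent whose
#' full-length responses are pre-recorded: items are selected by minimum
#' expected posterior variance, "administered" by reading the recorded
#' response, and the posterior updated, for exactly `max_items` items (the
#' fixed-length stopping rule; no standard-error or other stopping
#' criterion). The final score is the EAP estimate on the final posterior.
#'
#' @param true_responses named integer vector (0-based categories) covering
#'   every bank item.
#' @param bank an [item_bank()].
#' @param max_items fixed assessment length, `0 <= max_items <= length(bank)`.
#' @param grid a [quad_grid()].
#' @param trajectory if `TRUE`, also record the EAP estimate after every
#'   administered item.
#' @return object of class `cat_session`: list with `administered` (ordered
#'   (item_id, response) pairs), `theta_hat`, `se`, `n_items`, and
#'   optionally `trajectory` (data frame `step`, `theta_hat`, `se`).
#' @export
run_cat_session <- function(true_responses, bank, max_items,
                            grid = quad_grid(), trajectory = FALSE) {
  stopifnot(inherits(bank, "item_bank"))
  max_items <- as.integer(max_items)
  if (max_items < 0L || max_items > length(bank))
    stop("max_items must be between 0 and the bank size")
  missing_items <- setdiff(bank$item_id, names(true_responses))
  if (length(missing_items))
    stop("true_responses missing items: ",
         paste(missing_items, collapse = ", "))
  state <- cat_state_init(bank, grid)
  traj <- if (trajectory)
    data.frame(step = integer(), theta_hat = numeric(), se = numeric())
  for (step in seq_len(max_items)) {
    id <- select_next_item(state)
    state <- cat_update(state, id, true_responses[[id]])
    if (trajectory) {
      p <- cat_posterior(state)
      traj <- rbind(traj, data.frame(step = step, theta_hat = p$mean,
                                     se = p$sd))
    }
  }
  p <- cat_posterior(state)
  structure(list(administered = state$administered, theta_hat = p$mean,
                 se = p$sd, n_items = length(state$administered),
                 trajectory = traj),
            class = "cat_session")
}

#' @export
print.cat_session <- function(x, ...) {
  seqs <- vapply(x$administered, function(a)
    sprintf("%s=%d", a$item_id, a$response), character(1))
  cat(sprintf("CAT session: %d items [%s]\n  theta_hat %.3f (se %.3f)\n",
              x$n_items, paste(seqs, collapse = ", "), x$theta_hat, x$se))
  invisible(x)
}

#' Simulate adaptive sessions for a whole test sample
#'
#' @param responses integer response matrix (persons x bank items).
#' @param bank an [item_bank()].
#' @param max_items fixed assessment length.
#' @param grid a [quad_grid()].
#' @param trajectory record per-step EAP estimates (see
#'   [run_cat_session()]).
#' @return list of `cat_session` objects, one per row.
#' @export
run_cat_batch <- function(responses, bank, max_items, grid = quad_grid(),
                          trajectory = FALSE) {
  responses <- as_response_matrix(responses)
  lapply(seq_len(nrow(responses)), function(i)
    run_cat_session(responses[i, ], bank, max_items, grid,
                    trajectory = trajectory))
}

#' Write CAT session logs as JSON lines
#'
#' One session per line: person id, the ordered administered pairs, the
#' final score and its standard error.
#'
#' @param sessions list of `cat_session` objects.
#' @param path output file.
#' @param person_id optional ids (default row number).
#' @return `path`, invisibly.
#' @export
write_session_log <- function(sessions, path, person_id = NULL) {
  if (is.null(person_id)) person_id <- seq_along(sessions)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    rec <- list(person_id = person_id[[i]],
                administered = lapply(s$administered, function(a)
                  list(item_id = a$item_id, response = a$response)),
                theta_hat = s$theta_hat, se = s$se, n_items = s$n_items)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
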