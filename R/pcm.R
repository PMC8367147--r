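#' Partial credit model category probabilities
#'
#' For an item with step thresholds `delta_1..delta_K` (K + 1 categories) the
#' probability of response category k (0-based) at latent trait `theta` is
#' proportional to `exp(sum_{j<=k} (theta - delta_j))`, with the k = 0 term
#' equal to 1. This is the Rasch-family model for ordered polytomous items;
#' discrimination is fixed at 1.
#'
#' @param theta numeric vector of latent-trait values (logits), all finite.
#' @param thresholds numeric vector of step thresholds for one item.
#' @return matrix `length(theta) x (length(thresholds) + 1)`; rows sum to 1.
#' @examples
#' pcm_category_probs(0, 0)          # c(0.5, 0.5)
#' pcm_category_probs(0, c(0, 0))    # thirds
#' @export
pcm_category_probs <- function(theta, thresholds) {
  if (!all(is.finite(theta))) stop("theta must be finite")
  thresholds <- as.numeric(thresholds)
  K <- length(thresholds)
  # log numerator for category k: k*theta - cumsum(delta)[k]
  cum <- c(0, cumsum(thresholds))
  lognum <- outer(theta, 0:K) - rep(cum, each = length(theta))
  lognum <- lognum - apply(lognum, 1L, max)
  num <- exp(lognum)
  num / rowSums(num)
}

# list of (n_nodes x n_cat) probability matrices, one per item, at the grid
# nodes -- the workhorse precomputation shared by EM, EAP and the CAT.
bank_grid_probs <- function(bank, grid) {
  lapply(bank$thresholds, function(d) pcm_category_probs(grid$nodes, d))
}

# n_persons x n_nodes joint log-likelihood of the observed responses.
# responses: integer matrix (0-based categories, NA = not administered),
# columns named by item_id and matched to the bank.
response_loglik <- function(responses, bank, grid, probs = NULL) {
  if (is.null(probs)) probs <- bank_grid_probs(bank, grid)
  n <- nrow(responses)
  ll <- matrix(0, n, length(grid$nodes))
  for (id in colnames(responses)) {
    x <- responses[, id]
    obs <- !is.na(x)
    if (!any(obs)) next
    P <- probs[[id]]
    if (any(x[obs] < 0L | x[obs] > ncol(P) - 1L))
      stop(sprintf("response category out of range for item '%s'", id))
    ll[obs, ] <- ll[obs, , drop = FALSE] + log(t(P))[x[obs] + 1L, , drop = FALSE]
  }
  ll
}

#' Expected a posteriori (EAP) person scores
#'
#' Computes the posterior mean and SD of the latent trait for each person
#' given any subset of item responses, under the grid's standard-normal
#' prior: `posterior ~ prior_weights * prod(item likelihoods)`. With no
#' responses the posterior is the prior (score 0, SE ~ 1). Scores are
#' person-location logits.
#'
#' @param responses integer matrix or data frame of 0-based categories, one
#'   row per person, columns named by item id; `NA` marks an item not
#'   administered. A named vector is treated as a single person.
#' @param bank an [item_bank()] containing every responded item.
#' @param grid a [quad_grid()] (default 61 nodes on \[-6, 6\]).
#' @return data frame with columns `theta_hat` and `se` (posterior SD > 0).
#' @examples
#' b <- item_bank("i1", list(0))
#' eap_score(c(i1 = 1L), b)
#' @export
eap_score <- function(responses, bank, grid = quad_grid()) {
  stopifnot(inherits(bank, "item_bank"))
  grid <- as_quad_grid(grid)
  responses <- as_response_matrix(responses)
  unknown <- setdiff(colnames(responses), bank$item_id)
  if (length(unknown))
    stop("items not in bank: ", paste(unknown, collapse = ", "))
  ll <- response_loglik(responses, bank, grid)
  post <- exp(ll - apply(ll, 1L, max))
  post <- post * rep(grid$weights, each = nrow(post))
  post <- post / rowSums(post)
  m1 <- drop(post %*% grid$nodes)
  m2 <- drop(post %*% grid$nodes^2)
  data.frame(theta_hat = m1, se = sqrt(pmax(m2 - m1^2, 0)))
}

# coerce vectors / data frames to the canonical integer response matrix
as_response_matrix <- function(responses) {
  if (is.null(dim(responses))) {
    if (is.null(names(responses)))
      stop("a response vector must be named by item_id")
    responses <- matrix(responses, nrow = 1L,
                        dimnames = list(NULL, names(responses)))
  }
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    stop("response columns must be named by item_id")
  storage.mode(responses) <- "integer"
  responses
}

#' Calibrate a partial credit model by fixed-quadrature EM
#'
#' Marginal maximum likelihood estimation of the step thresholds under a
#' standard-normal latent-trait prior, via the Bock-Aitkin EM algorithm on a
#' fixed quadrature grid. The E-step computes each person's posterior over
#' the nodes; the M-step maximizes the expected complete-data log-likelihood
#' item by item (BFGS with analytic gradient). The prior is never updated
#' (mean/variance anchoring identifies the latent scale).
#'
#' @param responses complete integer matrix of 0-based categories, columns
#'   named by item id; every category of every item must be observed.
#' @param grid a [quad_grid()].
#' @param n_categories optional named integer vector forcing the category
#'   count per item (default: inferred as `max(response) + 1`).
#' @param tol convergence tolerance: maximum absolute threshold change
#'   between cycles (logits, default 1e-4).
#' @param max_iter maximum EM cycles (default 500). Non-convergence is
#'   flagged on the result (and warned), never silent.
#' @return object of class `pcm_fit`: list with `bank` (the calibrated
#'   [item_bank()]), `converged`, `iterations`, `max_change`, `loglik`
#'   (marginal), `grid`, and `n`.
#' @examples
#' set.seed(1)
#' b <- item_bank("i1", list(0))
#' x <- cbind(i1 = rbinom(400, 1, 0.5))
#' fit <- pcm_calibrate(x)
#' coef(fit)
#' @export
pcm_calibrate <- function(responses, grid = quad_grid(), n_categories = NULL,
                          tol = 1e-4, max_iter = 500L) {
  grid <- as_quad_grid(grid)
  responses <- as_response_matrix(responses)
  if (anyNA(responses)) stop("calibration requires complete responses")
  ids <- colnames(responses)
  if (anyDuplicated(ids)) stop("duplicate item ids in response matrix")

  ncat <- vapply(ids, function(id) {
    if (!is.null(n_categories) && id %in% names(n_categories))
      as.integer(n_categories[[id]]) else max(responses[, id]) + 1L
  }, integer(1))
  for (id in ids) {
    seen <- sort(unique(responses[, id]))
    need <- 0:(ncat[[id]] - 1L)
    missing_cat <- setdiff(need, seen)
    if (any(responses[, id] < 0L) || any(seen > ncat[[id]] - 1L))
      stop(sprintf("item '%s': response outside categories 0..%d",
                   id, ncat[[id]] - 1L))
    if (length(missing_cat))
      stop(sprintf("item '%s': category %s never observed",
                   id, paste(missing_cat, collapse = ", ")))
    if (ncat[[id]] < 2L) stop(sprintf("item '%s': needs >= 2 categories", id))
  }

  nodes <- grid$nodes
  Q <- length(nodes)
  delta <- lapply(ids, function(id) numeric(ncat[[id]] - 1L))
  names(delta) <- ids
  logw <- log(grid$weights)
  iter <- 0L
  max_change <- Inf
  loglik <- NA_real_

  # expected complete-data negative log-likelihood and gradient for one item
  item_obj <- function(d, r) {
    # r: ncat x Q expected counts at the nodes
    P <- pcm_category_probs(nodes, d)        # Q x ncat
    val <- -sum(r * t(log(P)))
    K <- length(d)
    Nq <- colSums(r)                         # total mass per node
    # d(-loglik)/d(delta_j) = sum_q [ sum_{k>=j} r_kq - N_q * P(X>=j | q) ]
    gr <- vapply(seq_len(K), function(j) {
      Sj <- rowSums(P[, (j + 1L):(K + 1L), drop = FALSE])
      sum(r[(j + 1L):(K + 1L), , drop = FALSE]) - sum(Nq * Sj)
    }, numeric(1))
    list(value = val, gradient = gr)
  }

  repeat {
    iter <- iter + 1L
    bank <- item_bank(ids, delta)
    ll <- response_loglik(responses, bank, grid)
    lmax <- apply(ll, 1L, max)
    joint <- exp(ll - lmax + rep(logw, each = nrow(ll)))
    marg <- rowSums(joint)
    loglik <- sum(log(marg) + lmax)
    post <- joint / marg                      # n x Q person posteriors

    new_delta <- delta
    for (id in ids) {
      r <- rowsum(post, group = responses[, id], reorder = TRUE)  # ncat x Q
      fit <- stats::optim(delta[[id]],
                          fn = function(d) item_obj(d, r)$value,
                          gr = function(d) item_obj(d, r)$gradient,
                          method = "BFGS",
                          control = list(maxit = 100, reltol = 1e-12))
      new_delta[[id]] <- fit$par
    }
    max_change <- max(abs(unlist(new_delta) - unlist(delta)))
    delta <- new_delta
    if (max_change < tol || iter >= max_iter) break
  }

  converged <- max_change < tol
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles (max change %.2e)",
                    iter, max_change))
  structure(list(bank = item_bank(ids, delta), converged = converged,
                 iterations = iter, max_change = max_change,
                 loglik = loglik, grid = grid, n = nrow(responses)),
            class = "pcm_fit")
}

#' @export
print.pcm_fit <- function(x, ...) {
  cat(sprintf(paste0("Partial credit model fit (fixed-quadrature EM)\n",
                     "  %d persons, %d items; %s in %d cycles ",
                     "(max change %.2e)\n  marginal log-likelihood %.2f\n"),
              x$n, length(x$bank),
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_change, x$loglik))
  invisible(x)
}

#' @export
coef.pcm_fit <- function(object, ...) {
  d <- object$bank$thresholds
  K <- max(lengths(d))
  out <- t(vapply(d, function(v) c(v, rep(NA_real_, K - length(v))),
                  numeric(K)))
  colnames(out) <- paste0("delta_", seq_len(K))
  out
}

#' @export
summary.pcm_fit <- function(object, ...) {
  cat(sprintf("Calibrated thresholds (logits), n = %d:\n", object$n))
  print(round(coef(object), 4))
  invisible(object)
}

#' Simulate responses from a calibrated partial credit model
#'
#' Draws complete response matrices at given person locations, one category
#' draw per person-item from [pcm_category_probs()].
#'
#' @param object a `pcm_fit`.
#' @param nsim number of replicate matrices.
#' @param seed integer seed (RNG state is restored on exit).
#' @param theta person locations to simulate at (default: `object$n` draws
#'   from N(0,1)).
#' @param ... unused.
#' @return a list of integer response matrices (length `nsim`).
#' @export
simulate.pcm_fit <- function(object, nsim = 1, seed = NULL, theta = NULL, ...) {
  run <- function() {
    if (is.null(theta)) theta <- stats::rnorm(object$n)
    lapply(seq_len(nsim), function(i)
      draw_pcm_responses(theta, object$bank))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# vectorized categorical draw per item at the given thetas
draw_pcm_responses <- function(theta, bank) {
  n <- length(theta)
  out <- matrix(0L, n, length(bank),
                dimnames = list(NULL, bank$item_id))
  for (id in bank$item_id) {
    P <- pcm_category_probs(theta, bank$thresholds[[id]])
    cum <- P %*% upper.tri(diag(ncol(P)), diag = TRUE)
    u <- stats::runif(n)
    out[, id] <- as.integer(rowSums(u > cum))
  }
  out
}

#' Whole-sample ground-truth scores
#'
#' Calibrates the partial credit model on the full sample and EAP-scores
#' every person on all items of the scale. These full-length,
#' whole-calibration scores are the reference ("ground truth") that both
#' the adaptive test and the regression tree try to recover from fewer
#' items.
#'
#' @inheritParams pcm_calibrate
#' @return list with `fit` (the `pcm_fit`) and `scores` (data frame of
#'   `theta_hat`, `se`, one row per person).
#' @export
ground_truth_scores <- function(responses, grid = quad_grid(), tol = 1e-4,
                                max_iter = 500L) {
  fit <- pcm_calibrate(responses, grid = grid, tol = tol, max_iter = max_iter)
  list(fit = fit,
       scores = eap_score(as_response_matrix(responses), fit$bank, grid))
}

# run expr with a temporary RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  expr <- substitute(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval(expr, envir = parent.frame())
}
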