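# Independent oracles used across the suite. Each one deliberately takes a
# different computational route from the package code it checks.

# Partial credit category probabilities by direct summation of the
# exponentiated score terms (no softmax shift, scalar theta).
pcm_probs_direct <- function(theta, thresholds) {
  K <- length(thresholds)
  num <- numeric(K + 1)
  for (k in 0:K) {
    s <- 0
    if (k > 0) for (j in 1:k) s <- s + (theta - thresholds[j])
    num[k + 1] <- exp(s)
  }
  num / sum(num)
}

# EAP by brute-force trapezoidal integration of the continuous posterior
# over a dense theta range, standard-normal prior (not renormalized).
eap_bruteforce <- function(responses, bank, n_points = 100001L,
                           range = c(-8, 8)) {
  th <- seq(range[1], range[2], length.out = n_points)
  dens <- stats::dnorm(th)
  for (id in names(responses)) {
    x <- responses[[id]]
    if (is.na(x)) next
    p <- vapply(th, function(t)
      pcm_probs_direct(t, bank$thresholds[[id]])[x + 1], numeric(1))
    dens <- dens * p
  }
  w <- rep(1, n_points)
  w[c(1, n_points)] <- 0.5                      # trapezoid ends
  m1 <- sum(w * th * dens) / sum(w * dens)
  m2 <- sum(w * th^2 * dens) / sum(w * dens)
  list(theta_hat = m1, se = sqrt(m2 - m1^2))
}

# Vectorized fine-grid EAP oracle: precomputes every item's category
# probabilities on a dense trapezoid grid once, then scores response
# vectors by direct accumulation (independent of the package's quadrature
# and scoring code paths).
make_fine_oracle <- function(bank, n_points = 100001L, range = c(-8, 8)) {
  th <- seq(range[1], range[2], length.out = n_points)
  w <- rep(1, n_points)
  w[c(1, n_points)] <- 0.5
  prior <- stats::dnorm(th)
  probs <- lapply(bank$thresholds, function(d) {
    K <- length(d)
    lognum <- sapply(0:K, function(k)
      k * th - if (k > 0) sum(d[1:k]) else 0)
    num <- exp(lognum)
    num / rowSums(num)
  })
  function(resp) {
    dens <- prior
    for (id in names(resp)) {
      if (is.na(resp[[id]])) next
      dens <- dens * probs[[id]][, resp[[id]] + 1]
    }
    m1 <- sum(w * th * dens) / sum(w * dens)
    m2 <- sum(w * th^2 * dens) / sum(w * dens)
    c(theta_hat = m1, se = sqrt(m2 - m1^2))
  }
}

# Expected posterior variance by explicit enumeration over candidate
# response categories, recomputing each hypothetical posterior from the
# administered responses on the supplied grid.
epv_bruteforce <- function(administered, candidate_id, bank, grid) {
  dens <- grid$weights
  for (a in administered) {
    p <- t(vapply(grid$nodes, function(t)
      pcm_probs_direct(t, bank$thresholds[[a$item_id]]),
      numeric(length(bank$thresholds[[a$item_id]]) + 1)))
    dens <- dens * p[, a$response + 1]
  }
  post <- dens / sum(dens)
  thr <- bank$thresholds[[candidate_id]]
  Pc <- t(vapply(grid$nodes, function(t) pcm_probs_direct(t, thr),
                 numeric(length(thr) + 1)))
  total <- 0
  for (k in seq_len(ncol(Pc))) {
    pk <- sum(post * Pc[, k])
    hypo <- post * Pc[, k] / pk
    m1 <- sum(hypo * grid$nodes)
    total <- total + pk * (sum(hypo * grid$nodes^2) - m1^2)
  }
  total
}

# Total SSE of the globally optimal depth-<=2 binary tree, by exhaustive
# enumeration: every root split, and for each child the exhaustive best
# single split (children are independent, so this enumerates all trees).
all_splits <- function(y, data) {
  out <- list()
  for (v in names(data)) {
    x <- data[[v]]
    if (is.numeric(x)) {
      vals <- sort(unique(x))
      if (length(vals) < 2) next
      for (i in seq_len(length(vals) - 1)) {
        thr <- (vals[i] + vals[i + 1]) / 2
        out[[length(out) + 1]] <- list(left = x <= thr)
      }
    } else {
      lev <- sort(unique(as.character(x)))
      if (length(lev) < 2) next
      for (mask in 0:(2^(length(lev) - 1) - 1)) {
        inl <- c(TRUE, bitwAnd(mask, 2^(0:(length(lev) - 2))) > 0)
        out[[length(out) + 1]] <-
          list(left = as.character(x) %in% lev[inl])
      }
    }
  }
  out
}

sse_of <- function(y) if (length(y)) sum((y - mean(y))^2) else 0

best_subtree_sse <- function(y, data, depth) {
  base <- sse_of(y)
  if (depth == 0 || length(y) < 2) return(base)
  best <- base
  for (s in all_splits(y, data)) {
    if (!any(s$left) || all(s$left)) next
    val <- best_subtree_sse(y[s$left], data[s$left, , drop = FALSE],
                            depth - 1) +
      best_subtree_sse(y[!s$left], data[!s$left, , drop = FALSE],
                       depth - 1)
    if (val < best) best <- val
  }
  best
}

# Two-sided permutation p-value for the paired signed-rank statistic,
# by Monte Carlo sign flips.
wilcoxon_permutation_p <- function(a, b, n_resample = 1e5, seed = 42) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  signs <- matrix(stats::runif(n_resample * n) < 0.5, n_resample, n)
  w_perm <- signs %*% r
  mean(abs(w_perm - mu) >= abs(w_obs - mu))
}

# small deterministic mixed-type regression fixture
make_tree_fixture <- function(n, seed) {
  set.seed(seed)
  d <- data.frame(
    x1 = sample(0:3, n, replace = TRUE),
    x2 = sample(0:3, n, replace = TRUE),
    x3 = round(stats::runif(n, 0, 10), 2),
    g = sample(c("a", "b", "c"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  d$y <- 0.8 * d$x1 - 0.5 * d$x2 + 0.1 * d$x3 +
    ifelse(d$g == "b", 0.7, 0) + stats::rnorm(n, sd = 0.5)
  d
}

# small calibrated bank + cohort for CAT / scoring tests
make_test_cohort <- function(n, n_items = 6, seed = 77, effects = TRUE) {
  cov <- if (effects) default_covariates() else list()
  cfg <- synth_config(n, n_items = n_items, seed = seed, covariates = cov)
  bank <- generate_item_bank(cfg)
  list(config = cfg, bank = bank, cohort = generate_cohort(cfg, bank))
}
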