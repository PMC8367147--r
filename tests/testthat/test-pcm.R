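test_that("partial credit probabilities match closed forms", {
  expect_equal(drop(pcm_category_probs(0, 0)), c(0.5, 0.5))
  expect_equal(drop(pcm_category_probs(0, c(0, 0))), rep(1 / 3, 3))
  e <- exp(1)
  expect_equal(drop(pcm_category_probs(1, 0)),
               c(1 / (1 + e), e / (1 + e)), tolerance = 1e-12)
  expect_error(pcm_category_probs(NA_real_, 0), "finite")
  expect_error(pcm_category_probs(Inf, 0), "finite")
})

test_that("category probabilities sum to one across the trait range", {
  set.seed(4)
  for (rep in 1:20) {
    K <- sample(1:3, 1)
    thr <- rnorm(K, sd = 2)
    P <- pcm_category_probs(seq(-6, 6, by = 0.25), thr)
    expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-12)
    expect_true(all(P > 0 & P < 1))
    expect_equal(unname(drop(pcm_category_probs(1.3, thr))),
                 pcm_probs_direct(1.3, thr), tolerance = 1e-12)
  }
})

test_that("EAP with no responses reproduces the prior", {
  b <- item_bank("i1", list(0))
  empty <- matrix(NA_integer_, 1, 1, dimnames = list(NULL, "i1"))
  s <- eap_score(empty, b)
  expect_equal(s$theta_hat, 0, tolerance = 1e-12)
  expect_equal(s$se, 1, tolerance = 0.01)   # truncated-normal SD on the grid
})

test_that("EAP is antisymmetric between mirrored response vectors", {
  b <- item_bank(paste0("i", 1:4), rep(list(c(0, 0, 0)), 4))
  lo <- matrix(0L, 1, 4, dimnames = list(NULL, b$item_id))
  hi <- matrix(3L, 1, 4, dimnames = list(NULL, b$item_id))
  expect_equal(eap_score(lo, b)$theta_hat, -eap_score(hi, b)$theta_hat,
               tolerance = 1e-10)
})

test_that("default-grid EAP matches brute-force numerical integration", {
  b <- item_bank("i1", list(0))
  got <- eap_score(c(i1 = 1L), b)
  want <- eap_bruteforce(list(i1 = 1L), b)
  expect_equal(got$theta_hat, want$theta_hat, tolerance = 1e-3)
  expect_equal(got$se, want$se, tolerance = 1e-3)
})

test_that("EAP rejects out-of-range categories", {
  b <- item_bank("i1", list(c(0, 1)))
  expect_error(eap_score(c(i1 = 5L), b), "out of range")
})

test_that("EM calibration recovers generating thresholds", {
  # moderate-spread bank so every category is well observed at n = 1000:
  # recovery error should then reflect the estimator, not a category with
  # a handful of responses
  cfg <- synth_config(1000, n_items = 5, threshold_spread = 0.7,
                      covariates = list(), seed = 21)
  bank <- generate_item_bank(cfg)
  cohort <- generate_cohort(cfg, bank)
  expect_gte(min(apply(cohort$responses, 2,
                       function(x) min(tabulate(x + 1L, 4L)))), 20L)
  fit <- pcm_calibrate(cohort$responses)
  expect_true(fit$converged)
  rmse <- sqrt(mean((unlist(fit$bank$thresholds) -
                       unlist(bank$thresholds))^2))
  expect_lt(rmse, 0.15)
})

test_that("EM calibration is deterministic and symmetric data gives a zero threshold", {
  x <- cbind(i1 = rep(0:1, each = 300))
  fit <- pcm_calibrate(x)
  expect_equal(fit$bank$thresholds[["i1"]], 0, tolerance = 1e-3)

  fx <- make_test_cohort(150, n_items = 4, seed = 5)
  f1 <- pcm_calibrate(fx$cohort$responses)
  f2 <- pcm_calibrate(fx$cohort$responses)
  expect_identical(coef(f1), coef(f2))
})

test_that("EM calibration validates its inputs loudly", {
  x <- cbind(i1 = c(0L, 1L, 1L, 0L), i2 = c(0L, 0L, 0L, 0L))
  expect_error(pcm_calibrate(x, n_categories = c(i1 = 2L, i2 = 2L)),
               "i2.*category 1 never observed")
  expect_error(pcm_calibrate(x), "i2.*>= 2 categories")
  x2 <- cbind(i1 = c(0L, NA, 1L))
  expect_error(pcm_calibrate(x2), "complete")
  expect_warning(
    fit <- pcm_calibrate(cbind(i1 = rep(c(0L, 1L, 2L), 50)), max_iter = 2L),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 2L)
})

test_that("ground-truth scoring is complete, deterministic and sum-score monotone", {
  fx <- make_test_cohort(400, n_items = 6, seed = 9)
  gt <- ground_truth_scores(fx$cohort$responses)
  expect_equal(nrow(gt$scores), 400)

  # identical response vectors get identical scores
  resp <- fx$cohort$responses
  dup <- which(duplicated(resp) | duplicated(resp, fromLast = TRUE))
  key <- apply(resp, 1, paste, collapse = "")
  for (k in unique(key[dup]))
    expect_lt(diff(range(gt$scores$theta_hat[key == k])), 1e-12)

  # Rasch sum-score sufficiency: EAP is a function of the raw sum, and a
  # non-decreasing one
  sums <- rowSums(resp)
  for (s in unique(sums))
    expect_lt(diff(range(gt$scores$theta_hat[sums == s])), 1e-10)
  agg <- tapply(gt$scores$theta_hat, sums, mean)
  expect_true(all(diff(agg[order(as.numeric(names(agg)))]) > 0))
})

test_that("quadrature fidelity: default grid matches a 10x finer grid", {
  fx <- make_test_cohort(40, n_items = 6, seed = 13)
  fine <- quad_grid(601L)
  a <- eap_score(fx$cohort$responses, fx$bank)
  b <- eap_score(fx$cohort$responses, fx$bank, fine)
  expect_lt(max(abs(a$theta_hat - b$theta_hat)), 1e-3)
})

test_that("simulate.pcm_fit round-trips through calibration machinery", {
  fx <- make_test_cohort(300, n_items = 4, seed = 31)
  fit <- pcm_calibrate(fx$cohort$responses)
  sims <- simulate(fit, nsim = 2, seed = 8)
  expect_length(sims, 2)
  expect_equal(dim(sims[[1]]), dim(fx$cohort$responses))
  expect_true(all(sims[[1]] >= 0 & sims[[1]] <= 3))
  expect_identical(simulate(fit, seed = 8)[[1]], sims[[1]])
})
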