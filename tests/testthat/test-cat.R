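bank3 <- item_bank(c("easy", "mid", "hard"), list(-2, 0, 2))

test_that("an uninformative candidate leaves the posterior variance unchanged", {
  b <- item_bank(c("mid", "flat", "vflat"), list(0, 10, 30))
  st <- cat_state_init(b)
  p <- promcat:::cat_posterior(st)
  # a +10-logit step still leaks ~e^-4 response probability at the top of
  # the trait range; +30 is deterministic to machine precision
  expect_equal(expected_posterior_variance(st, "flat"), p$sd^2,
               tolerance = 1e-3)
  expect_equal(expected_posterior_variance(st, "vflat"), p$sd^2,
               tolerance = 1e-9)
  expect_lt(expected_posterior_variance(st, "mid"), p$sd^2)
})

test_that("expected posterior variance matches brute-force enumeration", {
  fx <- make_test_cohort(5, n_items = 5, seed = 3)
  grid <- quad_grid()
  st <- cat_state_init(fx$bank, grid)
  st <- cat_update(st, "item02", 1L)
  st <- cat_update(st, "item04", 3L)
  for (id in c("item01", "item03", "item05")) {
    expect_equal(expected_posterior_variance(st, id),
                 epv_bruteforce(st$administered, id, fx$bank, grid),
                 tolerance = 1e-6)
  }
  expect_error(expected_posterior_variance(st, "item02"),
               "already administered")
})

test_that("items matched to the current estimate are preferred", {
  b <- item_bank(c("b0", "b3"), list(0, 3))
  st <- cat_state_init(b)
  expect_lt(expected_posterior_variance(st, "b0"),
            expected_posterior_variance(st, "b3"))
})

test_that("MEPV selection matches the argmin oracle as the session evolves", {
  st <- cat_state_init(bank3)
  expect_identical(select_next_item(st), "mid")
  st <- cat_update(st, "mid", 1L)   # top category -> posterior shifts up
  expect_identical(select_next_item(st), "hard")

  # agreement with explicit argmin over candidates at every tested state
  fx <- make_test_cohort(4, n_items = 6, seed = 19)
  for (person in 1:4) {
    st <- cat_state_init(fx$bank)
    for (step in 1:5) {
      cand <- setdiff(fx$bank$item_id, promcat:::administered_ids(st))
      epv <- vapply(cand, function(id)
        expected_posterior_variance(st, id), numeric(1))
      picked <- select_next_item(st)
      expect_identical(picked, cand[which.min(epv)])
      st <- cat_update(st, picked, fx$cohort$responses[person, picked])
    }
  }

  one <- cat_state_init(item_bank("only", list(0)))
  expect_identical(select_next_item(one), "only")
})

test_that("sessions respect the fixed-length stopping rule and never repeat items", {
  fx <- make_test_cohort(10, n_items = 6, seed = 23)
  resp <- fx$cohort$responses
  s0 <- run_cat_session(resp[1, ], fx$bank, 0)
  expect_equal(s0$theta_hat, 0, tolerance = 1e-12)
  expect_equal(s0$n_items, 0L)

  for (i in 1:10) {
    s <- run_cat_session(resp[i, ], fx$bank, 4)
    ids <- vapply(s$administered, `[[`, character(1), "item_id")
    expect_equal(s$n_items, 4L)
    expect_false(anyDuplicated(ids) > 0)
  }
  expect_error(run_cat_session(resp[1, ], fx$bank, 7), "bank size")
  expect_error(run_cat_session(resp[1, -2], fx$bank, 2), "missing items")
})

test_that("a full-length session reproduces the full-scale EAP score", {
  fx <- make_test_cohort(40, n_items = 6, seed = 29)
  full <- eap_score(fx$cohort$responses, fx$bank)
  sessions <- run_cat_batch(fx$cohort$responses, fx$bank, 6)
  expect_equal(vapply(sessions, `[[`, numeric(1), "theta_hat"),
               full$theta_hat, tolerance = 1e-12)
  expect_equal(vapply(sessions, `[[`, numeric(1), "se"),
               full$se, tolerance = 1e-12)
})

test_that("a scripted three-item dichotomous session matches the hand-run oracle", {
  b <- item_bank(c("d1", "d2", "d3"), list(-1, 0, 1))
  grid <- quad_grid()
  resp <- c(d1 = 1L, d2 = 1L, d3 = 1L)

  # oracle: enumerate MEPV by brute force at each step
  admin <- list()
  for (step in 1:2) {
    cand <- setdiff(b$item_id, vapply(admin, `[[`, character(1), "item_id"))
    epv <- vapply(cand, function(id)
      epv_bruteforce(admin, id, b, grid), numeric(1))
    pick <- cand[which.min(epv)]
    admin <- c(admin, list(list(item_id = pick, response = resp[[pick]])))
  }
  oracle_ids <- vapply(admin, `[[`, character(1), "item_id")
  oracle_score <- eap_bruteforce(
    stats::setNames(as.list(resp[oracle_ids]), oracle_ids), b)

  s <- run_cat_session(resp, b, 2, grid)
  expect_identical(vapply(s$administered, `[[`, character(1), "item_id"),
                   oracle_ids)
  expect_equal(s$theta_hat, oracle_score$theta_hat, tolerance = 1e-3)
})

test_that("longer assessments are more accurate on average", {
  fx <- make_test_cohort(500, n_items = 8, seed = 37)
  sessions <- run_cat_batch(fx$cohort$responses, fx$bank, 8,
                            trajectory = TRUE)
  theta <- fx$cohort$theta
  mse <- vapply(2:8, function(L) {
    est <- vapply(sessions, function(s) s$trajectory$theta_hat[L],
                  numeric(1))
    mean((est - theta)^2)
  }, numeric(1))
  expect_true(all(diff(mse) <= 0.05 * mse[-length(mse)]))
})

test_that("session logs round-trip as JSON lines", {
  fx <- make_test_cohort(3, n_items = 4, seed = 41)
  sessions <- run_cat_batch(fx$cohort$responses, fx$bank, 2)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_session_log(sessions, path)
  lines <- readLines(path)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[2], simplifyVector = FALSE)
  expect_equal(rec$person_id, 2L)
  expect_equal(rec$theta_hat, sessions[[2]]$theta_hat)
  expect_length(rec$administered, 2)
})
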