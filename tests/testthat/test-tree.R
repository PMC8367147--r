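test_that("best_split arithmetic on a perfectly separable node", {
  s <- best_split(c(0, 0, 10, 10), data.frame(x = c(1, 1, 2, 2)))
  expect_equal(s$variable, "x")
  expect_equal(s$threshold, 1.5)
  expect_equal(s$improve, 100)  # parent SSE 4 * 5^2, children 0

  expect_null(best_split(rep(3, 10), data.frame(x = 1:10)))
  expect_null(best_split(rnorm(5), data.frame(x = 1:5)[, 0]))
})

test_that("best_split equals exhaustive enumeration on mixed predictors", {
  for (seed in c(2, 7)) {
    d <- make_tree_fixture(50, seed)
    got <- best_split(d$y, d[c("x1", "x2", "x3", "g")])
    gains <- vapply(all_splits(d$y, d[c("x1", "x2", "x3", "g")]),
                    function(s) {
                      if (!any(s$left) || all(s$left)) return(-Inf)
                      sse_of(d$y) - sse_of(d$y[s$left]) -
                        sse_of(d$y[!s$left])
                    }, numeric(1))
    expect_equal(got$improve, max(gains), tolerance = 1e-10)
  }
})

test_that("grow_tree honours depth limits and fits perfect predictors exactly", {
  d <- data.frame(b = rep(0:1, each = 20))
  d$y <- ifelse(d$b == 1, 2.5, -1)
  t0 <- grow_tree(d$y, d["b"], max_depth = 0)
  expect_null(t0$root$split)
  expect_equal(t0$root$value, mean(d$y))

  t1 <- grow_tree(d$y, d["b"], max_depth = 3)
  expect_equal(promcat:::tree_depth(t1$root), 1L)
  expect_equal(sort(c(t1$root$left$value, t1$root$right$value)),
               c(-1, 2.5))

  d2 <- make_tree_fixture(120, 3)
  for (depth in 0:3) {
    t <- grow_tree(d2$y, d2[c("x1", "x2", "x3", "g")], max_depth = depth)
    expect_lte(promcat:::tree_n_leaves(t$root), 2^depth)
    expect_lte(promcat:::tree_depth(t$root), depth)
  }
  expect_error(grow_tree(numeric(0), data.frame(x = numeric(0))), "empty")
})

test_that("greedy depth-2 trees attain the exhaustive-search optimum", {
  for (seed in 1:3) {
    d <- make_tree_fixture(80, seed)
    x <- d[c("x1", "x2", "x3", "g")]
    t <- grow_tree(d$y, x, max_depth = 2)
    expect_equal(promcat:::tree_leaf_sse(t$root),
                 best_subtree_sse(d$y, x, 2), tolerance = 1e-9)
  }
})

test_that("unpruned SSE matches an independent CART implementation", {
  for (seed in c(11, 12)) {
    d <- make_tree_fixture(200, seed)
    ours <- grow_tree(d$y, d[c("x1", "x2", "x3", "g")], max_depth = 3)
    ref <- rpart::rpart(y ~ x1 + x2 + x3 + g, data = d, method = "anova",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0,
                          maxdepth = 3, xval = 0, maxcompete = 0,
                          maxsurrogate = 0, usesurrogate = 0))
    ref_sse <- sum(ref$frame$dev[ref$frame$var == "<leaf>"])
    expect_equal(promcat:::tree_leaf_sse(ours$root), ref_sse,
                 tolerance = 1e-9)
  }
})

test_that("pruning satisfies the subtree and cp-monotonicity properties", {
  d <- make_tree_fixture(150, 5)
  full <- grow_tree(d$y, d[c("x1", "x2", "x3", "g")], max_depth = 4)

  expect_identical(prune(full, 0)$root, full$root)
  expect_null(prune(full, Inf)$root$split)

  is_subtree <- function(sub, sup) {
    if (is.null(sub$split)) return(TRUE)
    if (is.null(sup$split)) return(FALSE)
    identical(sub$split, sup$split) &&
      is_subtree(sub$left, sup$left) && is_subtree(sub$right, sup$right)
  }
  cps <- c(0, 1e-4, 1e-3, 0.01, 0.05, 0.2, 1)
  leaves <- integer(length(cps))
  for (i in seq_along(cps)) {
    p <- prune(full, cps[i])
    expect_true(is_subtree(p$root, full$root))
    leaves[i] <- promcat:::tree_n_leaves(p$root)
  }
  expect_true(all(diff(leaves) <= 0))
})

test_that("cross-validation prunes pure noise to the root in most seeds", {
  prunes_to_root <- 0L
  for (seed in 1:10) {
    set.seed(1000 + seed)
    d <- data.frame(x1 = sample(0:3, 500, TRUE),
                    x2 = sample(0:3, 500, TRUE),
                    x3 = runif(500))
    y <- rnorm(500)
    sel <- cv_select_cp(y, d, max_depth = 3, seed = seed)
    expect_false(any(is.na(sel$cp_table$cv_error)))
    pruned <- prune(grow_tree(y, d, max_depth = 3), sel$cp)
    if (is.null(pruned$root$split)) prunes_to_root <- prunes_to_root + 1L
  }
  expect_gte(prunes_to_root, 9L)
})

test_that("cross-validation keeps a strong single-variable signal", {
  set.seed(77)
  d <- data.frame(x1 = sample(0:3, 400, TRUE), x2 = runif(400))
  y <- 2 * (d$x1 >= 2) + rnorm(400, sd = 0.2)
  sel <- cv_select_cp(y, d, max_depth = 3, seed = 1)
  pruned <- prune(grow_tree(y, d, max_depth = 3), sel$cp)
  expect_false(is.null(pruned$root$split))
  expect_equal(pruned$root$split$variable, "x1")
})

test_that("prediction routes to leaf means and counts distinct items", {
  d <- make_tree_fixture(100, 8)
  fit <- reg_tree(y ~ x1 + x2 + x3 + g, d, max_depth = 2,
                  item_vars = c("x1", "x2"), folds = 5, seed = 2)
  pred <- predict(fit, d)
  expect_equal(pred, fit$fitted)
  expect_equal(residuals(fit), d$y - pred)
  expect_lte(count_unique_scores(pred),
             promcat:::tree_n_leaves(fit$root))

  # hand-built tree: item3 / age / item3 / cleft_type along one path
  leaf <- function(v) list(n = 1L, value = v, sse = 0, depth = NA,
                           split = NULL, left = NULL, right = NULL)
  node <- function(var, thr, is_item, l, r)
    list(n = 2L, value = 0, sse = 1, depth = NA,
         split = list(variable = var, kind = "ordered_threshold",
                      threshold = thr, improve = 1, is_item = is_item),
         left = l, right = r)
  deep <- node("item3", 1.5, TRUE,
               node("age", 12, FALSE,
                    node("item3", 0.5, TRUE,
                         node("cleft_type", 2, FALSE, leaf(-2), leaf(-1)),
                         leaf(0)),
                    leaf(1)),
               leaf(2))
  tr <- structure(list(root = deep, max_depth = 4, item_vars =
                         c("item3"), cp_selected = 0), class = "reg_tree")
  person <- data.frame(item3 = 0, age = 10, cleft_type = 1)
  res <- predict_with_accounting(tr, person)
  expect_equal(res$prediction, -2)
  expect_equal(res$items_used, 1L)   # item3 answered once, reused
  res2 <- predict_with_accounting(tr, person,
                                  count_repeated_items = "per_split")
  expect_equal(res2$items_used, 2L)

  root_only <- structure(list(root = leaf(3.3), max_depth = 0,
                              item_vars = character(), cp_selected = 0),
                         class = "reg_tree")
  out <- predict_with_accounting(root_only, person)
  expect_equal(out$prediction, 3.3)
  expect_equal(out$items_used, 0L)

  expect_error(predict_with_accounting(tr, data.frame(age = 10)),
               "item3")
})

test_that("full-depth paths of a three-item tree cost three items", {
  # depth-3 tree over three distinct polytomous items: every full-depth
  # path administers exactly 3 items
  set.seed(14)
  d <- data.frame(i1 = sample(0:3, 300, TRUE), i2 = sample(0:3, 300, TRUE),
                  i3 = sample(0:3, 300, TRUE))
  d$y <- d$i1 - 0.8 * d$i2 + 0.6 * d$i3 + rnorm(300, sd = 0.1)
  fit <- grow_tree(d$y, d[c("i1", "i2", "i3")], max_depth = 3,
                   item_vars = c("i1", "i2", "i3"))
  acc <- predict(fit, d, accounting = TRUE)
  full_depth <- promcat:::tree_depth(fit$root) == 3
  expect_true(full_depth)
  expect_true(all(acc$items_used <= 3))
  expect_gte(max(acc$items_used), 3)
})

test_that("trees serialize to JSON and back without changing predictions", {
  d <- make_tree_fixture(80, 6)
  fit <- reg_tree(y ~ ., d, max_depth = 2, item_vars = "x1",
                  folds = 5, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_tree(fit, path)
  back <- read_tree(path)
  expect_equal(predict(back, d), predict(fit, d), tolerance = 1e-12)
  acc1 <- predict(fit, d[1:5, ], accounting = TRUE)
  acc2 <- predict(back, d[1:5, ], accounting = TRUE)
  expect_equal(acc1, acc2)
})
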