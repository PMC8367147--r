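#' Seeded train/test split
#'
#' Disjoint, exhaustive random partition of person indices at the given
#' ratio (default 2:1 train:test), with the training size rounded to the
#' nearest integer.
#'
#' @param n number of persons (or a `cohort`, whose size is used).
#' @param ratio length-2 positive numeric, train:test proportions.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `test`.
#' @examples
#' s <- split_train_test(300, seed = 1)
#' lengths(s)  # 200, 100
#' @export
split_train_test <- function(n, ratio = c(2, 1), seed = 1L) {
  if (inherits(n, "cohort")) n <- nrow(n$responses)
  n <- as.integer(n)
  stopifnot(length(ratio) == 2L, all(ratio > 0))
  if (n < 3L) stop("need at least 3 persons to split")
  n_train <- as.integer(round(n * ratio[1] / sum(ratio)))
  n_train <- max(1L, min(n - 1L, n_train))
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n_train)]),
       test = sort(idx[(n_train + 1L):n]))
}

#' Prediction accuracy metrics
#'
#' Pearson's correlation of predictions with ground truth, mean absolute
#' error and root mean squared error (which penalizes large errors more
#' heavily). With a constant truth or prediction vector the correlation is
#' undefined and
#' returned as `NA`; MAE and RMSE are still computed.
#'
#' @param pred,truth equal-length numeric vectors (logits), length >= 2.
#' @return list with `pearson_r`, `mae`, `rmse`.
#' @export
accuracy_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2L)
  err <- pred - truth
  r <- if (stats::sd(truth) == 0 || stats::sd(pred) == 0) NA_real_
       else stats::cor(pred, truth)
  list(pearson_r = r, mae = mean(abs(err)), rmse = sqrt(mean(err^2)))
}

#' Two-sided paired Wilcoxon signed-rank test
#'
#' Compares paired error vectors (here: squared prediction errors of the
#' two assessment arms). Zero differences are dropped; with `n <= 25`
#' nonzero differences the exact two-sided p-value is computed from the
#' full sign-flip distribution of the positive midrank sum (which remains
#' exact under tied absolute differences), otherwise a normal
#' approximation with tie correction and continuity correction is used.
#' If every difference is zero the test is degenerate and `p = 1` is
#' returned with `degenerate = TRUE`.
#'
#' @param a,b paired numeric vectors of equal length.
#' @param exact_max largest number of nonzero differences for which the
#'   exact distribution is enumerated (default 25).
#' @return list with `p_value`, `statistic` (positive rank sum `W+`),
#'   `n_nonzero`, `method`, `degenerate`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.25
#' @export
wilcoxon_signed_rank <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L,
                method = "degenerate", degenerate = TRUE))
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, w_pos)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w_pos - mu - sign(w_pos - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(p_value = p, statistic = w_pos, n_nonzero = n, method = method,
       degenerate = FALSE)
}

# exact two-sided p for the positive-rank sum under random sign flips,
# by generating-function convolution over the (mid)ranks; doubled ranks
# keep the support on integers even with .5 midranks.
signed_rank_exact_p <- function(r, w_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  dist <- numeric(total + 1L)   # dist[w+1] = #assignments with 2*W+ = w
  dist[1L] <- 1
  for (rk in r2) {
    shifted <- c(rep(0, rk), dist[seq_len(total + 1L - rk)])
    dist <- dist + shifted
  }
  dist <- dist / sum(dist)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(dist[seq_len(w2 + 1L)])
  p_ge <- sum(dist[(w2 + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Count unique attainable scores
#'
#' Number of distinct predicted scores in a vector (values equal within
#' 1e-9 are merged). A depth-d binary tree can attain at most `2^d`
#' distinct scores, far fewer than an adaptive test of equal length on
#' polytomous items — the underfitting mechanism this count quantifies.
#'
#' @param pred numeric vector of predictions.
#' @return integer count (0 for an empty vector).
#' @export
count_unique_scores <- function(pred) {
  if (!length(pred)) return(0L)
  length(unique(round(pred / 1e-9) * 1e-9))
}

#' Experiment configuration
#'
#' @param depth_limits integer vector of matched assessment lengths: each
#'   entry is used both as the tree's maximum depth and the adaptive
#'   test's fixed length. Defaults target roughly 75% and 50% of the
#'   scale length.
#' @param ratio train:test split ratio (default 2:1).
#' @param seed integer seed governing the split and the CV fold shuffle.
#' @param grid a [quad_grid()].
#' @param folds cross-validation folds for tree pruning.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(depth_limits = NULL, ratio = c(2, 1),
                              seed = 1L, grid = quad_grid(), folds = 10L) {
  structure(list(depth_limits = depth_limits, ratio = ratio,
                 seed = as.integer(seed), grid = as_quad_grid(grid),
                 folds = as.integer(folds)),
            class = "experiment_config")
}

default_depth_limits <- function(n_items)
  unique(pmax(1L, as.integer(round(n_items * c(0.75, 0.5)))))

#' Run the adaptive-test vs regression-tree comparison
#'
#' The full experiment on one cohort: (1) calibrate the partial credit
#' model on the whole sample and EAP-score everyone on the full scale
#' (ground truth); (2) split persons 2:1 into training and test sets;
#' (3) recalibrate on the training set only and build the adaptive test
#' from the training parameters; (4) grow and cross-validation-prune a
#' regression tree on the training set, predicting the ground-truth
#' logits from item responses, the overall-appearance item and the
#' clinical covariates; (5) for each matched length, simulate fixed-length
#' adaptive sessions and tree predictions for every test person;
#' (6) report the paired predictions and accuracy metrics per length.
#'
#' @param cohort a [generate_cohort()] result (complete responses).
#' @param config an [experiment_config()]; `depth_limits = NULL` uses
#'   roughly 75% and 50% of the scale length.
#' @return object of class `comparison_report`: list with one element per
#'   matched length, each holding `length_limit`, `per_person` (data
#'   frame: `person`, `ground_truth`, `cat_pred`, `tree_pred`,
#'   `cat_items`, `tree_items`), `cat` and `tree` aggregate lists
#'   (`mean_items`, `pearson_r`, `mae`, `rmse`, `unique_score_count`),
#'   `wilcoxon_p`, and `tree_first_split`; plus attributes `split`,
#'   `tree_fits`, `train_fit`, `gt_fit`.
#' @export
run_experiment <- function(cohort, config = experiment_config()) {
  stopifnot(inherits(cohort, "cohort"))
  if (anyNA(cohort$responses)) stop("cohort responses must be complete")
  grid <- config$grid
  depths <- config$depth_limits %||%
    default_depth_limits(ncol(cohort$responses))
  if (any(depths > ncol(cohort$responses)))
    stop("depth limit exceeds scale length")

  # (1) whole-sample calibration -> ground truth
  gt <- ground_truth_scores(cohort$responses, grid)
  truth <- gt$scores$theta_hat

  # (2) 2:1 split
  split <- split_train_test(nrow(cohort$responses), config$ratio,
                            config$seed)

  # (3) training-sample recalibration; the CAT uses these parameters
  train_fit <- pcm_calibrate(cohort$responses[split$train, , drop = FALSE],
                             grid)

  # tree training table: items + overall-appearance item + covariates
  tree_data <- cbind(as.data.frame(cohort$responses),
                     overall_appearance = cohort$global_item,
                     cohort$covariates)
  item_vars <- c(colnames(cohort$responses), "overall_appearance")
  tree_data$.outcome <- truth

  test_resp <- cohort$responses[split$test, , drop = FALSE]
  reports <- list()
  tree_fits <- list()
  max_len <- max(depths)
  # MEPV selection does not depend on the remaining budget, so a session
  # of the longest length contains every shorter fixed-length session as
  # a prefix; one batch with trajectories covers all matched lengths.
  sessions <- run_cat_batch(test_resp, train_fit$bank, max_len, grid,
                            trajectory = TRUE)

  for (L in depths) {
    # (4) grow + CV-prune the tree on the training rows
    tree <- reg_tree(.outcome ~ .,
                     tree_data[split$train, , drop = FALSE],
                     max_depth = L, item_vars = item_vars,
                     folds = config$folds, seed = config$seed)
    tree_fits[[as.character(L)]] <- tree

    # (5) matched-length predictions on test persons
    cat_pred <- vapply(sessions, function(s)
      if (L == 0L) 0 else s$trajectory$theta_hat[L], numeric(1))
    tree_out <- predict.reg_tree(tree,
                                 tree_data[split$test, , drop = FALSE],
                                 accounting = TRUE)
    per_person <- data.frame(person = split$test,
                             ground_truth = truth[split$test],
                             cat_pred = cat_pred,
                             tree_pred = tree_out$prediction,
                             cat_items = L,
                             tree_items = tree_out$items_used)
    cat_m <- accuracy_metrics(per_person$cat_pred, per_person$ground_truth)
    tree_m <- accuracy_metrics(per_person$tree_pred, per_person$ground_truth)
    wil <- wilcoxon_signed_rank((per_person$cat_pred -
                                   per_person$ground_truth)^2,
                                (per_person$tree_pred -
                                   per_person$ground_truth)^2)
    first <- tree$root$split
    reports[[as.character(L)]] <- list(
      length_limit = L,
      per_person = per_person,
      cat = c(list(mean_items = mean(per_person$cat_items)), cat_m,
              list(unique_score_count = count_unique_scores(per_person$cat_pred))),
      tree = c(list(mean_items = mean(per_person$tree_items)), tree_m,
               list(unique_score_count = count_unique_scores(per_person$tree_pred))),
      wilcoxon_p = wil$p_value,
      wilcoxon = wil,
      tree_first_split = if (is.null(first)) NULL else
        list(variable = first$variable, is_item = isTRUE(first$is_item)))
  }
  structure(reports, class = "comparison_report", split = split,
            tree_fits = tree_fits, train_fit = train_fit, gt_fit = gt$fit,
            seed = config$seed)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Adaptive test vs regression tree comparison\n")
  for (rep in x) {
    cat(sprintf("\nMatched length %d (%d test persons):\n", rep$length_limit,
                nrow(rep$per_person)))
    for (arm in c("cat", "tree")) {
      a <- rep[[arm]]
      cat(sprintf("  %-5s mean items %5.2f  r %.4f  MAE %.4f  RMSE %.4f  unique scores %d\n",
                  toupper(arm), a$mean_items, a$pearson_r, a$mae, a$rmse,
                  a$unique_score_count))
    }
    cat(sprintf("  Wilcoxon signed-rank on squared errors: p = %.3g\n",
                rep$wilcoxon_p))
    if (!is.null(rep$tree_first_split))
      cat(sprintf("  Tree first split: %s (%s)\n",
                  rep$tree_first_split$variable,
                  if (rep$tree_first_split$is_item) "item"
                  else "clinician-reported"))
  }
  invisible(x)
}

#' Flatten a comparison report to a summary data frame
#' @param x a `comparison_report`.
#' @param ... unused.
#' @return data frame, one row per (length, arm).
#' @export
as.data.frame.comparison_report <- function(x, ...) {
  do.call(rbind, lapply(x, function(rep)
    do.call(rbind, lapply(c("cat", "tree"), function(arm)
      data.frame(length_limit = rep$length_limit, arm = arm,
                 mean_items = rep[[arm]]$mean_items,
                 pearson_r = rep[[arm]]$pearson_r,
                 mae = rep[[arm]]$mae, rmse = rep[[arm]]$rmse,
                 unique_score_count = rep[[arm]]$unique_score_count,
                 wilcoxon_p = rep$wilcoxon_p)))))
}

#' Write a comparison report to disk
#'
#' Per-person rows as CSV (one file per matched length) plus a JSON
#' summary of the aggregates and the seed.
#'
#' @param report a `comparison_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  summ <- list(seed = attr(report, "seed"), arms = list())
  for (rep in report) {
    utils::write.csv(rep$per_person,
                     file.path(dir, sprintf("per_person_len%d.csv",
                                            rep$length_limit)),
                     row.names = FALSE)
    summ$arms[[as.character(rep$length_limit)]] <-
      list(length_limit = rep$length_limit, cat = rep$cat, tree = rep$tree,
           wilcoxon_p = rep$wilcoxon_p,
           tree_first_split = rep$tree_first_split)
  }
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
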