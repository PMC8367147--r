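#' Find the best binary split of a node
#'
#' Exhaustive least-squares split search, the greedy step of recursive
#' partitioning: the returned split maximizes the reduction in within-node
#' sum of squared deviations of the outcome (parent SSE minus the sum of
#' the two child SSEs). Numeric predictors (item responses, age) are
#' treated as ordered and searched over every threshold between distinct
#' observed values; factor/character predictors (cleft type, gender,
#' laterality) are searched over every proper subset of their observed
#' levels (capped at 12 levels). Ties break to the earlier candidate
#' variable, then to the smaller threshold / first subset enumerated, so
#' the search is deterministic.
#'
#' @param y numeric outcome (ground-truth person-location logits).
#' @param data data frame of predictors.
#' @param candidates character vector of candidate variable names
#'   (default: all columns of `data`).
#' @return a list (`variable`, `kind` = `"ordered_threshold"` or
#'   `"category_subset"`, `threshold` or `left_levels`, `improve` = SSE
#'   reduction), or `NULL` if no split reduces the SSE (e.g. a constant
#'   outcome) or `candidates` is empty.
#' @export
best_split <- function(y, data, candidates = names(data)) {
  for (v in candidates)
    if (is.null(data[[v]])) stop("candidate variable not in data: ", v)
  best_split_cols(y, normalize_columns(data, candidates), seq_along(y),
                  candidates)
}

# columns coerced once to numeric (ordered) or character (categorical)
normalize_columns <- function(data, candidates) {
  cols <- lapply(data[candidates], function(x) {
    if (is.numeric(x) || is.logical(x) || is.integer(x)) as.numeric(x)
    else as.character(x)
  })
  names(cols) <- candidates
  cols
}

best_split_cols <- function(y, cols, idx, candidates) {
  n <- length(idx)
  if (n < 2L || !length(candidates)) return(NULL)
  yy <- y[idx]
  tot <- sum(yy)
  best <- NULL
  best_improve <- 1e-10 * (stats::var(yy) + 1)  # guard against fp dust
  for (v in candidates) {
    x <- cols[[v]][idx]
    s <- if (is.numeric(x)) split_ordered(yy, x, tot, n)
         else split_categorical(yy, x, tot, n)
    if (!is.null(s) && s$improve > best_improve) {
      best_improve <- s$improve
      best <- c(list(variable = v), s)
    }
  }
  best
}

# threshold search by sorted cumulative sums; improve relative to parent
split_ordered <- function(y, x, tot, n) {
  ord <- order(x, method = "radix")
  xs <- x[ord]
  cy <- cumsum(y[ord])
  cut_ok <- which(xs[-n] < xs[-1L])      # boundaries between distinct values
  if (!length(cut_ok)) return(NULL)
  nl <- cut_ok
  gain <- cy[cut_ok]^2 / nl + (tot - cy[cut_ok])^2 / (n - nl) - tot^2 / n
  j <- which.max(gain)
  list(kind = "ordered_threshold",
       threshold = (xs[cut_ok[j]] + xs[cut_ok[j] + 1L]) / 2,
       improve = gain[j])
}

# exhaustive subset search; first observed level anchored to the left child
split_categorical <- function(y, x, tot, n) {
  x <- as.character(x)
  lev <- sort(unique(x))
  L <- length(lev)
  if (L < 2L) return(NULL)
  if (L > 12L) stop("categorical predictor has more than 12 levels")
  sy <- vapply(lev, function(l) sum(y[x == l]), numeric(1))
  sn <- vapply(lev, function(l) sum(x == l), numeric(1))
  best_gain <- -Inf
  best_mask <- NULL
  for (mask in 0:(2^(L - 1L) - 1L)) {        # lev[1] always left
    inl <- c(TRUE, bitwAnd(mask, 2^(0:(L - 2L))) > 0)
    nl <- sum(sn[inl])
    if (nl == n) next
    yl <- sum(sy[inl])
    gain <- yl^2 / nl + (tot - yl)^2 / (n - nl) - tot^2 / n
    if (gain > best_gain) {
      best_gain <- gain
      best_mask <- inl
    }
  }
  if (is.null(best_mask)) return(NULL)
  list(kind = "category_subset", left_levels = lev[best_mask],
       improve = best_gain)
}

node_sse <- function(y) sum((y - mean(y))^2)

# which rows go left under a split
split_goes_left <- function(split, data) {
  x <- data[[split$variable]]
  if (is.null(x)) stop("missing variable: ", split$variable)
  if (split$kind == "ordered_threshold") as.numeric(x) <= split$threshold
  else as.character(x) %in% split$left_levels
}

# column-wise variant avoiding data.frame row subsetting in hot loops
split_goes_left_idx <- function(split, cols, idx) {
  x <- cols[[split$variable]]
  if (is.null(x)) stop("missing variable: ", split$variable)
  if (split$kind == "ordered_threshold") x[idx] <= split$threshold
  else x[idx] %in% split$left_levels
}

#' Grow a regression tree by recursive partitioning
#'
#' Grows a binary regression tree to a prespecified maximum depth. Growth
#' is limited only by depth: any node with at least `min_node` (default 2)
#' observations is split whenever some split reduces the SSE, with no
#' complexity threshold during growth. Branches that do not generalize are
#' meant to be removed afterwards by cost-complexity pruning ([prune()] /
#' [cv_select_cp()]); [reg_tree()] bundles the whole procedure.
#'
#' @inheritParams best_split
#' @param max_depth maximum tree depth (root = depth 0); `0` yields a
#'   single leaf predicting the training mean.
#' @param item_vars variables that are patient-reported items (scale items
#'   and the overall-appearance item); recorded on each split for
#'   item-count accounting at prediction time.
#' @param min_node minimum observations in a splittable node.
#' @return object of class `reg_tree` (unpruned; `cp_selected = 0`).
#' @export
grow_tree <- function(y, data, candidates = names(data), max_depth = 3L,
                      item_vars = character(), min_node = 2L) {
  if (!length(y)) stop("empty training set")
  if (length(y) != nrow(data)) stop("outcome/data length mismatch")
  if (anyNA(y) || !all(is.finite(y))) stop("outcome must be finite")
  max_depth <- as.integer(max_depth)
  if (max_depth < 0L) stop("max_depth must be >= 0")

  for (v in candidates)
    if (is.null(data[[v]])) stop("candidate variable not in data: ", v)
  cols <- normalize_columns(data, candidates)

  grow_node <- function(idx, depth) {
    yy <- y[idx]
    node <- list(n = length(idx), value = mean(yy), sse = node_sse(yy),
                 depth = depth, split = NULL, left = NULL, right = NULL)
    if (depth >= max_depth || length(idx) < min_node) return(node)
    s <- best_split_cols(y, cols, idx, candidates)
    if (is.null(s)) return(node)
    s$is_item <- s$variable %in% item_vars
    left <- split_goes_left_idx(s, cols, idx)
    if (!any(left) || all(left)) return(node)
    node$split <- s
    node$left <- grow_node(idx[left], depth + 1L)
    node$right <- grow_node(idx[!left], depth + 1L)
    node
  }

  root <- grow_node(seq_along(y), 0L)
  structure(list(root = root, max_depth = max_depth,
                 item_vars = item_vars, candidates = candidates,
                 cp_selected = 0, cp_table = NULL,
                 y = y, fitted = NULL, call = match.call()),
            class = "reg_tree")
}

tree_n_leaves <- function(node) {
  if (is.null(node$split)) 1L
  else tree_n_leaves(node$left) + tree_n_leaves(node$right)
}

tree_leaf_sse <- function(node) {
  if (is.null(node$split)) node$sse
  else tree_leaf_sse(node$left) + tree_leaf_sse(node$right)
}

tree_depth <- function(node) {
  if (is.null(node$split)) 0L
  else 1L + max(tree_depth(node$left), tree_depth(node$right))
}

# Single bottom-up pass computing, per node, the weakest link
# g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1) -- the per-leaf SSE
# improvement of keeping t's subtree -- and returning the minimum.
min_link <- function(node) tree_scan(node)$gmin

tree_scan <- function(node) {
  if (is.null(node$split))
    return(list(r_sub = node$sse, leaves = 1L, gmin = Inf))
  l <- tree_scan(node$left)
  r <- tree_scan(node$right)
  r_sub <- l$r_sub + r$r_sub
  leaves <- l$leaves + r$leaves
  g <- (node$sse - r_sub) / (leaves - 1L)
  list(r_sub = r_sub, leaves = leaves, gmin = min(g, l$gmin, r$gmin))
}

# Single bottom-up pass collapsing every node whose cascaded per-leaf
# improvement satisfies cmp(g, alpha); children are pruned first so a
# parent is judged against its already-pruned subtree.
collapse_pass <- function(node, alpha, strict) {
  if (is.null(node$split))
    return(list(node = node, r_sub = node$sse, leaves = 1L))
  l <- collapse_pass(node$left, alpha, strict)
  r <- collapse_pass(node$right, alpha, strict)
  node$left <- l$node
  node$right <- r$node
  r_sub <- l$r_sub + r$r_sub
  leaves <- l$leaves + r$leaves
  g <- (node$sse - r_sub) / (leaves - 1L)
  collapse <- if (strict) g < alpha else g <= alpha
  if (collapse) {
    node$split <- NULL
    node$left <- NULL
    node$right <- NULL
    return(list(node = node, r_sub = node$sse, leaves = 1L))
  }
  list(node = node, r_sub = r_sub, leaves = leaves)
}

#' Cost-complexity (weakest-link) pruning
#'
#' Collapses every internal node whose per-split SSE improvement, measured
#' per extra leaf and relative to the root SSE, falls below the complexity
#' parameter `cp`: weakest links are removed iteratively until the
#' weakest surviving link is at least `cp`. `cp = 0` leaves the tree
#' unchanged; `cp = Inf` collapses it to the root leaf. The result is
#' always a subtree of the input, and a larger `cp` never yields more
#' leaves.
#'
#' @param tree a `reg_tree`.
#' @param cp nonnegative complexity parameter (fraction of root SSE).
#' @param ... unused.
#' @return the pruned `reg_tree` (with `cp_selected = cp`).
#' @export
prune <- function(tree, cp, ...) UseMethod("prune")

#' @rdname prune
#' @export
prune.reg_tree <- function(tree, cp, ...) {
  stopifnot(length(cp) == 1L, !is.na(cp), cp >= 0)
  root_sse <- tree$root$sse
  scale <- if (root_sse > 0) root_sse else 1
  tree$root <- collapse_pass(tree$root, cp * scale, strict = TRUE)$node
  tree$cp_selected <- cp
  tree
}

# nested weakest-link cp breakpoints (relative to root SSE), ascending,
# with the leaf count of the subtree each interval yields
cp_sequence <- function(tree) {
  root_sse <- tree$root$sse
  scale <- if (root_sse > 0) root_sse else 1
  node <- tree$root
  cps <- 0
  leaves <- tree_n_leaves(node)
  while (!is.null(node$split)) {
    alpha <- min_link(node)
    node <- collapse_pass(node, alpha, strict = FALSE)$node
    cps <- c(cps, alpha / scale)
    leaves <- c(leaves, tree_n_leaves(node))
  }
  # a collapse can remove several breakpoints at once; keep strictly
  # increasing cp with the coarsest tree at each value
  keep <- !duplicated(cps, fromLast = TRUE)
  data.frame(cp = cps[keep], n_leaves = leaves[keep])
}

# representative cp inside each interval of the sequence (geometric mean of
# neighbours), usable directly as a prune() argument
cp_representatives <- function(cp_table) {
  cp <- cp_table$cp
  J <- length(cp)
  if (J == 1L) return(0)
  reps <- c(0, sqrt(cp[-J][-1] * cp[-1][-1]), 2 * cp[J])
  reps[seq_len(J)]
}

#' Choose the complexity parameter by 10-fold cross-validation
#'
#' Builds the nested weakest-link cp sequence from the tree grown on the
#' full training set, then estimates each candidate subtree's prediction
#' error by k-fold cross-validation: trees are regrown on each fold
#' complement, pruned at each candidate cp, and scored on the held-out
#' fold. Returns the cp minimizing mean squared out-of-fold error (the
#' plain minimum, not the 1-SE rule); ties go to the larger cp (the
#' simpler tree). Fold assignment is a seeded shuffle and is returned for
#' reproducibility.
#'
#' @inheritParams grow_tree
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return list with `cp` (selected), `cp_table` (data frame `cp`,
#'   `n_leaves`, `cv_error`), and `fold_assignment`.
#' @export
cv_select_cp <- function(y, data, candidates = names(data), max_depth = 3L,
                         item_vars = character(), folds = 10L, seed = 1L) {
  folds <- as.integer(folds)
  n <- length(y)
  if (folds < 2L) stop("folds must be >= 2")
  if (n < 2L * folds) stop("not enough rows for ", folds, "-fold CV")
  full <- grow_tree(y, data, candidates, max_depth, item_vars)
  tab <- cp_sequence(full)
  reps <- cp_representatives(tab)

  assign_f <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  sq_err <- matrix(0, nrow(tab), folds)
  for (f in seq_len(folds)) {
    hold <- assign_f == f
    ft <- grow_tree(y[!hold], data[!hold, , drop = FALSE], candidates,
                    max_depth, item_vars)
    newd <- data[hold, , drop = FALSE]
    for (j in seq_along(reps)) {
      pt <- prune.reg_tree(ft, reps[j])
      pred <- predict_tree_rows(pt$root, newd)
      sq_err[j, f] <- sum((pred - y[hold])^2)
    }
  }
  tab$cv_error <- rowSums(sq_err) / n
  best <- which(tab$cv_error <= min(tab$cv_error) + 1e-12)
  j <- best[length(best)]                     # ties -> larger cp
  list(cp = reps[j], cp_table = tab, fold_assignment = assign_f)
}

#' Fit a pruned regression tree
#'
#' The full decision-tree procedure used in the adaptive-assessment
#' comparison: grow a binary regression tree to `max_depth` by recursive
#' partitioning over item responses and clinical covariates (growth
#' limited only by depth), then remove branches that do not improve
#' cross-validated prediction error through cost-complexity pruning with
#' the cp chosen by 10-fold cross-validation.
#'
#' @param formula model formula, e.g. `score ~ .`; predictors are taken
#'   from `data` as-is (numeric = ordered threshold splits,
#'   factor/character = subset splits).
#' @param data training data frame containing the outcome and predictors.
#' @param max_depth maximum depth (root = 0), matched to the adaptive
#'   test's fixed length in the comparison design.
#' @param item_vars names of predictors that count as administered items
#'   when a prediction path uses them; all other predictors are
#'   clinician-reported and cost 0 items.
#' @param cv if `FALSE`, skip pruning and return the fully grown tree.
#' @param folds,seed cross-validation folds and fold-shuffle seed.
#' @return object of class `reg_tree` with `cp_selected`, `cp_table`,
#'   `fitted` values and training outcome `y`.
#' @examples
#' d <- data.frame(x = rep(0:1, each = 10), z = rnorm(20))
#' d$y <- d$x * 2 + rnorm(20, sd = 0.1)
#' fit <- reg_tree(y ~ x + z, d, max_depth = 2, folds = 5, seed = 1)
#' predict(fit, d[1:2, ])
#' @export
reg_tree <- function(formula, data, max_depth = 3L, item_vars = character(),
                     cv = TRUE, folds = 10L, seed = 1L) {
  tf <- stats::terms(formula, data = data)
  vars <- all.vars(tf)
  outcome <- vars[1L]
  candidates <- attr(tf, "term.labels")
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome not found in data: ", outcome)
  x <- data[candidates]
  if (cv) {
    sel <- cv_select_cp(y, x, candidates, max_depth, item_vars,
                        folds = folds, seed = seed)
    fit <- grow_tree(y, x, candidates, max_depth, item_vars)
    fit <- prune.reg_tree(fit, sel$cp)
    fit$cp_table <- sel$cp_table
    fit$fold_assignment <- sel$fold_assignment
  } else {
    fit <- grow_tree(y, x, candidates, max_depth, item_vars)
  }
  fit$fitted <- predict_tree_rows(fit$root, x)
  fit$call <- match.call()
  fit
}

# vectorized routing of many rows through the tree
predict_tree_rows <- function(root, data) {
  vars <- collect_split_vars(root)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("missing variable: ", miss[1])
  cols <- normalize_columns(data, vars)
  out <- numeric(nrow(data))
  route <- function(node, idx) {
    if (!length(idx)) return()
    if (is.null(node$split)) {
      out[idx] <<- node$value
      return()
    }
    left <- split_goes_left_idx(node$split, cols, idx)
    if (anyNA(left)) stop("missing value for variable: ",
                          node$split$variable)
    route(node$left, idx[left])
    route(node$right, idx[!left])
  }
  route(root, seq_len(nrow(data)))
  out
}

collect_split_vars <- function(node) {
  if (is.null(node$split)) return(character())
  unique(c(node$split$variable, collect_split_vars(node$left),
           collect_split_vars(node$right)))
}

#' Predict from a regression tree, with item-count accounting
#'
#' Routes each row from the root to a leaf and returns the leaf mean (the
#' mean training person-location logit of that subgroup). With
#' `accounting = TRUE` it also reports how many items the assessment would
#' have required: splits on item variables (scale items and the
#' overall-appearance item) count, splits on clinician-reported variables
#' cost nothing, and — by default — repeated splits on the same item along
#' a path count once, since a respondent answers each item a single time
#' (`count_repeated_items = "per_split"` counts every item split).
#'
#' @param object a `reg_tree`.
#' @param newdata data frame providing every variable a routing path needs.
#' @param accounting if `TRUE`, return a data frame with `prediction` and
#'   `items_used`; otherwise a numeric vector of predictions.
#' @param count_repeated_items `"once"` (default) or `"per_split"`.
#' @param ... unused.
#' @export
predict.reg_tree <- function(object, newdata, accounting = FALSE,
                             count_repeated_items = c("once", "per_split"),
                             ...) {
  count_repeated_items <- match.arg(count_repeated_items)
  if (!accounting) return(predict_tree_rows(object$root, newdata))
  pred <- numeric(nrow(newdata))
  items <- integer(nrow(newdata))
  for (i in seq_len(nrow(newdata))) {
    row <- newdata[i, , drop = FALSE]
    node <- object$root
    used <- character()
    while (!is.null(node$split)) {
      s <- node$split
      if (is.null(row[[s$variable]]) || is.na(row[[s$variable]]))
        stop("missing variable: ", s$variable)
      if (isTRUE(s$is_item)) used <- c(used, s$variable)
      node <- if (split_goes_left(s, row)) node$left else node$right
    }
    pred[i] <- node$value
    items[i] <- if (count_repeated_items == "once") length(unique(used))
                else length(used)
  }
  data.frame(prediction = pred, items_used = items)
}

#' Predict one person with item-count accounting
#'
#' Convenience wrapper around `predict(tree, accounting = TRUE)` for a
#' single row.
#'
#' @inheritParams predict.reg_tree
#' @param person a one-row data frame.
#' @return list with `prediction` (logits) and `items_used` (integer).
#' @export
predict_with_accounting <- function(object, person,
                                    count_repeated_items = c("once",
                                                             "per_split")) {
  res <- predict.reg_tree(object, person, accounting = TRUE,
                          count_repeated_items = match.arg(count_repeated_items))
  list(prediction = res$prediction[1L], items_used = res$items_used[1L])
}

#' @export
residuals.reg_tree <- function(object, ...) {
  if (is.null(object$fitted))
    stop("tree has no stored fitted values; fit with reg_tree()")
  object$y - object$fitted
}

split_label <- function(s) {
  if (s$kind == "ordered_threshold")
    sprintf("%s <= %g", s$variable, s$threshold)
  else sprintf("%s in {%s}", s$variable, paste(s$left_levels, collapse = ","))
}

#' @export
print.reg_tree <- function(x, ...) {
  cat(sprintf("Regression tree: depth %d (max %d), %d leaves, cp = %g\n",
              tree_depth(x$root), x$max_depth, tree_n_leaves(x$root),
              x$cp_selected))
  show <- function(node, indent, label) {
    cat(sprintf("%s%s n=%d mean=%.3f%s\n", strrep("  ", indent), label,
                node$n, node$value,
                if (is.null(node$split)) " *" else ""))
    if (!is.null(node$split)) {
      s <- node$split
      show(node$left, indent + 1L, paste0(split_label(s), ": "))
      neg <- if (s$kind == "ordered_threshold")
        sprintf("%s > %g", s$variable, s$threshold)
      else sprintf("%s not in {%s}", s$variable,
                   paste(s$left_levels, collapse = ","))
      show(node$right, indent + 1L, paste0(neg, ": "))
    }
  }
  show(x$root, 0L, "root: ")
  invisible(x)
}

#' @export
summary.reg_tree <- function(object, ...) {
  print(object)
  if (!is.null(object$cp_table)) {
    cat("\nComplexity sequence (10-fold CV):\n")
    print(object$cp_table, row.names = FALSE)
  }
  first <- object$root$split
  if (!is.null(first))
    cat(sprintf("\nFirst split: %s (%s variable)\n", split_label(first),
                if (isTRUE(first$is_item)) "item" else "clinician-reported"))
  invisible(object)
}

#' @export
plot.reg_tree <- function(x, ...) {
  depth <- tree_depth(x$root)
  graphics::plot(NULL, xlim = c(0, 1), ylim = c(-depth - 0.5, 0.5),
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Regression tree")
  draw <- function(node, x0, x1, d) {
    xc <- (x0 + x1) / 2
    if (is.null(node$split)) {
      graphics::text(xc, -d, sprintf("%.2f\n(n=%d)", node$value, node$n),
                     cex = 0.7)
      return(xc)
    }
    xl <- draw(node$left, x0, xc, d + 1)
    xr <- draw(node$right, xc, x1, d + 1)
    graphics::segments(c(xl, xr), -d - 1 + 0.15, (xl + xr) / 2, -d - 0.15)
    graphics::text((xl + xr) / 2, -d, split_label(node$split), cex = 0.7)
    (xl + xr) / 2
  }
  draw(x$root, 0, 1, 0)
  invisible(x)
}

#' Serialize a regression tree to JSON
#' @param tree a `reg_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ser <- function(node) {
    out <- list(n = node$n, value = node$value, sse = node$sse,
                depth = node$depth)
    if (!is.null(node$split)) {
      out$split <- node$split
      out$left <- ser(node$left)
      out$right <- ser(node$right)
    }
    out
  }
  obj <- list(max_depth = tree$max_depth, cp_selected = tree$cp_selected,
              item_vars = as.list(tree$item_vars),
              cp_table = tree$cp_table, root = ser(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a regression tree from JSON
#' @param path file written by [write_tree()].
#' @return a `reg_tree` (without training data; `residuals()` unavailable).
#' @export
read_tree <- function(path) {
  obj <- jsonlite::read_json(path)
  de <- function(nd) {
    node <- list(n = nd$n, value = nd$value, sse = nd$sse, depth = nd$depth,
                 split = NULL, left = NULL, right = NULL)
    if (!is.null(nd$split)) {
      s <- nd$split
      if (!is.null(s$left_levels)) s$left_levels <- unlist(s$left_levels)
      node$split <- s
      node$left <- de(nd$left)
      node$right <- de(nd$right)
    }
    node
  }
  cp_table <- if (!is.null(obj$cp_table))
    do.call(rbind, lapply(obj$cp_table, as.data.frame))
  structure(list(root = de(obj$root), max_depth = obj$max_depth,
                 item_vars = unlist(obj$item_vars) %||% character(),
                 cp_selected = obj$cp_selected, cp_table = cp_table,
                 y = NULL, fitted = NULL),
            class = "reg_tree")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
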