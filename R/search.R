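# Simultaneous feature-subset and cost selection for the screening SVM.
#
# paper_faithful mode scores each candidate (subset, cost) by the same LOOCV
# used to report the final metrics (selection optimism is therefore part of
# the reported number, as in the study design it mirrors); nested mode
# repeats the whole selection inside every outer LOOCV fold, scoring inner
# candidates by stratified k-fold CV, and reports honest outer metrics.

default_cost_grid <- function() c(0.001, 0.01, 0.1, 1, 10)

# score comparator: higher accuracy, then higher sensitivity, then fewer
# variables, then smaller cost
score_better <- function(a, b) {
  if (is.null(b)) return(TRUE)
  if (a$accuracy != b$accuracy) return(a$accuracy > b$accuracy)
  sa <- ifelse(is.na(a$sensitivity), -1, a$sensitivity)
  sb <- ifelse(is.na(b$sensitivity), -1, b$sensitivity)
  if (sa != sb) return(sa > sb)
  if (length(a$subset) != length(b$subset)) {
    return(length(a$subset) < length(b$subset))
  }
  a$cost < b$cost
}

# evaluate one subset across the cost grid with a CV evaluator; returns the
# best score record (decisions retained for the winner)
eval_subset <- function(X, y, subset, cost_grid, cv_fun, memo) {
  key <- paste(sort(subset), collapse = "|")
  if (!is.null(memo) && !is.null(memo[[key]])) return(memo[[key]])
  yy <- y_pm1(y)
  best <- NULL
  for (C in cost_grid) {
    d <- cv_fun(X[, subset, drop = FALSE], yy, C)
    pred <- factor(ifelse(d > 0, "High", "Low"), levels = c("Low", "High"))
    cm <- confusion_metrics(pred, y)
    sc <- list(subset = subset, cost = C, accuracy = cm$accuracy,
               sensitivity = cm$sensitivity, decisions = d)
    if (score_better(sc, best)) best <- sc
  }
  if (!is.null(memo)) memo[[key]] <- best
  best
}

all_subsets <- function(cols) {
  n <- length(cols)
  unlist(lapply(seq_len(n), function(k) {
    m <- utils::combn(cols, k, simplify = FALSE)
    m
  }), recursive = FALSE)
}

# sequential forward floating selection over subsets, scored by eval_subset;
# stops once `patience` consecutive forward steps fail to improve the best
# score, or when a perfect score cannot be improved upon
sffs_search <- function(X, y, cols, cost_grid, cv_fun,
                        max_size = length(cols), patience = 2L) {
  memo <- new.env(parent = emptyenv())
  best_global <- NULL
  best_by_size <- vector("list", length(cols))
  current <- character(0)
  stale <- 0L
  while (length(current) < max_size) {
    cands <- setdiff(cols, current)
    step_best <- NULL
    for (v in cands) {
      sc <- eval_subset(X, y, c(current, v), cost_grid, cv_fun, memo)
      if (score_better(sc, step_best)) step_best <- sc
    }
    current <- step_best$subset
    k <- length(current)
    if (score_better(step_best, best_by_size[[k]])) {
      best_by_size[[k]] <- step_best
    }
    improved <- score_better(step_best, best_global)
    if (improved) best_global <- step_best
    stale <- if (improved) 0L else stale + 1L
    # floating backward: drop a variable while it strictly improves the best
    # known subset of the smaller size
    while (length(current) > 2L) {
      drop_best <- NULL
      for (v in current) {
        sc <- eval_subset(X, y, setdiff(current, v), cost_grid, cv_fun, memo)
        if (score_better(sc, drop_best)) drop_best <- sc
      }
      k1 <- length(current) - 1L
      if (score_better(drop_best, best_by_size[[k1]])) {
        best_by_size[[k1]] <- drop_best
        current <- drop_best$subset
        if (score_better(drop_best, best_global)) best_global <- drop_best
      } else {
        break
      }
    }
    if (stale >= patience) break
    if (!is.na(best_global$accuracy) && best_global$accuracy == 1 &&
        !is.na(best_global$sensitivity) && best_global$sensitivity == 1) {
      break # larger subsets cannot beat a perfect score under the tie-breaks
    }
  }
  best_global
}

exhaustive_search <- function(X, y, cols, cost_grid, cv_fun) {
  best <- NULL
  for (s in all_subsets(cols)) {
    sc <- eval_subset(X, y, s, cost_grid, cv_fun, NULL)
    if (score_better(sc, best)) best <- sc
  }
  best
}

# deterministic stratified fold assignment (0-based), round-robin per class
stratified_folds <- function(y, k) {
  f <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    f[idx] <- (seq_along(idx) - 1L) %% k
  }
  f
}

run_selection <- function(X, y, cols, cost_grid, strategy, cv_fun,
                          patience = 2L) {
  if (strategy == "exhaustive") {
    exhaustive_search(X, y, cols, cost_grid, cv_fun)
  } else {
    sffs_search(X, y, cols, cost_grid, cv_fun, patience = patience)
  }
}

#' Search the best screening model for a variable category
#'
#' Simultaneously selects the feature subset and the SVM cost. In
#' `paper_faithful` mode every candidate pair is scored by LOOCV accuracy on
#' the full table (ties broken by higher sensitivity, then fewer variables,
#' then smaller cost) and the winning pair's LOOCV predictions are reported.
#' In `nested` mode the same selection is repeated inside each outer LOOCV
#' fold — scored there by stratified `inner_folds`-fold CV — and the outer
#' out-of-fold predictions give an honest generalization estimate.
#' High-group probabilities are calibrated by [platt_probabilities()] on the
#' out-of-fold decision values, and the final model is refit on all rows.
#'
#' @param table An `olst_features` table.
#' @param category `"conventional"`, `"proposed"`, or `"combined"`.
#' @param cost_grid Candidate soft-margin costs.
#' @param strategy `"exhaustive"` (all non-empty subsets; default for up to
#'   10 variables) or `"forward_floating"` (default for the 16-variable
#'   combined category).
#' @param mode `"paper_faithful"` or `"nested"`.
#' @param standardize Z-score features with training-fold statistics.
#' @param inner_folds Stratified inner-CV folds used by nested selection.
#'
#' @return An object of class `olst_model`; see [tidy.olst_model()],
#'   [glance.olst_model()], [linear_shap()].
#' @export
search_best_model <- function(table, category,
                              cost_grid = default_cost_grid(),
                              strategy = NULL,
                              mode = c("paper_faithful", "nested"),
                              standardize = TRUE, inner_folds = 5L) {
  mode <- match.arg(mode)
  cols <- category_columns(category)
  if (length(cost_grid) == 0L) {
    stop_olst("`cost_grid` must be non-empty", "olst_config_error")
  }
  strategy <- strategy %||%
    (if (length(cols) > 10L) "forward_floating" else "exhaustive")
  strategy <- match.arg(strategy, c("exhaustive", "forward_floating"))
  tab <- complete_rows(table, cols)
  y <- as_group_factor(tab$group)
  n <- nrow(tab)
  if (n < 3L || min(table(y)) < 2L) {
    stop_olst("need n >= 3 and both classes with >= 2 members",
              "olst_domain_error")
  }
  X <- as.matrix(tab[, cols, drop = FALSE])
  storage.mode(X) <- "double"

  loocv_fun <- function(Xs, yy, C) {
    .smo_cv_decisions(Xs, yy, C, seq_len(nrow(Xs)) - 1L, standardize)
  }

  if (mode == "paper_faithful") {
    best <- run_selection(X, y, cols, cost_grid, strategy, loocv_fun)
    decisions <- best$decisions
    fold_subsets <- NULL
  } else {
    decisions <- numeric(n)
    fold_subsets <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- setdiff(seq_len(n), i)
      ytr <- y[tr]
      inner_fun <- function(Xs, yy, C) {
        .smo_cv_decisions(Xs, yy, C,
                          stratified_folds(yy, min(inner_folds, length(yy))),
                          standardize)
      }
      # the greedy inner search stops at the first non-improving step: with
      # n - 1 nearly identical selection problems, deeper floating passes
      # change the outer estimate only through noise
      sel <- run_selection(X[tr, , drop = FALSE], ytr, cols, cost_grid,
                           strategy, inner_fun, patience = 1L)
      fit <- fit_linear_svm(X[tr, sel$subset, drop = FALSE], ytr, sel$cost,
                            standardize)
      decisions[i] <- decision_values(fit, X[i, sel$subset, drop = FALSE])
      fold_subsets[[i]] <- list(subset = sel$subset, cost = sel$cost)
    }
    # the reported model: the same selection run on the full table
    best <- run_selection(X, y, cols, cost_grid, strategy, function(Xs, yy, C) {
      .smo_cv_decisions(Xs, yy, C,
                        stratified_folds(yy, min(inner_folds, length(yy))),
                        standardize)
    })
  }

  pred <- factor(ifelse(decisions > 0, "High", "Low"),
                 levels = c("Low", "High"))
  cm <- confusion_metrics(pred, y)
  platt <- platt_probabilities(decisions, y)
  final <- fit_linear_svm(X[, best$subset, drop = FALSE], y, best$cost,
                          standardize)
  structure(
    list(
      category = category, mode = mode, strategy = strategy,
      subset = best$subset, cost = best$cost, standardize = standardize,
      model = final,
      predictions = tibble(
        participant_id = tab$participant_id,
        srs_total = tab$srs_total,
        truth = y, decision = decisions, pred = pred,
        prob = platt$probabilities
      ),
      platt = list(A = platt$A, B = platt$B),
      confusion = cm,
      fold_selections = fold_subsets,
      n_rows = n,
      n_excluded = nrow(table) - n
    ),
    class = "olst_model"
  )
}

#' @export
print.olst_model <- function(x, ...) {
  cat(sprintf(
    "<olst_model> %s category, %s mode (%s search)\n", x$category, x$mode,
    x$strategy
  ))
  cat("  selected:", paste(x$subset, collapse = " + "),
      sprintf("(cost %g)\n", x$cost))
  cat(sprintf(
    "  LOOCV accuracy %.3f, sensitivity %.3f, specificity %.3f (n = %d)\n",
    x$confusion$accuracy, x$confusion$sensitivity, x$confusion$specificity,
    x$n_rows
  ))
  invisible(x)
}
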