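# Linear SVM screening: fitting, LOOCV prediction, confusion metrics, and
# Platt probability calibration. The quadratic program is solved by the
# package's SMO routine (src/svm_smo.cpp); High is always the positive class.

as_group_factor <- function(y) {
  if (is.factor(y)) {
    if (!all(levels(y) %in% c("Low", "High"))) {
      y <- factor(as.character(y), levels = c("Low", "High"))
    }
  } else {
    y <- factor(as.character(y), levels = c("Low", "High"))
  }
  if (any(is.na(y))) {
    stop_olst("labels must be 'High' or 'Low'", "olst_domain_error")
  }
  y
}

y_pm1 <- function(y) ifelse(as_group_factor(y) == "High", 1L, -1L)

#' Fit a soft-margin linear SVM
#'
#' Minimizes `1/2 ||w||^2 + C * sum(hinge)` with an unregularized intercept,
#' treating High as the positive class. When `standardize` is set the
#' features are z-scored first and the scaling is stored with the model, so
#' decision values can be computed for new data on the original scale.
#'
#' @param x Numeric feature matrix (or data frame), one row per participant.
#' @param y Labels (`High`/`Low`).
#' @param cost Soft-margin cost C, > 0.
#' @param standardize Z-score the features before fitting.
#'
#' @return An object of class `olst_svm` with `weights` (named, on the
#'   standardized scale when `standardize = TRUE`), `intercept`, `center`,
#'   `scale` and `cost`.
#' @export
fit_linear_svm <- function(x, y, cost, standardize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  yy <- y_pm1(y)
  if (nrow(x) < 2L) {
    stop_olst("need at least two rows", "olst_domain_error")
  }
  if (length(unique(yy)) < 2L) {
    stop_olst("both classes must be present to fit an SVM",
              "olst_degenerate_fit_error")
  }
  check_number(cost, "cost", lower = 0, strict_lower = TRUE)
  ctr <- if (standardize) colMeans(x) else rep(0, ncol(x))
  scl <- if (standardize) apply(x, 2L, sd) else rep(1, ncol(x))
  scl[!is.finite(scl) | scl <= 0] <- 1
  xs <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  fit <- .smo_fit(xs, yy, cost)
  structure(
    list(weights = setNames(as.numeric(fit$weights), colnames(x)),
         intercept = fit$intercept, center = ctr, scale = scl,
         cost = cost, standardize = standardize,
         dual_objective = fit$dual_objective),
    class = "olst_svm"
  )
}

#' Decision values of a fitted linear SVM
#'
#' @param object An `olst_svm` model.
#' @param newdata Feature matrix/data frame on the original scale.
#'
#' @return Numeric decision values; positive means High.
#' @export
decision_values <- function(object, newdata) {
  x <- as.matrix(newdata)
  if (!is.null(colnames(x))) {
    x <- x[, names(object$weights), drop = FALSE]
  }
  xs <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
  drop(xs %*% object$weights) + object$intercept
}

#' Model specification for screening
#'
#' @param category Variable category (`"conventional"`, `"proposed"`,
#'   `"combined"`).
#' @param subset Feature columns to use; defaults to the full category.
#' @param cost Soft-margin cost C.
#' @param standardize Z-score features with training-fold statistics.
#' @param mode `"paper_faithful"` (selection and evaluation share one LOOCV)
#'   or `"nested"` (selection repeated inside each outer fold).
#'
#' @return A list of class `olst_model_spec`.
#' @export
olst_model_spec <- function(category, subset = category_columns(category),
                            cost = 0.01, standardize = TRUE,
                            mode = c("paper_faithful", "nested")) {
  cols <- category_columns(category)
  if (length(subset) == 0L || !all(subset %in% cols)) {
    stop_olst("`subset` must be a non-empty subset of the category columns",
              "olst_config_error")
  }
  check_number(cost, "cost", lower = 0, strict_lower = TRUE)
  structure(list(category = category, subset = subset, cost = cost,
                 standardize = standardize, mode = match.arg(mode)),
            class = "olst_model_spec")
}

#' Leave-one-out cross-validated predictions
#'
#' Fits `n` models, each on `n - 1` participants (re-standardizing with the
#' training fold's statistics), and predicts the held-out participant.
#'
#' @param table An `olst_features` table (or any data frame with the feature
#'   columns, a `group` column, and `participant_id`).
#' @param spec An [olst_model_spec()].
#'
#' @return A tibble with `participant_id`, `truth`, `decision`, `pred`
#'   (one row per participant).
#' @export
loocv_predict <- function(table, spec) {
  stopifnot(inherits(spec, "olst_model_spec"))
  tab <- complete_rows(table, spec$subset)
  y <- as_group_factor(tab$group)
  n <- nrow(tab)
  if (n < 3L || min(table(y)) < 2L) {
    stop_olst("LOOCV needs n >= 3 and both classes with >= 2 members",
              "olst_domain_error")
  }
  X <- as.matrix(tab[, spec$subset, drop = FALSE])
  storage.mode(X) <- "double"
  d <- .smo_cv_decisions(X, y_pm1(y), spec$cost, seq_len(n) - 1L,
                         spec$standardize)
  tibble(
    participant_id = tab$participant_id,
    truth = y,
    decision = d,
    pred = factor(ifelse(d > 0, "High", "Low"), levels = c("Low", "High"))
  )
}

#' Confusion counts and screening metrics
#'
#' High is the positive class: sensitivity is the true-positive rate among
#' High participants, specificity the true-negative rate among Low.
#' A metric whose denominator is empty is returned as `NA`.
#'
#' @param pred,truth Predicted and true labels (`High`/`Low`).
#'
#' @return A one-row tibble: `tp`, `fn`, `tn`, `fp`, `accuracy`,
#'   `sensitivity`, `specificity`.
#' @export
confusion_metrics <- function(pred, truth) {
  pred <- as_group_factor(pred)
  truth <- as_group_factor(truth)
  if (length(pred) != length(truth)) {
    stop_olst("prediction/truth length mismatch", "olst_domain_error")
  }
  tp <- sum(pred == "High" & truth == "High")
  fn <- sum(pred == "Low" & truth == "High")
  tn <- sum(pred == "Low" & truth == "Low")
  fp <- sum(pred == "High" & truth == "Low")
  tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
  )
}

#' Platt scaling of decision values
#'
#' Fits the sigmoid `p(High | d) = 1 / (1 + exp(A d + B))` to decision
#' values by regularized maximum likelihood with Platt's smoothed targets
#' `(N+ + 1)/(N+ + 2)` and `1/(N- + 2)`, using the standard Newton iteration
#' with backtracking. Out-of-fold decision values should be supplied so the
#' probabilities are not inflated by training fit.
#'
#' @param decisions Numeric decision values (positive = High side).
#' @param labels True labels (`High`/`Low`).
#'
#' @return A list with `probabilities`, `A`, `B`.
#' @export
platt_probabilities <- function(decisions, labels) {
  if (any(!is.finite(decisions))) {
    stop_olst("decision values must be finite", "olst_domain_error")
  }
  y <- as_group_factor(labels)
  if (length(unique(y)) < 2L) {
    stop_olst("both classes must be present", "olst_degenerate_fit_error")
  }
  n_pos <- sum(y == "High")
  n_neg <- sum(y == "Low")
  hi <- (n_pos + 1) / (n_pos + 2)
  lo <- 1 / (n_neg + 2)
  t <- ifelse(y == "High", hi, lo)
  f <- decisions

  fval <- function(A, B) {
    fApB <- A * f + B
    sum(ifelse(fApB >= 0,
               t * fApB + log1p(exp(-fApB)),
               (t - 1) * fApB + log1p(exp(fApB))))
  }
  A <- 0
  B <- log((n_neg + 1) / (n_pos + 1))
  Fv <- fval(A, B)
  sigma <- 1e-12
  for (it in 1:200) {
    fApB <- A * f + B
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p # dF/d(A f + B) of the negative log likelihood is (t - p)
    h11 <- sum(f * f * p * q) + sigma
    h22 <- sum(p * q) + sigma
    h21 <- sum(f * p * q)
    g1 <- sum(f * d1)
    g2 <- sum(d1)
    if (abs(g1) < 1e-10 && abs(g2) < 1e-10) break
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    repeat {
      newA <- A + step * dA
      newB <- B + step * dB
      newF <- fval(newA, newB)
      if (newF < Fv + 1e-4 * step * gd) {
        A <- newA
        B <- newB
        Fv <- newF
        break
      }
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) break
  }
  list(probabilities = 1 / (1 + exp(A * f + B)), A = A, B = B)
}
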