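# Model interpretation: exact linear SHAP, probability-SRS rank correlation,
# and cohort summary statistics.

#' Exact SHAP attributions for a linear model
#'
#' For a linear model on (assumed independent) features the Shapley value of
#' feature j for row i has the closed form `w_j * (x_ij - mean_j(X))`, with
#' base value the mean decision value. Attributions are computed on the
#' standardized feature scale the model was fit on.
#'
#' @param model Either an `olst_model` from [search_best_model()] or a bare
#'   `olst_svm` fit.
#' @param newdata Feature data to attribute. Defaults to the scored rows of
#'   an `olst_model` (its out-of-fold prediction table is used for ids).
#' @param table Feature table supplying `newdata` when `model` is an
#'   `olst_model`.
#'
#' @return A tibble of class `olst_shap`, long format: `participant_id`,
#'   `variable`, `value` (feature value, original scale), `attribution`
#'   (decision-value units), `decision`; the base value is in
#'   `attr(, "base_value")`.
#' @export
linear_shap <- function(model, table = NULL, newdata = NULL) {
  if (inherits(model, "olst_model")) {
    fit <- model$model
    if (is.null(newdata)) {
      if (is.null(table)) {
        stop_olst("supply `table` (the feature table the model was built on)",
                  "olst_domain_error")
      }
      tab <- complete_rows(table, names(fit$weights))
      newdata <- tab[, names(fit$weights), drop = FALSE]
      ids <- tab$participant_id
    } else {
      ids <- seq_len(nrow(newdata))
    }
  } else if (inherits(model, "olst_svm")) {
    fit <- model
    if (is.null(newdata)) {
      stop_olst("supply `newdata` for a bare SVM fit", "olst_domain_error")
    }
    ids <- rownames(newdata) %||% seq_len(nrow(newdata))
  } else {
    stop_olst("`model` must be an olst_model or olst_svm", "olst_domain_error")
  }
  X <- as.matrix(newdata)[, names(fit$weights), drop = FALSE]
  if (any(!is.finite(X))) {
    stop_olst("non-finite feature values", "olst_domain_error")
  }
  Z <- sweep(sweep(X, 2L, fit$center), 2L, fit$scale, "/")
  dec <- drop(Z %*% fit$weights) + fit$intercept
  ctr <- colMeans(Z)
  contrib <- sweep(Z, 2L, ctr) *
    matrix(fit$weights, nrow(Z), ncol(Z), byrow = TRUE)
  base <- mean(dec)
  out <- tibble(
    participant_id = rep(ids, times = ncol(Z)),
    variable = rep(colnames(X), each = nrow(Z)),
    value = as.numeric(X),
    attribution = as.numeric(contrib),
    decision = rep(dec, times = ncol(Z))
  )
  attr(out, "base_value") <- base
  class(out) <- c("olst_shap", class(out))
  out
}

#' Spearman rank correlation with a t-based p-value
#'
#' Tie-corrected Spearman correlation (Pearson correlation of mid-ranks)
#' with significance assessed through `t = r_s * sqrt((n - 2)/(1 - r_s^2))`
#' on `n - 2` degrees of freedom.
#'
#' @param a,b Numeric vectors of equal length (n >= 3).
#'
#' @return A one-row tibble: `estimate`, `statistic`, `df`, `p_value`,
#'   `method`. A constant input gives `NA` estimates with a warning.
#' @export
spearman_corr <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop_olst("need two equal-length vectors with n >= 3",
              "olst_insufficient_data_error")
  }
  if (sd(a) == 0 || sd(b) == 0) {
    rlang::warn("constant input: Spearman correlation undefined")
    return(tibble(estimate = NA_real_, statistic = NA_real_,
                  df = length(a) - 2L, p_value = NA_real_,
                  method = "spearman"))
  }
  rs <- cor(a, b, method = "spearman")
  n <- length(a)
  tstat <- rs * sqrt((n - 2) / max(1 - rs^2, .Machine$double.eps))
  tibble(
    estimate = rs,
    statistic = tstat,
    df = n - 2L,
    p_value = 2 * pt(-abs(tstat), n - 2L),
    method = "spearman"
  )
}

#' Cohort characteristics by group
#'
#' Group means and SDs with Welch two-sample t-tests (age, SRS-2 total) and
#' an uncorrected Pearson chi-squared test (df 1) for the sex ratio, in the
#' style of a participant-characteristics table.
#'
#' @param table An `olst_features` table (columns `sex`, `srs_total`,
#'   `group`; `age` is taken from `cohort` when given).
#' @param cohort Optional cohort tibble supplying `age` by `participant_id`.
#'
#' @return A tibble with one row per characteristic: group summaries,
#'   `statistic`, `df`, `p_value`, `method`.
#' @export
cohort_stats <- function(table, cohort = NULL) {
  g <- as_group_factor(table$group)
  if (!all(c("High", "Low") %in% g)) {
    stop_olst("both groups must be non-empty", "olst_domain_error")
  }
  age <- NULL
  if (!is.null(cohort)) {
    age <- cohort$age[match(table$participant_id, cohort$id)]
  } else if ("age" %in% names(table)) {
    age <- table$age
  }
  welch_row <- function(x, label) {
    hi <- x[g == "High"]
    lo <- x[g == "Low"]
    if (length(hi) < 2L || length(lo) < 2L) {
      stop_olst("each group needs >= 2 members for the t-test",
                "olst_domain_error")
    }
    tt <- stats::t.test(hi, lo, var.equal = FALSE)
    tibble(
      characteristic = label,
      high_mean = mean(hi), high_sd = sd(hi),
      low_mean = mean(lo), low_sd = sd(lo),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, method = "welch_t"
    )
  }
  rows <- list()
  if (!is.null(age)) rows$age <- welch_row(age, "age")
  rows$srs <- welch_row(table$srs_total, "srs_total")
  counts <- table(table$sex, g)
  if (identical(dim(counts), c(2L, 2L))) {
    suppressWarnings(
      cs <- stats::chisq.test(counts, correct = FALSE)
    )
    rows$sex <- tibble(
      characteristic = "sex_ratio",
      high_mean = counts["male", "High"], high_sd = counts["female", "High"],
      low_mean = counts["male", "Low"], low_sd = counts["female", "Low"],
      statistic = unname(cs$statistic), df = unname(cs$parameter),
      p_value = cs$p.value, method = "chisq"
    )
  }
  dplyr::bind_rows(rows)
}

#' Probability-SRS association report
#'
#' For each fitted screening model, the Spearman rank correlation between
#' the calibrated High-group probability and the SRS-2 total, plus the
#' model's SHAP report — the interpretive summary of a screening run.
#'
#' @param models A single `olst_model` or a (possibly named) list of them.
#' @param table The `olst_features` table the models were built on.
#'
#' @return A list with `correlations` (one row per model: category, r_s, df,
#'   p-value), `scatter` (per-participant probability vs SRS), and `shap`
#'   (named list of `olst_shap` reports).
#' @export
probability_srs_report <- function(models, table) {
  if (inherits(models, "olst_model")) models <- list(models)
  if (is.null(names(models)) || any(names(models) == "")) {
    names(models) <- vapply(models, function(m) m$category, character(1))
  }
  cors <- purrr::imap(models, function(m, nm) {
    p <- m$predictions
    ct <- if (sd(p$prob) == 0) {
      rlang::warn(sprintf("constant probabilities in '%s'", nm))
      tibble(estimate = NA_real_, statistic = NA_real_,
             df = nrow(p) - 2L, p_value = NA_real_, method = "spearman")
    } else {
      spearman_corr(p$prob, p$srs_total)
    }
    dplyr::mutate(ct, category = nm, .before = 1L)
  })
  scatter <- purrr::imap(models, function(m, nm) {
    dplyr::mutate(m$predictions[, c("participant_id", "srs_total", "prob",
                                    "truth")],
                  category = nm, .before = 1L)
  })
  shap <- purrr::map(models, linear_shap, table = table)
  list(
    correlations = dplyr::bind_rows(cors),
    scatter = dplyr::bind_rows(scatter),
    shap = shap
  )
}
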