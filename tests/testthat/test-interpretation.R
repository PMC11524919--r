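# SHAP attributions, rank correlations, and cohort summary statistics.

test_that("linear SHAP is exact: additivity and hand computation", {
  # 3 x 2 hand-built example on an unstandardized fit
  X <- rbind(c(1, 10), c(2, 14), c(6, 12))
  colnames(X) <- c("f1", "f2")
  fit <- structure(
    list(weights = c(f1 = 0.5, f2 = -0.25), intercept = 1,
         center = c(0, 0), scale = c(1, 1), cost = 1, standardize = FALSE),
    class = "olst_svm"
  )
  sh <- linear_shap(fit, newdata = X)
  xbar <- colMeans(X)
  for (j in c("f1", "f2")) {
    got <- sh$attribution[sh$variable == j]
    expect_equal(got, fit$weights[[j]] * (X[, j] - xbar[[j]]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  base <- attr(sh, "base_value")
  tot <- tapply(sh$attribution, sh$participant_id, sum)
  dec <- tapply(sh$decision, sh$participant_id, head, 1)
  expect_true(all(abs(base + tot - dec) < 1e-9))

  # zero-weight features contribute nothing
  fit0 <- fit
  fit0$weights[["f2"]] <- 0
  sh0 <- linear_shap(fit0, newdata = X)
  expect_true(all(sh0$attribution[sh0$variable == "f2"] == 0))
})

test_that("SHAP on a fitted screening model satisfies additivity", {
  tab <- separable_table()
  m <- suppressMessages(search_best_model(tab, "combined",
                                          strategy = "forward_floating"))
  sh <- linear_shap(m, table = tab)
  base <- attr(sh, "base_value")
  tot <- tapply(sh$attribution, sh$participant_id, sum)
  dec <- tapply(sh$decision, sh$participant_id, head, 1)
  expect_true(all(abs(base + tot - dec[names(tot)]) < 1e-9))
})

test_that("Spearman correlation matches its rank-then-Pearson oracle", {
  expect_equal(spearman_corr(1:10, exp(1:10))$estimate, 1)
  expect_equal(spearman_corr(1:10, -(1:10)^3)$estimate, -1)

  withr::with_seed(61, {
    a <- sample(1:5, 10, replace = TRUE) # ties on both sides
    b <- sample(1:4, 10, replace = TRUE)
    got <- spearman_corr(a, b)
    expect_equal(got$estimate, spearman_oracle(a, b), tolerance = 1e-12)
    expect_equal(got$df, 8L)
    tt <- got$estimate * sqrt(8 / (1 - got$estimate^2))
    expect_equal(got$p_value, 2 * pt(-abs(tt), 8), tolerance = 1e-12)
  })
  expect_warning(res <- spearman_corr(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$estimate))
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(62, {
    a <- rnorm(30)
    b <- rnorm(30)
    r0 <- spearman_corr(a, b)$estimate
    expect_equal(spearman_corr(exp(a), b)$estimate, r0, tolerance = 1e-12)
    expect_equal(spearman_corr(a, qnorm(pnorm(b))^3)$estimate, r0,
                 tolerance = 1e-12)
  })
})

test_that("cohort statistics: identical groups give null statistics", {
  vals <- rep(c(30, 40, 50, 60), 2)
  tab <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:8),
    sex = rep(c("male", "male", "female", "female"), 2),
    srs_total = vals,
    group = factor(rep(c("High", "Low"), each = 4), c("Low", "High")),
    age = rep(c(5.0, 5.1, 5.2, 5.3), 2)
  )
  st <- cohort_stats(tab)
  srs_row <- st[st$characteristic == "srs_total", ]
  expect_equal(srs_row$statistic, 0)
  sex_row <- st[st$characteristic == "sex_ratio", ]
  expect_equal(sex_row$statistic, 0)
})

test_that("Welch t and chi-squared match the formula oracles", {
  withr::with_seed(63, {
    for (i in 1:10) {
      a <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2),
                 sd = runif(1, 0.5, 3))
      b <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2),
                 sd = runif(1, 0.5, 3))
      tab <- tibble::tibble(
        participant_id = sprintf("P%03d", seq_len(length(a) + length(b))),
        sex = rep(c("male", "female"), length.out = length(a) + length(b)),
        srs_total = c(a, b) + 60,
        group = factor(rep(c("High", "Low"), c(length(a), length(b))),
                       c("Low", "High"))
      )
      st <- cohort_stats(tab)
      row <- st[st$characteristic == "srs_total", ]
      want <- welch_oracle(a + 60, b + 60)
      expect_equal(row$statistic, want$t, tolerance = 1e-9)
      expect_equal(row$df, want$df, tolerance = 1e-9)
      expect_equal(row$p_value, want$p, tolerance = 1e-9)
    }
  })

  # sex split 10:10 High, 55:52 Low against the expected-count oracle
  tab2 <- tibble::tibble(
    participant_id = sprintf("P%03d", 1:127),
    sex = c(rep("male", 10), rep("female", 10),
            rep("male", 55), rep("female", 52)),
    srs_total = c(80 + seq_len(20), 30 - (seq_len(107) %% 25)),
    group = factor(rep(c("High", "Low"), c(20, 107)), c("Low", "High"))
  )
  st2 <- cohort_stats(tab2)
  counts <- table(tab2$sex, tab2$group)[, c("High", "Low")]
  expect_equal(st2$statistic[st2$characteristic == "sex_ratio"],
               chisq_oracle(counts), tolerance = 1e-12)
  expect_equal(st2$df[st2$characteristic == "sex_ratio"], 1)
})

test_that("the probability-SRS report carries one correlation per model", {
  tab <- separable_table(n_high = 6, n_low = 14, seed = 8)
  models <- list(
    conventional = suppressMessages(
      search_best_model(tab, "conventional", strategy = "forward_floating")
    ),
    proposed = suppressMessages(
      search_best_model(tab, "proposed", strategy = "forward_floating")
    )
  )
  rep <- probability_srs_report(models, tab)
  expect_equal(nrow(rep$correlations), 2L)
  expect_setequal(rep$correlations$category, c("conventional", "proposed"))
  expect_equal(nrow(rep$scatter), 2L * nrow(tab))
  expect_length(rep$shap, 2L)

  # degenerate probabilities still produce a report
  m <- models$conventional
  m$predictions$prob <- rep(0.5, nrow(tab))
  rep2 <- suppressWarnings(probability_srs_report(list(flat = m), tab))
  expect_true(is.na(rep2$correlations$estimate[1]))
  expect_equal(nrow(rep2$scatter), nrow(tab))
})
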