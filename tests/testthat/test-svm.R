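# The linear SVM engine, LOOCV machinery, confusion metrics, and Platt
# calibration. The solver is cross-checked against a brute-force primal
# minimization and against e1071 (libsvm).

test_that("separable one-dimensional data is classified with margin", {
  x <- matrix(rep(c(-1, 1), each = 5), ncol = 1)
  y <- rep(c("Low", "High"), each = 5)
  fit <- fit_linear_svm(x, y, cost = 100, standardize = FALSE)
  expect_gt(fit$weights[[1]], 0)
  d <- decision_values(fit, x)
  expect_true(all((d > 0) == (y == "High")))
})

test_that("duplicating every sample scales the objective uniformly", {
  withr::with_seed(51, {
    x <- matrix(rnorm(40), ncol = 2)
    y <- ifelse(x[, 1] + 0.5 * rnorm(20) > 0, "High", "Low")
    if (length(unique(y)) < 2) skip("degenerate draw")
    # doubling the data at half the cost doubles the hinge term only in
    # count, so the minimizer (the boundary) is unchanged
    f1 <- fit_linear_svm(x, y, cost = 1, standardize = FALSE)
    f2 <- fit_linear_svm(rbind(x, x), c(y, y), cost = 0.5,
                         standardize = FALSE)
    expect_equal(f1$weights, f2$weights, tolerance = 1e-3)
    expect_equal(f1$intercept, f2$intercept, tolerance = 1e-3)
    # on separable data at large cost the hard-margin boundary is invariant
    # to duplication at fixed cost as well
    xs <- matrix(rep(c(-1, 1), each = 5), ncol = 1)
    ys <- rep(c("Low", "High"), each = 5)
    g1 <- fit_linear_svm(xs, ys, cost = 100, standardize = FALSE)
    g2 <- fit_linear_svm(rbind(xs, xs), c(ys, ys), cost = 100,
                         standardize = FALSE)
    expect_equal(g1$weights, g2$weights, tolerance = 1e-4)
  })
})

test_that("the primal objective matches a brute-force oracle", {
  # 4-point 1-D problem at C = 1
  X <- matrix(c(-2, -0.5, 0.6, 1.5), ncol = 1)
  y <- c(-1, -1, 1, 1)
  fit <- olstscreen:::.smo_fit(X, y, 1, tol = 1e-10)
  oracle <- optim(c(0, 0), function(wb) svm_primal(wb[1], wb[2], X, y, 1),
                  method = "Nelder-Mead",
                  control = list(maxit = 50000, reltol = 1e-15))
  oracle <- optim(oracle$par, function(wb) svm_primal(wb[1], wb[2], X, y, 1),
                  method = "Nelder-Mead",
                  control = list(maxit = 50000, reltol = 1e-15))
  got <- svm_primal(fit$weights, fit$intercept, X, y, 1)
  expect_equal(got, oracle$value, tolerance = 1e-6)
  # strong duality: dual objective (min form) equals -primal at the optimum
  expect_equal(-fit$dual_objective, got, tolerance = 1e-6)
})

test_that("the solver agrees with libsvm across costs", {
  skip_if_not_installed("e1071")
  withr::with_seed(52, {
    n <- 60
    X <- matrix(rnorm(n * 3), n, 3)
    y <- c(rep(1L, 20), rep(-1L, 40))
    X[y == 1, 1] <- X[y == 1, 1] + 1.5
    for (C in c(0.01, 0.1, 1)) {
      mine <- olstscreen:::.smo_fit(X, y, C, tol = 1e-10)
      ref <- e1071::svm(X, factor(y, levels = c(1, -1)), kernel = "linear",
                        cost = C, scale = FALSE, tolerance = 1e-8)
      w_ref <- drop(t(ref$coefs) %*% ref$SV)
      b_ref <- -ref$rho
      # align the sign convention via the decision on the first point
      s <- sign(sum(w_ref * X[1, ]) + b_ref) ==
        sign(sum(mine$weights * X[1, ]) + mine$intercept)
      if (!s) {
        w_ref <- -w_ref
        b_ref <- -b_ref
      }
      expect_equal(as.numeric(mine$weights), as.numeric(w_ref),
                   tolerance = 1e-4)
      expect_equal(mine$intercept, b_ref, tolerance = 1e-4)
    }
  })
})

test_that("LOOCV returns one out-of-fold prediction per row", {
  tab <- separable_table()
  spec <- olst_model_spec("combined", cost = 1)
  pred <- loocv_predict(tab, spec)
  expect_equal(nrow(pred), nrow(tab))
  expect_setequal(pred$participant_id, tab$participant_id)

  # perfect separation: every out-of-fold prediction is correct
  spec2 <- olst_model_spec("conventional", subset = "cop_convex_hull",
                           cost = 10)
  pred2 <- loocv_predict(tab, spec2)
  expect_true(all(pred2$pred == pred2$truth))

  # permuting rows permutes, but does not change, the predictions
  perm <- tab[withr::with_seed(99, sample(nrow(tab))), ]
  pred3 <- loocv_predict(perm, spec2)
  m1 <- pred2[order(pred2$participant_id), c("participant_id", "pred")]
  m3 <- pred3[order(pred3$participant_id), c("participant_id", "pred")]
  expect_identical(m1, m3)
})

test_that("LOOCV refuses degenerate class structure", {
  tab <- separable_table(n_high = 1, n_low = 10)
  expect_error(loocv_predict(tab, olst_model_spec("combined", cost = 1)),
               class = "olst_domain_error")
})

test_that("confusion metrics reproduce the screening identities", {
  # 16 of 19 High correct, all 107 Low correct
  truth <- c(rep("High", 19), rep("Low", 107))
  pred <- c(rep("High", 16), rep("Low", 3), rep("Low", 107))
  cm <- confusion_metrics(pred, truth)
  expect_equal(cm$tp, 16)
  expect_equal(cm$fn, 3)
  expect_equal(cm$tn, 107)
  expect_equal(cm$fp, 0)
  expect_equal(round(cm$accuracy, 3), 0.976)
  expect_equal(round(cm$sensitivity, 3), 0.842)
  expect_equal(round(cm$specificity, 3), 1.000)
  expect_equal(cm$tp + cm$fn, sum(truth == "High"))
  expect_equal(cm$tn + cm$fp, sum(truth == "Low"))

  all_right <- confusion_metrics(truth, truth)
  expect_equal(c(all_right$accuracy, all_right$sensitivity,
                 all_right$specificity), c(1, 1, 1))

  flipped <- ifelse(truth == "High", "Low", "High")
  cm0 <- confusion_metrics(flipped, truth)
  expect_equal(c(cm0$accuracy, cm0$sensitivity, cm0$specificity), c(0, 0, 0))

  onesided <- confusion_metrics(rep("Low", 4), rep("Low", 4))
  expect_true(is.na(onesided$sensitivity))
})

test_that("Platt probabilities are monotone and near 0.5 at the margin", {
  # exactly symmetric decisions with balanced labels
  d <- rep(c(1, -1), each = 20)
  y <- rep(c("High", "Low"), each = 20)
  fit <- platt_probabilities(d, y)
  ord <- order(d)
  expect_true(all(diff(fit$probabilities[ord]) >= 0))
  p_at_zero <- 1 / (1 + exp(fit$B))
  expect_lt(abs(p_at_zero - 0.5), 0.05)
  withr::with_seed(53, {
    dn <- c(rnorm(20, 1), rnorm(20, -1))
    fitn <- platt_probabilities(dn, y)
    ordn <- order(dn)
    expect_true(all(diff(fitn$probabilities[ordn]) >= 0))
  })
  expect_error(platt_probabilities(c(1, NA), c("High", "Low")),
               class = "olst_domain_error")
})

test_that("Platt parameters match a generic optimizer on the same loss", {
  withr::with_seed(54, {
    d <- rnorm(10)
    y <- ifelse(d + 0.5 * rnorm(10) > 0, "High", "Low")
    if (length(unique(y)) < 2) skip("degenerate draw")
    fit <- platt_probabilities(d, y)
    np <- sum(y == "High")
    nn <- sum(y == "Low")
    t <- ifelse(y == "High", (np + 1) / (np + 2), 1 / (nn + 2))
    nll <- function(ab) {
      f <- ab[1] * d + ab[2]
      sum(ifelse(f >= 0, t * f + log1p(exp(-f)),
                 (t - 1) * f + log1p(exp(f))))
    }
    oracle <- optim(c(0, 0), nll, method = "BFGS",
                    control = list(maxit = 10000, reltol = 1e-14))
    expect_equal(fit$A, oracle$par[1], tolerance = 1e-4)
    expect_equal(fit$B, oracle$par[2], tolerance = 1e-4)
  })
})
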