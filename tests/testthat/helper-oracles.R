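# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Pincus approximate entropy by direct enumeration of template pairs,
# Chebyshev distance, self-matches included.
apen_oracle <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    nt <- n - mm + 1
    logc <- numeric(nt)
    for (i in seq_len(nt)) {
      cnt <- 0
      for (j in seq_len(nt)) {
        dmax <- 0
        for (k in 0:(mm - 1)) {
          d <- abs(x[i + k] - x[j + k])
          if (d > dmax) dmax <- d
        }
        if (dmax <= r) cnt <- cnt + 1
      }
      logc[i] <- log(cnt / nt)
    }
    mean(logc)
  }
  phi(m) - phi(m + 1)
}

# Convex hull area via Jarvis march (gift wrapping) and a triangle fan.
hull_oracle <- function(pts) {
  pts <- unique(as.matrix(pts))
  n <- nrow(pts)
  if (n < 3) return(0)
  cross <- function(o, a, b) {
    (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  }
  start <- which.min(pts[, 1] + 1e-12 * pts[, 2])
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1) 2 else 1
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0 ||
          (cr == 0 && sum((pts[r, ] - pts[p, ])^2) >
             sum((pts[q, ] - pts[p, ])^2))) {
        q <- r
      }
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) break
  }
  if (length(hull) < 3) return(0)
  v <- pts[hull, , drop = FALSE]
  area <- 0
  for (i in 2:(nrow(v) - 1)) {
    area <- area + cross(v[1, ], v[i, ], v[i + 1, ]) / 2
  }
  abs(area)
}

# Pearson correlation straight from the definition
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  (sum(x * y) - sx * sy / n) /
    sqrt((sum(x^2) - sx^2 / n) * (sum(y^2) - sy^2 / n))
}

# mid-ranks computed by hand (average rank over ties)
midrank_oracle <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    r[i] <- sum(x < x[i]) + (sum(x == x[i]) + 1) / 2
  }
  r
}

spearman_oracle <- function(x, y) {
  pearson_oracle(midrank_oracle(x), midrank_oracle(y))
}

# Welch two-sample t statistic and Welch-Satterthwaite df from the formulas
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Pearson chi-squared on a 2x2 table from expected counts, no correction
chisq_oracle <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

# primal objective of the soft-margin linear SVM
svm_primal <- function(w, b, X, y, C) {
  0.5 * sum(w^2) + C * sum(pmax(1 - y * (drop(X %*% w) + b), 0))
}
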