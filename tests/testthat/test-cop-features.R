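# COP trajectory computation and the sway / balance variables.

test_that("a point mass gives a constant COP at the cell centre", {
  frames <- rep(list(list(row = 10L, col = 20L, value = 2)), 5)
  ps <- make_pressure(frames)
  traj <- compute_cop_trajectory(ps, min_active = 1L)
  ctr <- cell_xy(10, 20)
  # motion may be rotated into the foot frame, but a constant stays constant
  expect_equal(sqrt(traj$x^2 + traj$y^2),
               rep(sqrt(sum(ctr^2)), 5), tolerance = 1e-12)
  expect_equal(sway_path_metrics(traj)$len_total_path, 0)
})

test_that("the COP is the pressure-weighted centroid", {
  # two cells on one row, 4 cm apart, pressures 1 and 3: centroid splits 3:1
  frames <- rep(list(list(row = c(24L, 24L), col = c(20L, 24L),
                          value = c(1, 3))), 4)
  ps <- make_pressure(frames)
  traj <- compute_cop_trajectory(ps, min_active = 1L)
  x1 <- cell_xy(24, 20)[[1]]
  x2 <- cell_xy(24, 24)[[1]]
  expected <- (1 * x1 + 3 * x2) / 4
  expect_equal(expected, x1 + 3, tolerance = 1e-12) # 3 cm past the light cell
  # the trajectory stores rotated coordinates; a static pattern's centroid
  # distance from the origin is rotation-invariant
  got <- sqrt(traj$x[1]^2 + traj$y[1]^2)
  want <- sqrt(expected^2 + cell_xy(24, 20)[[2]]^2)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("ellipse alignment rotates oblique line motion onto the Y axis", {
  # point mass tracing an exactly collinear path along direction (1, 2),
  # i.e. at an oblique angle to the grid axes
  ks <- -6:6
  frames <- lapply(ks, function(k) {
    list(row = as.integer(24 - 2 * k), col = as.integer(24 + k), value = 1)
  })
  ps <- make_pressure(frames)
  traj <- compute_cop_trajectory(ps, min_active = 1L)
  expect_lt(sd(traj$x), 1e-6 * sd(traj$y)) # motion entirely along Y
  expect_equal(traj$ellipse$orientation, atan2(2, 1), tolerance = 1e-6)
})

test_that("all-invalid frames raise an empty-trajectory error", {
  frames <- rep(list(list(row = 1L, col = 1L, value = 1)), 4)
  ps <- make_pressure(frames)
  expect_error(compute_cop_trajectory(ps, min_active = 3L),
               class = "olst_empty_trajectory_error")
})

test_that("path length and mean speed follow the hand examples", {
  tr <- make_traj(c(0, 1), c(0, 3), c(0, 4))
  pm <- sway_path_metrics(tr)
  expect_equal(pm$len_total_path, 5)
  expect_equal(pm$m_cop_speed, 5)

  tr2 <- make_traj((0:39) / 20, rep(1.5, 40), rep(-2, 40))
  pm2 <- sway_path_metrics(tr2)
  expect_equal(pm2$len_total_path, 0)
  expect_equal(pm2$m_cop_speed, 0)

  tr3 <- make_traj(0:3, c(0, 1, 1, 0), c(0, 0, 1, 1))
  pm3 <- sway_path_metrics(tr3)
  expect_equal(pm3$len_total_path, 3)
  expect_equal(pm3$m_cop_speed, 1)

  expect_error(sway_path_metrics(make_traj(0, 1, 1)),
               class = "olst_insufficient_data_error")
})

test_that("speed times elapsed time is exactly the path length", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- sample(10:60, 1)
      tr <- make_traj((0:(n - 1)) / 20, rnorm(n), rnorm(n))
      pm <- sway_path_metrics(tr)
      elapsed <- (n - 1) / 20
      expect_identical(pm$m_cop_speed * elapsed, pm$len_total_path)
    }
  })
})

test_that("path length and hull area are rigid-motion invariant", {
  withr::with_seed(32, {
    n <- 50
    x <- cumsum(rnorm(n)) / 4
    y <- cumsum(rnorm(n)) / 4
    a <- runif(1, 0, 2 * pi)
    dx <- runif(1, -5, 5)
    dy <- runif(1, -5, 5)
    xr <- cos(a) * x - sin(a) * y + dx
    yr <- sin(a) * x + cos(a) * y + dy
    p1 <- sway_path_metrics(make_traj((0:(n - 1)) / 20, x, y))
    p2 <- sway_path_metrics(make_traj((0:(n - 1)) / 20, xr, yr))
    expect_equal(p1$len_total_path, p2$len_total_path, tolerance = 1e-9)
    expect_equal(convex_hull_area(cbind(x, y)),
                 convex_hull_area(cbind(xr, yr)), tolerance = 1e-9)
  })
})

test_that("approximate entropy matches the brute-force definition", {
  expect_equal(approximate_entropy(rep(2, 30), m = 2, r = 0.1), 0)

  alt <- rep(c(1, 2), 20)
  expect_equal(approximate_entropy(alt, m = 2, r = 0.5),
               apen_oracle(alt, 2, 0.5), tolerance = 1e-9)

  withr::with_seed(33, {
    for (i in 1:12) {
      x <- rnorm(40)
      r <- 0.2 * sd(x)
      expect_equal(approximate_entropy(x, m = 2, r = r),
                   apen_oracle(x, 2, r), tolerance = 1e-9)
    }
  })
})

test_that("white noise is less regular than a sine of equal spread", {
  withr::with_seed(34, {
    noise <- rnorm(40)
    tt <- seq_len(40)
    sine <- sin(2 * pi * tt / 10)
    sine <- sine * sd(noise) / sd(sine)
    expect_gt(approximate_entropy(noise, 2, 0.2 * sd(noise)),
              approximate_entropy(sine, 2, 0.2 * sd(sine)))
  })
})

test_that("degenerate entropy inputs follow the conventions", {
  expect_error(approximate_entropy(c(1, 2, 3), m = 2),
               class = "olst_insufficient_data_error")
  expect_warning(v <- approximate_entropy(rep(1, 40), m = 2, r = 0.2 * 0),
                 "tolerance")
  expect_equal(v, 0)
})

test_that("convex hull area matches the Jarvis-march oracle", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(convex_hull_area(sq), 1)
  line <- cbind(1:5, 2 * (1:5))
  expect_equal(convex_hull_area(line), 0)
  expect_error(convex_hull_area(matrix(numeric(0), ncol = 2)),
               class = "olst_insufficient_data_error")

  withr::with_seed(35, {
    for (i in 1:15) {
      pts <- matrix(runif(2 * sample(5:50, 1)), ncol = 2)
      expect_equal(convex_hull_area(pts), hull_oracle(pts), tolerance = 1e-9)
      bbox <- diff(range(pts[, 1])) * diff(range(pts[, 2]))
      expect_lte(convex_hull_area(pts), bbox + 1e-12)
    }
  })
})

test_that("subsampling a trajectory never increases path length", {
  withr::with_seed(36, {
    for (i in 1:5) {
      n <- 60
      x <- cumsum(rnorm(n))
      y <- cumsum(rnorm(n))
      full <- sway_path_metrics(make_traj((0:(n - 1)) / 20, x, y))
      idx <- seq(1, n, by = 2)
      half <- sway_path_metrics(
        make_traj((idx - 1) / 20, x[idx], y[idx])
      )
      expect_lte(half$len_total_path, full$len_total_path)
    }
  })
})

test_that("COM-COP distance removes the offset and scores |sin| as 2/pi", {
  n <- 200 # ten full 1-Hz periods at 20 Hz
  tt <- (0:(n - 1)) / 20
  cop_x <- 0.5 * sin(2 * pi * 0.3 * tt)
  traj <- make_traj(tt, cop_x, numeric(n))

  same <- lapply(seq_len(n), function(i) {
    p <- template_pose()
    lapply(p, function(v) v + c(cop_x[i] + 7, 0)) # constant offset only
  })
  kp <- make_kp_series(same)
  expect_equal(com_cop_distance(kp, traj), 0, tolerance = 1e-9)

  shifted <- lapply(seq_len(n), function(i) {
    p <- template_pose()
    lapply(p, function(v) v + c(cop_x[i] + sin(2 * pi * tt[i]), 0))
  })
  kp2 <- make_kp_series(shifted)
  expect_equal(com_cop_distance(kp2, traj), 2 / pi, tolerance = 0.01)
  expect_gte(com_cop_distance(kp2, traj), 0)
})

test_that("the longest stand is the maximum over trials", {
  trials <- lapply(c(12, 20, 8, 20), function(d) list(duration = d))
  expect_equal(max_trial_duration(trials), 20)
  expect_equal(max_trial_duration(lapply(rep(5, 4), function(d)
    list(duration = d))), 5)
  expect_error(max_trial_duration(list()),
               class = "olst_insufficient_data_error")
})
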