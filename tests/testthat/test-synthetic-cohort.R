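# The generator must be deterministic, respect the trial protocol, and
# inject the documented severity effects with the right signs.

test_that("identical config and seed give identical cohorts", {
  cfg <- small_cfg()
  c1 <- generate_cohort(cfg, seed = 7)
  c2 <- generate_cohort(cfg, seed = 7)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cfg, seed = 8)
  expect_false(identical(c1$srs_total, c3$srs_total))
})

test_that("trials follow the protocol: alternating legs, caps, synchrony", {
  co <- fixture_cohort()
  cfg <- small_cfg()
  for (trials in co$trials) {
    expect_length(trials, cfg$n_trials)
    expect_identical(vapply(trials, `[[`, "", "leg"),
                     rep(c("right", "left"), length.out = cfg$n_trials))
    for (tr in trials) {
      expect_lte(tr$duration, cfg$trial_cap)
      expect_gt(tr$duration, 0)
      expect_identical(tr$pressure$timestamps, tr$keypoints$timestamps)
    }
  }
})

test_that("zero fall hazard censors every trial at the cap", {
  cfg <- olst_config(n_boys = 1, n_girls = 1,
                     effect = severity_effect(fall_hazard = 0))
  co <- generate_cohort(cfg, seed = 3)
  for (trials in co$trials) {
    for (tr in trials) {
      expect_equal(tr$duration, cfg$trial_cap)
      expect_equal(length(tr$pressure$timestamps),
                   cfg$trial_cap * cfg$sample_rate)
    }
  }
})

test_that("pressure frames are non-negative with at least 3 active cells", {
  co <- fixture_cohort()
  tr <- co$trials[[1]][[1]]
  expect_gte(min(tr$pressure$cells$value), 0)
  counts <- table(tr$pressure$cells$frame)
  expect_gte(min(counts), 3)
  expect_length(counts, length(tr$pressure$timestamps))
})

test_that("frame centroids track the simulated COP to within half a cell", {
  cfg <- olst_config()
  n <- 40
  tt <- (seq_len(n) - 1) / cfg$sample_rate
  cs_x <- 4 + 1.2 * sin(2 * pi * tt)        # stance blob centre path
  cs_y <- 0.8 * cos(2 * pi * 0.7 * tt)
  lam <- pmax(1 - tt / cfg$ramp, 0)
  m_lift <- 0.5 * lam
  m_stance <- 1 - m_lift
  foot_lift <- c(-4, 0)
  cells <- olstscreen:::render_pressure(cs_x, cs_y, m_stance, foot_lift,
                                        m_lift, cfg)
  cop_x <- m_stance * cs_x + m_lift * foot_lift[[1]]
  cop_y <- m_stance * cs_y + m_lift * foot_lift[[2]]
  size <- cfg$sensor_size
  for (i in seq_len(n)) {
    f <- cells[cells$frame == i, ]
    x <- (f$col + 0.5) * cfg$cell_pitch - size / 2
    y <- size / 2 - (f$row + 0.5) * cfg$cell_pitch
    gx <- sum(f$value * x) / sum(f$value)
    gy <- sum(f$value * y) / sum(f$value)
    expect_lt(sqrt((gx - cop_x[i])^2 + (gy - cop_y[i])^2),
              cfg$cell_pitch / 2)
  }
})

test_that("SRS draws respect the sex-specific cutoff truncation", {
  co <- generate_cohort(olst_config(n_boys = 30, n_girls = 30,
                                    trial_cap = 2, min_stand = 2), seed = 13)
  grp <- assign_group(co$sex, co$srs_total)
  cut <- ifelse(co$sex == "male", 53.5, 52.5)
  expect_true(all(co$srs_total[grp == "High"] > cut[grp == "High"]))
  expect_true(all(co$srs_total[grp == "Low"] < cut[grp == "Low"]))
  expect_true(all(co$srs_total >= 0))
  # severity is the within-cohort SRS percentile
  expect_equal(order(co$severity), order(rank(co$srs_total,
                                              ties.method = "average")))
})

test_that("larger sway amplitude increases expected path length", {
  cfg_small <- olst_config(effect = severity_effect(sway_sigma_base = 0.5,
                                                    sway_sigma = 0,
                                                    fall_hazard = 0))
  cfg_large <- olst_config(effect = severity_effect(sway_sigma_base = 1.5,
                                                    sway_sigma = 0,
                                                    fall_hazard = 0))
  paths <- vapply(list(cfg_small, cfg_large), function(cfg) {
    withr::with_seed(21, {
      tr <- simulate_trial(0.5, "right", cfg)
      traj <- compute_cop_trajectory(tr$pressure)
      sway_path_metrics(traj, c(cfg$ramp, cfg$trial_cap))$len_total_path
    })
  }, numeric(1))
  expect_gt(paths[[2]], paths[[1]])
})

test_that("high-severity groups sway over a smaller convex hull", {
  # small-footprint protocol variant keeps this multi-seed check fast; the
  # severity effects themselves are the documented strong defaults
  cfg <- olst_config(n_boys = 100, n_girls = 100, trial_cap = 3,
                     grid_cells = c(24, 24))
  wins <- vapply(1:10, function(s) {
    co <- generate_cohort(cfg, seed = s)
    grp <- assign_group(co$sex, co$srs_total)
    hull <- vapply(co$trials, function(trials) {
      tr <- trials[[1]]
      traj <- compute_cop_trajectory(tr$pressure)
      keep <- traj$valid & traj$timestamps < 2
      convex_hull_area(cbind(traj$x[keep], traj$y[keep]))
    }, numeric(1))
    mean(hull[grp == "High"]) < mean(hull[grp == "Low"])
  }, logical(1))
  expect_gte(sum(wins), 9)
})

test_that("severity outside [0, 1] and invalid configs are rejected", {
  expect_error(simulate_trial(1.2, "right", olst_config()),
               class = "olst_domain_error")
  expect_error(olst_config(grid_cells = c(4, 4)),
               class = "olst_config_error")
  expect_error(olst_config(n_boys = 0), class = "olst_config_error")
  expect_error(severity_effect(ou_theta = 0), class = "olst_config_error")
})
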