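test_that("COP is the force-weighted sensor centroid", {
  lay <- sensor_layout(rbind(c(0, 0), c(2, 2)), "right")
  traj <- compute_cop(rbind(c(1, 1)), lay, eps = 0)
  expect_equal(unname(traj$points[1, ]), c(1, 1))

  lay2 <- sensor_layout(rbind(c(0, 0), c(4, 0)), "right")
  traj2 <- compute_cop(rbind(c(3, 1)), lay2, eps = 0)
  expect_equal(unname(traj2$points[1, ]), c(1, 0))

  expect_error(compute_cop(matrix(0, 5, 2), lay2, eps = 0), "undefined-COP")
  expect_error(compute_cop(matrix(1, 2, 3), lay2), "sensors")
})

test_that("COP stays in the sensor hull and ignores force scaling", {
  lay <- default_insole_layout()$right
  set.seed(21)
  frames <- matrix(runif(1000 * 16, 0, 100), 1000, 16)
  traj <- compute_cop(frames, lay, eps = 0)
  expect_true(all(traj$points[, "x"] >= min(lay$coords[, "x"]) - 1e-9))
  expect_true(all(traj$points[, "x"] <= max(lay$coords[, "x"]) + 1e-9))
  expect_true(all(traj$points[, "y"] >= min(lay$coords[, "y"]) - 1e-9))
  expect_true(all(traj$points[, "y"] <= max(lay$coords[, "y"]) + 1e-9))
  # uniform per-frame force scaling cancels in the weighted mean
  scaled <- compute_cop(frames * 7.3, lay, eps = 0)
  expect_equal(scaled$points, traj$points)
})

test_that("weak foot is the side with smaller anterior-posterior sway", {
  expect_equal(select_weak_foot(2, 5), "left")
  expect_equal(select_weak_foot(5, 2), "right")
  expect_equal(select_weak_foot(3, 3), "right")   # tie -> right
})

test_that("posturography statistics match hand computation on two points", {
  fv <- suppressWarnings(extract_features(fix_two_point_window()))
  # weak-side tie resolves to the right foot; its COP points are (0,0),(0,2)
  expect_equal(fv$weak_side, "right")
  expect_equal(fv$Mean_y, 1)
  expect_equal(fv$Std_y, 1)         # population SD
  expect_equal(fv$MRD, 1)
  expect_equal(fv$SRD, 0)
  expect_equal(fv$TOTEX, 2)
  expect_equal(fv$CCA, pi)
  # mirrored, equally loaded feet: perfect symmetry
  expect_equal(fv$GA, 0)
  expect_equal(fv$SIM, 1)
  expect_equal(fv$JSD, 0)
})

test_that("identical repeated steps give perfect temporal consistency", {
  sim <- simulate_subject(gait_sim_config(phenotype = "DWF_LR",
                                          noise_mult = 0, noise_add = 0,
                                          jitter_cv = 0, fatigue_min = 0,
                                          fatigue_max = 0, drift_sd = 0,
                                          total_steps = 40L, seed = 3))
  idx <- segment_steps(sim$recording)
  wins <- cut_windows(sim$recording, idx, plan_windows(n_steps(idx), 10, 10))
  fv <- extract_features(wins[[1]])
  expect_equal(fv$GIC, 0, tolerance = 1e-8)
  expect_equal(fv$SSIM, 1, tolerance = 1e-10)
  expect_equal(fv$SJSD, 0, tolerance = 1e-10)
})

test_that("divergence and similarity comparators respect their bounds", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(8); q <- runif(8)
    j1 <- gaitDDI:::js_divergence(p, q)
    expect_equal(j1, gaitDDI:::js_divergence(q, p))
    expect_gte(j1, 0)
    expect_lte(j1, log(2) + 1e-12)
    s <- gaitDDI:::cosine_sim(p, q)
    expect_lte(s, 1 + 1e-12)
  }
  expect_equal(gaitDDI:::js_divergence(c(1, 0), c(0, 1)), log(2))
  expect_equal(gaitDDI:::cosine_sim(c(1, 2), c(2, 4)), 1)
})

test_that("window-level weak-side calls match the programmed side", {
  # deterministic at zero noise, any expressed attenuation
  sim <- simulate_subject(gait_sim_config(phenotype = "DWF_HR",
                                          weak_side = "left",
                                          atten = 0.5, noise_mult = 0,
                                          noise_add = 0,
                                          total_steps = 60L, seed = 5))
  tab0 <- suppressWarnings(
    extract_window_features(sim$recording, 20, run_config()))
  expect_true(all(tab0$weak_side == "left"))

  # stochastic at default settings: >= 95% of windows across subjects
  tabs <- lapply(1:4, function(i) {
    s <- simulate_subject(gait_sim_config(phenotype = "DWF_HR",
                                          weak_side = "right",
                                          total_steps = 120L,
                                          seed = 500 + i))
    suppressWarnings(extract_window_features(s$recording, 20, run_config()))
  })
  hit <- mean(unlist(lapply(tabs, function(t) t$weak_side == "right")))
  expect_gte(hit, 0.95)
})

test_that("z-scoring reproduces (x - mu)/sigma and flags missing features", {
  set.seed(41)
  tab <- random_feature_table(10)
  sc <- fit_scaler(tab, c("Std_y", "MRD"))
  z <- weak_vector(tab, c("Std_y", "MRD"), sc)
  mu <- mean(tab$Std_y); sd <- gaitDDI:::pop_sd(tab$Std_y)
  expect_equal(z[, "Std_y"], (tab$Std_y - mu) / sd, ignore_attr = TRUE)

  id <- identity_scaler(c("Std_y", "MRD"))
  expect_equal(weak_vector(tab, c("Std_y", "MRD"), id)[, "MRD"],
               tab$MRD, ignore_attr = TRUE)

  expect_error(weak_vector(tab, c("Std_y", "nope"), sc), "nope")
  tab$MRD[3] <- NA
  expect_error(weak_vector(tab, c("Std_y", "MRD"), sc), "MRD")
})
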