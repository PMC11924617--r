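test_that("simulation is byte-identical under a fixed seed", {
  a <- simulate_subject(gait_sim_config(total_steps = 40L, seed = 42))
  b <- simulate_subject(gait_sim_config(total_steps = 40L, seed = 42))
  expect_identical(a$recording$left, b$recording$left)
  expect_identical(a$truth, b$truth)
  c <- simulate_subject(gait_sim_config(total_steps = 40L, seed = 43))
  expect_false(identical(a$recording$left, c$recording$left))
})

test_that("emitted force is zero outside and positive inside contact spans", {
  sim <- simulate_subject(gait_sim_config(phenotype = "RWF",
                                          total_steps = 60L, seed = 2))
  for (side in c("left", "right")) {
    tot <- rowSums(sim$recording[[side]])
    spans <- sim$truth$steps[sim$truth$steps$side == side, ]
    inside <- unlist(Map(seq, spans$onset, spans$end))
    expect_true(all(tot[-inside] == 0))
    expect_true(all(tot[spans$onset] > 0))
    expect_true(all(tot[spans$end] > 0))
  }
})

test_that("attenuation 1 with no noise leaves the feet statistically identical", {
  sim <- simulate_subject(gait_sim_config(phenotype = "DWF_LR", atten = 1,
                                          weak_side = "left",
                                          noise_mult = 0, noise_add = 0,
                                          jitter_cv = 0, fatigue_min = 0,
                                          fatigue_max = 0, drift_sd = 0,
                                          total_steps = 40L, seed = 3))
  l <- colSums(sim$recording$left); r <- colSums(sim$recording$right)
  expect_equal(l / sum(l), r / sum(r), tolerance = 1e-6)
})

test_that("high-risk attenuation lowers weak-side AP sway in every window", {
  sim <- simulate_subject(gait_sim_config(phenotype = "DWF_HR", atten = 0.5,
                                          weak_side = "left",
                                          noise_mult = 0, noise_add = 0,
                                          total_steps = 60L, seed = 4))
  idx <- segment_steps(sim$recording)
  wins <- cut_windows(sim$recording, idx, plan_windows(n_steps(idx), 10, 10))
  for (w in wins) {
    cop_l <- compute_cop(w$left, w$layout$left, w$eps)
    cop_r <- compute_cop(w$right, w$layout$right, w$eps)
    expect_lt(gaitDDI:::pop_sd(cop_l$points[, "y"]),
              gaitDDI:::pop_sd(cop_r$points[, "y"]))
  }
})

test_that("the episodic state sequence visits both states", {
  sim <- simulate_subject(gait_sim_config(phenotype = "RWF", switch_p = 0.3,
                                          total_steps = 180L, seed = 5))
  expect_setequal(unique(sim$truth$steps$state), c(0L, 1L))
  # DWF phenotypes have constant state
  for (ph in c("DWF_LR", "DWF_HR")) {
    s <- simulate_subject(gait_sim_config(phenotype = ph,
                                          total_steps = 20L, seed = 6))
    expect_length(unique(s$truth$steps$state), 1L)
  }
})

test_that("cohorts have the configured composition and labels", {
  cohort <- simulate_cohort(16, 16, 0, seed = 7, total_steps = 10L)
  expect_length(cohort, 32L)
  labs <- sapply(cohort, function(s) s$recording$label)
  expect_equal(sum(labs == "LR"), 16L)
  expect_equal(sum(labs == "HR"), 16L)
  expect_false(any(sapply(cohort, function(s) s$truth$phenotype) == "RWF"))

  one <- simulate_cohort(0, 0, 1, seed = 8, total_steps = 10L)
  expect_length(one, 1L)
  expect_equal(one[[1]]$truth$phenotype, "RWF")
  expect_equal(one[[1]]$recording$label, "HR")

  # same master seed twice -> identical recordings
  again <- simulate_cohort(16, 16, 0, seed = 7, total_steps = 10L)
  expect_identical(cohort[[5]]$recording$left, again[[5]]$recording$left)
})

test_that("invalid simulator configurations are rejected", {
  expect_error(gait_sim_config(atten = 0), "atten")
  expect_error(gait_sim_config(switch_p = 1.5), "switch_p")
  expect_error(gait_sim_config(total_steps = 2), "total_steps")
})
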