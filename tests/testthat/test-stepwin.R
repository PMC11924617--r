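square_wave_recording <- function(n_bursts = 4, frames_on = 20,
                                  frames_off = 20, amp = 100) {
  lay <- default_insole_layout(n_col = 1, n_row = 2)
  total <- n_bursts * (frames_on + frames_off) + frames_off
  left <- matrix(0, total, 2); right <- matrix(0, total, 2)
  for (k in seq_len(n_bursts)) {
    start <- frames_off + (k - 1) * (frames_on + frames_off) + 1
    rows <- start:(start + frames_on - 1)
    if (k %% 2 == 1) left[rows, ] <- amp else right[rows, ] <- amp
  }
  gait_recording("sq", left, right, 100, lay)
}

test_that("segmentation finds alternating square-wave contacts", {
  rec <- square_wave_recording(4)
  idx <- segment_steps(rec)
  expect_equal(n_steps(idx), 4L)
  expect_equal(idx$events$side, c("left", "right", "left", "right"))
  # idempotent
  expect_identical(segment_steps(rec)$events, idx$events)
})

test_that("all-zero pressure raises an empty-gait error", {
  lay <- default_insole_layout(n_col = 1, n_row = 2)
  rec <- gait_recording("z", matrix(0, 50, 2), matrix(0, 50, 2), 100, lay)
  expect_error(segment_steps(rec, eps = 1), "empty-gait")
})

test_that("segmentation recovers every programmed simulator contact", {
  sim <- simulate_subject(gait_sim_config(phenotype = "DWF_HR",
                                          total_steps = 120L, seed = 11))
  idx <- segment_steps(sim$recording)
  expect_equal(n_steps(idx), 120L)
  expect_equal(sum(idx$events$side == "left"), 60L)
  # detected spans lie within the programmed support spans
  expect_true(all(idx$events$onset >= sim$truth$steps$onset))
  expect_true(all(idx$events$end <= sim$truth$steps$end))
})

test_that("start-up discard removes exactly the first k steps", {
  rec <- square_wave_recording(10)
  idx <- segment_steps(rec)
  out <- discard_startup(idx, 2)
  expect_equal(n_steps(out), 8L)
  expect_equal(out$startup_discarded, 2L)
  expect_equal(out$events, idx$events[-(1:2), ], ignore_attr = TRUE)
  expect_identical(discard_startup(idx, 0)$events, idx$events)
  short <- idx; short$events <- idx$events[1:2, ]
  expect_error(discard_startup(short, 2), "insufficient-data")
})

test_that("window plans follow N = floor((S - L)/s) + 1", {
  expect_equal(plan_windows(180, 130, 10)$N, 6L)
  expect_equal(plan_windows(180, 130, 10)$starts, seq(0L, 50L, 10L))
  expect_equal(plan_windows(55, 55, 7)$N, 1L)
  expect_equal(plan_windows(100, 20, 10)$N, 9L)
  expect_error(plan_windows(100, 130, 10), "insufficient-data")
  expect_error(plan_windows(10, 5, 0), "stride")
})

test_that("window plans agree with brute-force start enumeration", {
  for (S in c(7, 20, 55, 131, 200)) for (L in c(1, 5, S %/% 2, S))
    for (s in c(1, 3, 10)) {
      starts <- seq(0, S - L, by = s)
      plan <- plan_windows(S, L, s)
      expect_equal(plan$N, length(starts))
      expect_equal(plan$starts, as.integer(starts))
    }
})

test_that("cut windows span their steps and overlap by L - s", {
  rec <- square_wave_recording(12)
  idx <- segment_steps(rec)
  plan <- plan_windows(n_steps(idx), 6, 2)
  wins <- cut_windows(rec, idx, plan)
  expect_length(wins, plan$N)
  for (w in wins) {
    expect_equal(w$frames[1], min(w$steps$onset))
    expect_equal(w$frames[2], max(w$steps$end))
    expect_equal(nrow(w$left), w$frames[2] - w$frames[1] + 1L)
  }
  # stride-2 neighbours share exactly L - s = 4 steps
  shared <- intersect(
    paste(wins[[1]]$steps$onset, wins[[1]]$steps$side),
    paste(wins[[2]]$steps$onset, wins[[2]]$steps$side))
  expect_length(shared, 4L)
  expect_error(cut_windows(rec, idx, plan_windows(5, 2, 1)), "inconsistent")
})
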