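# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# small mixed cohort with window features at the DDI lengths
fix_cohort_small <- function() memo("cohort_small", {
  simulate_cohort(3, 3, 2, seed = 101)
})

fix_tab_small <- function() memo("tab_small", {
  cfg <- run_config()
  do.call(rbind, lapply(fix_cohort_small(), function(s)
    suppressWarnings(extract_window_features(s$recording, c(20, 130), cfg))))
})

# LOSO result on the small cohort (expensive; shared across tests)
fix_loso_small <- function() memo("loso_small", {
  suppressWarnings(evaluate_loso(fix_tab_small(), fast_config(), seed = 1))
})

# hand-built two-sensor layout and a window whose weak-foot COP trajectory
# is exactly the two points (0, 0) and (0, 2)
fix_two_point_window <- function() {
  lay <- layout_pair(sensor_layout(rbind(c(0, 0), c(0, 2)), "left"),
                     sensor_layout(rbind(c(0, 0), c(0, 2)), "right"))
  # frame 1 loads sensor 1 only, frame 2 loads sensor 2 only, per foot;
  # feet are loaded in alternating steps
  left <- rbind(c(1, 0), c(0, 1), c(0, 0), c(0, 0))
  right <- rbind(c(0, 0), c(0, 0), c(1, 0), c(0, 1))
  steps <- data.frame(onset = c(1L, 3L), end = c(2L, 4L),
                      side = c("left", "right"), stringsAsFactors = FALSE)
  structure(list(subject_id = "hand", label = "unlabeled", L = 2L,
                 start = 0L, rate = 1, steps = steps, frames = c(1L, 4L),
                 left = left, right = right, layout = lay, eps = 0),
            class = "gait_window")
}

# random valid feature table rows for round-trip tests
random_feature_table <- function(n, seed = 1) {
  set.seed(seed)
  feats <- matrix(stats::rnorm(n * 5), n, 5,
                  dimnames = list(NULL, c("Std_y", "Std_x", "MRD",
                                          "TOTEX", "CCA")))
  cbind(data.frame(subject = sprintf("S%02d", sample(1:5, n, TRUE)),
                   label = sample(c("HR", "LR"), n, TRUE),
                   L = sample(c(20L, 130L), n, TRUE),
                   start = sample(0:10, n, TRUE) * 10L,
                   weak_side = sample(c("left", "right"), n, TRUE),
                   stringsAsFactors = FALSE),
        as.data.frame(feats))
}
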