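brute_force_d <- function(vs) {
  n <- nrow(vs); tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + sqrt(sum((vs[i, ] - vs[j, ])^2))
  tot / (n * (n - 1))
}

test_that("full-connection distance matches hand values", {
  expect_equal(full_connection_distance(rbind(c(1, 2), c(1, 2))), 0)
  expect_equal(full_connection_distance(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(full_connection_distance(rbind(c(0, 0), c(1, 0), c(0, 1))),
               (2 + sqrt(2)) / 3)
  expect_error(full_connection_distance(rbind(c(1, 2))),
               "insufficient-samples")
  expect_error(full_connection_distance(rbind(c(1, NA), c(0, 1))), "finite")
})

test_that("full-connection distance equals the ordered-pair double loop", {
  set.seed(13)
  for (i in 1:100) {
    n <- sample(2:6, 1); d <- sample(1:5, 1)
    vs <- matrix(rnorm(n * d), n, d)
    expect_equal(full_connection_distance(vs), brute_force_d(vs),
                 tolerance = 1e-12)
  }
})

test_that("d_L is permutation-invariant, non-negative, zero iff equal", {
  set.seed(14)
  vs <- matrix(rnorm(12), 4, 3)
  expect_equal(full_connection_distance(vs),
               full_connection_distance(vs[sample(4), ]))
  expect_gt(full_connection_distance(vs), 0)
  expect_equal(full_connection_distance(vs[c(1, 1, 1), ]), 0)
})

test_that("DDI is the low/high dispersion ratio and scale-invariant", {
  set.seed(15)
  v_low <- matrix(rnorm(20), 10, 2)
  v_high <- matrix(rnorm(8), 4, 2)
  rec <- compute_ddi(v_low, v_high, "s1")
  expect_equal(rec$DDI, rec$d_l / rec$d_h)
  expect_equal(compute_ddi(v_low * 2.4, v_high * 1.2, "x")$DDI,
               2 * rec$DDI, tolerance = 1e-12)
  for (c_scale in c(0.013, 7, 1e4)) {
    scaled <- compute_ddi(v_low * c_scale, v_high * c_scale, "s1")
    expect_equal(scaled$DDI, rec$DDI, tolerance = 1e-12)
  }
  expect_error(compute_ddi(v_low, v_high[c(1, 1), ]), "degenerate-gait")
  expect_error(compute_ddi(v_low[1, , drop = FALSE], v_high),
               "insufficient-samples")
})

test_that("the adaptive threshold interpolates the training DDI range", {
  m <- fit_threshold(c(1, 3), alpha = 0.3)
  expect_equal(m$T, 1.6)
  expect_equal(fit_threshold(c(1, 3), alpha = 0)$T, 1)
  expect_equal(fit_threshold(c(1, 3), alpha = 1)$T, 3)
  expect_error(fit_threshold(c(1, 3), alpha = 1.2), "alpha")
  expect_error(fit_threshold(2, alpha = 0.5), "insufficient-samples")
  expect_warning(fit_threshold(c(2, 2, 2), alpha = 0.5), "degenerate-cohort")

  # robust bounds clip mu +/- 3 sigma to the observed range
  x <- c(seq(1, 2, length.out = 20), 10)
  r <- fit_threshold(x, 0.5, robust = TRUE)
  expect_lt(r$ddi_max, 10)
  expect_equal(r$ddi_max, mean(x) + 3 * sd(x))
  expect_gte(r$ddi_min, min(x))
})

test_that("RWF calls use a strict threshold with boundary conventions", {
  m <- fit_threshold(c(1, 2, 3, 4), alpha = 0.5)   # T = 2.5
  expect_equal(classify_type(2.5, m), "DWF")       # DDI == T -> DWF
  expect_equal(classify_type(2.5 + 1e-12, m), "RWF")
  # alpha = 1: threshold at the maximum, nobody strictly above
  m1 <- fit_threshold(c(1, 2, 3, 4), alpha = 1)
  expect_true(all(classify_type(c(1, 2, 3, 4), m1) == "DWF"))
  # alpha = 0: everyone except the minimum subject is flagged
  m0 <- fit_threshold(c(1, 2, 3, 4), alpha = 0)
  expect_equal(classify_type(c(1, 2, 3, 4), m0),
               c("DWF", "RWF", "RWF", "RWF"))
})

test_that("the flagged count never increases with alpha", {
  set.seed(16)
  for (i in 1:50) {
    ddis <- rlnorm(sample(5:40, 1), meanlog = 1, sdlog = 0.5)
    for (robust in c(FALSE, TRUE)) {
      counts <- sapply(seq(0, 1, by = 0.02), function(a)
        sum(classify_type(ddis, fit_threshold(ddis, a, robust)) == "RWF"))
      expect_true(all(diff(counts) <= 0))
    }
  }
})

test_that("cohort DDI uses per-length scalers and falls back when short", {
  tab <- fix_tab_small()
  cfg <- run_config()
  ddi <- cohort_ddi(tab, cfg)
  expect_equal(nrow(ddi), length(unique(tab$subject)))
  expect_true(all(ddi$d_l >= 0) && all(ddi$d_h > 0))
  expect_true(all(ddi$n_low >= 2) && all(ddi$n_high >= 2))

  # recomputing a single subject with the cohort scalers reproduces the row
  sc <- fit_ddi_scalers(tab, cfg)
  sid <- ddi$subject[1]
  again <- cohort_ddi(tab[tab$subject == sid, ], cfg, sc)
  expect_equal(again$DDI, ddi$DDI[1])

  # a subject too short for the trained high length falls back to their
  # longest usable length, with a warning
  short <- random_feature_table(8, seed = 3)
  short$subject <- "S1"
  short$L <- rep(c(20L, 70L), each = 4)
  sc_short <- structure(list(low = identity_scaler(cfg$weak_features),
                             high = identity_scaler(cfg$weak_features),
                             d_l_length = 20L, d_h_length = 130L),
                        class = "ddi_scalers")
  expect_warning(out <- cohort_ddi(short, cfg, sc_short), "falling back")
  expect_equal(out$n_high, 4)
})
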