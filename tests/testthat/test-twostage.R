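test_that("metrics follow the closed forms", {
  r <- metrics(21, 20, 4, 3)
  expect_equal(r$accuracy, 41 / 48)
  expect_equal(r$sensitivity, 21 / 24)
  expect_equal(r$f1, 42 / (42 + 4 + 3))
  expect_warning(r0 <- metrics(0, 10, 0, 0), "F1 undefined")
  expect_equal(r0$accuracy, 1); expect_equal(r0$f1, 0)
  r5 <- metrics(5, 5, 5, 5)
  expect_equal(r5$accuracy, 0.5); expect_equal(r5$f1, 0.5)
  expect_equal(metrics(1, 0, 0, 0)$f1, 1)
  expect_error(metrics(0, 0, 0, 0), "undefined-metrics")
  expect_error(metrics(-1, 0, 0, 1), "non-negative")
})

test_that("metrics agree with a confusion-matrix oracle on random counts", {
  set.seed(17)
  for (i in 1:1000) {
    cts <- sample(0:50, 4, replace = TRUE)
    if (sum(cts) == 0) cts[1] <- 1
    r <- suppressWarnings(metrics(cts[1], cts[2], cts[3], cts[4]))
    expect_equal(r$accuracy, (cts[1] + cts[2]) / sum(cts))
    if (2 * cts[1] + cts[3] + cts[4] > 0)
      expect_equal(r$f1, 2 * cts[1] / (2 * cts[1] + cts[3] + cts[4]))
  }
})

test_that("branch tuning finds a perfect model on separable data", {
  set.seed(18)
  groups <- rep(sprintf("S%d", 1:8), each = 5)
  y <- factor(rep(rep(c("LR", "HR"), 4), each = 5), levels = c("LR", "HR"))
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  x[, "a"] <- ifelse(y == "HR", 4, -4) + rnorm(40, 0, 0.2)
  tuned <- tune_branch(x, y, groups, fast_config(), seed = 1)
  expect_equal(tuned$cv_accuracy, 1)
  expect_true(tuned$name %in% fast_config()$roster)
  expect_length(tuned$params, 2L)
})

test_that("permuted labels give chance-level CV for every candidate", {
  set.seed(19)
  groups <- rep(sprintf("S%02d", 1:20), each = 10)
  x <- matrix(rnorm(200 * 2), 200, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(sample(rep(c("LR", "HR"), each = 100)), levels = c("LR", "HR"))
  tuned <- tune_branch(x, y, groups, run_config(), seed = 4)
  expect_true(all(tuned$scores >= 0.35 & tuned$scores <= 0.65))
})

test_that("under-populated or single-class branches signal fallback", {
  set.seed(20)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  groups2 <- rep(c("S1", "S2"), each = 10)
  y2 <- factor(rep(c("LR", "HR"), each = 10), levels = c("LR", "HR"))
  expect_null(tune_branch(x, y2, groups2, run_config(), seed = 1))
  groups4 <- rep(sprintf("S%d", 1:4), each = 5)
  y_one <- factor(rep("HR", 20), levels = c("LR", "HR"))
  expect_null(tune_branch(x, y_one, groups4, run_config(), seed = 1))
  # one lone subject in a class cannot support grouped stratified CV
  y_lone <- factor(rep(c("HR", "HR", "HR", "LR"), each = 5),
                   levels = c("LR", "HR"))
  expect_null(tune_branch(x, y_lone, groups4, run_config(), seed = 1))
})

test_that("the two-stage fit scans the alpha grid and predicts new subjects", {
  tab <- fix_tab_small()
  cfg <- fast_config()
  model <- suppressWarnings(fit_two_stage(tab, cfg, seed = 1))
  expect_s3_class(model, "two_stage_model")
  expect_equal(nrow(model$trace$alpha), length(alpha_grid(cfg)))
  expect_true(model$alpha %in% alpha_grid(cfg))
  expect_true(all(c("RWF", "DWF") %in% names(model$branches)))
  # chosen alpha attains the maximum recorded training accuracy
  expect_equal(max(model$trace$alpha$accuracy),
               model$trace$alpha$accuracy[model$trace$alpha$alpha ==
                                            model$alpha])
  preds <- suppressWarnings(predict(model, tab))
  expect_setequal(preds$subject, unique(tab$subject))
  expect_true(all(preds$call %in% c("HR", "LR")))
  expect_true(all(preds$type %in% c("RWF", "DWF")))
})

test_that("a cohort with no flagged subjects reduces to the pooled model", {
  tab <- fix_tab_small()
  cfg <- fast_config(alpha_min = 1, alpha_max = 1, alpha_step = 1)
  model <- suppressWarnings(fit_two_stage(tab, cfg, seed = 1))
  expect_true(model$branches$RWF$pooled)   # empty RWF branch -> fallback
})

test_that("leave-one-subject-out never trains on the held-out subject", {
  tab <- fix_tab_small()
  res <- fix_loso_small()
  subjects <- unique(tab$subject)
  expect_setequal(names(res$folds), subjects)
  for (sid in subjects) {
    expect_false(sid %in% res$folds[[sid]]$training)
    expect_setequal(res$folds[[sid]]$training, setdiff(subjects, sid))
  }
  expect_equal(nrow(res$predictions), length(subjects))
  expect_equal(res$report$tp + res$report$tn + res$report$fp + res$report$fn,
               length(subjects))
})
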