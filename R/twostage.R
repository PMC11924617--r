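#' Confusion-count evaluation metrics
#'
#' Closed-form metrics with the high-risk class as positive:
#' `accuracy = (TP + TN)/(TP + TN + FP + FN)`,
#' `F1 = 2TP/(2TP + FP + FN)`, sensitivity `TP/(TP + FN)`, specificity
#' `TN/(TN + FP)`. An undefined F1 (no positives anywhere) is reported as
#' 0 with a warning; undefined sensitivity/specificity are `NA`.
#'
#' @param tp,tn,fp,fn non-negative confusion counts.
#' @return A list of class `eval_report`: the four counts plus `accuracy`,
#'   `f1`, `sensitivity`, `specificity`.
#' @examples
#' metrics(21, 20, 4, 3)$accuracy  # 41/48
#' @export
metrics <- function(tp, tn, fp, fn) {
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) stop("undefined-metrics error: all counts are zero")
  f1 <- if (2 * tp + fp + fn == 0) {
    warning("F1 undefined (no positive calls or cases); reporting 0")
    0
  } else 2 * tp / (2 * tp + fp + fn)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 accuracy = (tp + tn) / tot, f1 = f1,
                 sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> TP=%d TN=%d FP=%d FN=%d | acc=%.3f ",
                     "F1=%.3f sens=%s spec=%s\n"),
              x$tp, x$tn, x$fp, x$fn, x$accuracy, x$f1,
              formatC(x$sensitivity, digits = 3, format = "f"),
              formatC(x$specificity, digits = 3, format = "f")))
  invisible(x)
}

#' Select and tune a branch classifier
#'
#' Grid-searches the two documented hyperparameters of every roster
#' candidate by subject-grouped, label-stratified cross-validation on the
#' branch's training windows, and returns the winning (classifier,
#' parameters) pair. A branch whose training side holds a single class (or
#' too few subjects) cannot be tuned: `NULL` is returned as the
#' fall-back-to-pooled signal.
#'
#' @param x numeric window-by-feature matrix of the branch's training data.
#' @param y two-level label factor per window.
#' @param groups subject id per window.
#' @param cfg a [run_config()] (uses `roster`, `cv_folds`, `branch_min`).
#' @param grids hyperparameter grids from [default_grids()].
#' @param seed integer seed.
#' @return list `(name, params, cv_accuracy, scores)` or `NULL` (fallback
#'   signal); `scores` records every candidate's best CV accuracy.
#' @export
tune_branch <- function(x, y, groups, cfg = run_config(),
                        grids = NULL, seed = 1L) {
  if (is.null(grids)) grids <- default_grids(cfg$fast_grids)
  y <- droplevels(as.factor(y))
  if (length(unique(groups)) < cfg$branch_min || nlevels(y) < 2L)
    return(NULL)
  # subject-grouped stratified CV needs at least 2 subjects per class
  subj_class <- table(y[!duplicated(groups)])
  if (min(subj_class) < 2L) return(NULL)
  best <- list(acc = -Inf)
  scores <- stats::setNames(numeric(length(cfg$roster)), cfg$roster)
  for (nm in cfg$roster) {
    grid <- grids[[nm]]
    for (g in seq_len(nrow(grid))) {
      params <- as.list(grid[g, , drop = FALSE])
      a <- cv_accuracy(nm, params, x, y, groups, cfg$cv_folds, seed)
      if (is.na(a)) next
      if (a > scores[nm]) scores[nm] <- a
      if (a > best$acc)
        best <- list(acc = a, name = nm, params = params)
    }
  }
  if (!is.finite(best$acc)) return(NULL)
  list(name = best$name, params = best$params, cv_accuracy = best$acc,
       scores = scores)
}

subject_labels <- function(tab) {
  subj <- unique(tab$subject)
  stats::setNames(tab$label[match(subj, tab$subject)], subj)
}

#' Fit the two-stage fall-risk model
#'
#' Step 1 scans the alpha grid: each alpha fits the adaptive DDI threshold
#' on the training cohort, partitions subjects into RWF/DWF, runs
#' three-phase feature selection per branch, and scores the partition by
#' the subject-weighted, subject-level (majority-vote) CV accuracy of the
#' fixed default-setting surrogate classifier; the best (alpha, feature
#' sets) is kept, ties resolved toward the largest alpha (the more
#' conservative partition: do not flag subjects without evidence). Step 2
#' tunes each
#' branch's classifier and hyperparameters via [tune_branch()] and refits
#' it on the branch's full training windows. A branch with fewer than
#' `cfg$branch_min` subjects (or one class) falls back to the pooled
#' one-stage model.
#'
#' @param tab training feature table containing windows at
#'   `cfg$d_l_length`, `cfg$d_h_length` and `cfg$operating_length`.
#' @param cfg a [run_config()].
#' @param seed integer seed; every stochastic component derives from it.
#' @param grids hyperparameter grids (see [default_grids()]).
#' @param random_ddi if `TRUE` the DDI reference is replaced by uniform
#'   random numbers (ablation of the reference value).
#' @return A `two_stage_model`: threshold model, DDI scaler, per-branch
#'   `(features, name, params, fit)`, pooled fallback model, `cfg`, and a
#'   selection `trace` (per-alpha accuracies and RWF counts, chosen alpha,
#'   per-branch tuning scores).
#' @export
fit_two_stage <- function(tab, cfg = run_config(), seed = 1L,
                          grids = NULL, random_ddi = FALSE) {
  if (is.null(grids)) grids <- default_grids(cfg$fast_grids)
  labs <- subject_labels(tab)
  if (length(unique(labs)) < 2L || min(table(labs)) < 2L)
    stop("need >= 2 training subjects per class")
  ddi_scaler <- fit_ddi_scalers(tab, cfg)
  ddi <- cohort_ddi(tab, cfg, ddi_scaler)
  if (random_ddi) {
    set.seed(seed)
    ddi$DDI <- stats::runif(nrow(ddi))
  }

  op <- tab[tab$L == cfg$operating_length, , drop = FALSE]
  feats_all <- intersect(cfg$registry, colnames(op))
  X <- as.matrix(op[, feats_all, drop = FALSE])
  y <- factor(op$label, levels = c("LR", "HR"))
  groups <- op$subject

  # pooled (one-stage) selection, reused by fallbacks
  pooled_sel <- select_features(X, y, groups, cfg, seed)
  pooled_acc <- cv_accuracy(cfg$surrogate, NULL,
                            X[, pooled_sel$features, drop = FALSE],
                            y, groups, cfg$cv_folds, seed,
                            by_subject = TRUE)
  if (is.na(pooled_acc)) pooled_acc <- 0

  sel_cache <- list()
  branch_select <- function(rows) {
    key <- paste(sort(unique(groups[rows])), collapse = "|")
    if (!is.null(sel_cache[[key]])) return(sel_cache[[key]])
    res <- if (length(unique(groups[rows])) < cfg$branch_min ||
               length(unique(y[rows])) < 2L ||
               min(table(y[rows][!duplicated(groups[rows])])) < 2L) {
      list(pooled = TRUE, features = pooled_sel$features, acc = pooled_acc)
    } else {
      s <- select_features(X[rows, , drop = FALSE], y[rows], groups[rows],
                           cfg, seed)
      a <- cv_accuracy(cfg$surrogate, NULL,
                       X[rows, s$features, drop = FALSE], y[rows],
                       groups[rows], cfg$cv_folds, seed,
                       by_subject = TRUE)
      list(pooled = FALSE, features = s$features,
           acc = if (is.na(a)) 0 else a)
    }
    sel_cache[[key]] <<- res
    res
  }

  grid <- alpha_grid(cfg)
  trace_alpha <- data.frame(alpha = grid, accuracy = NA_real_,
                            n_rwf = NA_integer_)
  best <- list(acc = -Inf)
  # scan from the largest alpha down: on equal training accuracy the more
  # conservative partition (fewer flagged subjects) wins
  for (i in rev(seq_along(grid))) {
    thr <- fit_threshold(ddi, grid[i], cfg$robust_bounds)
    type <- stats::setNames(classify_type(ddi, thr), ddi$subject)
    wtype <- type[groups]
    parts <- lapply(c(RWF = "RWF", DWF = "DWF"),
                    function(tp) which(wtype == tp))
    accs <- ns <- numeric(0)
    sels <- list()
    for (tp in names(parts)) {
      rows <- parts[[tp]]
      if (!length(rows)) next
      sels[[tp]] <- branch_select(rows)
      accs <- c(accs, sels[[tp]]$acc)
      ns <- c(ns, length(unique(groups[rows])))
    }
    overall <- sum(accs * ns) / sum(ns)
    trace_alpha$accuracy[i] <- overall
    trace_alpha$n_rwf[i] <- sum(type == "RWF")
    if (overall > best$acc + 1e-12)   # strict: ties keep the largest alpha
      best <- list(acc = overall, alpha = grid[i], thr = thr, type = type,
                   sels = sels, parts = parts)
  }

  # step 2: per-branch classifier selection + final refit
  pooled_tuned <- tune_branch(X[, pooled_sel$features, drop = FALSE], y,
                              groups, cfg, grids, seed)
  if (is.null(pooled_tuned))
    stop("degenerate training set: pooled model cannot be tuned")
  pooled_fit <- fit_classifier(pooled_tuned$name, X[, pooled_sel$features,
                                                    drop = FALSE],
                               y, pooled_tuned$params, seed)
  pooled_model <- list(features = pooled_sel$features,
                       name = pooled_tuned$name,
                       params = pooled_tuned$params, fit = pooled_fit,
                       pooled = TRUE)

  branches <- list()
  for (tp in c("RWF", "DWF")) {
    rows <- best$parts[[tp]]
    sel <- best$sels[[tp]]
    if (is.null(sel) || sel$pooled ||
        length(unique(groups[rows])) < cfg$branch_min ||
        length(unique(y[rows])) < 2L) {
      branches[[tp]] <- pooled_model
      next
    }
    tuned <- tune_branch(X[rows, sel$features, drop = FALSE], y[rows],
                         groups[rows], cfg, grids, seed)
    if (is.null(tuned)) { branches[[tp]] <- pooled_model; next }
    fit <- fit_classifier(tuned$name, X[rows, sel$features, drop = FALSE],
                          y[rows], tuned$params, seed)
    branches[[tp]] <- list(features = sel$features, name = tuned$name,
                           params = tuned$params, fit = fit, pooled = FALSE,
                           tuning = tuned$scores)
  }

  structure(list(threshold = best$thr, alpha = best$alpha,
                 ddi_scaler = ddi_scaler, branches = branches,
                 pooled = pooled_model, cfg = cfg, random_ddi = random_ddi,
                 seed = seed,
                 training_subjects = sort(unique(tab$subject)),
                 trace = list(alpha = trace_alpha, chosen_alpha = best$alpha,
                              types = best$type,
                              pooled_features = pooled_sel$features)),
            class = "two_stage_model")
}

#' @export
print.two_stage_model <- function(x, ...) {
  cat(sprintf("<two_stage_model> alpha=%.2f (T=%.3f), %d training subjects\n",
              x$alpha, x$threshold$T, length(x$training_subjects)))
  for (tp in names(x$branches)) {
    b <- x$branches[[tp]]
    cat(sprintf("  %s: %s [%s]%s\n", tp, b$name,
                paste(b$features, collapse = ", "),
                if (b$pooled) " (pooled fallback)" else ""))
  }
  invisible(x)
}

#' Predict held-out subjects with a two-stage model
#'
#' Computes each subject's DDI from their own (unlabeled) windows using
#' the training-fitted scaler, routes the subject to the RWF or DWF
#' branch by the trained threshold, predicts every window at the operating
#' length, and aggregates to a subject call by majority vote (ties go to
#' HR - screening favors sensitivity).
#'
#' @param object a fitted `two_stage_model`.
#' @param tab feature table of the new subject(s), with windows at the
#'   model's DDI and operating lengths.
#' @param ... unused.
#' @return data.frame per subject: `subject`, `DDI`, `type`, `call`,
#'   `n_windows`, `prop_hr` (fraction of HR window votes).
#' @export
predict.two_stage_model <- function(object, tab, ...) {
  cfg <- object$cfg
  ddi <- cohort_ddi(tab, cfg, object$ddi_scaler)
  if (object$random_ddi) {
    set.seed(object$seed + 1L)
    ddi$DDI <- stats::runif(nrow(ddi))
  }
  type <- classify_type(ddi, object$threshold)
  op <- tab[tab$L == cfg$operating_length, , drop = FALSE]
  out <- lapply(seq_len(nrow(ddi)), function(i) {
    sid <- ddi$subject[i]
    branch <- object$branches[[type[i]]]
    rows <- op[op$subject == sid, , drop = FALSE]
    if (!nrow(rows))
      stop("no windows at the operating length for subject ", sid)
    preds <- predict(branch$fit,
                     as.matrix(rows[, branch$features, drop = FALSE]))
    data.frame(subject = sid, DDI = ddi$DDI[i], type = type[i],
               call = majority_vote(as.character(preds)),
               n_windows = nrow(rows),
               prop_hr = mean(preds == "HR"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Leave-one-subject-out evaluation
#'
#' For each held-out subject the full pipeline - DDI scaler, threshold,
#' feature selection, classifier tuning - is refit on the remaining
#' subjects only, then the held-out subject is predicted. Subject calls
#' are scored against the fall-risk labels with HR as positive.
#'
#' @param tab cohort feature table (all subjects, all needed lengths).
#' @param cfg a [run_config()].
#' @param seed integer seed shared by every fold.
#' @param method `"two_stage"` (default), `"one_stage"` (pooled model, no
#'   routing) or `"random_ddi"` (two-stage with a random reference value,
#'   the ablation control).
#' @param grids hyperparameter grids.
#' @return list of class `loso_result`: `report` (an [metrics()]
#'   `eval_report`), `predictions` (per-subject data.frame incl. truth),
#'   `folds` (per-fold fingerprint: held-out id and sorted training ids).
#' @export
evaluate_loso <- function(tab, cfg = run_config(), seed = 1L,
                          method = c("two_stage", "one_stage", "random_ddi"),
                          grids = NULL) {
  method <- match.arg(method)
  if (is.null(grids)) grids <- default_grids(cfg$fast_grids)
  labs <- subject_labels(tab)
  subjects <- names(labs)
  if (length(subjects) < 3L || length(unique(labs)) < 2L)
    stop("need >= 3 subjects and both classes")
  preds <- list(); folds <- list()
  for (sid in subjects) {
    train <- tab[tab$subject != sid, , drop = FALSE]
    test <- tab[tab$subject == sid, , drop = FALSE]
    p <- if (method == "one_stage") {
      model <- fit_one_stage(train, cfg, seed, grids)
      predict_one_stage(model, test)
    } else {
      model <- fit_two_stage(train, cfg, seed, grids,
                             random_ddi = method == "random_ddi")
      predict(model, test)
    }
    p$truth <- unname(labs[sid])
    preds[[sid]] <- p
    folds[[sid]] <- list(held_out = sid,
                         training = sort(unique(train$subject)))
  }
  preds <- do.call(rbind, preds)
  rep <- metrics(tp = sum(preds$call == "HR" & preds$truth == "HR"),
                 tn = sum(preds$call == "LR" & preds$truth == "LR"),
                 fp = sum(preds$call == "HR" & preds$truth == "LR"),
                 fn = sum(preds$call == "LR" & preds$truth == "HR"))
  structure(list(report = rep, predictions = preds, folds = folds,
                 method = method), class = "loso_result")
}

#' @export
print.loso_result <- function(x, ...) {
  cat(sprintf("<loso_result> %s, %d subjects\n", x$method,
              nrow(x$predictions)))
  print(x$report)
  invisible(x)
}

#' Pooled one-stage baseline model
#'
#' Feature selection and classifier tuning on all training subjects with
#' no RWF/DWF routing; the comparison baseline for the two-stage model.
#'
#' @inheritParams fit_two_stage
#' @return list of class `one_stage_model`.
#' @export
fit_one_stage <- function(tab, cfg = run_config(), seed = 1L,
                          grids = NULL) {
  if (is.null(grids)) grids <- default_grids(cfg$fast_grids)
  op <- tab[tab$L == cfg$operating_length, , drop = FALSE]
  feats_all <- intersect(cfg$registry, colnames(op))
  X <- as.matrix(op[, feats_all, drop = FALSE])
  y <- factor(op$label, levels = c("LR", "HR"))
  groups <- op$subject
  sel <- select_features(X, y, groups, cfg, seed)
  tuned <- tune_branch(X[, sel$features, drop = FALSE], y, groups, cfg,
                       grids, seed)
  if (is.null(tuned)) stop("degenerate training set")
  fit <- fit_classifier(tuned$name, X[, sel$features, drop = FALSE], y,
                        tuned$params, seed)
  structure(list(features = sel$features, name = tuned$name,
                 params = tuned$params, fit = fit, cfg = cfg),
            class = "one_stage_model")
}

#' @rdname fit_one_stage
#' @param model a fitted `one_stage_model`.
#' @param tab feature table of new subjects.
#' @export
predict_one_stage <- function(model, tab) {
  op <- tab[tab$L == model$cfg$operating_length, , drop = FALSE]
  out <- lapply(unique(op$subject), function(sid) {
    rows <- op[op$subject == sid, , drop = FALSE]
    preds <- predict(model$fit,
                     as.matrix(rows[, model$features, drop = FALSE]))
    data.frame(subject = sid, DDI = NA_real_, type = NA_character_,
               call = majority_vote(as.character(preds)),
               n_windows = nrow(rows), prop_hr = mean(preds == "HR"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
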