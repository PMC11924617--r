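#' Pilot window-length sweep
#'
#' Repeats leave-one-subject-out feature selection and a fixed
#' default-setting classifier fit across a range of window lengths,
#' recording per-length LOSO accuracy and how often each feature is
#' selected. With 48 subjects and the 17 lengths 20-180 this is the
#' 816-run pilot design; the function runs at whatever scale the supplied
#' table supports.
#'
#' @param tab cohort feature table holding windows at every length in
#'   `lengths` (see [extract_window_features()]).
#' @param lengths window lengths (steps) to sweep.
#' @param cfg a [run_config()]; the `surrogate` classifier with default
#'   hyperparameters scores each fold.
#' @param seed integer seed.
#' @return list of class `length_sweep`: `accuracy` (data.frame `L`,
#'   `n_subjects`, `accuracy`), `selection_counts` (feature x length count
#'   matrix), `n_runs` (total feature-selection runs).
#' @export
length_sweep <- function(tab, lengths, cfg = run_config(), seed = 1L) {
  feats_all <- intersect(cfg$registry, colnames(tab))
  counts <- matrix(0L, length(feats_all), length(lengths),
                   dimnames = list(feats_all, as.character(lengths)))
  acc <- data.frame(L = lengths, n_subjects = NA_integer_,
                    accuracy = NA_real_)
  n_runs <- 0L
  for (li in seq_along(lengths)) {
    L <- lengths[li]
    opt <- tab[tab$L == L, , drop = FALSE]
    subjects <- unique(opt$subject)
    if (length(subjects) < 3L) {
      warning("length ", L, ": fewer than 3 subjects with windows, skipped")
      next
    }
    labs <- subject_labels(opt)
    calls <- character(0); truth <- character(0)
    for (sid in subjects) {
      tr <- opt[opt$subject != sid, , drop = FALSE]
      te <- opt[opt$subject == sid, , drop = FALSE]
      if (length(unique(tr$label)) < 2L) next
      X <- as.matrix(tr[, feats_all, drop = FALSE])
      y <- factor(tr$label, levels = c("LR", "HR"))
      sel <- select_features(X, y, tr$subject, cfg, seed)
      n_runs <- n_runs + 1L
      counts[sel$features, li] <- counts[sel$features, li] + 1L
      fit <- fit_classifier(cfg$surrogate,
                            X[, sel$features, drop = FALSE], y, NULL, seed)
      preds <- predict(fit, as.matrix(te[, sel$features, drop = FALSE]))
      calls <- c(calls, majority_vote(as.character(preds)))
      truth <- c(truth, unname(labs[sid]))
    }
    acc$n_subjects[li] <- length(calls)
    acc$accuracy[li] <- mean(calls == truth)
  }
  structure(list(accuracy = acc, selection_counts = counts,
                 n_runs = n_runs), class = "length_sweep")
}

#' Count the runs a full pilot sweep performs
#'
#' The sweep performs one feature-selection run per (LOSO fold, length)
#' pair: `n_subjects * n_lengths`.
#'
#' @param n_subjects cohort size.
#' @param lengths vector of window lengths (or their count).
#' @return integer run count.
#' @examples
#' sweep_run_count(48, seq(20, 180, by = 10))  # 816
#' @export
sweep_run_count <- function(n_subjects, lengths) {
  n_len <- if (length(lengths) == 1L) as.integer(lengths) else length(lengths)
  as.integer(n_subjects) * n_len
}
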