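# Subject-grouped, label-stratified fold assignment.
# All windows of one subject land in the same fold (windows at stride
# overlap heavily, so splitting a subject across folds would leak), and
# subjects are dealt to folds per label so each fold sees both classes
# when counts allow.
grouped_folds <- function(groups, labels, k, seed = 1L) {
  subj <- unique(groups)
  subj_lab <- labels[match(subj, groups)]
  set.seed(seed)
  fold_of <- stats::setNames(integer(length(subj)), subj)
  for (lab in unique(subj_lab)) {
    s <- sample(subj[subj_lab == lab])
    fold_of[s] <- rep_len(seq_len(k), length(s))
  }
  unname(fold_of[as.character(groups)])
}

# CV accuracy of one classifier setting under grouped folds: window-level
# by default, or subject-level (majority vote per held-out subject) when
# by_subject = TRUE. Folds whose training side is single-class are
# skipped; NA if none valid.
cv_accuracy <- function(name, params, x, y, groups, k = 5L, seed = 1L,
                        by_subject = FALSE) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  k <- min(k, length(unique(groups)))
  if (k < 2L) return(NA_real_)
  folds <- grouped_folds(groups, as.character(y), k, seed)
  hits <- tot <- 0L
  for (f in seq_len(k)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L || !any(!tr)) next
    fit <- fit_classifier(name, x[tr, , drop = FALSE], y[tr],
                          params = params, seed = seed + f)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    if (by_subject) {
      te_groups <- groups[!tr]; te_y <- y[!tr]
      for (sid in unique(te_groups)) {
        call <- majority_vote(as.character(pred[te_groups == sid]))
        hits <- hits + (call == as.character(te_y[te_groups == sid][1]))
        tot <- tot + 1L
      }
    } else {
      hits <- hits + sum(pred == y[!tr])
      tot <- tot + sum(!tr)
    }
  }
  if (tot == 0L) return(NA_real_)
  hits / tot
}

# majority vote over a character vector; tie -> "HR" (screening favors
# sensitivity)
majority_vote <- function(calls, positive = "HR") {
  tab <- table(calls)
  top <- names(tab)[tab == max(tab)]
  if (positive %in% top) positive else top[1]
}
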