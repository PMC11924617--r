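#' Three-phase feature selection
#'
#' Selects a feature subset from window-level training data in three
#' phases. Phase 1 pre-selects features whose class means differ by a
#' two-sample t-test at p < 0.05 (if none survive, the top
#' `cfg$selector_subset` by p-value are kept with a warning). Phase 2 runs
#' eleven selectors - five filters (ANOVA-F, mutual information,
#' point-biserial correlation, variance rank, Relief-style margin), four
#' wrappers (forward and backward sequential search around logistic
#' regression and a decision stump, scored by subject-grouped CV) and two
#' embedded methods (L1-penalized logistic regression, tree-ensemble
#' impurity importance) - each nominating a fixed-size subset. Phase 3
#' ranks features by nomination frequency and picks the cardinality that
#' maximizes subject-grouped cross-validated accuracy of the surrogate
#' classifier.
#'
#' @param x numeric matrix of training windows (rows) by features
#'   (columns, named).
#' @param y two-level label factor per window.
#' @param groups subject id per window; selection never splits a subject
#'   across CV folds.
#' @param cfg a [run_config()] (uses `selector_subset`, `max_phase3`,
#'   `cv_folds`, `surrogate`).
#' @param seed integer seed.
#' @return list with `features` (selected names), `trace` (list:
#'   `phase1` surviving names, `p_values`, `nominations` named count
#'   vector, `phase3` data.frame of cardinality vs CV accuracy).
#' @export
select_features <- function(x, y, groups, cfg = run_config(), seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2L) stop("need 2 classes in training labels")
  keep <- !apply(x, 2, anyNA)
  if (!all(keep)) {
    warning("dropping feature(s) with missing values: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  m <- min(cfg$selector_subset, ncol(x))

  # phase 1: t-test pre-selection
  pv <- apply(x, 2, function(col) {
    if (pop_sd(col) == 0) return(1)
    stats::t.test(col[y == levels(y)[1]], col[y == levels(y)[2]])$p.value
  })
  surv <- names(pv)[pv < 0.05]
  if (length(surv) < 2L) {
    warning("phase 1 relaxation: keeping top ", m, " features by p-value")
    surv <- names(sort(pv))[seq_len(min(m, length(pv)))]
  }
  if (length(surv) > cfg$max_phase1)
    surv <- intersect(names(sort(pv)), surv)[seq_len(cfg$max_phase1)]
  xs <- x[, surv, drop = FALSE]
  m <- min(m, ncol(xs))

  # phase 2: eleven selectors, each nominating m features
  noms <- list(
    anova_f = filter_rank(abs(apply(xs, 2, function(col)
      stats::t.test(col[y == levels(y)[1]], col[y == levels(y)[2]])$statistic)), m),
    mutual_info = filter_rank(apply(xs, 2, mutual_info_score, y = y), m),
    pb_cor = filter_rank(abs(apply(xs, 2, function(col)
      stats::cor(col, as.numeric(y)))), m),
    variance = filter_rank(apply(xs, 2, stats::var), m),
    relief = filter_rank(relief_score(xs, y, seed), m),
    fwd_lr = wrapper_select(xs, y, groups, "lr", m, "forward", seed),
    bwd_lr = wrapper_select(xs, y, groups, "lr", m, "backward", seed),
    fwd_stump = wrapper_select(xs, y, groups, "stump", m, "forward", seed),
    bwd_stump = wrapper_select(xs, y, groups, "stump", m, "backward", seed),
    l1 = l1_select(xs, y, m),
    tree_imp = {
      set.seed(seed)
      imp <- ranger::ranger(x = xs, y = y, num.trees = 200,
                            importance = "impurity", seed = seed,
                            num.threads = 1)$variable.importance
      filter_rank(imp, m)
    })
  counts <- sort(table(unlist(noms)), decreasing = TRUE)
  nominated <- names(counts)

  # unanimous nomination needs no arbitration
  if (all(vapply(noms, function(s) setequal(s, noms[[1]]), logical(1)))) {
    return(list(features = sort(noms[[1]]),
                trace = list(phase1 = surv, p_values = pv,
                             nominations = counts, phase3 = NULL)))
  }

  # phase 3: cardinality by surrogate CV accuracy (ties -> fewer features)
  kmax <- min(cfg$max_phase3, length(nominated))
  acc <- vapply(seq_len(kmax), function(k) {
    cv_accuracy(cfg$surrogate, NULL, xs[, nominated[seq_len(k)], drop = FALSE],
                y, groups, cfg$cv_folds, seed)
  }, numeric(1))
  acc[is.na(acc)] <- 0
  best_k <- which.max(acc)
  list(features = nominated[seq_len(best_k)],
       trace = list(phase1 = surv, p_values = pv,
                    nominations = counts,
                    phase3 = data.frame(k = seq_len(kmax), cv_accuracy = acc)))
}

filter_rank <- function(score, m) {
  score[!is.finite(score)] <- -Inf
  names(sort(score, decreasing = TRUE))[seq_len(min(m, length(score)))]
}

# mutual information between a feature (quantile-binned) and the label
mutual_info_score <- function(col, y, bins = 5L) {
  br <- unique(stats::quantile(col, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2L) return(0)
  b <- cut(col, breaks = br, include.lowest = TRUE)
  joint <- table(b, y) / length(col)
  px <- rowSums(joint); py <- colSums(joint)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (joint[i, j] > 0)
      mi <- mi + joint[i, j] * log(joint[i, j] / (px[i] * py[j]))
  }
  mi
}

# Relief-style margin: nearest hit vs nearest miss on standardized data
relief_score <- function(x, y, seed = 1L, max_inst = 50L) {
  xs <- scale(x)
  xs[, !is.finite(colSums(xs))] <- 0
  n <- nrow(xs)
  set.seed(seed)
  inst <- if (n > max_inst) sort(sample.int(n, max_inst)) else seq_len(n)
  d <- as.matrix(stats::dist(xs))
  score <- numeric(ncol(xs))
  for (i in inst) {
    same <- which(y == y[i]); same <- same[same != i]
    diff <- which(y != y[i])
    if (!length(same) || !length(diff)) next
    hit <- same[which.min(d[i, same])]
    miss <- diff[which.min(d[i, diff])]
    score <- score + abs(xs[i, ] - xs[miss, ]) - abs(xs[i, ] - xs[hit, ])
  }
  stats::setNames(score, colnames(x))
}

# greedy sequential wrapper around a lightweight base learner (logistic
# regression or a decision stump), grouped 3-fold CV on precomputed folds
wrapper_select <- function(x, y, groups, learner, m, direction, seed) {
  feats <- colnames(x)
  k <- min(3L, length(unique(groups)))
  folds <- grouped_folds(groups, as.character(y), k, seed)
  y01 <- as.numeric(y) - 1
  base_acc <- function(xtr, ytr, xte) {
    if (learner == "lr") {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, xtr), ytr,
                       family = stats::binomial(),
                       control = stats::glm.control(maxit = 8)))
      co <- fit$coefficients
      co[is.na(co)] <- 0   # collinear columns
      as.numeric(cbind(1, xte) %*% co > 0)
    } else {  # best single-feature threshold (depth-1 stump)
      best <- list(acc = -1, j = 1L, thr = 0, dir = 1)
      for (j in seq_len(ncol(xtr))) {
        o <- order(xtr[, j])
        v <- unname(xtr[o, j]); lab <- ytr[o]
        cum1 <- cumsum(lab); tot1 <- cum1[length(cum1)]
        n <- length(lab)
        # accuracy of rule (x > v_i): right side positive
        acc_gt <- ((tot1 - cum1) + (seq_len(n) - cum1)) / n
        acc_le <- 1 - acc_gt
        i_gt <- which.max(acc_gt); i_le <- which.max(acc_le)
        if (acc_gt[i_gt] > best$acc)
          best <- list(acc = acc_gt[i_gt], j = j, thr = v[i_gt], dir = 1)
        if (acc_le[i_le] > best$acc)
          best <- list(acc = acc_le[i_le], j = j, thr = v[i_le], dir = -1)
      }
      pred <- xte[, best$j] > best$thr
      if (best$dir > 0) as.numeric(pred) else as.numeric(!pred)
    }
  }
  score_set <- function(set) {
    hits <- tot <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(y01[tr])) < 2L || !any(!tr)) next
      pr <- base_acc(x[tr, set, drop = FALSE], y01[tr],
                     x[!tr, set, drop = FALSE])
      hits <- hits + sum(pr == y01[!tr], na.rm = TRUE)
      tot <- tot + sum(!tr)
    }
    if (tot == 0) 0 else hits / tot
  }
  if (direction == "forward") {
    sel <- character(0)
    while (length(sel) < m) {
      cand <- setdiff(feats, sel)
      sc <- vapply(cand, function(f) score_set(c(sel, f)), numeric(1))
      sel <- c(sel, cand[which.max(sc)])
    }
    sel
  } else {
    sel <- feats
    while (length(sel) > m) {
      sc <- vapply(sel, function(f) score_set(setdiff(sel, f)), numeric(1))
      sel <- setdiff(sel, sel[which.max(sc)])
    }
    sel
  }
}

# L1-penalized logistic regression: first lambda on the path reaching m
# active features; rank by |coef| there
l1_select <- function(x, y, m) {
  fit <- glmnet::glmnet(pad1(scale(x)), y, family = "binomial", alpha = 1,
                        nlambda = 30, dfmax = m + 2L)
  beta <- as.matrix(fit$beta)[colnames(x), , drop = FALSE]
  nact <- colSums(beta != 0)
  j <- which(nact >= m)[1]
  if (is.na(j)) j <- ncol(beta)
  filter_rank(abs(beta[, j]), m)
}
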