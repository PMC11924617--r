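#' Feature registry
#'
#' Names of the center-of-pressure features the package computes per window,
#' in three families. Foot-level statistics of the weak-foot COP trajectory:
#' `Std_x`, `Mean_x`, `Std_y`, `Mean_y` (mm), `MRD`/`SRD` (mean/SD of the
#' resultant distance from the trajectory centroid, mm), `TOTEX` (total
#' excursion, mm) and `CCA` (95% confidence-circle area,
#' `pi * (MRD + 1.645 SRD)^2`, mm^2). Symmetry features comparing the two
#' feet: `GA` (gait asymmetry, `100 |ln(m_L/m_R)|` of mean stance
#' durations), `SIM` (cosine similarity of the per-sensor mean-pressure
#' distributions) and `JSD` (their Jensen-Shannon divergence, natural log).
#' Temporal-consistency features applying the same comparators to
#' consecutive weak-foot steps: `GIC`, `SSIM`, `SJSD`.
#'
#' @return character vector of feature names.
#' @export
feature_registry <- function() {
  c("Std_x", "Mean_x", "Std_y", "Mean_y", "MRD", "SRD", "TOTEX", "CCA",
    "GA", "SIM", "JSD", "GIC", "SSIM", "SJSD")
}

# population SD: stable for short windows and the documented convention here
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Center-of-pressure trajectory of one foot
#'
#' Per stance frame (total force above `eps`), the COP is the force-weighted
#' mean of the sensor coordinates: `(sum F_i x_i / sum F_i, sum F_i y_i /
#' sum F_i)`. Swing frames are excluded; every COP point therefore lies in
#' the convex hull of the sensor coordinates.
#'
#' @param frames numeric matrix `[frames x n_sensors]` of pressures.
#' @param layout a [sensor_layout()] matching the sensor count.
#' @param eps stance threshold on the per-frame total force.
#' @return A list of class `cop_trajectory`: `points` (`m x 2` matrix of
#'   `(x, y)` mm), `stance` (frame indices used), `side`.
#' @export
compute_cop <- function(frames, layout, eps = 0) {
  frames <- as.matrix(frames)
  if (ncol(frames) != layout$n)
    stop(sprintf("layout has %d sensors but frames have %d columns",
                 layout$n, ncol(frames)))
  tot <- rowSums(frames)
  stance <- which(tot > eps)
  if (!length(stance))
    stop("undefined-COP error: no stance frames above eps")
  w <- frames[stance, , drop = FALSE] / tot[stance]
  points <- cbind(x = as.vector(w %*% layout$coords[, "x"]),
                  y = as.vector(w %*% layout$coords[, "y"]))
  structure(list(points = points, stance = stance, side = layout$side),
            class = "cop_trajectory")
}

#' Select the functionally weak foot
#'
#' The weak foot is the side with the smaller anterior-posterior COP
#' standard deviation (`Std_y`): reduced forward-backward COP travel marks a
#' foot that has partially lost gait integrity. Ties go to the right foot
#' (the selection rule is strict `<` for the left).
#'
#' @param std_y_left,std_y_right per-foot `Std_y` in mm.
#' @return `"left"` or `"right"`.
#' @export
select_weak_foot <- function(std_y_left, std_y_right) {
  if (std_y_left < std_y_right) "left" else "right"
}

# Jensen-Shannon divergence (natural log) of two non-negative vectors,
# normalized to sum 1; NA if either sums to zero
js_divergence <- function(p, q) {
  sp <- sum(p); sq <- sum(q)
  if (sp <= 0 || sq <= 0) return(NA_real_)
  p <- p / sp; q <- q / sq
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

cosine_sim <- function(p, q) {
  np <- sqrt(sum(p^2)); nq <- sqrt(sum(q^2))
  if (np == 0 || nq == 0) return(NA_real_)
  sum(p * q) / (np * nq)
}

#' Extract COP features from one window
#'
#' Computes the [feature_registry()] features on a [cut_windows()] window.
#' Foot-level statistics are taken over the weak foot's COP trajectory
#' across the whole window, with the left foot's `x` mirrored (negated) into
#' the right-foot frame so `Mean_x` is comparable across subjects. Symmetry
#' features compare the two feet's per-sensor mean stance pressures
#' (distributions aligned by sensor index) and mean stance durations.
#' Temporal-consistency features apply the same comparators to consecutive
#' weak-foot steps and average.
#'
#' Degenerate inputs (an all-zero pressure distribution) yield `NA` for the
#' affected feature with a warning, never a silent zero.
#'
#' @param window a `gait_window` with at least 2 steps and stance frames on
#'   both feet.
#' @param registry feature names to report (subset of [feature_registry()]).
#' @return One-row data.frame: `subject`, `label`, `L`, `start`,
#'   `weak_side`, then one column per registry feature.
#' @export
extract_features <- function(window, registry = feature_registry()) {
  stopifnot(inherits(window, "gait_window"))
  if (nrow(window$steps) < 2L)
    stop("window must contain at least 2 steps")
  bad <- setdiff(registry, feature_registry())
  if (length(bad)) stop("unknown features: ", paste(bad, collapse = ", "))
  eps <- window$eps
  cop_l <- compute_cop(window$left, window$layout$left, eps)
  cop_r <- compute_cop(window$right, window$layout$right, eps)
  std_y <- c(left = pop_sd(cop_l$points[, "y"]),
             right = pop_sd(cop_r$points[, "y"]))
  weak <- select_weak_foot(std_y["left"], std_y["right"])
  cop_w <- if (weak == "left") cop_l else cop_r
  pts <- cop_w$points
  if (weak == "left") pts[, "x"] <- -pts[, "x"]   # mirror into right frame

  out <- list()
  out$Std_x <- pop_sd(pts[, "x"]); out$Mean_x <- mean(pts[, "x"])
  out$Std_y <- pop_sd(pts[, "y"]); out$Mean_y <- mean(pts[, "y"])
  ctr <- colMeans(pts)
  rd <- sqrt((pts[, "x"] - ctr["x"])^2 + (pts[, "y"] - ctr["y"])^2)
  out$MRD <- mean(rd); out$SRD <- pop_sd(rd)
  out$TOTEX <- if (nrow(pts) > 1)
    sum(sqrt(rowSums(diff(pts)^2))) else 0
  out$CCA <- pi * (out$MRD + 1.645 * out$SRD)^2

  # symmetry: per-sensor mean stance pressure of each foot + stance durations
  dist_l <- colMeans(window$left[cop_l$stance, , drop = FALSE])
  dist_r <- colMeans(window$right[cop_r$stance, , drop = FALSE])
  durs <- (window$steps$end - window$steps$onset + 1L) / window$rate
  m_l <- mean(durs[window$steps$side == "left"])
  m_r <- mean(durs[window$steps$side == "right"])
  out$GA <- if (is.finite(m_l) && is.finite(m_r) && m_l > 0 && m_r > 0)
    100 * abs(log(m_l / m_r)) else NA_real_
  out$SIM <- cosine_sim(dist_l, dist_r)
  out$JSD <- js_divergence(dist_l, dist_r)

  # temporal consistency on consecutive weak-foot steps
  wsteps <- window$steps[window$steps$side == weak, , drop = FALSE]
  wmat <- window[[weak]]
  f0 <- window$frames[1] - 1L
  if (nrow(wsteps) >= 2L) {
    step_dist <- lapply(seq_len(nrow(wsteps)), function(i) {
      colMeans(wmat[(wsteps$onset[i] - f0):(wsteps$end[i] - f0), , drop = FALSE])
    })
    n_pair <- nrow(wsteps) - 1L
    ssim <- sjsd <- numeric(n_pair)
    for (i in seq_len(n_pair)) {
      ssim[i] <- cosine_sim(step_dist[[i]], step_dist[[i + 1]])
      sjsd[i] <- js_divergence(step_dist[[i]], step_dist[[i + 1]])
    }
    wdur <- (wsteps$end - wsteps$onset + 1L) / window$rate
    out$GIC <- 100 * mean(abs(log(wdur[-1] / wdur[-length(wdur)])))
    out$SSIM <- mean(ssim); out$SJSD <- mean(sjsd)
  } else {
    out$GIC <- out$SSIM <- out$SJSD <- NA_real_
  }

  vals <- unlist(out)[registry]
  if (anyNA(vals))
    warning("undefined feature(s) for subject ", window$subject_id, ": ",
            paste(registry[is.na(vals)], collapse = ", "))
  cbind(data.frame(subject = window$subject_id, label = window$label,
                   L = window$L, start = window$start, weak_side = weak,
                   stringsAsFactors = FALSE),
        as.data.frame(as.list(vals)))
}

#' Window and featurize a recording
#'
#' Pipeline wrapper: segment steps, discard start-up, window at each
#' requested length with the configured stride, and extract the registry
#' features per window.
#'
#' @param rec a `gait_recording`.
#' @param lengths window lengths in steps.
#' @param cfg a [run_config()] supplying stride, discard count and contact
#'   thresholds.
#' @return Feature table data.frame, one row per (length, window). Lengths
#'   exceeding the available step count are skipped with a warning.
#' @export
extract_window_features <- function(rec, lengths, cfg = run_config()) {
  idx <- segment_steps(rec, min_dur = cfg$min_dur_ms)
  idx <- discard_startup(idx, cfg$discard_steps)
  S <- n_steps(idx)
  rows <- list()
  for (L in lengths) {
    if (L > S) {
      warning(sprintf("subject %s: length %d exceeds %d steps, skipped",
                      rec$subject_id, L, S))
      next
    }
    wins <- cut_windows(rec, idx, plan_windows(S, L, cfg$stride))
    rows <- c(rows, lapply(wins, extract_features, registry = cfg$registry))
  }
  if (!length(rows))
    stop("insufficient-data error: no usable window length for subject ",
         rec$subject_id)
  do.call(rbind, rows)
}

#' Fit / apply a z-score feature scaler
#'
#' Standardization statistics are always fitted on training subjects only
#' and reused at test time, so held-out subjects never leak into the scale.
#' Constant features (SD 0) get unit scale and standardize to 0.
#'
#' @param x data.frame or matrix of feature values (training rows).
#' @param names feature columns to scale; default all numeric columns of the
#'   registry present in `x`.
#' @return `fit_scaler()`: an object of class `feature_scaler`;
#'   `apply_scaler()`: a numeric matrix of z-scored columns `names`.
#' @export
fit_scaler <- function(x, names = NULL) {
  if (is.null(names))
    names <- intersect(feature_registry(), colnames(x))
  m <- as.matrix(as.data.frame(x)[, names, drop = FALSE])
  mu <- colMeans(m, na.rm = TRUE)
  sd <- apply(m, 2, function(v) pop_sd(v[!is.na(v)]))
  sd[sd == 0 | !is.finite(sd)] <- 1
  structure(list(names = names, mean = mu, sd = sd), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `feature_scaler`.
#' @export
apply_scaler <- function(x, scaler) {
  m <- as.matrix(as.data.frame(x)[, scaler$names, drop = FALSE])
  scale(m, center = scaler$mean, scale = scaler$sd)[, , drop = FALSE]
}

#' Identity scaler over given features
#' @param names feature names.
#' @return A `feature_scaler` that leaves values unchanged.
#' @export
identity_scaler <- function(names) {
  structure(list(names = names,
                 mean = stats::setNames(rep(0, length(names)), names),
                 sd = stats::setNames(rep(1, length(names)), names)),
            class = "feature_scaler")
}

#' Weak-foot feature vectors for distance computations
#'
#' Extracts the configured weak-foot features (default 5-dimensional) from a
#' feature table and z-scores them with a training-fitted scaler. These are
#' the vectors whose pairwise dispersion defines the full-connection
#' distance and the DDI.
#'
#' @param fv feature table rows (data.frame).
#' @param names ordered weak-foot feature names.
#' @param scaler a `feature_scaler` fitted on training subjects (or
#'   [identity_scaler()]).
#' @return numeric matrix, one row per window, columns `names`.
#' @export
weak_vector <- function(fv, names, scaler) {
  missing_cols <- setdiff(names, colnames(fv))
  if (length(missing_cols))
    stop("missing feature(s): ", paste(missing_cols, collapse = ", "))
  m <- as.matrix(as.data.frame(fv)[, names, drop = FALSE])
  if (anyNA(m)) {
    bad <- names[apply(is.na(m), 2, any)]
    stop("missing feature value(s): ", paste(bad, collapse = ", "))
  }
  sub <- scaler
  ord <- match(names, scaler$names)
  if (anyNA(ord)) stop("scaler does not cover: ",
                       paste(names[is.na(ord)], collapse = ", "))
  sub$names <- names; sub$mean <- scaler$mean[ord]; sub$sd <- scaler$sd[ord]
  apply_scaler(as.data.frame(m), sub)
}
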