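#' Full-connection distance of a set of feature vectors
#'
#' Mean Euclidean distance over all ordered pairs of a subject's weak-foot
#' feature vectors at one window length:
#' `d_L = 1/(N(N-1)) * sum_{i != j} ||v_i - v_j||`. By symmetry this equals
#' the mean over unordered pairs. Elevated values at short window lengths
#' signal dispersed, episodically expressed gait.
#'
#' @param vs numeric matrix, one feature vector per row (`N >= 2`).
#' @return non-negative scalar; 0 iff all vectors are equal.
#' @examples
#' full_connection_distance(rbind(c(0, 0), c(3, 4)))  # 5
#' @export
full_connection_distance <- function(vs) {
  vs <- as.matrix(vs)
  if (nrow(vs) < 2L)
    stop("insufficient-samples error: need at least 2 feature vectors")
  if (anyNA(vs) || !all(is.finite(vs)))
    stop("feature vectors must be finite")
  mean(stats::dist(vs))
}

#' Distribution Difference Index for one subject
#'
#' `DDI = d_l / d_h`: the full-connection distance of the subject's
#' weak-foot vectors at a short window length divided by that at a long
#' window length. The long-length dispersion is the subject's own baseline,
#' cancelling overall gait variability; the ratio is invariant to a common
#' positive rescaling of all vectors. Individuals whose high-risk gait is
#' expressed only intermittently scatter at short lengths but not at long
#' lengths, elevating the DDI.
#'
#' @param v_low,v_high numeric matrices of weak-foot vectors (rows) at the
#'   low and high window lengths, already standardized with a
#'   training-fitted scaler.
#' @param subject_id subject identifier carried into the record.
#' @return A one-row data.frame of class `ddi_record`: `subject`, `d_l`,
#'   `d_h`, `DDI`, `n_low`, `n_high`.
#' @export
compute_ddi <- function(v_low, v_high, subject_id = NA_character_) {
  d_l <- full_connection_distance(v_low)
  d_h <- full_connection_distance(v_high)
  if (d_h == 0)
    stop("degenerate-gait error: zero dispersion at the high window length")
  structure(data.frame(subject = subject_id, d_l = d_l, d_h = d_h,
                       DDI = d_l / d_h,
                       n_low = nrow(as.matrix(v_low)),
                       n_high = nrow(as.matrix(v_high)),
                       stringsAsFactors = FALSE),
            class = c("ddi_record", "data.frame"))
}

#' DDI feature scalers
#'
#' Fits one z-score scaler per window length (features such as the total
#' excursion scale with the window length, so standardization statistics
#' are length-specific). Fit on training subjects only.
#'
#' @param tab training feature table.
#' @param cfg a [run_config()].
#' @return list of class `ddi_scalers` with `low`, `high`
#'   ([fit_scaler()] objects) and the two lengths.
#' @export
fit_ddi_scalers <- function(tab, cfg = run_config()) {
  Lh <- cfg$d_h_length
  if (!any(tab$L == Lh)) {
    avail <- sort(unique(tab$L[tab$L > cfg$d_l_length]), decreasing = TRUE)
    if (!length(avail))
      stop("insufficient-samples error: no windows above L=", cfg$d_l_length)
    Lh <- avail[1]
    warning("no windows at L=", cfg$d_h_length,
            "; fitting the high-length scaler at L=", Lh)
  }
  structure(list(
    low = fit_scaler(tab[tab$L == cfg$d_l_length, ], cfg$weak_features),
    high = fit_scaler(tab[tab$L == Lh, ], cfg$weak_features),
    d_l_length = cfg$d_l_length, d_h_length = Lh),
    class = "ddi_scalers")
}

#' Per-subject DDI over a feature table
#'
#' Computes each subject's DDI from a window feature table containing rows
#' at (at least) the configured low and high lengths. When `scalers` is
#' `NULL` they are fitted on the table itself (training use); at test
#' time pass the training-fitted [fit_ddi_scalers()]. If a subject lacks
#' windows at the configured high length, the longest length available for
#' that subject is used instead, with a warning.
#'
#' @param tab feature table (see [extract_window_features()]).
#' @param cfg a [run_config()] (uses `d_l_length`, `d_h_length`,
#'   `weak_features`).
#' @param scalers optional training-fitted [fit_ddi_scalers()] object.
#' @return data.frame with one `ddi_record` row per subject.
#' @export
cohort_ddi <- function(tab, cfg = run_config(), scalers = NULL) {
  if (is.null(scalers)) scalers <- fit_ddi_scalers(tab, cfg)
  out <- lapply(unique(tab$subject), function(sid) {
    sub <- tab[tab$subject == sid, , drop = FALSE]
    low <- sub[sub$L == cfg$d_l_length, , drop = FALSE]
    if (nrow(low) < 2L)
      stop("insufficient-samples error: subject ", sid,
           " has < 2 windows at L=", cfg$d_l_length)
    Lh <- scalers$d_h_length
    high <- sub[sub$L == Lh, , drop = FALSE]
    if (nrow(high) < 2L) {
      avail <- sort(unique(sub$L[sub$L > cfg$d_l_length]), decreasing = TRUE)
      Lh <- avail[vapply(avail, function(l) sum(sub$L == l) >= 2L, logical(1))][1]
      if (is.na(Lh))
        stop("insufficient-samples error: subject ", sid,
             " has no length with >= 2 windows above L=", cfg$d_l_length)
      warning(sprintf("subject %s: falling back to d_h at L=%d", sid, Lh))
      high <- sub[sub$L == Lh, , drop = FALSE]
    }
    compute_ddi(weak_vector(low, cfg$weak_features, scalers$low),
                weak_vector(high, cfg$weak_features, scalers$high), sid)
  })
  do.call(rbind, out)
}

#' Fit the adaptive RWF threshold
#'
#' The threshold interpolates between the training cohort's DDI extremes:
#' `T = DDI_min + (DDI_max - DDI_min) * alpha`, with trainable
#' `alpha` in `[0, 1]`. In robust mode the extremes are replaced by
#' `mu +/- 3 sigma` of the training DDIs, clipped to the observed range, so
#' outliers cannot stretch the alpha scale.
#'
#' @param ddi data.frame of training [compute_ddi()] records (or a numeric
#'   vector of DDIs).
#' @param alpha interpolation parameter in `[0, 1]`.
#' @param robust use `mu +/- 3 sigma` bounds instead of raw extremes.
#' @return A list of class `threshold_model`: `alpha`, `ddi_min`, `ddi_max`,
#'   `mu`, `sigma`, `robust`, `T`.
#' @examples
#' fit_threshold(c(1, 3), alpha = 0.3)$T  # 1.6
#' @export
fit_threshold <- function(ddi, alpha, robust = FALSE) {
  x <- if (is.data.frame(ddi)) ddi$DDI else as.numeric(ddi)
  if (length(x) < 2L)
    stop("insufficient-samples error: need at least 2 training subjects")
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  mu <- mean(x); sigma <- stats::sd(x)
  lo <- min(x); hi <- max(x)
  if (robust) {
    lo <- max(lo, mu - 3 * sigma)
    hi <- min(hi, mu + 3 * sigma)
  }
  if (lo == hi)
    warning("degenerate-cohort warning: all training DDIs equal; T = ", lo)
  structure(list(alpha = alpha, ddi_min = lo, ddi_max = hi,
                 mu = mu, sigma = sigma, robust = robust,
                 T = lo + (hi - lo) * alpha),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> alpha=%.3f, DDI range [%.3f, %.3f]%s -> T=%.3f\n",
              x$alpha, x$ddi_min, x$ddi_max,
              if (x$robust) " (robust)" else "", x$T))
  invisible(x)
}

#' Classify a subject as RWF or DWF
#'
#' A subject whose DDI is strictly greater than the fitted threshold `T` is
#' a recessive-weak-foot (RWF) individual; otherwise dominant weak foot
#' (DWF). At `DDI == T` the call is DWF.
#'
#' @param ddi a `ddi_record` row, numeric DDI value(s), or the data.frame
#'   from [cohort_ddi()].
#' @param model a fitted [fit_threshold()] model.
#' @return character vector of `"RWF"` / `"DWF"` calls.
#' @export
classify_type <- function(ddi, model) {
  x <- if (is.data.frame(ddi)) ddi$DDI else as.numeric(ddi)
  ifelse(x > model$T, "RWF", "DWF")
}
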