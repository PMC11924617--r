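#' Segment a recording into foot-contact steps
#'
#' A step is one foot-contact event of either foot. For each foot the total
#' force is summed across sensors; a contact starts when the total rises
#' above `eps` and ends when it stays at or below `eps` for at least
#' `min_dur` milliseconds (shorter dropouts are bridged, since real sensors
#' flicker near zero). Events from both feet are merged in onset order.
#'
#' @param rec a [gait_recording()].
#' @param eps pressure threshold; default 2% of the recording's
#'   95th-percentile per-foot total force.
#' @param min_dur minimum off time in ms that terminates a contact.
#' @return A `step_index`: list with `events` (data.frame `onset`, `end`
#'   frame indices and `side`) and `startup_discarded` count (0 here; see
#'   [discard_startup()]).
#' @export
segment_steps <- function(rec, eps = NULL, min_dur = 50) {
  tot <- list(left = rowSums(rec$left), right = rowSums(rec$right))
  if (is.null(eps)) {
    ref <- stats::quantile(c(tot$left, tot$right), 0.95, names = FALSE)
    eps <- 0.02 * ref
  }
  gap_frames <- max(1L, ceiling(min_dur / 1000 * rec$rate))
  ev <- do.call(rbind, lapply(names(tot), function(side) {
    contact_intervals(tot[[side]] > eps, gap_frames, side)
  }))
  if (is.null(ev) || nrow(ev) == 0L)
    stop("empty-gait error: no steps detected (eps = ", signif(eps, 4), ")")
  ev <- ev[order(ev$onset, ev$end), , drop = FALSE]
  rownames(ev) <- NULL
  structure(list(events = ev, startup_discarded = 0L, eps = eps),
            class = "step_index")
}

# TRUE runs of `active`, with FALSE gaps < gap_frames bridged and
# TRUE runs shorter than gap_frames discarded (sensor blips, not contacts)
contact_intervals <- function(active, gap_frames, side) {
  r <- rle(active)
  # bridge short off-gaps strictly inside the signal
  if (length(r$lengths) > 2L) {
    inner <- which(!r$values & r$lengths < gap_frames)
    inner <- inner[inner > 1L & inner < length(r$values)]
    if (length(inner)) {
      r$values[inner] <- TRUE
      active <- inverse.rle(r)
      r <- rle(active)
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths >= gap_frames)
  if (!length(keep)) return(NULL)
  data.frame(onset = starts[keep], end = ends[keep],
             side = rep(side, length(keep)), stringsAsFactors = FALSE)
}

#' @export
print.step_index <- function(x, ...) {
  cat(sprintf("<step_index> %d steps (%d left, %d right), %d start-up discarded\n",
              nrow(x$events), sum(x$events$side == "left"),
              sum(x$events$side == "right"), x$startup_discarded))
  invisible(x)
}

#' Number of steps in a step index
#' @param idx a `step_index`.
#' @return integer step count.
#' @export
n_steps <- function(idx) nrow(idx$events)

#' Discard gait start-up steps
#'
#' Removes the first `k` contact events (default 2), which reflect gait
#' initiation rather than steady-state walking.
#'
#' @param idx a `step_index`.
#' @param k number of leading steps to drop.
#' @return A `step_index` with `startup_discarded` incremented by `k`.
#' @export
discard_startup <- function(idx, k = 2L) {
  k <- as.integer(k)
  if (k < 0) stop("k must be >= 0")
  if (nrow(idx$events) < k + 1L)
    stop(sprintf("insufficient-data error: %d steps, cannot discard %d",
                 nrow(idx$events), k))
  if (k > 0L) idx$events <- idx$events[-seq_len(k), , drop = FALSE]
  rownames(idx$events) <- NULL
  idx$startup_discarded <- idx$startup_discarded + k
  idx
}

#' Plan step-level sliding windows
#'
#' A walk of `S` steps is cut into windows of `L` consecutive steps advanced
#' by a stride of `s` steps, giving `N = floor((S - L)/s) + 1` windows; when
#' `(S - L)` is not divisible by `s` the trailing remainder is dropped.
#'
#' @param S total steps available (after start-up discard).
#' @param L window length in steps.
#' @param s stride in steps.
#' @return A list of class `windowing_plan` with `S`, `L`, `s`, `N` and
#'   `starts`, the 0-based step offsets of each window.
#' @examples
#' plan_windows(180, 130, 10)$N  # 6
#' @export
plan_windows <- function(S, L, s = 10L) {
  S <- as.integer(S); L <- as.integer(L); s <- as.integer(s)
  if (s < 1) stop("stride must be >= 1")
  if (L < 1) stop("window length must be >= 1")
  if (L > S)
    stop(sprintf("insufficient-data error: window length %d exceeds %d steps", L, S))
  N <- (S - L) %/% s + 1L
  structure(list(S = S, L = L, s = s, N = N,
                 starts = s * (seq_len(N) - 1L)),
            class = "windowing_plan")
}

#' @export
print.windowing_plan <- function(x, ...) {
  cat(sprintf("<windowing_plan> S=%d, L=%d, s=%d -> N=%d windows\n",
              x$S, x$L, x$s, x$N))
  invisible(x)
}

#' Cut a recording into step windows
#'
#' Materializes the windows of a [plan_windows()] plan: window `i` covers
#' steps `[i*s, i*s + L)` in onset order across both feet, and spans the
#' frames from the onset of its first step to the end of its last step, with
#' both feet's signals retained over that span so symmetry features remain
#' computable.
#'
#' @param rec a `gait_recording`.
#' @param idx a `step_index` (after start-up discard).
#' @param plan a `windowing_plan` consistent with `idx` (`plan$S ==
#'   n_steps(idx)`).
#' @return A list of `gait_window` objects; each carries `subject_id`,
#'   `label`, `L`, `start` (0-based step offset), the event subset `steps`,
#'   the frame range `frames`, and matrices `left`, `right` clipped to it.
#' @export
cut_windows <- function(rec, idx, plan) {
  if (plan$S != nrow(idx$events))
    stop(sprintf("plan (S=%d) inconsistent with step index (%d steps)",
                 plan$S, nrow(idx$events)))
  lapply(plan$starts, function(off) {
    steps <- idx$events[off + seq_len(plan$L), , drop = FALSE]
    fr <- c(min(steps$onset), max(steps$end))
    structure(list(subject_id = rec$subject_id, label = rec$label,
                   L = plan$L, start = off, rate = rec$rate,
                   steps = steps, frames = fr,
                   left = rec$left[fr[1]:fr[2], , drop = FALSE],
                   right = rec$right[fr[1]:fr[2], , drop = FALSE],
                   layout = rec$layout, eps = idx$eps),
              class = "gait_window")
  })
}

#' @export
print.gait_window <- function(x, ...) {
  cat(sprintf("<gait_window> subject %s, L=%d steps @ offset %d, frames %d..%d\n",
              x$subject_id, x$L, x$start, x$frames[1], x$frames[2]))
  invisible(x)
}
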