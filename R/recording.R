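#' Bilateral plantar-pressure recording
#'
#' A `gait_recording` holds synchronized per-sensor pressure time series for
#' both feet of one subject, plus the sensor layout that frames them.
#' Pressures are non-negative and in arbitrary linear units (raw ADC counts
#' or newtons); every downstream statistic is either scale-invariant or
#' documented as scale-dependent.
#'
#' @param subject_id subject identifier string.
#' @param left,right numeric matrices `[frames x n_sensors]` of per-sensor
#'   pressure, one row per frame, same frame count on both feet.
#' @param rate sampling rate in Hz.
#' @param layout a [layout_pair()] whose sensor count matches the matrices.
#' @param label fall-risk label: `"HR"` (high risk), `"LR"` (low risk) or
#'   `"unlabeled"`.
#' @param meta free-form list of metadata.
#' @return An object of class `gait_recording`.
#' @export
gait_recording <- function(subject_id, left, right, rate, layout,
                           label = c("unlabeled", "HR", "LR"), meta = list()) {
  label <- match.arg(label)
  left <- as.matrix(left); right <- as.matrix(right)
  storage.mode(left) <- "double"; storage.mode(right) <- "double"
  if (nrow(left) != nrow(right))
    stop("left and right must share the frame count")
  if (!inherits(layout, "layout_pair"))
    stop("layout must be a layout_pair")
  if (ncol(left) != layout$left$n || ncol(right) != layout$right$n)
    stop(sprintf("sensor count mismatch: matrices have %d/%d columns, layout has %d",
                 ncol(left), ncol(right), layout$left$n))
  if (!all(is.finite(left)) || !all(is.finite(right)))
    stop("pressures must be finite")
  if (min(left) < 0 || min(right) < 0)
    stop("pressures must be non-negative")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  structure(list(subject_id = as.character(subject_id), label = label,
                 rate = rate, left = left, right = right,
                 layout = layout, meta = meta),
            class = "gait_recording")
}

#' @export
print.gait_recording <- function(x, ...) {
  cat(sprintf("<gait_recording> subject %s [%s], %d frames @ %g Hz, %d sensors/foot\n",
              x$subject_id, x$label, nrow(x$left), x$rate, ncol(x$left)))
  invisible(x)
}

#' Number of frames in a recording
#' @param rec a `gait_recording`.
#' @return integer frame count.
#' @export
n_frames <- function(rec) nrow(rec$left)

#' Read a plantar-pressure recording
#'
#' Two dialects are supported. `wide_csv` is the package's canonical format:
#' a header row, then columns `time_s`, left sensors 1..n, right sensors 1..n.
#' `physionet_vgrf` reads the tab/space-separated 19-column vertical
#' ground-reaction-force text used by the public Parkinson's gait records:
#' time, 8 left sensors, 8 right sensors, left total, right total; the two
#' total columns are dropped.
#'
#' @param path file path.
#' @param layout a [layout_pair()]; sensor count must match the file.
#' @param dialect `"wide_csv"` or `"physionet_vgrf"`.
#' @param subject_id subject id; defaults to the file base name.
#' @param label optional fall-risk label.
#' @param rate sampling rate in Hz; for `wide_csv` inferred from the time
#'   column when `NULL` (PhysioNet VGRF records are 100 Hz).
#' @return A validated `gait_recording`; frames are never silently dropped.
#' @export
read_recording <- function(path, layout, dialect = c("wide_csv", "physionet_vgrf"),
                           subject_id = NULL, label = "unlabeled", rate = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(subject_id))
    subject_id <- sub("\\.[^.]+$", "", basename(path))
  n <- layout$left$n
  if (dialect == "wide_csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    want <- 1L + 2L * n
    if (ncol(df) != want)
      stop(sprintf("wide_csv schema error: expected %d columns (time + 2x%d sensors), found %d",
                   want, n, ncol(df)))
    bad <- which(!vapply(df, is.numeric, logical(1)))
    if (length(bad))
      stop(sprintf("parse error: non-numeric values in column %d (data line %d)",
                   bad[1], which(!grepl("^[-+0-9.eE ]*$",
                                        as.character(df[[bad[1]]])))[1]))
    tm <- df[[1]]
    left <- unname(as.matrix(df[, 1L + seq_len(n), drop = FALSE]))
    right <- unname(as.matrix(df[, 1L + n + seq_len(n), drop = FALSE]))
    if (is.null(rate))
      rate <- if (nrow(df) > 1) 1 / stats::median(diff(tm)) else 100
  } else {
    df <- utils::read.table(path, header = FALSE)
    if (ncol(df) != 19L)
      stop(sprintf("physionet_vgrf schema error: expected 19 columns, found %d",
                   ncol(df)))
    if (n != 8L)
      stop("physionet_vgrf carries 8 sensors per foot; layout has ", n)
    left <- unname(as.matrix(df[, 2:9]))
    right <- unname(as.matrix(df[, 10:17]))
    if (is.null(rate)) rate <- 100
  }
  if (anyNA(left) || anyNA(right))
    stop("parse error: missing pressure values (first bad line ",
         which(apply(is.na(cbind(left, right)), 1, any))[1], ")")
  if (min(left) < 0 || min(right) < 0)
    stop("validation error: negative pressure (first bad line ",
         which(apply(cbind(left, right) < 0, 1, any))[1], ")")
  gait_recording(subject_id, left, right, rate, layout, label = label)
}

#' Write a recording as wide CSV
#'
#' Canonical on-disk format: `time_s`, left sensors `L1..Ln`, right sensors
#' `R1..Rn`, with a header. Values are written at full double precision so a
#' write/read round trip is value-exact.
#'
#' @param rec a `gait_recording`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  n <- ncol(rec$left)
  tm <- (seq_len(nrow(rec$left)) - 1L) / rec$rate
  header <- c("time_s", paste0("L", seq_len(n)), paste0("R", seq_len(n)))
  m <- cbind(tm, rec$left, rec$right)
  lines <- c(paste(header, collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}
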