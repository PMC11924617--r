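#' Run configuration
#'
#' Assembles every tunable of the pipeline with documented defaults. All
#' entries can be overridden from a YAML file via [load_config()] or by
#' arguments here.
#'
#' Defaults: step windows slide with stride `s = 10`; the short dispersion
#' length `d_l_length = 20` steps and the long baseline `d_h_length = 130`
#' steps; the threshold parameter alpha is searched over 0.14 to 0.40 in
#' steps of 0.02 (14 grid points); the weak-foot feature vector is
#' `Std_y, Std_x, MRD, TOTEX, CCA`; seven candidate classifiers with two
#' tuned hyperparameters each; startup discard of 2 steps; contact threshold
#' `eps` at 2% of the recording's 95th-percentile per-foot total force and a
#' 50 ms release time.
#'
#' @param ... named overrides of the defaults listed above (see
#'   `names(run_config())`).
#' @return A list of class `run_config`.
#' @examples
#' cfg <- run_config(d_h_length = 180)
#' cfg$alpha_grid
#' @export
run_config <- function(...) {
  cfg <- list(
    lengths = seq(20L, 180L, by = 10L),   # pilot sweep lengths (steps)
    operating_length = 130L,              # L used by the two-stage model
    d_l_length = 20L,
    d_h_length = 130L,
    stride = 10L,
    discard_steps = 2L,
    eps_frac = 0.02,
    min_dur_ms = 50,
    alpha_min = 0.14,
    alpha_max = 0.40,
    alpha_step = 0.02,
    robust_bounds = FALSE,
    weak_features = c("Std_y", "Std_x", "MRD", "TOTEX", "CCA"),
    registry = feature_registry(),
    roster = c("lr", "svm", "knn", "dt", "rf", "gbdt", "adaboost"),
    surrogate = "svm",                    # stage-1 default-setting classifier
    branch_min = 3L,                      # min subjects before branch training
    cv_folds = 5L,
    selector_subset = 5L,                 # features each selector nominates
    max_phase1 = 999L,                    # cap on phase-1 survivors
    max_phase3 = 8L,                      # largest cardinality tried in phase 3
    fast_grids = FALSE,                   # reduced hyperparameter grids
    seed = 1L,
    paths = list()
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config entries: ",
                            paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (cfg$alpha_min < 0 || cfg$alpha_max > 1 || cfg$alpha_min > cfg$alpha_max)
    stop("validation error: alpha grid must lie within [0, 1]")
  if (cfg$alpha_step <= 0) stop("validation error: alpha_step must be > 0")
  if (cfg$d_l_length >= cfg$d_h_length)
    stop("validation error: d_l_length must be smaller than d_h_length")
  if (cfg$stride < 1) stop("validation error: stride must be >= 1")
  if (!all(cfg$weak_features %in% cfg$registry))
    stop("validation error: weak_features outside the feature registry")
  bad <- setdiff(cfg$roster, c("lr", "svm", "knn", "dt", "rf", "gbdt", "adaboost"))
  if (length(bad)) stop("validation error: unknown classifiers: ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Alpha search grid of a configuration
#' @param cfg a `run_config`.
#' @return numeric vector of candidate alpha values.
#' @export
alpha_grid <- function(cfg) {
  g <- seq(cfg$alpha_min, cfg$alpha_max, by = cfg$alpha_step)
  round(g, 10)
}

#' Scaled-down configuration for compact experiments
#'
#' A [run_config()] preset that shrinks the expensive search dimensions -
#' three-classifier roster, reduced hyperparameter grids, 3-fold inner CV,
#' 3-feature selector nominations, capped phase-1 pool, alpha grid at twice
#' the step - while leaving the method's structure (three-phase selection,
#' eleven selectors, DDI lengths) untouched. Used for the package's
#' simulation studies so a full leave-one-subject-out run stays tractable
#' on one core.
#'
#' @param ... further [run_config()] overrides.
#' @return A `run_config`.
#' @export
fast_config <- function(...) {
  run_config(roster = c("lr", "svm", "dt"), cv_folds = 3L,
             selector_subset = 3L, max_phase1 = 8L, max_phase3 = 4L,
             alpha_step = 0.04, fast_grids = TRUE, ...)
}

#' Load a configuration from YAML
#'
#' Any subset of the [run_config()] entries may appear in the file; missing
#' entries take the documented defaults. An empty or absent-keyed file yields
#' the full default configuration.
#'
#' @param path YAML file path.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj)) obj <- list()
  do.call(run_config, obj)
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(paste0("<run_config> L_op=%d, d_l=%d, d_h=%d, stride=%d, ",
                     "alpha %.2f..%.2f/%.2f, %d classifiers\n"),
              x$operating_length, x$d_l_length, x$d_h_length, x$stride,
              x$alpha_min, x$alpha_max, x$alpha_step, length(x$roster)))
  invisible(x)
}
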