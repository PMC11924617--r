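#' Synthetic gait simulator configuration
#'
#' Parameters of the bilateral plantar-pressure simulator. Each foot contact
#' emits per-sensor half-sine pressure bursts whose onsets progress from
#' heel to toe (rollover). One side is the programmed weak side: its
#' anterior sensors' amplitudes and onsets are compressed by an attenuation
#' factor, reducing the anterior-posterior COP excursion so the weak-foot
#' selection rule keys on it. How strongly the attenuation is expressed
#' depends on a per-step high-risk state:
#'
#' * `DWF_LR` - the state is always low-risk; the weak side expresses only
#'   the fraction `lr_frac` of the risk effect (a mild, stable asymmetry).
#' * `DWF_HR` - the state is always high-risk; the full attenuation `atten`
#'   applies on every weak-side step.
#' * `RWF` - the state toggles between the two by a symmetric two-state
#'   Markov chain with per-step switching probability `switch_p`, producing
#'   temporally clustered high-risk episodes; short windows then scatter in
#'   feature space while long windows average out, which is exactly what
#'   elevates the DDI.
#'
#' @param phenotype `"DWF_LR"`, `"DWF_HR"` or `"RWF"`.
#' @param weak_side `"left"` or `"right"`.
#' @param total_steps contacts summed over both feet (default 222: a
#'   little over two minutes of walking at the default cadence, matching
#'   the collection protocol's two-minute minimum; 220 steady-state steps
#'   remain after the standard 2-step start-up discard).
#' @param cadence steps per minute over both feet.
#' @param rate sampling rate, Hz.
#' @param stance_s nominal stance duration, seconds.
#' @param jitter_cv coefficient of variation of step timing.
#' @param hr_jitter_mult timing-jitter inflation on high-risk weak-side
#'   steps.
#' @param atten strongest anterior rollover attenuation (full expression),
#'   in `(0, 1]` (1 = no effect anywhere).
#' @param lr_frac fraction of an RWF subject's severity expressed during
#'   their low-risk episodes.
#' @param sev_hr,sev_lr per-subject severity ranges (uniform draws)
#'   multiplying the maximal effect `1 - atten`: high-risk subjects
#'   (`DWF_HR`) draw from `sev_hr`, low-risk subjects from `sev_lr`, and
#'   episodic (`RWF`) subjects from `sev_rwf`. The default `sev_hr` /
#'   `sev_lr` ranges overlap slightly, so the hardest low-risk subjects
#'   resemble the mildest high-risk subjects - inter-individual severity
#'   heterogeneity as seen in real cohorts. `sev_rwf` sits at the high
#'   end: the episodic phenotype is defined by discontinuous episodes of
#'   frank high-risk gait, not by borderline severity.
#' @param sev_rwf severity range for `RWF` subjects.
#' @param switch_p per-step state-switching probability (RWF only).
#' @param noise_mult multiplicative amplitude noise SD (per step, sensor).
#' @param noise_add additive in-stance noise SD as a fraction of the
#'   amplitude scale.
#' @param fatigue_min,fatigue_max bounds of the per-subject fatigue trend:
#'   a monotone bilateral change in rollover depth across the walk, total
#'   magnitude drawn uniformly from this interval with random direction.
#'   Long windows centred at different walk positions then differ
#'   systematically, giving every subject a stable nonzero baseline
#'   dispersion for the DDI denominator.
#' @param drift_sd SD of the residual slow bilateral rollover-depth drift
#'   (AR(1) over steps) on top of the trend.
#' @param drift_len correlation length of the residual drift, in steps.
#' @param amp_scale pressure amplitude scale, arbitrary units.
#' @param layout a [layout_pair()]; default [default_insole_layout()].
#' @param template data.frame `onset`, `dur`, `amp` per sensor (fractions of
#'   stance, amplitude multipliers), heel to toe; default derived from the
#'   layout's rows.
#' @param seed integer RNG seed.
#' @return A list of class `gait_sim_config`.
#' @export
gait_sim_config <- function(phenotype = c("DWF_LR", "DWF_HR", "RWF"),
                            weak_side = c("left", "right"),
                            total_steps = 222L, cadence = 100, rate = 100,
                            stance_s = 0.8, jitter_cv = 0.05,
                            hr_jitter_mult = 1,
                            atten = 0.55, lr_frac = 0.12,
                            sev_hr = c(0.4, 1), sev_lr = c(0.18, 0.49),
                            sev_rwf = c(0.6, 1), switch_p = 0.15,
                            noise_mult = 0.04, noise_add = 0.01,
                            fatigue_min = 0.12, fatigue_max = 0.2,
                            drift_sd = 0.02, drift_len = 20,
                            amp_scale = 100,
                            layout = default_insole_layout(),
                            template = NULL, seed = 1L) {
  phenotype <- match.arg(phenotype)
  weak_side <- match.arg(weak_side)
  if (atten <= 0 || atten > 1) stop("atten must lie in (0, 1]")
  if (switch_p < 0 || switch_p > 1) stop("switch_p must lie in [0, 1]")
  if (lr_frac < 0 || lr_frac > 1) stop("lr_frac must lie in [0, 1]")
  if (total_steps < 4L) stop("total_steps must be >= 4")
  if (is.null(template)) template <- rollover_template(layout$right)
  if (nrow(template) != layout$right$n)
    stop("template must have one row per sensor")
  structure(list(phenotype = phenotype, weak_side = weak_side,
                 total_steps = as.integer(total_steps), cadence = cadence,
                 rate = rate, stance_s = stance_s, jitter_cv = jitter_cv,
                 hr_jitter_mult = hr_jitter_mult, atten = atten,
                 lr_frac = lr_frac, sev_hr = sev_hr, sev_lr = sev_lr,
                 sev_rwf = sev_rwf, switch_p = switch_p,
                 noise_mult = noise_mult, noise_add = noise_add,
                 fatigue_min = fatigue_min, fatigue_max = fatigue_max,
                 drift_sd = drift_sd, drift_len = drift_len,
                 amp_scale = amp_scale, layout = layout,
                 template = template, seed = as.integer(seed)),
            class = "gait_sim_config")
}

#' Heel-to-toe rollover activation template
#'
#' Maps sensor rows (by anterior-posterior position) to activation onset
#' fractions 0 to 0.55 of stance, fixed duration fraction 0.45, and a
#' loading profile that is strong at heel and toe and lighter midfoot.
#'
#' @param layout a [sensor_layout()].
#' @return data.frame with columns `onset`, `dur`, `amp` (one row per
#'   sensor).
#' @export
rollover_template <- function(layout) {
  y <- layout$coords[, "y"]
  pos <- (y - min(y)) / max(max(y) - min(y), 1e-9)   # 0 heel .. 1 toe
  data.frame(onset = 0.55 * pos,
             dur = rep(0.45, length(y)),
             amp = 0.65 + 0.35 * (2 * abs(pos - 0.45))^1.5)
}

#' Simulate one subject's walk
#'
#' Emits alternating left/right foot contacts per the configuration, with
#' per-sensor pressure bursts, weak-side anterior attenuation gated by the
#' per-step high-risk state, and reproducible noise under the config seed.
#' Pressure is exactly zero outside contact support.
#'
#' @param cfg a [gait_sim_config()].
#' @return A list with `recording` (a [gait_recording()]) and `truth`, a
#'   list holding the programmed per-step contact spans (`steps`: data.frame
#'   `side`, `onset`, `end` frame indices, `state` 0/1 high-risk flag),
#'   `weak_side`, `phenotype` and the fall-risk `label`.
#' @export
simulate_subject <- function(cfg) {
  stopifnot(inherits(cfg, "gait_sim_config"))
  set.seed(cfg$seed)
  n_steps <- cfg$total_steps
  sides <- rep(c("left", "right"), length.out = n_steps)
  if (stats::runif(1) < 0.5) sides <- rev(sides)  # random leading foot

  # per-step high-risk state
  state <- switch(cfg$phenotype,
    DWF_LR = rep(0L, n_steps),
    DWF_HR = rep(1L, n_steps),
    RWF = {
      s <- integer(n_steps)
      s[1] <- stats::rbinom(1, 1, 0.5)
      flip <- stats::runif(n_steps - 1) < cfg$switch_p
      for (i in seq_len(n_steps - 1)) s[i + 1] <- if (flip[i]) 1L - s[i] else s[i]
      s
    })
  label <- if (cfg$phenotype == "DWF_LR") "LR" else "HR"

  step_dt <- 60 / cfg$cadence
  jit <- function(n, cv) pmax(0.4, 1 + stats::rnorm(n, 0, cv))
  hr_weak <- state == 1L & sides == cfg$weak_side
  cv_step <- ifelse(hr_weak, cfg$jitter_cv * cfg$hr_jitter_mult, cfg$jitter_cv)
  onsets_s <- 0.5 + cumsum(c(0, step_dt * jit(n_steps - 1, cv_step[-1])))
  stance_dur <- cfg$stance_s * jit(n_steps, cv_step)
  # keep consecutive same-foot contacts disjoint even under extreme jitter
  for (side in c("left", "right")) {
    i <- which(sides == side)
    if (length(i) > 1) {
      head_i <- i[-length(i)]
      stance_dur[head_i] <- pmin(stance_dur[head_i], 0.9 * diff(onsets_s[i]))
    }
  }
  rate <- cfg$rate
  total_frames <- ceiling((max(onsets_s + stance_dur) + 0.5) * rate)

  n_sens <- cfg$layout$right$n
  press <- list(left = matrix(0, total_frames, n_sens),
                right = matrix(0, total_frames, n_sens))
  anterior <- list(
    left = cfg$layout$left$coords[, "y"] > mean(cfg$layout$left$coords[, "y"]),
    right = cfg$layout$right$coords[, "y"] > mean(cfg$layout$right$coords[, "y"]))
  spans <- matrix(NA_integer_, n_steps, 2)

  # bilateral rollover-depth modulation: monotone fatigue trend + slow drift
  fat <- sample(c(-1, 1), 1) * stats::runif(1, cfg$fatigue_min, cfg$fatigue_max)
  rho <- exp(-1 / cfg$drift_len)
  g <- stats::filter(stats::rnorm(n_steps, 0, sqrt(1 - rho^2)), rho,
                     method = "recursive")
  drift <- 1 + fat * (seq_len(n_steps) / n_steps - 0.5) +
    cfg$drift_sd * as.numeric(g)
  drift <- pmin(1.3, pmax(0.7, drift))

  # per-subject severity: how much of the maximal effect this subject shows
  sev_range <- switch(cfg$phenotype, DWF_LR = cfg$sev_lr,
                      DWF_HR = cfg$sev_hr, RWF = cfg$sev_rwf)
  sev <- stats::runif(1, sev_range[1], sev_range[2])

  for (k in seq_len(n_steps)) {
    side <- sides[k]
    a_eff <- drift[k]
    if (side == cfg$weak_side) {
      expr <- switch(cfg$phenotype,
                     DWF_LR = sev,
                     DWF_HR = sev,
                     RWF = if (state[k] == 1L) sev else sev * cfg$lr_frac)
      a_eff <- a_eff * (1 - (1 - cfg$atten) * expr)
    }
    on_fr <- floor(onsets_s[k] * rate) + 1L
    nfr <- max(4L, round(stance_dur[k] * rate))
    phase <- (seq_len(nfr) - 0.5) / nfr
    onset <- cfg$template$onset
    dur <- cfg$template$dur
    amp <- cfg$template$amp * cfg$amp_scale
    ant <- anterior[[side]]
    # attenuated rollover: anterior load is weaker and briefer
    amp[ant] <- amp[ant] * a_eff
    dur[ant] <- dur[ant] * a_eff
    amp <- amp * pmax(0.05, 1 + stats::rnorm(n_sens, 0, cfg$noise_mult))
    # rollover bursts + a sustained whole-stance component on every sensor;
    # the sustained posterior load keeps the COP a blend of all sensors, so
    # anterior attenuation monotonically shrinks the AP excursion
    burst <- matrix(0, nfr, n_sens)
    sustain <- sin(pi * phase)
    for (j in seq_len(n_sens)) {
      rel <- (phase - onset[j]) / dur[j]
      act <- rel > 0 & rel < 1
      burst[act, j] <- amp[j] * sin(pi * rel[act])
      burst[, j] <- burst[, j] + 0.05 * amp[j] * sustain
    }
    if (cfg$noise_add > 0) {
      # floor at 5% of the clean value so noise cannot zero loaded frames
      # (keeps each contact's support contiguous)
      act <- burst > 0
      burst[act] <- pmax(0.05 * burst[act], burst[act] +
        stats::rnorm(sum(act), 0, cfg$noise_add * cfg$amp_scale))
    }
    rows <- on_fr:(on_fr + nfr - 1L)
    press[[side]][rows, ] <- press[[side]][rows, ] + burst
    sup <- which(rowSums(burst) > 0)
    spans[k, ] <- c(on_fr + sup[1] - 1L, on_fr + sup[length(sup)] - 1L)
  }

  rec <- gait_recording(sprintf("sim%06d", cfg$seed %% 1000000L),
                        press$left, press$right, rate, cfg$layout,
                        label = label,
                        meta = list(phenotype = cfg$phenotype,
                                    weak_side = cfg$weak_side))
  truth <- list(steps = data.frame(side = sides, onset = spans[, 1],
                                   end = spans[, 2], state = state,
                                   stringsAsFactors = FALSE),
                weak_side = cfg$weak_side, phenotype = cfg$phenotype,
                label = label, severity = sev)
  list(recording = rec, truth = truth)
}

#' Simulate a cohort
#'
#' Independent subjects with per-subject seeds derived from one master
#' seed; weak sides are randomized per subject. The fall-risk label is LR
#' for `DWF_LR` subjects and HR for `DWF_HR` and `RWF` subjects, so a
#' `(n, n, 0)` design gives a balanced low/high-risk cohort without
#' episodic individuals.
#'
#' @param n_dwf_lr,n_dwf_hr,n_rwf subjects per phenotype cell.
#' @param seed master seed.
#' @param ... shared [gait_sim_config()] overrides (e.g. `total_steps`,
#'   `atten`).
#' @return A list of `simulate_subject()` results; subject ids are
#'   `"LRnn"`, `"HRnn"`, `"RWFnn"`.
#' @export
simulate_cohort <- function(n_dwf_lr, n_dwf_hr, n_rwf, seed = 1L, ...) {
  cells <- c(rep("DWF_LR", n_dwf_lr), rep("DWF_HR", n_dwf_hr),
             rep("RWF", n_rwf))
  ids <- c(sprintf("LR%02d", seq_len(n_dwf_lr)),
           sprintf("HR%02d", seq_len(n_dwf_hr)),
           sprintf("RWF%02d", seq_len(n_rwf)))
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(cells))
  weak <- sample(c("left", "right"), length(cells), replace = TRUE)
  lapply(seq_along(cells), function(i) {
    cfg <- gait_sim_config(phenotype = cells[i], weak_side = weak[i],
                           seed = sub_seeds[i], ...)
    out <- simulate_subject(cfg)
    out$recording$subject_id <- ids[i]
    out
  })
}
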