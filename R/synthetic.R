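#' Effect specification for the synthetic cohort generator
#'
#' Controls the group differences imposed on the affected group (group A,
#' labelled `"case"`). Defaults emulate Parkinsonian-like gait alterations:
#' reduced distal movement amplitude (bradykinesia-like), added postural
#' drift (positional variability), a stronger shared trunk/head oscillator
#' (more centralized proximal coupling), and weakened arm-leg shared-phase
#' amplitude (interlimb decoupling).
#'
#' Each field at its null value makes the two groups exchangeable in
#' distribution (apart from the demographic age/sex differences, which do
#' not enter the signals). `distal_speed_scale` is multiplicative, so its
#' null value is 1; a value of 0 is also accepted as "disabled" (no
#' scaling), so that an all-zero specification is a valid null. All other
#' fields are additive with null value 0.
#'
#' @param distal_speed_scale Multiplicative factor on foot/toe/hand
#'   oscillation amplitude in the affected group; values in (0, 1) attenuate
#'   distal movement; 0 or 1 disable the effect.
#' @param positional_drift_sd Per-sample standard deviation (m) of a shared
#'   whole-body random-walk drift added to affected subjects.
#' @param proximal_coupling_gain Extra weight of the shared trunk/head
#'   latent oscillator in the affected group (added to a common baseline).
#' @param interlimb_decoupling Fractional reduction of the arm-leg
#'   shared-phase oscillator weight in the affected group, in \[0, 1\].
#' @param severity_noise_sd Noise on the clinical scores, expressed as a
#'   fraction of each score's nominal SD.
#' @return An `EffectSpec` (named list).
#' @export
effect_spec <- function(distal_speed_scale = 0.6,
                        positional_drift_sd = 0.008,
                        proximal_coupling_gain = 0.5,
                        interlimb_decoupling = 0.5,
                        severity_noise_sd = 0.3) {
  vals <- list(distal_speed_scale = distal_speed_scale,
               positional_drift_sd = positional_drift_sd,
               proximal_coupling_gain = proximal_coupling_gain,
               interlimb_decoupling = interlimb_decoupling,
               severity_noise_sd = severity_noise_sd)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop("effect field ", nm, " must be a single nonnegative number",
           call. = FALSE)
    }
  }
  if (interlimb_decoupling > 1) {
    stop("interlimb_decoupling must lie in [0, 1]", call. = FALSE)
  }
  structure(vals, class = "EffectSpec")
}

#' Null effect specification
#'
#' Convenience constructor for the no-effect condition under which the two
#' groups are exchangeable in distribution.
#'
#' @return An `EffectSpec` with every effect disabled.
#' @export
null_effects <- function() {
  effect_spec(distal_speed_scale = 1, positional_drift_sd = 0,
              proximal_coupling_gain = 0, interlimb_decoupling = 0,
              severity_noise_sd = 0.3)
}

#' Cohort specification for the synthetic generator
#'
#' @param n_group_a Number of affected subjects (group `"case"`).
#' @param n_group_b Number of control subjects (group `"control"`).
#' @param n_segments Number of body segments (prefix of [body_segments()];
#'   default all 23).
#' @param fs Sampling rate in Hz (default 100; must exceed twice the 10 Hz
#'   low-pass cutoff used downstream).
#' @param duration Recording length in seconds (default 15;
#'   `duration * fs` must be at least 256 samples).
#' @param effect An [effect_spec()].
#' @param seed Integer seed; the generator is fully deterministic given the
#'   specification.
#' @return A `CohortSpec` (named list).
#' @export
cohort_spec <- function(n_group_a = 25, n_group_b = 25, n_segments = 23,
                        fs = 100, duration = 15, effect = effect_spec(),
                        seed = 1L) {
  if (n_group_a < 1 || n_group_b < 1) {
    stop("group counts must be >= 1", call. = FALSE)
  }
  if (n_segments < 2 || n_segments > 23) {
    stop("n_segments must lie in [2, 23]", call. = FALSE)
  }
  if (fs <= 20) {
    stop("fs must exceed twice the 10 Hz low-pass cutoff", call. = FALSE)
  }
  if (duration * fs < 256) {
    stop("duration * fs must be at least 256 samples", call. = FALSE)
  }
  if (!inherits(effect, "EffectSpec")) {
    stop("effect must be an EffectSpec (see effect_spec())", call. = FALSE)
  }
  structure(list(n_group_a = as.integer(n_group_a),
                 n_group_b = as.integer(n_group_b),
                 n_segments = as.integer(n_segments), fs = fs,
                 duration = duration, effect = effect,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic gait cohort
#'
#' Simulates multi-segment 3D position recordings for two groups. Each
#' segment's position is the sum of a segment-specific anatomical offset, a
#' gait oscillator (subject-specific fundamental near 1 Hz plus two
#' harmonics, segment-specific amplitude and phase, left/right limbs in
#' anti-phase and arms in anti-phase with their ipsilateral legs), shared
#' latent oscillators implementing trunk/head and arm-leg coupling, white
#' measurement noise, and (for affected subjects) an optional whole-body
#' random-walk drift. Group effects are scaled per subject by a latent
#' severity, which also generates the clinical scores of affected subjects
#' via [generate_clinical_scores()].
#'
#' Demographics are sampled per group from the normal/binomial
#' approximations of a typical patient/control cohort (cases older, more
#' often male); the demographic sampling is independent of the signals, so
#' with null effects the group labels are exchangeable with respect to all
#' kinematic features.
#'
#' @param spec A [cohort_spec()].
#' @return A cohort: list with `recordings` (list of `SegmentRecording`) and
#'   `metadata` (data.frame with `subject_id`, `group`, `age`, `sex`
#'   (1 = male), `fs`, latent `severity`, and clinical score columns, `NA`
#'   for controls).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "CohortSpec")) {
    stop("spec must be a CohortSpec (see cohort_spec())", call. = FALSE)
  }
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  eff <- spec$effect
  tpl <- segment_template()[seq_len(spec$n_segments), ]
  n_a <- spec$n_group_a
  n_b <- spec$n_group_b
  n <- n_a + n_b
  tt <- seq(0, spec$duration - 1 / spec$fs, by = 1 / spec$fs)
  T_len <- length(tt)

  group <- c(rep("case", n_a), rep("control", n_b))
  ids <- sprintf("S%03d", seq_len(n))

  # demographics: cases older and more often male, matching a typical
  # clinic-recruited patient group vs. community controls
  age <- ifelse(group == "case",
                rnorm(n, 69.6, 8.67), rnorm(n, 51.3, 17.03))
  age <- pmin(pmax(age, 25), 95)
  sex <- ifelse(group == "case",
                rbinom(n, 1, 37 / 51), rbinom(n, 1, 19 / 53))
  severity <- rnorm(n)
  # per-subject effect intensity in (0.5, 1.5), monotone in severity
  intensity <- 0.5 + pnorm(severity)

  # base oscillation amplitude per segment (m): distal segments move most,
  # comparable to the vertical spacing between adjacent segments so that
  # neighbouring amplitude distributions overlap partially
  base_amp <- ifelse(tpl$distal, 0.30,
                     ifelse(tpl$limb == "arm", 0.18,
                            ifelse(tpl$limb == "leg", 0.22, 0.11)))
  # gait phase per segment: right leg reference, left leg anti-phase,
  # arms anti-phase with ipsilateral legs
  seg_phase <- numeric(nrow(tpl))
  seg_phase[tpl$side == "left" & tpl$limb == "leg"] <- pi
  seg_phase[tpl$side == "right" & tpl$limb == "arm"] <- pi
  seg_phase[tpl$side == "left" & tpl$limb == "arm"] <- 0
  harm_amp <- c(1, 0.4, 0.15)
  # per-axis oscillation gain/phase and projection of the shared latent
  # oscillators; the vertical axis carries a first-order contribution to
  # the position magnitude for axial segments (whose lateral offsets are 0)
  ax_amp <- c(x = 1, y = 0.3, z = 0.8)
  ax_phase <- c(x = 0, y = pi / 3, z = pi / 2)
  sh_w <- c(x = 0.6, y = 0.2, z = 0.8)

  scale0 <- eff$distal_speed_scale
  distal_on <- scale0 > 0 && scale0 != 1

  recordings <- vector("list", n)
  clin_rows <- vector("list", n)
  for (k in seq_len(n)) {
    is_case <- group[k] == "case"
    m_k <- intensity[k]
    f0 <- min(max(rnorm(1, 1.0, 0.08), 0.7), 1.3)
    phi <- runif(1, 0, 2 * pi)

    # shared latent oscillators (common across segments of this subject)
    trunk_lat <- sin(2 * pi * f0 * tt + phi + 0.7) +
      0.3 * sin(4 * pi * f0 * tt + phi)
    armleg_lat <- sin(2 * pi * f0 * tt + phi + 1.9)
    g_prox <- 0.03 + if (is_case) 0.08 * eff$proximal_coupling_gain * m_k else 0
    w_al <- 0.12 * (1 - if (is_case) min(eff$interlimb_decoupling * m_k, 1) else 0)

    drift <- NULL
    if (is_case && eff$positional_drift_sd > 0) {
      sd_step <- eff$positional_drift_sd * m_k
      drift <- cbind(cumsum(rnorm(T_len, 0, sd_step)),
                     cumsum(rnorm(T_len, 0, sd_step)),
                     cumsum(rnorm(T_len, 0, sd_step)))
    }

    series <- vector("list", nrow(tpl))
    names(series) <- tpl$segment
    for (si in seq_len(nrow(tpl))) {
      amp <- base_amp[si]
      if (is_case && distal_on && tpl$distal[si]) {
        amp <- amp * max(1 - (1 - scale0) * m_k, 0.05)
      }
      shared <- numeric(T_len)
      if (tpl$proximal[si]) shared <- shared + g_prox * trunk_lat
      if (tpl$limb[si] %in% c("arm", "leg")) {
        shared <- shared + w_al * armleg_lat
      }
      xyz <- vapply(c("x", "y", "z"), function(axn) {
        off <- if (axn == "x") tpl$x[si] else if (axn == "z") tpl$z[si] else 0
        osc_ax <- harmonic_stack(f0, tt, phi + seg_phase[si],
                                 ax_phase[[axn]], harm_amp)
        off + ax_amp[[axn]] * amp * osc_ax + sh_w[[axn]] * shared +
          rnorm(T_len, 0, 0.01)
      }, numeric(T_len))
      if (!is.null(drift)) xyz <- xyz + drift
      series[[si]] <- unname(xyz)
    }
    recordings[[k]] <- structure(list(
      subject_id = ids[k], group = group[k], age = age[k], sex = sex[k],
      clinical = NULL, fs = spec$fs, series = series
    ), class = "SegmentRecording")
  }

  clin <- generate_clinical_scores(severity[seq_len(n_a)], eff)
  clin_full <- as.data.frame(lapply(clin, function(col) {
    c(col, rep(NA_real_, n_b))
  }))
  metadata <- data.frame(
    subject_id = ids, group = group, age = age, sex = sex, fs = spec$fs,
    severity = severity, stringsAsFactors = FALSE
  )
  metadata <- cbind(metadata, clin_full)
  for (k in seq_len(n_a)) {
    recordings[[k]]$clinical <- as.list(clin_full[k, ])
  }
  names(recordings) <- ids
  list(recordings = recordings, metadata = metadata)
}

# Fundamental plus two harmonics with a per-axis phase offset, so each axis
# oscillates coherently but not identically.
harmonic_stack <- function(f0, tt, phase, ax_phase, harm_amp) {
  rowSums(vapply(1:3, function(h) {
    harm_amp[h] * sin(2 * pi * h * f0 * tt + h * phase + ax_phase)
  }, numeric(length(tt))))
}

#' Generate clinical scores from a latent severity
#'
#' Maps a per-subject latent severity (standard-normal scale) to clinical
#' score columns through affine functions with positive slopes anchored to
#' typical patient-cohort moments, adds noise proportional to each score's
#' nominal SD (`severity_noise_sd`), and clips to plausible ranges
#' (stage score in \[0, 5\], subscores nonnegative). With zero noise every
#' score is a monotone non-decreasing function of severity.
#'
#' @param latent_severity Numeric vector of latent severities (finite).
#' @param effect An [effect_spec()]; only `severity_noise_sd` is used.
#' @return data.frame of clinical score columns, one row per subject.
#' @export
generate_clinical_scores <- function(latent_severity, effect = effect_spec()) {
  if (!all(is.finite(latent_severity))) {
    stop("latent severity must be finite", call. = FALSE)
  }
  z <- latent_severity
  nsd <- effect$severity_noise_sd
  n <- length(z)
  mk <- function(mean, sd, lo, hi) {
    pmin(pmax(mean + sd * z + rnorm(n, 0, nsd * sd), lo), hi)
  }
  data.frame(
    mds_updrs_total = mk(29.9, 19.0, 0, 200),
    mds_updrs_iii = mk(17.0, 11.0, 0, 132),
    hy_stage = mk(1.54, 0.60, 0, 5),
    disease_duration = mk(7.6, 4.49, 0.5, 40),
    disease_onset = mk(62.0, 8.96, 25, 90),
    bradykinesia_left = mk(2.91, 3.39, 0, 40),
    bradykinesia_right = mk(3.08, 3.22, 0, 40),
    rigidity_left = mk(0.94, 0.94, 0, 20),
    rigidity_right = mk(1.13, 1.19, 0, 20),
    tremor_left = mk(0.61, 1.37, 0, 40),
    tremor_right = mk(0.74, 1.15, 0, 40),
    total_left = mk(4.46, 4.80, 0, 60),
    total_right = mk(4.95, 4.62, 0, 60)
  )
}
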