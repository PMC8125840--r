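# Synthetic 5xSTS cohort generator. Recordings are built from a smooth
# parametric waveform model (raised-cosine segment-pitch transitions,
# smoothstep vertical rise) so that every downstream kinematic quantity has
# a closed form available for recovery tests; a direct feature-table
# generator bypasses waveforms for statistical unit tests.

# movement phase fractions within one stand-sit cycle
.PHASE_RISE <- 0.4
.PHASE_DWELL <- 0.2

# seated conventions (pitch from vertical, rad)
.THIGH_SEATED <- 1.40
.SHANK_BASE <- 0.35
.SHANK_MOD <- 0.08

#' Specify a synthetic 5xSTS cohort
#'
#' Defines group sizes, the random seed, the sampling rate and the
#' standardized group-difference profile applied to the frail group's
#' movement parameters. Defaults emulate a cohort of 42 robust and 60
#' pre-frail/frail community-dwelling older adults recorded at 100 Hz,
#' with the frail group slower (longer cycles), slightly smaller in
#' movement amplitude, weaker vertically and more variable cycle-to-cycle.
#'
#' @param n_robust,n_frail Group sizes (total >= 4).
#' @param seed Integer seed; identical specs generate identical cohorts.
#' @param sampling_rate Sampling rate in Hz.
#' @param effects Named numeric vector of standardized shifts (frail minus
#'   robust, in between-subject SD units) on the generator parameter
#'   families `timing` (cycle duration), `amplitude` (thigh/trunk
#'   excursion), `vertical` (vertical rise) and `variability`
#'   (cycle-to-cycle CV).
#' @param noise_sd Additive white measurement noise SD on the angle
#'   channels (rad).
#' @return A `cohort_spec` object.
#' @export
#' @examples
#' spec <- cohort_spec(n_robust = 5, n_frail = 5, seed = 7)
cohort_spec <- function(n_robust = 42, n_frail = 60, seed = 1L,
                        sampling_rate = 100,
                        effects = default_profile_effects(),
                        noise_sd = 0.01) {
  if (n_robust + n_frail < 4) rlang::abort("Need at least 4 subjects in total.")
  if (sampling_rate <= 0) rlang::abort("`sampling_rate` must be positive.")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  bad <- setdiff(names(effects), c("timing", "amplitude", "vertical", "variability"))
  if (length(bad)) rlang::abort(paste("Unknown effect families:", paste(bad, collapse = ", ")))
  structure(
    list(n_robust = as.integer(n_robust), n_frail = as.integer(n_frail),
         seed = as.integer(seed), sampling_rate = sampling_rate,
         effects = effects, noise_sd = noise_sd),
    class = "cohort_spec"
  )
}

#' Default standardized frail-vs-robust shifts on movement parameters
#'
#' Frail subjects draw longer cycle durations (+1 SD), marginally smaller
#' pitch excursions (-0.3 SD), a lower vertical rise (-0.8 SD) and higher
#' cycle-to-cycle variability (+1.5 SD). Feature-level group differences
#' (slower velocities, lower powers, higher CVs) emerge from these through
#' the extraction stage.
#'
#' @return Named numeric vector of standardized shifts.
#' @export
default_profile_effects <- function() {
  c(timing = 1.0, amplitude = -0.3, vertical = -0.8, variability = 1.5)
}

# robust-group baselines (mean, between-subject sd) for movement parameters
.profile_baselines <- list(
  cycle_duration = c(1.20, 0.15),   # s
  pause_duration = c(0.30, 0.05),   # s
  thigh_amplitude = c(1.30, 0.10),  # rad
  trunk_lean = c(0.35, 0.05),       # rad
  vertical_rise = c(0.25, 0.03),    # m
  cycle_cv = c(0.05, 0.015)         # dimensionless
)

# group-specific anthropometrics (mean, sd): pre-frail/frail heavier
.anthro_baselines <- list(
  mass = list(`0` = c(66.8, 12.2), `1` = c(78.6, 19.9)),   # kg
  height = list(`0` = c(1.62, 0.073), `1` = c(1.65, 0.108)) # m
)

#' Construct a subject movement profile
#'
#' Validates the invariants of a per-subject parameter set for the 5xSTS
#' waveform generator.
#'
#' @param group Frailty status, 0 (robust) or 1 (pre-frail/frail).
#' @param mass,height Body mass (kg) and height (m), > 0.
#' @param cycle_duration Mean per-cycle movement duration (s), > 0.
#' @param pause_duration Seated pause between cycles (s), >= 0.
#' @param thigh_amplitude Seated-to-standing thigh pitch excursion (rad).
#' @param trunk_lean Peak forward trunk lean per cycle (rad).
#' @param vertical_rise Vertical trunk displacement per stand (m).
#' @param cycle_cv Relative SD of per-cycle duration/amplitude jitter,
#'   in `[0, 1)`.
#' @param noise_sd Additive angle noise SD (rad), >= 0.
#' @return A `subject_profile` object.
#' @export
subject_profile <- function(group, mass = 70, height = 1.65,
                            cycle_duration = 1.2, pause_duration = 0.3,
                            thigh_amplitude = 1.3, trunk_lean = 0.35,
                            vertical_rise = 0.25, cycle_cv = 0.05,
                            noise_sd = 0.01) {
  if (!group %in% c(0, 1)) rlang::abort("`group` must be 0 (robust) or 1 (frail).")
  if (mass <= 0 || height <= 0) rlang::abort("`mass` and `height` must be positive.")
  if (cycle_duration <= 0) rlang::abort("`cycle_duration` must be positive.")
  if (pause_duration < 0) rlang::abort("`pause_duration` must be non-negative.")
  if (cycle_cv < 0 || cycle_cv >= 1) rlang::abort("`cycle_cv` must be in [0, 1).")
  if (noise_sd < 0) rlang::abort("`noise_sd` must be non-negative.")
  structure(
    list(group = as.integer(group), mass = mass, height = height,
         cycle_duration = cycle_duration, pause_duration = pause_duration,
         thigh_amplitude = thigh_amplitude, trunk_lean = trunk_lean,
         vertical_rise = vertical_rise, cycle_cv = cycle_cv,
         noise_sd = noise_sd),
    class = "subject_profile"
  )
}

#' Draw a random subject profile for one cohort member
#'
#' Parameters are drawn from Gaussian between-subject distributions; frail
#' subjects' means are shifted by the spec's standardized effect profile.
#' Each subject uses a private sub-stream derived from the cohort seed and
#' the subject counter, so adding subjects never perturbs earlier ones.
#'
#' @param spec A [cohort_spec()].
#' @param group 0 or 1.
#' @param counter Subject counter within the cohort (1-based).
#' @return A [subject_profile()] object.
#' @export
draw_subject_profile <- function(spec, group, counter = 1L) {
  if (!group %in% c(0, 1)) rlang::abort("`group` must be 0 (robust) or 1 (frail).")
  eff <- function(fam) if (fam %in% names(spec$effects)) spec$effects[[fam]] else 0
  bl <- .profile_baselines
  withr::with_seed(.derive_seed(spec$seed, counter), {
    mass_b <- .anthro_baselines$mass[[as.character(group)]]
    height_b <- .anthro_baselines$height[[as.character(group)]]
    draw <- function(b, shift = 0) stats::rnorm(1, b[1] + shift * b[2], b[2])
    subject_profile(
      group = group,
      mass = max(35, draw(mass_b)),
      height = max(1.3, draw(height_b)),
      cycle_duration = max(0.4, draw(bl$cycle_duration, group * eff("timing"))),
      pause_duration = max(0.10, draw(bl$pause_duration)),
      thigh_amplitude = max(0.30, draw(bl$thigh_amplitude, group * eff("amplitude"))),
      trunk_lean = max(0.05, draw(bl$trunk_lean, group * eff("amplitude"))),
      vertical_rise = max(0.05, draw(bl$vertical_rise, group * eff("vertical"))),
      cycle_cv = min(0.9, max(0, draw(bl$cycle_cv, group * eff("variability")))),
      noise_sd = spec$noise_sd
    )
  })
}

# --- waveform primitives -------------------------------------------------

# movement shape s(u) on u in [0,1]: raised-cosine rise, dwell, raised-cosine
# return; s = 0 seated, s = 1 standing
.shape_cos <- function(u) {
  r <- .PHASE_RISE; dw <- .PHASE_DWELL
  s <- numeric(length(u))
  q <- u / r
  i <- u >= 0 & u < r
  s[i] <- (1 - cos(pi * q[i])) / 2
  s[u >= r & u <= r + dw] <- 1
  q2 <- (u - r - dw) / r
  i <- u > r + dw & u <= 1
  s[i] <- (1 + cos(pi * q2[i])) / 2
  s
}

.shape_cos_deriv <- function(u) { # ds/du
  r <- .PHASE_RISE; dw <- .PHASE_DWELL
  d <- numeric(length(u))
  i <- u >= 0 & u < r
  d[i] <- (pi / (2 * r)) * sin(pi * u[i] / r)
  i <- u > r + dw & u <= 1
  d[i] <- -(pi / (2 * r)) * sin(pi * (u[i] - r - dw) / r)
  d
}

# smoothstep variant for the vertical rise
.shape_smooth <- function(u) {
  r <- .PHASE_RISE; dw <- .PHASE_DWELL
  s <- numeric(length(u))
  q <- u / r
  i <- u >= 0 & u < r
  s[i] <- q[i]^2 * (3 - 2 * q[i])
  s[u >= r & u <= r + dw] <- 1
  q2 <- (u - r - dw) / r
  i <- u > r + dw & u <= 1
  s[i] <- 1 - q2[i]^2 * (3 - 2 * q2[i])
  s
}

.shape_smooth_deriv <- function(u) {
  r <- .PHASE_RISE; dw <- .PHASE_DWELL
  d <- numeric(length(u))
  q <- u / r
  i <- u >= 0 & u < r
  d[i] <- 6 * q[i] * (1 - q[i]) / r
  q2 <- (u - r - dw) / r
  i <- u > r + dw & u <= 1
  d[i] <- -6 * q2[i] * (1 - q2[i]) / r
  d
}

# forward-lean pulse for the trunk, one pulse per cycle
.shape_lean <- function(u) sin(pi * pmin(pmax(u, 0), 1))^2
.shape_lean_deriv <- function(u) {
  d <- pi * sin(2 * pi * u)
  d[u < 0 | u > 1] <- 0
  d
}

# evaluate all noiseless channels (and time-derivatives if wanted) at times t
# given a cycle schedule: tibble(start_s, duration_s, amp_factor)
.eval_channels <- function(t, schedule, profile, deriv = FALSE) {
  trunk <- numeric(length(t))
  sc <- numeric(length(t))   # cosine shape accumulated
  sv <- numeric(length(t))   # smoothstep shape accumulated
  dtrunk <- dsc <- dsv <- numeric(length(t))
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start_s[i]; d <- schedule$duration_s[i]; fa <- schedule$amp_factor[i]
    u <- (t - t0) / d
    inside <- u >= 0 & u <= 1
    if (!any(inside)) next
    ui <- u[inside]
    sc[inside] <- sc[inside] + fa * .shape_cos(ui)
    sv[inside] <- sv[inside] + fa * .shape_smooth(ui)
    trunk[inside] <- trunk[inside] + fa * .shape_lean(ui)
    if (deriv) {
      dsc[inside] <- dsc[inside] + fa * .shape_cos_deriv(ui) / d
      dsv[inside] <- dsv[inside] + fa * .shape_smooth_deriv(ui) / d
      dtrunk[inside] <- dtrunk[inside] + fa * .shape_lean_deriv(ui) / d
    }
  }
  out <- list(
    trunk = profile$trunk_lean * trunk,
    thigh = .THIGH_SEATED - profile$thigh_amplitude * sc,
    shank = .SHANK_BASE + .SHANK_MOD * sc,
    vert = profile$vertical_rise * sv
  )
  if (deriv) {
    out$dtrunk <- profile$trunk_lean * dtrunk
    out$dthigh <- -profile$thigh_amplitude * dsc
    out$dshank <- .SHANK_MOD * dsc
    out$dvert <- profile$vertical_rise * dsv
  }
  out
}

# per-cycle schedule for a profile: jittered durations/amplitudes snapped to
# the sample grid so that jitter-free cohorts have bit-identical cycles
.make_schedule <- function(profile, sampling_rate, lead = 1.0) {
  snap <- function(x) round(x * sampling_rate) / sampling_rate
  durs <- pmax(0.2 * profile$cycle_duration,
               profile$cycle_duration * (1 + profile$cycle_cv * stats::rnorm(5)))
  amps <- pmax(0.2, 1 + profile$cycle_cv * stats::rnorm(5))
  durs <- snap(durs)
  starts <- numeric(5)
  starts[1] <- snap(lead)
  for (i in 2:5) starts[i] <- snap(starts[i - 1] + durs[i - 1] + profile$pause_duration)
  tibble::tibble(cycle = 1:5, start_s = starts, duration_s = durs, amp_factor = amps)
}

#' Generate one synthetic 5xSTS recording
#'
#' Produces sampled trunk/thigh/shank pitch and vertical-displacement
#' series containing exactly five stand-sit cycles: raised-cosine thigh
#' transitions between seated and standing pitch, a forward trunk-lean
#' pulse per cycle, a small shank modulation and a smoothstep vertical
#' rise. Per-cycle durations and amplitudes are jittered with relative SD
#' `cycle_cv`; white noise of SD `noise_sd` is added to the angle channels.
#'
#' @param profile A [subject_profile()].
#' @param seed Integer seed for the jitter and noise draws.
#' @param sampling_rate Sampling rate in Hz.
#' @param subject_id Optional subject identifier carried on the object.
#' @return An `sts_recording`: list with `data` (tibble with columns
#'   `time_s`, `trunk_pitch_rad`, `thigh_pitch_rad`, `shank_pitch_rad`,
#'   `vert_disp_m`), `sampling_rate`, `mass`, `height`, `status`,
#'   `subject_id` and the generating `cycles` schedule.
#' @export
#' @examples
#' rec <- generate_recording(subject_profile(0, cycle_cv = 0, noise_sd = 0), seed = 1)
#' nrow(rec$cycles)
generate_recording <- function(profile, seed = 1L, sampling_rate = 100,
                               subject_id = NA_character_) {
  stopifnot(inherits(profile, "subject_profile"))
  withr::with_seed(.derive_seed(seed, 0L), {
    sched <- .make_schedule(profile, sampling_rate)
    t_end <- sched$start_s[5] + sched$duration_s[5] + profile$pause_duration + 1.0
    t <- seq(0, t_end, by = 1 / sampling_rate)
    ch <- .eval_channels(t, sched, profile)
    if (profile$noise_sd > 0) {
      ch$trunk <- ch$trunk + stats::rnorm(length(t), 0, profile$noise_sd)
      ch$thigh <- ch$thigh + stats::rnorm(length(t), 0, profile$noise_sd)
      ch$shank <- ch$shank + stats::rnorm(length(t), 0, profile$noise_sd)
    }
    structure(
      list(
        data = tibble::tibble(
          time_s = t,
          trunk_pitch_rad = ch$trunk,
          thigh_pitch_rad = ch$thigh,
          shank_pitch_rad = ch$shank,
          vert_disp_m = ch$vert
        ),
        sampling_rate = sampling_rate,
        mass = profile$mass, height = profile$height,
        status = profile$group, subject_id = subject_id,
        profile = profile, cycles = sched
      ),
      class = "sts_recording"
    )
  })
}

#' Closed-form per-cycle kinematic ground truth for a recording
#'
#' Evaluates the recording's generating waveform and its analytic time
#' derivatives on a 20x oversampled grid, returning the true per-cycle
#' duration and the true ranges of hip/knee angle, hip/knee angular
#' velocity, vertical velocity and vertical displacement. Serves as the
#' independent oracle for feature-recovery tests.
#'
#' @param recording An `sts_recording` produced by [generate_recording()].
#' @return Tibble with one row per cycle.
#' @export
recording_truth <- function(recording) {
  stopifnot(inherits(recording, "sts_recording"))
  prof <- recording$profile
  sched <- recording$cycles
  fs <- recording$sampling_rate
  purrr::map_dfr(seq_len(nrow(sched)), function(i) {
    t <- seq(sched$start_s[i], sched$start_s[i] + sched$duration_s[i],
             by = 1 / (20 * fs))
    ch <- .eval_channels(t, sched[i, ], prof, deriv = TRUE)
    hip <- ch$trunk - ch$thigh
    knee <- ch$thigh - ch$shank
    dhip <- ch$dtrunk - ch$dthigh
    dknee <- ch$dthigh - ch$dshank
    tibble::tibble(
      cycle = i,
      duration_s = sched$duration_s[i],
      hip_angle_range = diff(range(hip)),
      knee_angle_range = diff(range(knee)),
      hip_angular_velocity_range = diff(range(dhip)),
      knee_angular_velocity_range = diff(range(dknee)),
      vertical_velocity_range = diff(range(ch$dvert)),
      vertical_disp_range = diff(range(ch$vert))
    )
  })
}

#' Simulate a full synthetic cohort of 5xSTS recordings
#'
#' Draws one movement profile per subject (robust subjects first) and
#' generates each recording from a subject-specific sub-stream of the
#' cohort seed, so the cohort is a pure function of its spec.
#'
#' @param spec A [cohort_spec()].
#' @return List with `recordings` (list of `sts_recording`) and `manifest`
#'   (tibble: subject_id, status, mass_kg, height_m).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep(0L, spec$n_robust), rep(1L, spec$n_frail))
  ids <- sprintf("S%03d", seq_along(groups))
  recs <- purrr::map(seq_along(groups), function(i) {
    prof <- draw_subject_profile(spec, groups[i], counter = i)
    generate_recording(prof, seed = .derive_seed(spec$seed, 1000L + i),
                       sampling_rate = spec$sampling_rate, subject_id = ids[i])
  })
  manifest <- tibble::tibble(
    subject_id = ids, status = groups,
    mass_kg = purrr::map_dbl(recs, "mass"),
    height_m = purrr::map_dbl(recs, "height")
  )
  list(recordings = recs, manifest = manifest)
}

#' Simulate a subject-by-feature table directly
#'
#' Fast parametric path that emits the 17 named features from independent
#' Gaussian between-subject distributions, bypassing waveforms. Frail
#' subjects' feature means are shifted by `effects` (standardized units of
#' the between-subject SD); unshifted features are exchangeable between
#' groups. Intended for statistical unit tests of the screening and
#' selection stages with exactly known ground truth.
#'
#' @param n_robust,n_frail Group sizes, each >= 2.
#' @param seed Integer seed.
#' @param effects Named numeric vector of standardized shifts (frail minus
#'   robust); names must be a subset of `features`.
#' @param features Feature columns to generate (default the canonical 17).
#'   Features without a baseline entry use mean 0, SD 1.
#' @return Tibble with columns `subject_id`, `status` and one column per
#'   feature; `n_robust + n_frail` rows.
#' @export
#' @examples
#' tbl <- simulate_feature_table(n_robust = 42, n_frail = 60, seed = 1)
#' nrow(tbl)
simulate_feature_table <- function(n_robust = 42, n_frail = 60, seed = 1L,
                                   effects = default_feature_effects(),
                                   features = sts_feature_names()) {
  if (n_robust < 2 || n_frail < 2) rlang::abort("Need at least 2 subjects per group.")
  bad <- setdiff(names(effects), features)
  if (length(bad)) rlang::abort(paste("Effects on unknown features:", paste(bad, collapse = ", ")))
  base <- .sts_feature_baselines()
  n <- n_robust + n_frail
  status <- c(rep(0L, n_robust), rep(1L, n_frail))
  withr::with_seed(as.integer(seed), {
    cols <- purrr::map(features, function(f) {
      b <- base[base$feature == f, ]
      mu <- if (nrow(b)) b$mean else 0
      sdv <- if (nrow(b)) b$sd else 1
      shift <- if (f %in% names(effects)) effects[[f]] else 0
      stats::rnorm(n, mu + status * shift * sdv, sdv)
    })
  })
  names(cols) <- features
  dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%03d", seq_len(n)), status = status),
    tibble::as_tibble(cols)
  )
}

#' @export
print.sts_recording <- function(x, ...) {
  cat(sprintf(
    "<sts_recording> %s: %d samples at %g Hz (%.1f s), mass %.1f kg, height %.2f m, status %d\n",
    ifelse(is.na(x$subject_id), "?", x$subject_id), nrow(x$data),
    x$sampling_rate, max(x$data$time_s), x$mass, x$height, x$status
  ))
  invisible(x)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d robust + %d frail at %g Hz, seed %d\n",
              x$n_robust, x$n_frail, x$sampling_rate, x$seed))
  invisible(x)
}
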