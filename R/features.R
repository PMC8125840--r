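# Cycle segmentation and extraction of the 17 sensor-derived features from
# a 5xSTS recording.

#' Segment a 5xSTS recording into stand-sit cycles
#'
#' Hysteresis thresholding of the thigh pitch: the low-pass-filtered signal
#' is normalized to its global amplitude, and a standing episode opens when
#' the normalized pitch drops below the 40% band and closes when it returns
#' above the 60% band (the nominal switching point is the 50% amplitude
#' level). Each episode's bounds are then refined outward on the RAW signal
#' to the last/first samples still at the seated baseline, with a tolerance
#' of five noise SDs (noise estimated from the seated plateau), so that on
#' clean signals the interval spans the full seated-to-seated movement to
#' within one sample.
#'
#' @param recording An `sts_recording`.
#' @param min_amplitude Minimum thigh-pitch amplitude (rad) below which the
#'   trial is declared movement-free.
#' @return An `sts_cycles` object: list with `intervals` (tibble of
#'   half-open sample-index intervals `start`, `end`), `n_cycles`, `valid`
#'   (exactly 5 cycles), `onset`, `offset` and `duration_s`
#'   (= (offset - onset) / sampling_rate).
#' @export
segment_cycles <- function(recording, min_amplitude = 0.1) {
  stopifnot(inherits(recording, "sts_recording"))
  th <- recording$data$thigh_pitch_rad
  fs <- recording$sampling_rate
  n <- length(th)
  if (n < 2) rlang::abort("Recording too short to segment.")

  ths <- lowpass_zerophase(th, fs, 6)
  lo_v <- min(ths); amp <- max(ths) - lo_v

  empty <- function(n_cycles) {
    structure(list(
      intervals = tibble::tibble(start = integer(), end = integer()),
      n_cycles = n_cycles, valid = FALSE,
      onset = NA_integer_, offset = NA_integer_, duration_s = NA_real_
    ), class = "sts_cycles")
  }
  if (amp < min_amplitude) return(empty(0L))

  nrm <- (ths - lo_v) / amp      # ~1 seated, ~0 standing

  # seated baseline and noise SD estimated on the plateau core (top 5% of
  # the normalized smoothed amplitude, eroded by the filter half-width so
  # transition smear does not contaminate the residual); refinement runs
  # on the raw signal
  plateau <- nrm > 0.95
  half <- round(1.75 * fs / 6)
  cs <- cumsum(c(0, as.numeric(plateau)))
  core <- rep(FALSE, n)
  if (n > 2 * half) {
    idx <- (half + 1L):(n - half)
    core[idx] <- (cs[idx + half + 1L] - cs[idx - half]) == (2L * half + 1L)
  }
  if (!any(core)) core <- plateau
  base <- stats::median(th[core])
  noise_est <- 1.4826 * stats::median(abs((th - ths)[core]))
  tol <- max(5 * noise_est, 1e-6 * amp)

  # hysteresis state machine around the 50% switching level (40/60 bands)
  standing <- FALSE
  entries <- integer(0); exits <- integer(0)
  for (i in seq_len(n)) {
    if (!standing && nrm[i] < 0.4) { standing <- TRUE; entries <- c(entries, i) }
    else if (standing && nrm[i] > 0.6) { standing <- FALSE; exits <- c(exits, i) }
  }
  if (standing) exits <- c(exits, n)  # trial ends mid-episode
  n_cyc <- length(entries)
  if (n_cyc != 5L) return(empty(as.integer(n_cyc)))

  starts <- integer(n_cyc); ends <- integer(n_cyc)
  for (j in seq_len(n_cyc)) {
    i <- entries[j]
    while (i > 1 && th[i - 1] < base - tol) i <- i - 1L
    starts[j] <- max(1L, i - 1L)
    i <- exits[j]
    while (i < n && th[i + 1] < base - tol) i <- i + 1L
    ends[j] <- min(n, i + 1L)
  }
  structure(list(
    intervals = tibble::tibble(start = starts, end = ends),
    n_cycles = 5L, valid = TRUE,
    onset = starts[1], offset = ends[n_cyc],
    duration_s = (ends[n_cyc] - starts[1]) / fs
  ), class = "sts_cycles")
}

#' @export
print.sts_cycles <- function(x, ...) {
  cat(sprintf("<sts_cycles> %d cycle(s)%s\n", x$n_cycles,
              if (x$valid) sprintf(", duration %.2f s", x$duration_s) else " (invalid trial)"))
  invisible(x)
}

# sample CV (SD/mean, n-1 denominator) with numerical guards: SD at
# floating-point-noise level reports 0; near-zero mean reports NA
.guarded_cv <- function(x) {
  m <- mean(x)
  s <- stats::sd(x)
  if (abs(m) < 1e-9) return(NA_real_)
  if (s < 1e-10 + 1e-9 * abs(m)) return(0)
  s / m
}

#' Extract the 17 sensor-derived features from a recording
#'
#' Computes hip and knee angles from segment pitch, angular velocities and
#' accelerations by smoothed differentiation, angular powers
#' (I * alpha * omega with anthropometric segment inertias: trunk for the
#' hip, thigh for the knee), vertical velocity/acceleration from the
#' vertical displacement and vertical power (m * v * a). For each of the
#' eight primary signals, the per-cycle range (max - min within each
#' stand-sit cycle) is summarized by its mean and coefficient of variation
#' over the five cycles; together with the sensor-based 5xSTS duration this
#' yields exactly 17 named features.
#'
#' @param recording An `sts_recording`.
#' @param bounds Optional pre-computed [segment_cycles()] result.
#' @param cutoff Low-pass cutoff (Hz) for differentiation smoothing.
#' @return One-row tibble: `subject_id`, `status`, then the 17 canonical
#'   feature columns.
#' @export
#' @examples
#' rec <- generate_recording(subject_profile(0), seed = 2)
#' extract_features(rec)
extract_features <- function(recording, bounds = NULL, cutoff = 6) {
  stopifnot(inherits(recording, "sts_recording"))
  if (is.null(bounds)) bounds <- segment_cycles(recording)
  if (!bounds$valid) {
    rlang::abort(
      sprintf("Invalid 5xSTS trial: %d cycle(s) detected (expected 5).", bounds$n_cycles),
      class = "sts_invalid_trial", n_cycles = bounds$n_cycles
    )
  }
  fs <- recording$sampling_rate
  ang <- joint_angles(recording)
  hip_vel <- differentiate(ang$hip, fs, cutoff = cutoff)
  knee_vel <- differentiate(ang$knee, fs, cutoff = cutoff)
  hip_acc <- differentiate(hip_vel, fs, smooth = FALSE)
  knee_acc <- differentiate(knee_vel, fs, smooth = FALSE)
  I_hip <- segment_inertia("trunk", recording$mass, recording$height)
  I_knee <- segment_inertia("thigh", recording$mass, recording$height)
  v_vel <- differentiate(recording$data$vert_disp_m, fs, cutoff = cutoff)
  v_acc <- differentiate(v_vel, fs, smooth = FALSE)

  signals <- list(
    hip_angle = ang$hip,
    hip_angular_velocity = hip_vel,
    hip_power = angular_power(I_hip, hip_acc, hip_vel),
    knee_angle = ang$knee,
    knee_angular_velocity = knee_vel,
    knee_power = angular_power(I_knee, knee_acc, knee_vel),
    vertical_velocity = v_vel,
    vertical_power = vertical_power(recording$mass, v_vel, v_acc)
  )

  iv <- bounds$intervals
  per_cycle_range <- function(x) {
    vapply(seq_len(nrow(iv)), function(i) {
      seg <- x[iv$start[i]:(iv$end[i] - 1L)]
      max(seg) - min(seg)
    }, numeric(1))
  }

  out <- list(subject_id = recording$subject_id, status = recording$status,
              sts_duration = bounds$duration_s)
  for (nm in names(signals)) {
    r <- per_cycle_range(signals[[nm]])
    out[[paste0("mean_", nm, "_range")]] <- mean(r)
    out[[paste0("cv_", nm, "_range")]] <- .guarded_cv(r)
  }
  tibble::as_tibble(out)[, c("subject_id", "status", sts_feature_names())]
}

#' Extract features for every recording in a cohort
#'
#' Applies [extract_features()] to each recording; trials that do not
#' contain exactly five cycles are excluded (not silently dropped: they are
#' reported in the `excluded` attribute and a warning).
#'
#' @param cohort A list with a `recordings` element (as returned by
#'   [simulate_cohort()]) or a bare list of `sts_recording` objects.
#' @param cutoff Low-pass cutoff (Hz) passed to [extract_features()].
#' @return Feature table tibble (one row per valid recording) with
#'   attribute `excluded`: tibble of `subject_id`, `n_cycles`.
#' @export
extract_cohort_features <- function(cohort, cutoff = 6) {
  recs <- if (!is.null(cohort$recordings)) cohort$recordings else cohort
  rows <- list(); excl <- list()
  for (rec in recs) {
    row <- tryCatch(extract_features(rec, cutoff = cutoff),
                    sts_invalid_trial = function(e) e)
    if (inherits(row, "sts_invalid_trial")) {
      excl[[length(excl) + 1L]] <- tibble::tibble(
        subject_id = rec$subject_id, n_cycles = row$n_cycles)
    } else {
      rows[[length(rows) + 1L]] <- row
    }
  }
  excluded <- if (length(excl)) dplyr::bind_rows(excl) else
    tibble::tibble(subject_id = character(), n_cycles = integer())
  if (nrow(excluded)) {
    rlang::warn(sprintf("%d recording(s) excluded (not exactly 5 cycles).", nrow(excluded)))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "excluded") <- excluded
  out
}
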