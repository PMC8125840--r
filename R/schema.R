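# Canonical feature schema shared by the generator, the extractor and the
# selection/evaluation stages. Features are named snake_case by what they
# measure; order below is the canonical order used for tie-breaking.

.sts_primary_signals <- c(
  "hip_angle", "hip_angular_velocity", "hip_power",
  "knee_angle", "knee_angular_velocity", "knee_power",
  "vertical_velocity", "vertical_power"
)

#' Canonical names of the 17 sensor-derived features
#'
#' The feature set comprises the sensor-based five-times sit-to-stand (5xSTS)
#' duration plus, for each of the eight primary per-cycle range signals
#' (hip/knee angle, hip/knee angular velocity, hip/knee power, vertical
#' velocity, vertical power), the mean and the coefficient of variation (CV)
#' across the five cycles: 1 + 8 x 2 = 17 features.
#'
#' @return Character vector of 17 canonical feature column names.
#' @export
#' @examples
#' sts_feature_names()
sts_feature_names <- function() {
  c("sts_duration",
    as.vector(rbind(
      paste0("mean_", .sts_primary_signals, "_range"),
      paste0("cv_", .sts_primary_signals, "_range")
    )))
}

#' Frailty-phenotype tags for the 17 features
#'
#' Maps each canonical feature to the frailty phenotype it indicates:
#' angular/vertical velocity means and the 5xSTS duration indicate slowness,
#' angle and power means indicate weakness, and all cycle-to-cycle CVs
#' indicate exhaustion.
#'
#' @return Named character vector: feature name -> one of
#'   `"slowness"`, `"weakness"`, `"exhaustion"`.
#' @export
#' @examples
#' sts_phenotype_map()[c("mean_hip_angular_velocity_range", "cv_vertical_power_range")]
sts_phenotype_map <- function() {
  feats <- sts_feature_names()
  tag <- function(f) {
    if (f == "sts_duration") return("slowness")
    if (startsWith(f, "cv_")) return("exhaustion")
    if (grepl("velocity", f)) return("slowness")
    "weakness"
  }
  stats::setNames(vapply(feats, tag, character(1)), feats)
}

# Plausible population baselines (robust-group mean and between-subject SD)
# for the direct feature-table generator. Units: s, rad, rad/s, W, m/s;
# CVs dimensionless. Fixtures, not estimates of any real cohort.
.sts_feature_baselines <- function() {
  tibble::tribble(
    ~feature,                            ~mean,  ~sd,
    "sts_duration",                      12.0,   2.0,
    "mean_hip_angle_range",              1.60,   0.25,
    "cv_hip_angle_range",                0.10,   0.03,
    "mean_hip_angular_velocity_range",   4.00,   0.80,
    "cv_hip_angular_velocity_range",     0.12,   0.035,
    "mean_hip_power_range",              60.0,   15.0,
    "cv_hip_power_range",                0.20,   0.06,
    "mean_knee_angle_range",             1.30,   0.20,
    "cv_knee_angle_range",               0.10,   0.03,
    "mean_knee_angular_velocity_range",  3.50,   0.70,
    "cv_knee_angular_velocity_range",    0.12,   0.035,
    "mean_knee_power_range",             45.0,   12.0,
    "cv_knee_power_range",               0.20,   0.06,
    "mean_vertical_velocity_range",      0.80,   0.15,
    "cv_vertical_velocity_range",        0.12,   0.035,
    "mean_vertical_power_range",         300.0,  80.0,
    "cv_vertical_power_range",           0.25,   0.07
  )
}

#' Default group-difference profile for the direct feature-table generator
#'
#' Standardized mean shifts (frail minus robust, in units of the
#' between-subject SD) planted on the eight features that separate the
#' groups: longer duration, slower angular/vertical velocities, lower
#' powers, higher cycle-to-cycle CVs in the pre-frail/frail group.
#' Features not listed get no shift.
#'
#' @return Named numeric vector of standardized shifts.
#' @export
default_feature_effects <- function() {
  c(
    sts_duration                     =  0.8,
    mean_hip_angular_velocity_range  = -0.8,
    mean_knee_angular_velocity_range = -0.8,
    mean_hip_power_range             = -0.6,
    mean_vertical_power_range        = -0.8,
    cv_hip_angular_velocity_range    =  0.6,
    cv_vertical_velocity_range       =  0.6,
    cv_vertical_power_range          =  0.8
  )
}

# Numeric feature columns of a table (everything except identifiers/status).
.feature_columns <- function(table) {
  cand <- setdiff(names(table), c("subject_id", "status"))
  cand[vapply(table[cand], is.numeric, logical(1))]
}

# sub-seed derivation: keeps every derived seed a valid 32-bit integer
.derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(counter)) %% 2147483647)
}
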