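# Kinematic and kinetic primitives: smoothing, numerical differentiation,
# sagittal joint angles, angular and vertical power, body-segment inertia.

#' Gravitational acceleration (m/s^2) used throughout
#' @export
sts_gravity <- 9.81

#' Zero-phase low-pass filter a signal
#'
#' Linear-phase FIR low-pass (windowed-sinc, symmetric kernel, delay
#' compensated) with edge-reflection padding. Being a finite symmetric
#' convolution, the filter is exactly translation invariant: identical
#' movement cycles embedded in identical local context filter to
#' bit-identical outputs, which IIR forward-backward filtering does not
#' guarantee. Constants and linear trends pass through exactly. Standard
#' pre-conditioning for human-movement kinematics sampled at 100 Hz before
#' numerical differentiation.
#'
#' @param x Numeric series.
#' @param sampling_rate Sampling rate in Hz.
#' @param cutoff Cutoff frequency in Hz (default 6, well above the ~1-3 Hz
#'   energy of sit-to-stand movement but far under the Nyquist limit; the
#'   kernel's passband is flat to ~0.3% through 3 Hz).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_zerophase <- function(x, sampling_rate, cutoff = 6) {
  n <- length(x)
  if (n < 10) return(x)
  stopifnot(sampling_rate > 0, cutoff > 0, cutoff < sampling_rate / 2)
  half <- min(round(1.75 * sampling_rate / cutoff), (n - 1L) %/% 2L)
  if (half < 1) return(x)
  kern <- signal::fir1(2L * half, cutoff / (sampling_rate / 2), type = "low")
  kern <- kern / sum(kern)  # unit DC gain: constants and trends pass exactly
  left <- 2 * x[1] - x[(half + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - half)]
  y <- stats::filter(c(left, x, right), kern, sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Differentiate a sampled series
#'
#' Optional zero-phase low-pass smoothing followed by central differences;
#' one-sided differences at the endpoints. Exact for linear series when
#' smoothing is off.
#'
#' @param x Numeric series of length >= 3.
#' @param sampling_rate Sampling rate in Hz.
#' @param smooth Apply [lowpass_zerophase()] before differencing?
#' @param cutoff Low-pass cutoff in Hz when smoothing.
#' @return Numeric series of derivatives, same length as `x`.
#' @export
#' @examples
#' t <- seq(0, 1, by = 0.01)
#' differentiate(3 * t, 100, smooth = FALSE)[5] # = 3
differentiate <- function(x, sampling_rate, smooth = TRUE, cutoff = 6) {
  n <- length(x)
  if (n < 3) rlang::abort("`x` must have at least 3 samples to differentiate.")
  stopifnot(sampling_rate > 0)
  if (smooth) x <- lowpass_zerophase(x, sampling_rate, cutoff)
  dt <- 1 / sampling_rate
  d <- numeric(n)
  d[2:(n - 1L)] <- (x[3:n] - x[1:(n - 2L)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1L]) / dt
  d
}

#' Sagittal hip and knee angles from segment pitch
#'
#' Hip angle is trunk pitch minus thigh pitch; knee angle is thigh pitch
#' minus shank pitch (all sagittal-plane pitch relative to vertical, rad).
#'
#' @param recording An [sts_recording] object, or a trunk pitch series when
#'   `thigh` and `shank` are given.
#' @param thigh,shank Thigh and shank pitch series (rad), when the first
#'   argument is a trunk pitch series.
#' @return Tibble with columns `hip` and `knee` (rad).
#' @export
joint_angles <- function(recording, thigh = NULL, shank = NULL) {
  if (inherits(recording, "sts_recording")) {
    trunk <- recording$data$trunk_pitch_rad
    thigh <- recording$data$thigh_pitch_rad
    shank <- recording$data$shank_pitch_rad
  } else {
    trunk <- recording
  }
  if (length(trunk) != length(thigh) || length(thigh) != length(shank)) {
    rlang::abort("trunk, thigh and shank pitch series must have equal length.")
  }
  tibble::tibble(hip = trunk - thigh, knee = thigh - shank)
}

#' Angular power of a rotating segment
#'
#' Power = I * alpha * omega = torque * omega, with moment of inertia I
#' (kg m^2), angular acceleration alpha (rad/s^2) and angular velocity
#' omega (rad/s).
#'
#' @param I Moment of inertia, >= 0 (scalar or series).
#' @param alpha Angular acceleration series (rad/s^2).
#' @param omega Angular velocity series (rad/s).
#' @return Power series in W.
#' @export
#' @examples
#' angular_power(2, 3, 4) # 24 W
angular_power <- function(I, alpha, omega) {
  if (any(I < 0)) rlang::abort("Moment of inertia `I` must be non-negative.")
  I * alpha * omega
}

#' Vertical power of the body centre of mass
#'
#' Product of body mass (kg), vertical velocity (m/s) and vertical
#' acceleration (m/s^2).
#'
#' @param m Body mass in kg, > 0.
#' @param v Vertical velocity series (m/s).
#' @param a Vertical acceleration series (m/s^2).
#' @return Power series in W.
#' @export
vertical_power <- function(m, v, a) {
  if (m <= 0) rlang::abort("Body mass `m` must be positive.")
  m * v * a
}

#' Dimensionless body-size scaling of vertical power
#'
#' Default (`form = "printed"`) divides by `m * g^2 * h`; the conventional
#' biomechanical normalization `m * g * sqrt(g * h)` is available as
#' `form = "conventional"`. Both use g = 9.81 m/s^2.
#'
#' @param P Vertical power (W).
#' @param m Body mass (kg), > 0.
#' @param h Body height (m), > 0.
#' @param form Scaling denominator variant.
#' @return Dimensionless scaled power.
#' @export
#' @examples
#' scaled_vertical_power(70 * 9.81^2 * 1.7, 70, 1.7) # 1
scaled_vertical_power <- function(P, m, h, form = c("printed", "conventional")) {
  form <- match.arg(form)
  if (m <= 0 || h <= 0) rlang::abort("`m` and `h` must be positive.")
  g <- sts_gravity
  denom <- switch(form,
    printed = m * g * g * h,
    conventional = m * g * sqrt(g * h)
  )
  P / denom
}

# Body-segment inertia parameters: de Leva's adjustment of the
# Zatsiorsky-Seluyanov anthropometric tables (male, sagittal plane).
# mass_frac = segment mass / body mass, length_frac = segment length / height,
# rog_frac = sagittal radius of gyration / segment length.
.segment_params <- function() {
  tibble::tribble(
    ~segment, ~mass_frac, ~length_frac, ~rog_frac,
    "trunk",  0.4346,     0.3056,       0.328,
    "thigh",  0.1416,     0.2425,       0.329,
    "shank",  0.0433,     0.2493,       0.255
  )
}

#' Segment moment of inertia from anthropometric tables
#'
#' I = m_seg * (k * L_seg)^2 with segment mass m_seg, segment length L_seg
#' and sagittal radius-of-gyration fraction k taken from the de Leva-adjusted
#' Zatsiorsky-Seluyanov body-segment parameter table embedded in the package.
#'
#' @param segment One of `"trunk"`, `"thigh"`, `"shank"`.
#' @param mass Body mass in kg, > 0.
#' @param height Body height in m, > 0.
#' @return Moment of inertia in kg m^2.
#' @export
#' @examples
#' segment_inertia("trunk", 70, 1.70)
segment_inertia <- function(segment = c("trunk", "thigh", "shank"), mass, height) {
  segment <- match.arg(segment)
  if (mass <= 0 || height <= 0) rlang::abort("`mass` and `height` must be positive.")
  p <- .segment_params()
  p <- p[p$segment == segment, ]
  (p$mass_frac * mass) * (p$rog_frac * p$length_frac * height)^2
}
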