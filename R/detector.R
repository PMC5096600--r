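# Finite-foil detector model, retarded-depth conversion, amplitude
# calibration against a reference trace, and utilities for measured traces.

#' Transducer foil model
#'
#' The finite thickness of the piezoelectric foil smears the detected
#' pressure over the acoustic transit time through the foil. It is modelled
#' as a centred moving mean over a ct window equal to the foil thickness
#' (equivalently a time window of thickness / sound speed).
#'
#' @param delta_w foil thickness in micrometres, non-negative. `0` disables
#'   the averaging.
#' @return an object of class `oa_foil`.
#' @export
oa_foil <- function(delta_w = 50) {
  stopifnot(is.numeric(delta_w), length(delta_w) == 1, delta_w >= 0)
  structure(list(delta_w = delta_w), class = "oa_foil")
}

#' @export
print.oa_foil <- function(x, ...) {
  cat("Transducer foil: delta_w =", x$delta_w, "um\n")
  invisible(x)
}

#' Average a signal over the foil thickness
#'
#' Centred moving mean over a window of `delta_w` in ct units (1 um =
#' 1e-4 cm), rounded to the nearest odd number of bins. At the record edges
#' the window shrinks symmetrically (no zero padding). The operation never
#' increases the maximum absolute amplitude.
#'
#' @param signal an [oa_signal].
#' @param foil an [oa_foil()].
#' @return the foil-averaged [oa_signal].
#' @export
foil_average <- function(signal, foil) {
  stopifnot(inherits(signal, "oa_signal"), inherits(foil, "oa_foil"))
  if (foil$delta_w == 0) return(signal)
  w_ct <- foil$delta_w * 1e-4                 # um -> cm
  n <- max(1L, round(w_ct / signal$bin_width))
  if (n %% 2 == 0) n <- n + 1L
  if (n > length(signal$p)) stop("foil window exceeds signal length")
  signal$p <- moving_average(signal$p, n)
  signal
}

#' Convert a signal to the retarded-depth axis
#'
#' Adds the retarded signal depth \eqn{c\tau = ct + z_D} (with \eqn{z_D < 0})
#' to a transient: a monotone shift of the axis so that \eqn{c\tau = 0}
#' corresponds to the absorber surface; the sample values are untouched and
#' the shift is invertible.
#'
#' @param signal an [oa_signal] carrying detection metadata.
#' @return the signal with a `ctau` axis.
#' @export
to_retarded_depth <- function(signal) {
  stopifnot(inherits(signal, "oa_signal"))
  if (is.null(signal$detection))
    stop("signal carries no detection metadata")
  signal$ctau <- signal$ct + signal$detection$z_D
  signal
}

#' Least-squares amplitude calibration
#'
#' Scalar factor matching a simulated transient (in arbitrary units) to a
#' reference trace on a common axis: the \eqn{s} minimizing
#' \eqn{\sum_i (s\,\mathrm{sim}_i - \mathrm{ref}_i)^2}, i.e.
#' \eqn{s = \sum \mathrm{sim}\cdot\mathrm{ref} / \sum \mathrm{sim}^2}.
#'
#' @param simulated,reference numeric vectors of equal length, or
#'   [oa_signal]s already resampled to a common axis.
#' @return the scalar scale factor.
#' @export
amplitude_calibration <- function(simulated, reference) {
  sim <- if (inherits(simulated, "oa_signal")) simulated$p else simulated
  ref <- if (inherits(reference, "oa_signal")) reference$p else reference
  if (length(sim) != length(ref))
    stop("signals must be resampled to a common axis first")
  ss <- sum(sim^2)
  if (ss == 0) stop("cannot calibrate against an identically zero simulation")
  sum(sim * ref) / ss
}

#' Measured voltage trace
#'
#' A uniformly sampled detector voltage trace, e.g. digitized at 2 GS/s.
#'
#' @param values voltage samples (arbitrary units).
#' @param sample_rate sampling rate in samples per second.
#' @return an object of class `oa_trace`.
#' @export
oa_trace <- function(values, sample_rate) {
  stopifnot(is.numeric(values), is.numeric(sample_rate), sample_rate > 0)
  structure(list(values = values, sample_rate = sample_rate),
            class = "oa_trace")
}

#' Smoothing window in samples for a measured trace
#'
#' @param window_ns smoothing window in nanoseconds.
#' @param sample_rate sampling rate in samples per second.
#' @return integer number of samples, `round(window_ns * 1e-9 * sample_rate)`.
#' @examples
#' smoothing_samples(20, 2e9)   # 40 samples
#' @export
smoothing_samples <- function(window_ns, sample_rate) {
  n <- round(window_ns * 1e-9 * sample_rate)
  if (n < 1) n <- 1L
  as.integer(n)
}

#' Smooth a measured trace
#'
#' Moving average over `round(window_ns * sample_rate)` consecutive samples
#' (forced odd for a centred window; a 1-sample window is the identity).
#'
#' @param trace an [oa_trace()].
#' @param window_ns smoothing window in nanoseconds.
#' @return the smoothed [oa_trace()].
#' @export
smooth_measured <- function(trace, window_ns) {
  stopifnot(inherits(trace, "oa_trace"))
  n <- smoothing_samples(window_ns, trace$sample_rate)
  if (n > length(trace$values)) stop("smoothing window longer than trace")
  if (n %% 2 == 0) n <- n + 1L
  if (n > length(trace$values)) n <- n - 2L
  trace$values <- moving_average(trace$values, max(1L, n))
  trace
}

#' Read a measured trace from CSV
#'
#' Two-column CSV of a digitized detector trace: a time axis in seconds
#' (column `t_s`) or a propagation-distance axis in cm (column `ct_cm`),
#' followed by the sample values. With a `ct_cm` axis the supplied speed of
#' sound converts spacing to a sampling rate.
#'
#' @param path file path.
#' @param c_sound speed of sound in cm/s, used only for a `ct_cm` axis.
#' @return an [oa_trace()].
#' @export
read_trace_csv <- function(path, c_sound = 1.5e5) {
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 2) stop("expected a two-column CSV (axis, value)")
  ax <- df[[1]]
  if (length(ax) < 2) stop("trace too short")
  step <- stats::median(diff(ax))
  if (step <= 0) stop("axis must be increasing")
  dt <- if (names(df)[1] == "ct_cm") step / c_sound else step
  oa_trace(values = df[[2]], sample_rate = 1 / dt)
}

#' Convert a ct axis to time
#'
#' The core works entirely in propagation distance ct (cm); this utility
#' converts to seconds for interfacing with measured traces, given a
#' user-supplied speed of sound.
#'
#' @param ct propagation distance(s) in cm.
#' @param c_sound speed of sound in cm/s; default `1.5e5` (soft tissue /
#'   water-like media).
#' @return time(s) in seconds.
#' @export
ct_to_time <- function(ct, c_sound = 1.5e5) {
  stopifnot(c_sound > 0)
  ct / c_sound
}
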