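#' Depth-controlled indentation protocols
#'
#' Describes one ferrule-top indentation: an approach, a constant-speed ramp
#' to the target depth, a stress-relaxation hold, and (optionally) a series
#' of small sinusoidal depth oscillations at one or more frequencies.
#'
#' The `"map_sweep"` preset is the rheology protocol used for viscoelastic
#' mapping: 2 um/s ramp to 15 um, 10 s relaxation, 0.3 um oscillations at
#' 0.1, 1 and 10 Hz. The stimulation presets mirror the three
#' electrophysiology protocols: `"static"` (no oscillation), `"small_osc"`
#' (1 um at 0.1 Hz) and `"mild_osc"` (3 um at 0.1 Hz).
#'
#' @param mode One of `"map_sweep"`, `"static"`, `"small_osc"`, `"mild_osc"`.
#' @param ramp_speed_um_s Ramp speed, um/s.
#' @param target_depth_um Target indentation depth, um.
#' @param relaxation_s Stress-relaxation hold, s.
#' @param oscillation_amplitude_um Oscillation amplitude h0, um.
#' @param oscillation_frequencies_hz Oscillation frequencies, Hz.
#' @param n_periods Minimum full periods per oscillation segment (>= 3).
#' @param min_oscillation_s Minimum duration of each oscillation segment, s;
#'   high-frequency segments run for `ceiling(min_oscillation_s * f)`
#'   periods so the phase estimate keeps a usable signal-to-noise ratio.
#' @param approach_s Pre-contact approach duration, s (>= 1).
#' @return An object of class `indentation_protocol`.
#' @examples
#' indentation_protocol("map_sweep")
#' indentation_protocol("mild_osc", target_depth_um = 30)
#' @export
indentation_protocol <- function(mode = c("map_sweep", "static", "small_osc", "mild_osc"),
                                 ramp_speed_um_s = 2,
                                 target_depth_um = NULL,
                                 relaxation_s = 10,
                                 oscillation_amplitude_um = NULL,
                                 oscillation_frequencies_hz = NULL,
                                 n_periods = 4,
                                 min_oscillation_s = 5,
                                 approach_s = 4) {
  mode <- match.arg(mode)
  defaults <- switch(mode,
    map_sweep = list(depth = 15, h0 = 0.3, freqs = c(0.1, 1, 10)),
    static    = list(depth = 30, h0 = 0,   freqs = numeric(0)),
    small_osc = list(depth = 30, h0 = 1,   freqs = 0.1),
    mild_osc  = list(depth = 30, h0 = 3,   freqs = 0.1)
  )
  if (is.null(target_depth_um)) target_depth_um <- defaults$depth
  if (is.null(oscillation_amplitude_um)) oscillation_amplitude_um <- defaults$h0
  if (is.null(oscillation_frequencies_hz)) oscillation_frequencies_hz <- defaults$freqs
  check_positive(target_depth_um, "target_depth_um")
  check_positive(ramp_speed_um_s, "ramp_speed_um_s")
  if (oscillation_amplitude_um < 0) stop_invalid("oscillation_amplitude_um must be >= 0")
  if (mode == "static" && oscillation_amplitude_um != 0) {
    stop_invalid("static protocol requires zero oscillation amplitude")
  }
  if (length(oscillation_frequencies_hz) && any(oscillation_frequencies_hz <= 0)) {
    stop_invalid("oscillation frequencies must be > 0")
  }
  if (n_periods < 3) stop_invalid("n_periods must be >= 3")
  if (min_oscillation_s < 0) stop_invalid("min_oscillation_s must be >= 0")
  if (approach_s < 1) stop_invalid("approach_s must be >= 1")
  structure(list(
    mode = mode,
    ramp_speed_um_s = ramp_speed_um_s,
    target_depth_um = target_depth_um,
    relaxation_s = relaxation_s,
    oscillation_amplitude_um = oscillation_amplitude_um,
    oscillation_frequencies_hz = oscillation_frequencies_hz,
    n_periods = n_periods,
    min_oscillation_s = min_oscillation_s,
    approach_s = approach_s
  ), class = "indentation_protocol")
}

#' @export
print.indentation_protocol <- function(x, ...) {
  cat("<indentation_protocol:", x$mode, ">\n")
  cat(sprintf("  ramp %.3g um/s to %.3g um, relax %.3g s\n",
              x$ramp_speed_um_s, x$target_depth_um, x$relaxation_s))
  if (length(x$oscillation_frequencies_hz)) {
    cat(sprintf("  oscillation h0 = %.3g um at %s Hz (%d periods each)\n",
                x$oscillation_amplitude_um,
                paste(x$oscillation_frequencies_hz, collapse = "/"),
                x$n_periods))
  } else {
    cat("  no oscillation (static hold)\n")
  }
  invisible(x)
}
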