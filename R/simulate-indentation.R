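#' Simulate a depth-controlled indentation trace
#'
#' Synthesizes the synchronized piezo-position / cantilever-deflection / load
#' time series produced by a ferrule-top indentation probe running a
#' depth-controlled protocol on a viscoelastic tissue. The oscillation
#' segments invert the dynamic-indentation relations: at drive frequency
#' \eqn{f}, with contact radius \eqn{a=\sqrt{R\bar h}} at the mean depth, the
#' load oscillation has amplitude \eqn{F_0 = h_0\,2a\,|K^*|} and phase lag
#' \eqn{\Phi = \mathrm{atan2}(K'', K')}, so the downstream moduli extraction
#' can be checked in closed loop against the planted tissue model.
#'
#' The ramp load follows Hertzian contact \eqn{F = \tfrac{4}{3} K \sqrt{R}\,
#' h^{3/2}} with the model's instantaneous modulus, relaxing exponentially to
#' the equilibrium modulus during the hold; these segments are qualitative
#' scaffolding (contact detection, mean load), while the oscillation segments
#' are quantitative.
#'
#' Measurement noise is Gaussian on the cantilever deflection; the load is
#' always `spring_constant * deflection`, so load noise is coherent with
#' deflection noise as in the real transducer.
#'
#' @param protocol An [indentation_protocol()].
#' @param tissue A [tissue_model][sls_tissue].
#' @param probe_radius_um Spherical tip radius R, um.
#' @param noise_sd_um Deflection noise SD, um (5 nm = 0.005 by default).
#' @param seed Integer seed; the trace is deterministic given the seed.
#' @param spring_constant_n_m Cantilever spring constant, N/m.
#' @param fs_hz Sampling rate, Hz.
#' @param x_um,y_um Scan-grid coordinates carried on the trace for map
#'   assembly.
#' @return An `indentation_trace`: a data.frame with columns `time_s`,
#'   `piezo_um`, `deflection_um`, `load_un`, `segment`, plus attributes
#'   `probe_radius_um`, `spring_constant_n_m`, `fs_hz`, `true_contact_time_s`.
#' @examples
#' tr <- simulate_indentation_trace(indentation_protocol("map_sweep"),
#'                                  sls_tissue_preset(), seed = 1)
#' head(tr)
#' @export
simulate_indentation_trace <- function(protocol, tissue,
                                       probe_radius_um = 57,
                                       noise_sd_um = 0.005,
                                       seed = NULL,
                                       spring_constant_n_m = 0.45,
                                       fs_hz = 1000,
                                       x_um = 0, y_um = 0) {
  stopifnot(inherits(protocol, "indentation_protocol"),
            inherits(tissue, "tissue_model"))
  check_positive(probe_radius_um, "probe_radius_um")
  check_positive(spring_constant_n_m, "spring_constant_n_m")
  if (noise_sd_um < 0) stop_invalid("noise_sd_um must be >= 0")

  R_m <- probe_radius_um * 1e-6
  depth_um <- protocol$target_depth_um
  # instantaneous / equilibrium apparent moduli (Pa) for ramp & relaxation
  if (identical(tissue$model_kind, "standard_linear_solid")) {
    k_inst <- tissue$k_eq + tissue$k_delta
    k_eq <- tissue$k_eq
    tau_relax <- tissue$tau_s
  } else {
    k_inst <- tissue$k_storage_fn(10)
    k_eq <- tissue$k_storage_fn(0.1)
    tau_relax <- 1
  }
  hertz_un <- function(h_um, k_pa) {
    1e6 * (4 / 3) * k_pa * sqrt(R_m) * pmax(h_um * 1e-6, 0)^1.5
  }

  dt <- 1 / fs_hz
  seg_piece <- function(n, depth, load, label) {
    data.frame(depth_um = depth, load_un = load,
               segment = rep(label, n), stringsAsFactors = FALSE)
  }

  pieces <- list()
  # approach: piezo advances at ramp speed, no contact
  n_app <- round(protocol$approach_s * fs_hz)
  pieces$approach <- seg_piece(n_app, 0, 0, "approach")
  # ramp to target depth
  ramp_s <- depth_um / protocol$ramp_speed_um_s
  n_ramp <- round(ramp_s * fs_hz)
  h_ramp <- seq_len(n_ramp) / n_ramp * depth_um
  pieces$ramp <- seg_piece(n_ramp, h_ramp, hertz_un(h_ramp, k_inst), "ramp")
  # stress relaxation at constant depth
  if (protocol$relaxation_s > 0) {
    n_rel <- round(protocol$relaxation_s * fs_hz)
    t_rel <- seq_len(n_rel) * dt
    f_rel <- hertz_un(depth_um, k_eq) +
      (hertz_un(depth_um, k_inst) - hertz_un(depth_um, k_eq)) * exp(-t_rel / tau_relax)
    pieces$relax <- seg_piece(n_rel, depth_um, f_rel, "relaxation")
  }
  # oscillation segments, one per frequency
  h0 <- protocol$oscillation_amplitude_um
  a_m <- sqrt(R_m * depth_um * 1e-6)
  f_mean_un <- hertz_un(depth_um, k_eq)
  min_osc <- if (is.null(protocol$min_oscillation_s)) 0 else protocol$min_oscillation_s
  for (f in protocol$oscillation_frequencies_hz) {
    np <- max(protocol$n_periods, ceiling(min_osc * f))
    n_osc <- round(np / f * fs_hz)
    t_osc <- seq_len(n_osc) * dt
    kp <- tissue$k_storage_fn(f)
    kpp <- tissue$k_loss_fn(f)
    phi <- atan2(kpp, kp)
    f0_un <- 1e6 * (h0 * 1e-6) * 2 * a_m * sqrt(kp^2 + kpp^2)
    depth_osc <- depth_um + h0 * sin(2 * pi * f * t_osc)
    load_osc <- f_mean_un + f0_un * sin(2 * pi * f * t_osc + phi)
    pieces[[paste0("osc_", f)]] <-
      seg_piece(n_osc, depth_osc, load_osc, paste0("osc_", f))
  }

  body <- do.call(rbind, pieces)
  n <- nrow(body)
  time_s <- seq_len(n) * dt

  trace <- with_local_seed(seed, {
    deflection <- body$load_un / spring_constant_n_m
    if (noise_sd_um > 0) deflection <- deflection + rnorm(n, 0, noise_sd_um)
    load <- deflection * spring_constant_n_m
    in_contact <- body$segment != "approach"
    # approach: piezo closes on the surface (contact at piezo = 0)
    piezo <- numeric(n)
    piezo[!in_contact] <- -rev(seq_len(sum(!in_contact))) * dt * protocol$ramp_speed_um_s
    piezo[in_contact] <- body$depth_um[in_contact] + deflection[in_contact]
    data.frame(time_s = time_s, piezo_um = piezo,
               deflection_um = deflection, load_un = load,
               segment = body$segment, stringsAsFactors = FALSE)
  })
  rownames(trace) <- NULL
  structure(trace,
            probe_radius_um = probe_radius_um,
            spring_constant_n_m = spring_constant_n_m,
            fs_hz = fs_hz,
            true_contact_time_s = n_app * dt,
            x_um = x_um, y_um = y_um,
            class = c("indentation_trace", "data.frame"))
}

#' @export
print.indentation_trace <- function(x, ...) {
  segs <- rle(as.character(x$segment))
  cat(sprintf("<indentation_trace: %d samples @ %g Hz, R = %g um, k = %g N/m>\n",
              nrow(x), attr(x, "fs_hz"), attr(x, "probe_radius_um"),
              attr(x, "spring_constant_n_m")))
  cat("  segments:", paste(segs$values, collapse = " -> "), "\n")
  invisible(x)
}
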