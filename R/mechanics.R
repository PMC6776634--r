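#' Detect the tissue contact point in an indentation trace
#'
#' Estimates contact as the first sample where the load exceeds the
#' pre-contact baseline mean by `n_sigma` baseline SDs and stays above that
#' threshold for at least `hold_s` seconds. On a noise-free trace the
#' threshold degenerates to the baseline mean plus a vanishing epsilon, so
#' the first loaded sample is returned.
#'
#' After contact, indentation depth is
#' `h(t) = (piezo(t) - piezo_contact) - (deflection(t) - deflection_baseline)`;
#' see [trace_depth()].
#'
#' @param trace An `indentation_trace` (needs >= 1 s of pre-contact
#'   baseline).
#' @param baseline_s Initial window used for the load baseline, s.
#' @param n_sigma Threshold in baseline SDs above the baseline mean.
#' @param hold_s Time the load must stay above threshold, s.
#' @return A list with `time_s`, `piezo_um`, `index`,
#'   `deflection_baseline_um`, `threshold_un`.
#' @export
detect_contact_point <- function(trace, baseline_s = 1, n_sigma = 3, hold_s = 0.05) {
  stopifnot(inherits(trace, "indentation_trace"))
  fs <- attr(trace, "fs_hz")
  n_base <- max(2L, round(baseline_s * fs))
  if (n_base >= nrow(trace)) stop_invalid("trace shorter than baseline window")
  base <- trace$load_un[seq_len(n_base)]
  mu <- mean(base)
  sigma <- stats::sd(base)
  eps <- max(1e-12, 1e-9 * max(abs(trace$load_un)))
  thr <- mu + max(n_sigma * sigma, eps)
  above <- trace$load_un > thr
  n_hold <- max(1L, round(hold_s * fs))
  # forward run length of TRUE starting at each index
  run <- integer(length(above))
  cnt <- 0L
  for (i in rev(seq_along(above))) {
    cnt <- if (above[i]) cnt + 1L else 0L
    run[i] <- cnt
  }
  idx <- which(run >= n_hold)
  idx <- idx[idx > n_base]
  if (!length(idx)) {
    stop(structure(class = c("retinamech_no_contact", "error", "condition"),
                   list(message = "no contact point found (load never crosses baseline + 3 SD)",
                        call = sys.call())))
  }
  i0 <- idx[1]
  list(time_s = trace$time_s[i0],
       piezo_um = trace$piezo_um[i0],
       index = i0,
       deflection_baseline_um = mean(trace$deflection_um[seq_len(n_base)]),
       threshold_un = thr)
}

#' Indentation depth from a trace and its contact point
#'
#' @param trace An `indentation_trace`.
#' @param contact Result of [detect_contact_point()].
#' @return Numeric vector of depths (um), 0 before contact.
#' @export
trace_depth <- function(trace, contact) {
  h <- (trace$piezo_um - contact$piezo_um) -
    (trace$deflection_um - contact$deflection_baseline_um)
  h[seq_len(contact$index - 1L)] <- 0
  h
}

#' Fit a sinusoid at a known drive frequency to depth and load
#'
#' Linear least squares of both channels on
#' `c + A sin(2 pi f t) + B cos(2 pi f t)`; amplitudes are
#' \eqn{\sqrt{A^2+B^2}} and the phase lag is
#' `phase(load) - phase(depth)` wrapped to \eqn{[-\pi, \pi]}. A phase lag
#' outside \eqn{[0, \pi/2]} is physically inadmissible for a passive
#' viscoelastic response and is flagged (`physical = FALSE`), never clipped.
#'
#' @param time_s,depth_um,load_un Sampled oscillation segment (>= 3 full
#'   periods).
#' @param freq_hz Known drive frequency, Hz.
#' @return An `oscillation_fit`: list with `freq_hz`, `f0_un`, `h0_um`,
#'   `phase_rad`, `mean_depth_um`, `mean_load_un`, `residual_rms_un`,
#'   `physical`.
#' @export
fit_oscillation <- function(time_s, depth_um, load_un, freq_hz) {
  check_positive(freq_hz, "freq_hz")
  n <- length(time_s)
  if (length(depth_um) != n || length(load_un) != n) {
    stop_invalid("time, depth and load must have equal length")
  }
  # segment coverage counts whole samples: n points at spacing dt span n*dt
  span <- max(time_s) - min(time_s) + stats::median(diff(time_s))
  if (span * freq_hz < 3 - 1e-9) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = sprintf(
                     "oscillation segment spans %.2f periods at %g Hz; >= 3 required",
                     span * freq_hz, freq_hz), call = sys.call())))
  }
  w <- 2 * pi * freq_hz * time_s
  X <- cbind(1, sin(w), cos(w))
  ch <- qr.coef(qr(X), depth_um)
  cf <- qr.coef(qr(X), load_un)
  amp <- function(co) sqrt(co[2]^2 + co[3]^2)
  phs <- function(co) atan2(co[3], co[2])
  phi <- phs(cf) - phs(ch)
  phi <- atan2(sin(phi), cos(phi))  # wrap to [-pi, pi]
  res <- load_un - X %*% cf
  structure(list(
    freq_hz = freq_hz,
    f0_un = unname(amp(cf)),
    h0_um = unname(amp(ch)),
    phase_rad = unname(phi),
    mean_depth_um = unname(ch[1]),
    mean_load_un = unname(cf[1]),
    residual_rms_un = sqrt(mean(res^2)),
    physical = phi >= 0 && phi <= pi / 2
  ), class = "oscillation_fit")
}

#' Hertzian contact geometry
#'
#' For a rigid sphere of radius `R` at indentation depth `h`, the contact
#' radius is \eqn{a = \sqrt{R h}} and the contact area \eqn{A = \pi a^2}.
#'
#' @param probe_radius_um Sphere radius R, um.
#' @param depth_um Indentation depth h, um (>= 0).
#' @return Contact radius in um (`contact_radius`) or area in um^2
#'   (`contact_area`).
#' @examples
#' contact_radius(125, 20)  # 50 um
#' @export
contact_radius <- function(probe_radius_um, depth_um) {
  check_positive(probe_radius_um, "probe_radius_um")
  if (any(depth_um < 0)) stop_invalid("depth_um must be >= 0")
  sqrt(probe_radius_um * depth_um)
}

#' @rdname contact_radius
#' @export
contact_area <- function(probe_radius_um, depth_um) {
  pi * contact_radius(probe_radius_um, depth_um)^2
}

#' Apparent storage and loss moduli and the loss tangent
#'
#' From an oscillation fit and the contact area, the apparent moduli (in the
#' \eqn{E/(1-\nu^2)} normalization, with \eqn{\nu = 0.5} for incompressible
#' tissue) are
#' \deqn{K' = \frac{F_0}{h_0}\cos\Phi\,\frac{\sqrt\pi}{2\sqrt A},\qquad
#'       K'' = \frac{F_0}{h_0}\sin\Phi\,\frac{\sqrt\pi}{2\sqrt A},}
#' equivalently \eqn{(F_0/h_0)\cos\Phi/(2a)} since \eqn{A=\pi a^2}. Inputs
#' are recorded in um/uN (so \eqn{F_0/h_0} is already N/m); area is
#' converted to SI before evaluation and the result is in Pa. The loss
#' tangent is \eqn{\tan\Phi = K''/K'}.
#'
#' @param fit An [oscillation_fit][fit_oscillation].
#' @param area_um2 Contact area A at the segment's mean depth, um^2.
#' @return Modulus in Pa (`storage_modulus`, `loss_modulus`) or the
#'   dimensionless ratio (`loss_tangent`).
#' @export
storage_modulus <- function(fit, area_um2) {
  check_positive(area_um2, "area_um2")
  check_positive(fit$h0_um, "h0_um")
  (fit$f0_un / fit$h0_um) * cos(fit$phase_rad) * sqrt(pi) / (2 * sqrt(area_um2 * 1e-12))
}

#' @rdname storage_modulus
#' @export
loss_modulus <- function(fit, area_um2) {
  check_positive(area_um2, "area_um2")
  check_positive(fit$h0_um, "h0_um")
  (fit$f0_un / fit$h0_um) * sin(fit$phase_rad) * sqrt(pi) / (2 * sqrt(area_um2 * 1e-12))
}

#' @rdname storage_modulus
#' @param k_storage_pa,k_loss_pa Moduli in Pa (`k_storage_pa > 0`).
#' @export
loss_tangent <- function(k_storage_pa, k_loss_pa) {
  if (any(k_storage_pa <= 0)) stop_invalid("k_storage_pa must be > 0")
  k_loss_pa / k_storage_pa
}

#' Per-trial contact pressure and indentation strain
#'
#' Pressure is the maximal load over the Hertzian contact area at the trial
#' depth, `pressure = max_load / (pi R h)`; strain is `a/R = sqrt(h/R)`.
#'
#' @param max_load_un Maximal load during the trial, uN.
#' @param probe_radius_um Sphere radius, um.
#' @param depth_um Indentation depth, um.
#' @return List with `contact_area_um2`, `pressure_pa`, `strain`.
#' @examples
#' trial_pressure_strain(0.3, 125, 20)
#' @export
trial_pressure_strain <- function(max_load_un, probe_radius_um, depth_um) {
  check_positive(probe_radius_um, "probe_radius_um")
  check_positive(depth_um, "depth_um")
  if (max_load_un < 0) stop_invalid("max_load_un must be >= 0")
  area_um2 <- contact_area(probe_radius_um, depth_um)
  list(contact_area_um2 = area_um2,
       pressure_pa = (max_load_un * 1e-6) / (area_um2 * 1e-12),
       strain = sqrt(depth_um / probe_radius_um))
}

#' Extract viscoelastic moduli from one indentation trace
#'
#' Runs contact detection, fits every labeled oscillation segment at its
#' drive frequency, and evaluates the apparent storage/loss moduli and loss
#' tangent at the Hertzian contact area of each segment's mean depth (the
#' oscillation is <= 2% of the depth, so the area is treated as constant per
#' segment).
#'
#' @param trace An `indentation_trace` with `osc_<f>` segment labels.
#' @param baseline_s Baseline window for contact detection, s.
#' @return A `visco_moduli` data.frame: one row per frequency with columns
#'   `x_um`, `y_um`, `freq_hz`, `h0_um`, `f0_un`, `phase_rad`,
#'   `mean_depth_um`, `contact_radius_um`, `contact_area_um2`,
#'   `k_storage_pa`, `k_loss_pa`, `tan_phi`, `physical`.
#' @examples
#' tr <- simulate_indentation_trace(indentation_protocol("map_sweep"),
#'                                  sls_tissue_preset(), noise_sd_um = 0, seed = 1)
#' analyze_indentation_trace(tr)
#' @export
analyze_indentation_trace <- function(trace, baseline_s = 1) {
  stopifnot(inherits(trace, "indentation_trace"))
  contact <- detect_contact_point(trace, baseline_s = baseline_s)
  h <- trace_depth(trace, contact)
  R <- attr(trace, "probe_radius_um")
  segs <- unique(as.character(trace$segment))
  osc <- segs[startsWith(segs, "osc_")]
  if (!length(osc)) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "trace has no oscillation segments", call = sys.call())))
  }
  rows <- lapply(osc, function(lab) {
    f <- as.numeric(sub("^osc_", "", lab))
    sel <- trace$segment == lab
    fit <- fit_oscillation(trace$time_s[sel], h[sel], trace$load_un[sel], f)
    a <- contact_radius(R, fit$mean_depth_um)
    A <- pi * a^2
    kp <- storage_modulus(fit, A)
    kpp <- loss_modulus(fit, A)
    data.frame(x_um = attr(trace, "x_um"), y_um = attr(trace, "y_um"),
               freq_hz = f, h0_um = fit$h0_um, f0_un = fit$f0_un,
               phase_rad = fit$phase_rad, mean_depth_um = fit$mean_depth_um,
               contact_radius_um = a, contact_area_um2 = A,
               k_storage_pa = kp, k_loss_pa = kpp,
               tan_phi = loss_tangent(kp, kpp), physical = fit$physical)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$freq_hz), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("visco_moduli", "data.frame")
  out
}

#' Assemble an indentation map from traces on a scan grid
#'
#' @param traces List of `indentation_trace` objects carrying scan
#'   coordinates.
#' @param spacing_um Declared grid spacing (um); nearest-neighbour distances
#'   among locations are validated against it (warning on mismatch).
#' @return Long-format data.frame: `x_um`, `y_um`, `freq_hz`,
#'   `k_storage_pa`, `k_loss_pa`, `tan_phi`.
#' @export
build_indentation_map <- function(traces, spacing_um = 50) {
  stopifnot(length(traces) >= 1)
  per <- lapply(traces, analyze_indentation_trace)
  coords <- unique(do.call(rbind, lapply(per, function(d) d[1, c("x_um", "y_um")])))
  all_coords <- do.call(rbind, lapply(per, function(d) d[1, c("x_um", "y_um")]))
  if (nrow(unique(all_coords)) < nrow(all_coords)) {
    stop(structure(class = c("retinamech_duplicate_location", "error", "condition"),
                   list(message = "duplicate scan coordinates among traces", call = sys.call())))
  }
  if (nrow(coords) > 1) {
    d <- as.matrix(stats::dist(coords))
    diag(d) <- Inf
    nn <- min(d)
    if (abs(nn - spacing_um) > 0.05 * spacing_um) {
      warning(sprintf("nearest-neighbour spacing %.1f um differs from declared %.1f um",
                      nn, spacing_um))
    }
  }
  out <- do.call(rbind, per)
  out <- out[, c("x_um", "y_um", "freq_hz", "k_storage_pa", "k_loss_pa", "tan_phi")]
  rownames(out) <- NULL
  out
}

#' Frequency-comparison statistics for an indentation map
#'
#' Tests normality of the per-frequency modulus samples (Shapiro-Wilk) and
#' compares distributions across frequencies with the non-parametric
#' Kruskal-Wallis test, separately for the storage and loss moduli.
#' Significance is flagged at 0.01 and 0.0005. With all observations
#' identical, H = 0 and p = 1 by convention (the ties correction is
#' degenerate there).
#'
#' @param map Long-format map table from [build_indentation_map()] (columns
#'   `freq_hz`, `k_storage_pa`, `k_loss_pa`).
#' @return A `stats_report` list: per-modulus Shapiro-Wilk p per frequency,
#'   Kruskal-Wallis H and p, and significance flags.
#' @export
frequency_sweep_stats <- function(map) {
  stopifnot(all(c("freq_hz", "k_storage_pa", "k_loss_pa") %in% names(map)))
  freqs <- sort(unique(map$freq_hz))
  if (length(freqs) < 2) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "need >= 2 frequencies", call = sys.call())))
  }
  counts <- table(map$freq_hz)
  if (any(counts < 3)) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "need >= 3 locations per frequency", call = sys.call())))
  }
  one <- function(values, groups) {
    sw <- vapply(freqs, function(f) {
      x <- values[groups == f]
      if (length(unique(x)) < 3) NA_real_ else shapiro.test(x)$p.value
    }, numeric(1))
    names(sw) <- paste0(freqs, "Hz")
    if (length(unique(values)) == 1L) {
      kw_h <- 0; kw_p <- 1
    } else {
      kw <- kruskal.test(values, factor(groups))
      kw_h <- unname(kw$statistic); kw_p <- kw$p.value
    }
    list(shapiro_p = sw, kruskal_h = kw_h, kruskal_p = kw_p,
         significant_0.01 = kw_p < 0.01, significant_0.0005 = kw_p < 0.0005)
  }
  structure(list(
    frequencies_hz = freqs,
    n_per_frequency = as.integer(counts),
    k_storage = one(map$k_storage_pa, map$freq_hz),
    k_loss = one(map$k_loss_pa, map$freq_hz)
  ), class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("<frequency sweep statistics>\n")
  for (m in c("k_storage", "k_loss")) {
    r <- x[[m]]
    star <- if (r$significant_0.0005) "***" else if (r$significant_0.01) "**" else ""
    cat(sprintf("  %s: Kruskal-Wallis H = %.3f, p = %.3g %s\n",
                m, r$kruskal_h, r$kruskal_p, star))
    cat("    Shapiro-Wilk p:", paste(sprintf("%s %.3g", names(r$shapiro_p),
                                             r$shapiro_p), collapse = ", "), "\n")
  }
  invisible(x)
}
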