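#' Build a stimulation or flash schedule
#'
#' `stim_schedule()` lists indentation windows (onset/offset pairs with the
#' mechanical parameters of each trial); `flash_schedule()` builds the
#' alternating white/black full-field flash sequence used for ON/OFF
#' characterization.
#'
#' @param onset_s,offset_s Indentation window bounds, s.
#' @param depth_um,amplitude_um,frequency_hz Mechanical trial parameters
#'   (recycled).
#' @return A data.frame schedule.
#' @export
stim_schedule <- function(onset_s, offset_s, depth_um = 30,
                          amplitude_um = 0, frequency_hz = NA_real_) {
  if (length(offset_s) != length(onset_s) || any(offset_s <= onset_s)) {
    stop_invalid("each stimulation needs offset_s > onset_s")
  }
  data.frame(onset_s = onset_s, offset_s = offset_s,
             depth_um = rep_len(depth_um, length(onset_s)),
             amplitude_um = rep_len(amplitude_um, length(onset_s)),
             frequency_hz = rep_len(frequency_hz, length(onset_s)))
}

#' @rdname stim_schedule
#' @param start_s Time of the first flash, s.
#' @param n_repeats Number of white/black pairs.
#' @param period_s Time between consecutive flashes, s.
#' @param duration_s Flash duration, s.
#' @export
flash_schedule <- function(start_s = 10, n_repeats = 20, period_s = 2,
                           duration_s = 0.5) {
  times <- start_s + (seq_len(2 * n_repeats) - 1) * period_s
  data.frame(time_s = times,
             color = rep(c("white", "black"), n_repeats),
             duration_s = duration_s)
}

# distance (in electrode pitches) of each unit from an electrode coordinate
electrode_distance <- function(unit_positions, center) {
  sqrt((unit_positions[, 1] - center[1])^2 + (unit_positions[, 2] - center[2])^2)
}

# exponential-rise box-car envelope on [start, start+duration]
rise_envelope <- function(t, start, duration, tau) {
  e <- numeric(length(t))
  inside <- t >= start & t < start + duration
  e[inside] <- 1 - exp(-(t[inside] - start) / tau)
  e
}

#' Simulate HD-MEA spike trains with planted response structure
#'
#' Each unit fires as an inhomogeneous Poisson process (piecewise-constant
#' rate on a `dt_s` grid): a basal rate, plus flash-locked transients per
#' functional type (ON: white flash; OFF: black flash; ON_OFF: both; NC:
#' none; 200 ms half-cosine kernel peaking at `flash_gain x basal`), plus
#' the planted-cluster modulation around each indentation window (box-car
#' gain with exponential rise; per-unit latency grows with electrode
#' distance from the indentation center). Spike times are strictly
#' increasing per unit and the whole set is deterministic given `seed`.
#'
#' @param config A [retina_config()].
#' @param stim A [stim_schedule()] data.frame (or `NULL`).
#' @param flashes A [flash_schedule()] data.frame (or `NULL`).
#' @param duration_s Recording duration, s (must cover all events).
#' @param seed Integer seed.
#' @param dt_s Rate-grid resolution, s.
#' @param refractory_s Optional absolute refractory period, s (0 = pure
#'   Poisson).
#' @return A `spike_train_set`: list with `units` (data.frame: `unit_id`,
#'   `electrode_row`, `electrode_col`, `cell_type`, `basal_rate_hz`,
#'   `planted_cluster`), `spikes` (list of spike-time vectors),
#'   `duration_s`, and `events` (kind in `indent_on`, `indent_off`,
#'   `flash_white`, `flash_black`).
#' @examples
#' cfg <- retina_config(n_units = 20, seed = 1)
#' sts <- simulate_spike_trains(cfg, stim = stim_schedule(60, 90),
#'                              duration_s = 120, seed = 1)
#' sts
#' @export
simulate_spike_trains <- function(config, stim = NULL, flashes = NULL,
                                  duration_s, seed = NULL, dt_s = 0.01,
                                  refractory_s = 0) {
  stopifnot(inherits(config, "retina_config"))
  check_positive(duration_s, "duration_s")
  ev_times <- c(if (!is.null(stim)) c(stim$onset_s, stim$offset_s),
                if (!is.null(flashes)) flashes$time_s + flashes$duration_s)
  if (length(ev_times) && max(ev_times) > duration_s) {
    stop_invalid("duration_s must cover all scheduled events")
  }

  n <- config$n_units
  nbin <- ceiling(duration_s / dt_s)
  tgrid <- (seq_len(nbin) - 0.5) * dt_s
  dist_mm <- electrode_distance(config$unit_positions, config$indent_center) *
    config$pitch_um / 1000

  # per-unit stimulus multiplier spec: list of (sign, start, duration, tau, gain)
  cluster_of <- integer(n)
  for (ci in seq_along(config$planted_clusters)) {
    cluster_of[config$planted_clusters[[ci]]$members] <- ci
  }

  unit_multiplier <- function(u) {
    ci <- cluster_of[u]
    if (ci == 0L || is.null(stim) || !nrow(stim)) return(NULL)
    pc <- config$planted_clusters[[ci]]
    if (pc$kind == "none") return(NULL)
    lat <- pc$latency_s + config$latency_slope_s_per_mm * dist_mm[u]
    exc <- NULL; sup <- NULL
    stim_rows <- if (is.null(pc$events)) seq_len(nrow(stim)) else pc$events
    for (i in stim_rows) {
      on <- stim$onset_s[i]; off <- stim$offset_s[i]
      if (pc$kind %in% c("onset_excited", "both")) {
        exc <- cbind(exc, rise_envelope(tgrid, on + lat, pc$duration_s, pc$tau_s))
      }
      if (pc$kind %in% c("offset_excited", "both", "rebound")) {
        sta <- off + lat
        exc <- cbind(exc, rise_envelope(tgrid, sta, pc$duration_s, pc$tau_s))
      }
      if (pc$kind == "onset_suppressed") {
        sup <- cbind(sup, rise_envelope(tgrid, on + lat, pc$duration_s, pc$tau_s))
      }
      if (pc$kind == "offset_suppressed") {
        sup <- cbind(sup, rise_envelope(tgrid, off + lat, pc$duration_s, pc$tau_s))
      }
      if (pc$kind == "rebound") {
        sup <- cbind(sup, rise_envelope(tgrid, on + lat, max(off - on - lat, dt_s), pc$tau_s))
      }
    }
    e_exc <- if (is.null(exc)) numeric(nbin) else do.call(pmax, as.data.frame(exc))
    e_sup <- if (is.null(sup)) numeric(nbin) else do.call(pmax, as.data.frame(sup))
    if (pc$kind != "rebound" && any(e_exc > 1e-9 & e_sup > 1e-9)) {
      stop(structure(class = c("retinamech_schedule_conflict", "error", "condition"),
                     list(message = sprintf(
                       "unit %d has overlapping excitatory and suppressive modulation", u),
                       call = sys.call())))
    }
    m <- 1 + (pc$gain - 1) * e_exc
    m <- m * (1 - (1 - 1 / pc$gain) * e_sup)
    m
  }

  flash_kernel <- function(type, basal) {
    if (is.null(flashes) || !nrow(flashes) || type == "NC" || basal <= 0) return(NULL)
    want <- switch(type, ON = "white", OFF = "black", ON_OFF = c("white", "black"))
    sel <- flashes$color %in% want
    if (!any(sel)) return(NULL)
    add <- numeric(nbin)
    amp <- (config$flash_gain - 1) * basal
    for (tf in flashes$time_s[sel]) {
      inside <- tgrid >= tf & tgrid < tf + 0.2
      add[inside] <- add[inside] + amp * sin(pi * (tgrid[inside] - tf) / 0.2)
    }
    add
  }

  spikes <- with_local_seed(seed, {
    lapply(seq_len(n), function(u) {
      basal <- config$basal_rates_hz[u]
      m <- unit_multiplier(u)
      fk <- flash_kernel(config$cell_types[u], basal)
      if (is.null(m) && is.null(fk)) {
        # homogeneous Poisson fast path
        k <- rpois(1, basal * duration_s)
        st <- sort(runif(k, 0, duration_s))
      } else {
        rate <- basal * (if (is.null(m)) 1 else m) + (if (is.null(fk)) 0 else fk)
        counts <- rpois(nbin, rate * dt_s)
        pos <- counts > 0L
        idx <- rep.int(which(pos), counts[pos])
        st <- sort((idx - 1) * dt_s + runif(length(idx)) * dt_s)
      }
      if (length(st) > 1) st <- st[c(TRUE, diff(st) > 0)]
      if (refractory_s > 0 && length(st) > 1) {
        keep <- logical(length(st)); keep[1] <- TRUE; last <- st[1]
        for (i in 2:length(st)) {
          if (st[i] - last >= refractory_s) { keep[i] <- TRUE; last <- st[i] }
        }
        st <- st[keep]
      }
      st
    })
  })

  events <- rbind(
    if (!is.null(stim) && nrow(stim)) {
      rbind(data.frame(kind = "indent_on", time_s = stim$onset_s,
                       depth_um = stim$depth_um, amplitude_um = stim$amplitude_um,
                       frequency_hz = stim$frequency_hz),
            data.frame(kind = "indent_off", time_s = stim$offset_s,
                       depth_um = stim$depth_um, amplitude_um = stim$amplitude_um,
                       frequency_hz = stim$frequency_hz))
    },
    if (!is.null(flashes) && nrow(flashes)) {
      data.frame(kind = paste0("flash_", flashes$color), time_s = flashes$time_s,
                 depth_um = NA_real_, amplitude_um = NA_real_,
                 frequency_hz = NA_real_)
    }
  )
  if (!is.null(events)) events <- events[order(events$time_s), , drop = FALSE]

  structure(list(
    units = data.frame(unit_id = seq_len(n),
                       electrode_row = config$unit_positions[, 1],
                       electrode_col = config$unit_positions[, 2],
                       cell_type = config$cell_types,
                       basal_rate_hz = config$basal_rates_hz,
                       planted_cluster = cluster_of),
    spikes = spikes,
    duration_s = duration_s,
    events = events
  ), class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  nsp <- sum(lengths(x$spikes))
  cat(sprintf("<spike_train_set: %d units, %.0f s, %d spikes (%.2f Hz mean)>\n",
              nrow(x$units), x$duration_s, nsp,
              nsp / max(1, nrow(x$units)) / x$duration_s))
  if (!is.null(x$events)) {
    cat("  events:", paste(sprintf("%s@%.0fs", x$events$kind, x$events$time_s),
                           collapse = " "), "\n")
  }
  invisible(x)
}

#' Simulate a far-red-light saturation frame
#'
#' Under far-red light every electrode saturates except those shadowed by
#' the indentation probe. The frame is `TRUE` for saturating electrodes and
#' `FALSE` inside the probe-shadow disk; each entry is then flipped
#' independently with probability `flip_noise`.
#'
#' @param grid_shape Electrode grid (rows, cols).
#' @param probe_center Shadow-disk center (row, col).
#' @param probe_outline_radius Disk radius, in electrode pitches.
#' @param flip_noise Independent flip probability per electrode.
#' @param seed Integer seed.
#' @return Logical matrix of class `saturation_frame`.
#' @export
simulate_saturation_frame <- function(grid_shape = c(64, 64), probe_center,
                                      probe_outline_radius, flip_noise = 0,
                                      seed = NULL) {
  if (probe_outline_radius < 0) stop_invalid("probe_outline_radius must be >= 0")
  if (flip_noise < 0 || flip_noise >= 1) stop_invalid("flip_noise must be in [0, 1)")
  r0 <- probe_center[1]; c0 <- probe_center[2]
  if (r0 < 1 - probe_outline_radius || r0 > grid_shape[1] + probe_outline_radius ||
      c0 < 1 - probe_outline_radius || c0 > grid_shape[2] + probe_outline_radius) {
    stop_invalid("probe disk does not intersect the electrode grid")
  }
  rows <- matrix(seq_len(grid_shape[1]), grid_shape[1], grid_shape[2])
  cols <- matrix(seq_len(grid_shape[2]), grid_shape[1], grid_shape[2], byrow = TRUE)
  frame <- (rows - r0)^2 + (cols - c0)^2 > probe_outline_radius^2
  if (flip_noise > 0) {
    frame <- with_local_seed(seed, {
      flip <- matrix(runif(length(frame)) < flip_noise, nrow(frame))
      xor(frame, flip)
    })
  }
  structure(frame, class = c("saturation_frame", "matrix", "array"))
}
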