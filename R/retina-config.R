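#' Configure a synthetic retina on an HD-MEA grid
#'
#' Describes the unit population used by [simulate_spike_trains()]: unit
#' positions on the electrode grid (64 x 64, 42 um pitch by default),
#' per-unit functional type (ON / OFF / ON_OFF / NC, governing flash
#' responses), basal firing rates, and planted clusters of mechanically
#' responsive units around the indentation center.
#'
#' @param n_units Number of sorted units.
#' @param grid_shape Electrode grid (rows, cols).
#' @param pitch_um Electrode pitch, um.
#' @param unit_positions Integer matrix `n_units x 2` of (row, col)
#'   electrode coordinates (1-based); sampled uniformly without replacement
#'   when `NULL`.
#' @param cell_types Character vector of per-unit types in
#'   `c("ON","OFF","ON_OFF","NC")`; sampled from `type_probs` when `NULL`.
#' @param type_probs Sampling probabilities for ON/OFF/ON_OFF/NC when
#'   `cell_types` is `NULL`. The default is OFF-dominated, as under scotopic
#'   luminance.
#' @param basal_rates_hz Per-unit basal rates (recycled), Hz.
#' @param flash_gain Peak flash-response rate as a multiple of the basal
#'   rate (peak = gain x basal for the preferred polarity).
#' @param planted_clusters List of [planted_cluster()] specs; member sets
#'   must be disjoint.
#' @param indent_center Electrode coordinate (row, col) of the indentation.
#' @param latency_slope_s_per_mm Added response latency per mm of distance
#'   from `indent_center` (delays grow with distance from the probe).
#' @param seed Seed used only for sampling positions/types when not given.
#' @return A `retina_config` object.
#' @examples
#' cfg <- retina_config(n_units = 50, seed = 1)
#' cfg
#' @export
retina_config <- function(n_units,
                          grid_shape = c(64, 64),
                          pitch_um = 42,
                          unit_positions = NULL,
                          cell_types = NULL,
                          type_probs = c(ON = 0.2, OFF = 0.4, ON_OFF = 0.2, NC = 0.2),
                          basal_rates_hz = 5,
                          flash_gain = 4,
                          planted_clusters = list(),
                          indent_center = c(32, 32),
                          latency_slope_s_per_mm = 0.5,
                          seed = NULL) {
  check_positive(n_units, "n_units")
  cfg <- with_local_seed(seed, {
    if (is.null(unit_positions)) {
      idx <- sample.int(prod(grid_shape), n_units,
                        replace = n_units > prod(grid_shape))
      unit_positions <- cbind(row = (idx - 1L) %/% grid_shape[2] + 1L,
                              col = (idx - 1L) %% grid_shape[2] + 1L)
    }
    if (is.null(cell_types)) {
      cell_types <- sample(names(type_probs), n_units, replace = TRUE,
                           prob = type_probs)
    }
    list(unit_positions = unit_positions, cell_types = cell_types)
  })
  unit_positions <- cfg$unit_positions
  cell_types <- cfg$cell_types
  stopifnot(nrow(unit_positions) == n_units, length(cell_types) == n_units,
            all(cell_types %in% c("ON", "OFF", "ON_OFF", "NC")))
  if (any(unit_positions[, 1] < 1 | unit_positions[, 1] > grid_shape[1] |
          unit_positions[, 2] < 1 | unit_positions[, 2] > grid_shape[2])) {
    stop_invalid("unit positions outside electrode grid")
  }
  basal_rates_hz <- rep_len(basal_rates_hz, n_units)
  if (any(basal_rates_hz < 0)) stop_invalid("basal rates must be >= 0")
  members <- unlist(lapply(planted_clusters, `[[`, "members"))
  if (anyDuplicated(members)) stop_invalid("planted cluster member sets must be disjoint")
  if (length(members) && (any(members < 1) || any(members > n_units))) {
    stop_invalid("planted cluster members out of range")
  }
  structure(list(
    n_units = as.integer(n_units),
    grid_shape = as.integer(grid_shape),
    pitch_um = pitch_um,
    unit_positions = unit_positions,
    cell_types = cell_types,
    basal_rates_hz = basal_rates_hz,
    flash_gain = flash_gain,
    planted_clusters = planted_clusters,
    indent_center = indent_center,
    latency_slope_s_per_mm = latency_slope_s_per_mm
  ), class = "retina_config")
}

#' Specify one planted mechanically responsive cluster
#'
#' Members share a slow firing-rate modulation locked to the indentation
#' window: a box-car gain with exponential rise (time constant `tau_s`)
#' starting `latency_s` after stimulation onset and/or offset. Kinds:
#' `onset_excited`, `offset_excited`, `both`, `onset_suppressed`,
#' `offset_suppressed`, `rebound` (suppressed during the stimulus, excited
#' after release), `none`.
#'
#' @param members Integer unit indices.
#' @param kind Response kind (see above).
#' @param latency_s Cluster-level latency after the locking event, s.
#' @param duration_s Modulation duration, s.
#' @param gain Peak rate multiplier (> 1 excitation; suppression uses
#'   `1/gain`).
#' @param tau_s Exponential rise time constant, s.
#' @param events Optional indices of the stimulation-schedule rows this
#'   cluster locks to (`NULL` = every stimulation).
#' @return A `planted_cluster` spec (list).
#' @export
planted_cluster <- function(members,
                            kind = c("onset_excited", "offset_excited", "both",
                                     "onset_suppressed", "offset_suppressed",
                                     "rebound", "none"),
                            latency_s = 2, duration_s = 5, gain = 3, tau_s = 1,
                            events = NULL) {
  kind <- match.arg(kind)
  if (latency_s < 0) stop_invalid("latency_s must be >= 0")
  check_positive(duration_s, "duration_s")
  check_positive(gain, "gain")
  structure(list(members = as.integer(members), kind = kind,
                 latency_s = latency_s, duration_s = duration_s,
                 gain = gain, tau_s = tau_s, events = events),
            class = "planted_cluster")
}

#' @export
print.retina_config <- function(x, ...) {
  cat(sprintf("<retina_config: %d units on %dx%d grid (%g um pitch)>\n",
              x$n_units, x$grid_shape[1], x$grid_shape[2], x$pitch_um))
  print(table(x$cell_types))
  cat(sprintf("  %d planted cluster(s); indent center (%d, %d)\n",
              length(x$planted_clusters), x$indent_center[1], x$indent_center[2]))
  invisible(x)
}
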