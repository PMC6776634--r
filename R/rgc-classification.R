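#' Peak flash-response amplitudes per unit
#'
#' Builds the trial-averaged peri-stimulus rate (PSTH) around white and
#' black full-field flashes and takes the peak elevation above the basal
#' mean within the response window (flash duration + 0.5 s by default).
#' Amplitudes are floored at 0 so the bias index stays in `[-1, 1]`;
#' suppressive responses are not signed. Basal statistics (mean and
#' single-window SD) come from the pre-flash baseline interval.
#'
#' Use a short rate window (e.g. 0.2 s) for flash analysis: the 200 ms
#' transients would be washed out by the 2 s window used for the slow
#' mechanical responses.
#'
#' @param frm A raw (non-z-scored) `firing_rate_matrix`.
#' @param flashes A [flash_schedule()] data.frame, or an events table with
#'   `kind` in `flash_white` / `flash_black`.
#' @param response_window_s Post-onset window searched for the peak;
#'   default flash duration + 0.5 s.
#' @param baseline_interval `c(t0, t1)` for basal statistics; default from
#'   the start of the matrix to the first flash.
#' @return A `flash_response` data.frame: `unit_id`, `a_w_hz`, `a_b_hz`,
#'   `peak_w_hz`, `peak_b_hz`, `basal_mean_hz`, `basal_sd_hz`.
#' @export
peak_amplitudes <- function(frm, flashes, response_window_s = NULL,
                            baseline_interval = NULL) {
  stopifnot(inherits(frm, "firing_rate_matrix"))
  if (isTRUE(frm$normalized)) stop_invalid("peak_amplitudes needs raw (Hz) rates")
  if ("kind" %in% names(flashes)) {
    sel <- flashes$kind %in% c("flash_white", "flash_black")
    flashes <- data.frame(time_s = flashes$time_s[sel],
                          color = sub("^flash_", "", flashes$kind[sel]),
                          duration_s = 0.5)
  }
  if (!all(c("white", "black") %in% flashes$color)) {
    stop(structure(class = c("retinamech_protocol_error", "error", "condition"),
                   list(message = "need at least one white and one black flash",
                        call = sys.call())))
  }
  if (is.null(response_window_s)) response_window_s <- flashes$duration_s[1] + 0.5
  if (is.null(baseline_interval)) {
    baseline_interval <- c(min(frm$bin_centers_s), min(flashes$time_s))
  }
  bc <- frm$bin_centers_s
  base_sel <- bc >= baseline_interval[1] & bc < baseline_interval[2]
  if (sum(base_sel) < 2) stop_invalid("baseline interval too short for basal statistics")
  basal_mean <- rowMeans(frm$rates[, base_sel, drop = FALSE])
  basal_sd <- apply(frm$rates[, base_sel, drop = FALSE], 1, stats::sd)

  psth_peak <- function(color) {
    onsets <- flashes$time_s[flashes$color == color]
    slices <- lapply(onsets, function(on) {
      which(bc >= on & bc < on + response_window_s)
    })
    len <- min(lengths(slices))
    if (len < 1) stop_invalid("response window contains no rate bins")
    slices <- lapply(slices, function(ix) ix[seq_len(len)])
    acc <- matrix(0, nrow(frm$rates), len)
    for (ix in slices) acc <- acc + frm$rates[, ix, drop = FALSE]
    psth <- acc / length(slices)
    apply(psth, 1, max)
  }
  peak_w <- psth_peak("white")
  peak_b <- psth_peak("black")
  structure(data.frame(unit_id = frm$unit_ids,
                       a_w_hz = pmax(peak_w - basal_mean, 0),
                       a_b_hz = pmax(peak_b - basal_mean, 0),
                       peak_w_hz = peak_w, peak_b_hz = peak_b,
                       basal_mean_hz = basal_mean, basal_sd_hz = basal_sd,
                       row.names = NULL),
            class = c("flash_response", "data.frame"))
}

#' Bias index from white/black flash amplitudes
#'
#' `BI = (A_w - A_b) / (A_w + A_b)`; `NA` (undefined) when both amplitudes
#' are zero. Antisymmetric under swapping white and black.
#'
#' @param a_w,a_b Non-negative peak response amplitudes, Hz.
#' @return Bias index in `[-1, 1]`, or `NA` where undefined.
#' @examples
#' bias_index(1, 3)  # -0.5
#' @export
bias_index <- function(a_w, a_b) {
  if (any(a_w < 0, na.rm = TRUE) || any(a_b < 0, na.rm = TRUE)) {
    stop_invalid("amplitudes must be >= 0")
  }
  tot <- a_w + a_b
  ifelse(tot > 0, (a_w - a_b) / tot, NA_real_)
}

#' Classify units as ON / OFF / ON-OFF / NC
#'
#' The non-classified (NC) test runs first: units whose peak flash rate
#' does not rise above `basal_mean + basal_sd` (no excursion beyond
#' baseline variability), or whose bias index is undefined, are NC. The
#' remaining units are ON if `BI > 0.3`, OFF if `BI < -0.3`, and ON-OFF
#' otherwise (strict inequalities; `BI = 0.3` is ON-OFF).
#'
#' @param responses A `flash_response` data.frame from [peak_amplitudes()].
#' @return The data.frame with added `bias_index` and `label` columns.
#' @export
classify_units <- function(responses) {
  stopifnot(inherits(responses, "data.frame"))
  bi <- bias_index(responses$a_w_hz, responses$a_b_hz)
  peak <- pmax(responses$peak_w_hz, responses$peak_b_hz)
  nc <- peak < responses$basal_mean_hz + responses$basal_sd_hz | is.na(bi)
  label <- ifelse(nc, "NC",
                  ifelse(bi > 0.3, "ON", ifelse(bi < -0.3, "OFF", "ON_OFF")))
  responses$bias_index <- bi
  responses$label <- label
  responses
}

#' Cell-type composition of responsive vs unresponsive clusters
#'
#' @param labels Per-unit cell-type labels (`ON`, `OFF`, `ON_OFF`, `NC`).
#' @param clusters A `cluster_assignment` (or integer cluster labels) for
#'   the same units.
#' @param responsive_cluster_ids Cluster indices counted as "responsive to
#'   stimuli".
#' @return Data.frame with one row per group (`responsive`,
#'   `unresponsive`) and one fraction column per cell type; fractions sum
#'   to 1 per group. Empty groups yield a warning and an all-`NA` row.
#' @export
cluster_composition <- function(labels, clusters, responsive_cluster_ids) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$labels else clusters
  stopifnot(length(labels) == length(cl))
  group <- ifelse(cl %in% responsive_cluster_ids, "responsive", "unresponsive")
  types <- c("ON", "OFF", "ON_OFF", "NC")
  out <- do.call(rbind, lapply(c("responsive", "unresponsive"), function(g) {
    sel <- group == g
    if (!any(sel)) {
      warning(sprintf("group '%s' is empty", g))
      frac <- rep(NA_real_, length(types))
    } else {
      frac <- as.numeric(table(factor(labels[sel], levels = types)) / sum(sel))
    }
    stats::setNames(data.frame(g, sum(sel), t(frac)),
                    c("group", "n_units", types))
  }))
  rownames(out) <- NULL
  out
}
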