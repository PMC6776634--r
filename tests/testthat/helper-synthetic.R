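# Shared fixtures and independent oracles, built in code at test time.

# FFT-bin oracle for amplitude/phase at a known frequency on an
# integer-period, noise-free segment; independent of the least-squares path.
fft_bin_oracle <- function(x, f, fs) {
  n <- length(x)
  k <- round(f * n / fs)
  X <- stats::fft(x - mean(x))[k + 1]
  # for A*sin(w t + phi), Arg(X_k) = phi - pi/2
  list(amp = 2 * Mod(X) / n,
       phase = atan2(Im(X), Re(X)) + pi / 2)
}

# hand-built spike_train_set from a list of spike-time vectors
make_sts <- function(spike_list, duration_s, rows = NULL, cols = NULL) {
  n <- length(spike_list)
  structure(list(
    units = data.frame(unit_id = seq_len(n),
                       electrode_row = if (is.null(rows)) rep(32L, n) else rows,
                       electrode_col = if (is.null(cols)) seq_len(n) else cols),
    spikes = spike_list,
    duration_s = duration_s,
    events = NULL
  ), class = "spike_train_set")
}

# hand-built firing_rate_matrix
make_frm <- function(rates, step_s = 0.01, window_s = 2, normalized = FALSE) {
  structure(list(rates = rates,
                 bin_centers_s = window_s / 2 + (seq_len(ncol(rates)) - 1) * step_s,
                 unit_ids = seq_len(nrow(rates)),
                 window_s = window_s, step_s = step_s, normalized = normalized),
            class = "firing_rate_matrix")
}

# the 4-cluster recovery scenario: 300 units partitioned into four planted
# response clusters with staggered latencies (orthogonal time courses),
# 120 s basal + 60 s indentation
make_cluster_scenario <- function(seed, gain = 3, duration_s = 8) {
  members <- split(1:300, rep(1:4, each = 75))
  pcs <- list(
    planted_cluster(members[[1]], "onset_excited",  latency_s = 1,
                    duration_s = duration_s, gain = gain),
    planted_cluster(members[[2]], "onset_excited",  latency_s = 20,
                    duration_s = duration_s, gain = gain),
    planted_cluster(members[[3]], "onset_excited",  latency_s = 40,
                    duration_s = duration_s, gain = gain),
    planted_cluster(members[[4]], "offset_excited", latency_s = 1,
                    duration_s = duration_s, gain = gain)
  )
  cfg <- retina_config(n_units = 300, basal_rates_hz = 5,
                       planted_clusters = pcs, indent_center = c(32, 32),
                       seed = seed)
  sts <- simulate_spike_trains(cfg, stim = stim_schedule(120, 180),
                               duration_s = 200, seed = seed + 1000)
  list(sts = sts, truth = rep(1:4, each = 75))
}

# run the correlation-clustering pipeline on a scenario; returns selection,
# exactness of planted-partition recovery, and the phase contrast summary
run_cluster_pipeline <- function(sts, truth, k_range = c(4, 60)) {
  aligned <- align_stimulation_window(sts, cbind(120, 180))
  ind <- zscore_rates(compute_firing_rate(aligned, c(120, 190), 2, 0.01))
  bas <- zscore_rates(compute_firing_rate(aligned, c(0, 120), 2, 0.01))
  ci <- correlation_matrix(ind)
  cb <- correlation_matrix(bas)
  ca <- cluster_units(ci, k_range)
  tr <- truth[as.integer(ca$unit_ids)]
  tab <- table(tr, ca$labels)
  exact <- all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  ro <- reorder_basal(cb, ca, indent_corr = ci)
  list(assignment = ca, exact = exact, summary = ro$summary)
}

# feature table with a planted (pressure AND d5) success rule + label noise
make_rule_table <- function(n = 200, noise = 0.05, seed = 7) {
  retinamech:::with_local_seed(seed, {
    tbl <- data.frame(contact_area_um2 = runif(n, 3000, 12000),
                      strain = runif(n, 0.2, 0.7),
                      pressure_pa = runif(n, 50, 600),
                      depth_um = runif(n, 10, 60),
                      d5 = rpois(n, 6),
                      r5 = rgamma(n, 5, 1))
    out <- tbl$pressure_pa > 300 & tbl$d5 >= 6
    tbl$outcome <- xor(out, runif(n) < noise)
    tbl
  })
}
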