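#' Default configuration for the full demo pipeline
#'
#' All stage parameters with their standard defaults: 2 s rate window with
#' 10 ms steps, cluster count selected in 4..60, bias-index thresholds at
#' +/-0.3, 0.1 Hz minimum unit rate, d5 radius of 5 electrodes, 1000
#' decision-tree repeats. Unknown keys passed through `...` are rejected.
#'
#' @param ... Overrides for any listed parameter.
#' @return Named list of pipeline parameters.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    # synthetic dataset
    n_units = 300, basal_rate_hz = 5, flash_gain = 4, n_flash_repeats = 20,
    n_trials = 16, trial_period_s = 150, stim_duration_s = 30,
    trial_depths_um = c(10, 20, 30, 60), probe_radius_um = 125,
    response_gain = 3, response_duration_s = 8, response_latency_s = 1,
    pressure_threshold_pa = 400, d5_threshold = 5,
    # mechanics map
    map_locations = 4, map_spacing_um = 50, map_noise_sd_um = 0.005,
    # analysis parameters (paper defaults)
    window_s = 2, step_s = 0.01, flash_window_s = 0.2, flash_step_s = 0.02,
    k_range = c(4, 60), bi_threshold = 0.3, min_rate_hz = 0.1,
    d5_radius = 5, n_repeats = 1000, post_offset_margin_s = 10,
    # optional external inputs (simulated when NULL)
    spike_csv = NULL, event_csv = NULL
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_invalid("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg
}

# crude per-trial responsiveness call from spike counts near the center
detect_trial_response <- function(spikes, center, onset, offset, radius = 5,
                                  basal_s = 120, margin_s = 10, z_thresh = 3,
                                  min_units = 3) {
  pos <- cbind(spikes$units$electrode_row, spikes$units$electrode_col)
  near <- which(electrode_distance(pos, center) <= radius)
  if (!length(near)) return(list(outcome = FALSE, n_responsive = 0L))
  t_ind <- offset + margin_s - onset
  z <- vapply(spikes$spikes[near], function(st) {
    r_bas <- sum(st >= onset - basal_s & st < onset) / basal_s
    r_ind <- sum(st >= onset & st < offset + margin_s) / t_ind
    se <- sqrt(max(r_bas, 0.1) / t_ind)
    (r_ind - r_bas) / se
  }, numeric(1))
  n_resp <- sum(z > z_thresh)
  list(outcome = n_resp >= min_units, n_responsive = n_resp)
}

#' Run the full mechano-electrophysiology pipeline on a synthetic dataset
#'
#' Executes every stage in order — viscoelastic map mechanics, probe
#' localization, spike-train clustering, ON/OFF classification, and
#' decision-tree predictors — on a self-generated synthetic retina (or on
#' spike/event CSVs named in the config), writing all artifacts plus a JSON
#' run report to `out_dir`. The same config and seed reproduce the outputs
#' byte for byte.
#'
#' The synthetic experiment plants a mechanically responsive cell cluster
#' under the probe for every trial whose contact pressure and local unit
#' count (d5) clear the configured thresholds, so trial success is detected
#' from the spiking data, not copied from the ground truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; every stochastic stage derives its own
#'   stream from it.
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages.
#' @return The run report, invisibly (also written to
#'   `<out_dir>/report.json`).
#' @export
run_full_pipeline <- function(out_dir, seed = 1, config = pipeline_config(),
                              verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", ..., "]")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  report <- list(package_version = as.character(utils::packageVersion("retinamech")),
                 seed = seed, parameters = config[!vapply(config, is.null, logical(1))])

  ## stage 1: mechanics ------------------------------------------------
  say("mechanics: simulating and analyzing indentation map")
  tissue <- sls_tissue_preset()
  map <- stage("mechanics", {
    traces <- lapply(seq_len(config$map_locations), function(i) {
      simulate_indentation_trace(indentation_protocol("map_sweep"), tissue,
                                 noise_sd_um = config$map_noise_sd_um,
                                 seed = derive_seed(seed, 100 + i),
                                 x_um = (i - 1) * config$map_spacing_um, y_um = 0)
    })
    build_indentation_map(traces, spacing_um = config$map_spacing_um)
  })
  write.csv(map, file.path(out_dir, "map.csv"), row.names = FALSE, quote = FALSE)
  sweep_stats <- stage("mechanics", frequency_sweep_stats(map))
  jsonlite::write_json(
    list(kruskal_p_storage = sweep_stats$k_storage$kruskal_p,
         kruskal_p_loss = sweep_stats$k_loss$kruskal_p),
    file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
  report$mechanics <- list(
    n_locations = length(unique(map$x_um)),
    k_storage_mean_pa = stats::setNames(
      as.list(tapply(map$k_storage_pa, map$freq_hz, mean)),
      paste0(sort(unique(map$freq_hz)), "Hz")),
    kruskal_p_storage = sweep_stats$k_storage$kruskal_p)

  ## stage 2: synthetic retina / or external spikes --------------------
  say("simulate: building retina recording")
  trial_grid <- expand.grid(row = c(12, 24, 36, 48), col = c(12, 24, 36, 48))
  n_trials <- min(config$n_trials, nrow(trial_grid))
  depths <- rep_len(config$trial_depths_um, n_trials)
  loads <- vapply(depths, function(h) {
    1e6 * (4 / 3) * 2000 * sqrt(config$probe_radius_um * 1e-6) * (h * 1e-6)^1.5
  }, numeric(1))
  flashes <- flash_schedule(start_s = 10, n_repeats = config$n_flash_repeats)
  t0 <- max(flashes$time_s) + 150  # >= 120 s basal before the first trial
  onsets <- t0 + (seq_len(n_trials) - 1) * config$trial_period_s
  stim <- stim_schedule(onsets, onsets + config$stim_duration_s,
                        depth_um = depths)
  duration <- max(stim$offset_s) + 60

  built <- stage("simulate", {
    if (!is.null(config$spike_csv)) {
      if (!file.exists(config$spike_csv)) {
        stop("missing input path: ", config$spike_csv)
      }
      sts <- read_spike_csv(config$spike_csv, config$event_csv)
      list(sts = sts, trials = NULL)
    } else {
      cfg0 <- retina_config(n_units = config$n_units,
                            basal_rates_hz = config$basal_rate_hz,
                            flash_gain = config$flash_gain,
                            indent_center = as.integer(trial_grid[1, ]),
                            seed = derive_seed(seed, 200))
      pos <- cfg0$unit_positions
      trials <- data.frame(trial_id = seq_len(n_trials),
                           center_row = trial_grid$row[seq_len(n_trials)],
                           center_col = trial_grid$col[seq_len(n_trials)],
                           depth_um = depths, max_load_un = loads,
                           probe_radius_um = config$probe_radius_um)
      trials$pressure_pa <- vapply(seq_len(n_trials), function(i) {
        trial_pressure_strain(loads[i], config$probe_radius_um, depths[i])$pressure_pa
      }, numeric(1))
      trials$d5_true <- vapply(seq_len(n_trials), function(i) {
        sum(electrode_distance(pos, c(trials$center_row[i], trials$center_col[i])) <=
              config$d5_radius)
      }, numeric(1))
      qualifies <- trials$pressure_pa >= config$pressure_threshold_pa &
        trials$d5_true >= config$d5_threshold
      clusters <- list()
      for (i in which(qualifies)) {
        members <- which(electrode_distance(
          pos, c(trials$center_row[i], trials$center_col[i])) <= config$d5_radius)
        clusters[[length(clusters) + 1L]] <- planted_cluster(
          members, "onset_excited", latency_s = config$response_latency_s,
          duration_s = config$response_duration_s, gain = config$response_gain,
          events = i)
      }
      cfg <- retina_config(n_units = config$n_units,
                           unit_positions = pos, cell_types = cfg0$cell_types,
                           basal_rates_hz = config$basal_rate_hz,
                           flash_gain = config$flash_gain,
                           planted_clusters = clusters,
                           indent_center = as.integer(trial_grid[1, ]))
      sts <- simulate_spike_trains(cfg, stim = stim, flashes = flashes,
                                   duration_s = duration,
                                   seed = derive_seed(seed, 201))
      list(sts = sts, trials = trials, qualifies = qualifies)
    }
  })
  sts <- filter_units(built$sts, config$min_rate_hz)
  write_spike_csv(sts, file.path(out_dir, "spikes.csv"),
                  file.path(out_dir, "events.csv"))

  ## stage 3: probe localization ---------------------------------------
  say("locate: probe localization from saturation frame")
  loc <- stage("locate", {
    frame <- simulate_saturation_frame(
      probe_center = as.integer(trial_grid[1, ]), probe_outline_radius = 6,
      flip_noise = 0.02, seed = derive_seed(seed, 300))
    write_saturation_csv(frame, file.path(out_dir, "saturation.csv"))
    locate_probe(frame)
  })
  jsonlite::write_json(list(row = loc$center[["row"]], col = loc$center[["col"]]),
                       file.path(out_dir, "center.json"), auto_unbox = TRUE)
  report$localization <- list(center_row = loc$center[["row"]],
                              center_col = loc$center[["col"]])

  ## stage 4: trial outcomes + spike clustering ------------------------
  say("spikes: trial outcomes, correlation clustering")
  trials <- built$trials
  if (is.null(trials)) {
    # external spikes: recover trial windows from the event table and take
    # the localized probe center for every trial
    on_ev <- sts$events[sts$events$kind == "indent_on", , drop = FALSE]
    off_ev <- sts$events[sts$events$kind == "indent_off", , drop = FALSE]
    n_trials <- nrow(on_ev)
    if (!n_trials) stop("pipeline stage 'spikes' failed: no indentation events")
    stim <- stim_schedule(on_ev$time_s, off_ev$time_s,
                          depth_um = on_ev$depth_um)
    trials <- data.frame(trial_id = seq_len(n_trials),
                         center_row = loc$center[["row"]],
                         center_col = loc$center[["col"]],
                         depth_um = on_ev$depth_um,
                         max_load_un = NA_real_,
                         probe_radius_um = config$probe_radius_um)
  }
  outcomes <- stage("spikes", vapply(seq_len(n_trials), function(i) {
    detect_trial_response(sts, c(trials$center_row[i], trials$center_col[i]),
                          stim$onset_s[i], stim$offset_s[i],
                          radius = config$d5_radius,
                          margin_s = config$post_offset_margin_s)$outcome
  }, logical(1)))
  trials$outcome <- outcomes

  focus <- if (any(outcomes)) which(outcomes)[1] else 1L
  cl_res <- stage("spikes", {
    aligned <- align_stimulation_window(
      sts, cbind(stim$onset_s[focus], stim$offset_s[focus]))
    w <- aligned$windows
    basal_frm <- zscore_rates(compute_firing_rate(
      aligned, c(w$basal_start_s, w$basal_end_s), config$window_s, config$step_s))
    ind_frm <- zscore_rates(compute_firing_rate(
      aligned, c(w$indent_start_s, w$indent_end_s + config$post_offset_margin_s),
      config$window_s, config$step_s))
    ind_corr <- correlation_matrix(ind_frm)
    basal_corr <- correlation_matrix(basal_frm)
    common <- intersect(rownames(ind_corr), rownames(basal_corr))
    ca <- cluster_units(ind_corr[common, common], config$k_range)
    ro <- reorder_basal(basal_corr[common, common], ca,
                        indent_corr = ind_corr[common, common])
    tc <- cluster_timecourse(ind_frm, ca)
    resp <- which(vapply(tc, function(d) max(abs(d$mean_z)) >= 2, logical(1)))
    list(assignment = ca, reorder = ro, responsive_clusters = unname(resp))
  })
  write.csv(data.frame(unit_id = cl_res$assignment$unit_ids,
                       cluster = cl_res$assignment$labels),
            file.path(out_dir, "clusters.csv"), row.names = FALSE, quote = FALSE)
  report$clustering <- list(
    focus_trial = focus, k_selected = cl_res$assignment$k_selected,
    n_responsive_clusters = length(cl_res$responsive_clusters),
    phase_summary = cl_res$reorder$summary)

  ## stage 5: ON/OFF classification ------------------------------------
  say("classify: bias-index classification")
  cls <- stage("classify", {
    frm_flash <- compute_firing_rate(
      sts, c(0, max(flashes$time_s) + 5), config$flash_window_s, config$flash_step_s)
    classify_units(peak_amplitudes(frm_flash, flashes))
  })
  write.csv(cls[, c("unit_id", "a_w_hz", "a_b_hz", "bias_index", "label")],
            file.path(out_dir, "classification.csv"), row.names = FALSE, quote = FALSE)
  comp <- stage("classify", {
    ids <- as.integer(cl_res$assignment$unit_ids)
    cluster_composition(cls$label[match(ids, cls$unit_id)],
                        cl_res$assignment, cl_res$responsive_clusters)
  })
  write.csv(comp, file.path(out_dir, "composition.csv"), row.names = FALSE, quote = FALSE)
  report$classification <- list(label_counts = as.list(table(cls$label)))

  ## stage 6: predictors ------------------------------------------------
  say("predict: feature table and tree importance")
  imp <- stage("predict", {
    trials$basal_start_s <- stim$onset_s - 120
    trials$basal_end_s <- stim$onset_s
    ft <- build_feature_table(trials, sts, radius = config$d5_radius)
    write.csv(ft, file.path(out_dir, "features.csv"), row.names = FALSE, quote = FALSE)
    if (length(unique(ft$outcome)) < 2) {
      NULL  # degenerate outcome: skip the tree, keep the table
    } else {
      feature_importance(ft, n_repeats = config$n_repeats,
                         seed = derive_seed(seed, 600))
    }
  })
  if (!is.null(imp)) {
    jsonlite::write_json(imp$importance, file.path(out_dir, "importance.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    report$predictors <- list(
      n_trials = n_trials, n_successful = sum(trials$outcome),
      top_features = head(imp$importance$feature, 3))
  } else {
    report$predictors <- list(n_trials = n_trials,
                              n_successful = sum(trials$outcome),
                              top_features = character(0))
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done: report written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
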