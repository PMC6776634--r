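#' Drop units firing below a minimum rate
#'
#' Units with fewer than `min_rate_hz` spikes per second over the whole
#' recording are removed (the threshold is inclusive: a unit at exactly the
#' minimum rate is kept). Unit order is preserved.
#'
#' @param spikes A `spike_train_set`.
#' @param min_rate_hz Minimum mean rate, Hz.
#' @return Filtered `spike_train_set`.
#' @export
filter_units <- function(spikes, min_rate_hz = 0.1) {
  stopifnot(inherits(spikes, "spike_train_set"))
  rate <- lengths(spikes$spikes) / spikes$duration_s
  keep <- rate >= min_rate_hz
  if (!any(keep)) warning("no units survive the rate filter")
  spikes$units <- spikes$units[keep, , drop = FALSE]
  rownames(spikes$units) <- NULL
  spikes$spikes <- spikes$spikes[keep]
  spikes
}

#' Sliding-window firing rates
#'
#' Counts spikes in a `window_s`-long window sliding in steps of `step_s`
#' over `interval`; bin centers are placed so that every window lies fully
#' inside the interval, and each rate is `count / window_s`. Windows are
#' left-closed, right-open.
#'
#' @param spikes A `spike_train_set`.
#' @param interval `c(t0, t1)` in s (defaults to the whole recording).
#' @param window_s Window length, s.
#' @param step_s Step between bin centers, s.
#' @return A `firing_rate_matrix`: list with `rates` (units x bins, Hz),
#'   `bin_centers_s`, `unit_ids`, `window_s`, `step_s`, `normalized`.
#' @export
compute_firing_rate <- function(spikes, interval = NULL, window_s = 2,
                                step_s = 0.01) {
  stopifnot(inherits(spikes, "spike_train_set"))
  if (is.null(interval)) interval <- c(0, spikes$duration_s)
  t0 <- interval[1]; t1 <- interval[2]
  if (t1 - t0 < window_s) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "interval shorter than the rate window",
                        call = sys.call())))
  }
  centers <- seq(t0 + window_s / 2, t1 - window_s / 2 + 1e-12, by = step_s)
  lo <- centers - window_s / 2
  hi <- centers + window_s / 2
  rates <- t(matrix(vapply(spikes$spikes, function(st) {
    (findInterval(hi, st, left.open = TRUE) -
       findInterval(lo, st, left.open = TRUE)) / window_s
  }, numeric(length(centers))), nrow = length(centers)))
  structure(list(rates = rates, bin_centers_s = centers,
                 unit_ids = spikes$units$unit_id,
                 window_s = window_s, step_s = step_s, normalized = FALSE),
            class = "firing_rate_matrix")
}

#' Z-score a firing-rate matrix per unit
#'
#' Each row is centered and scaled by its population SD (divisor `n`) over
#' the matrix's own bins. Rows with zero SD (constant rate) are flagged in
#' `constant_units` and left as all-zero rows rather than NaN; downstream
#' correlation/clustering excludes them.
#'
#' @param frm A `firing_rate_matrix`.
#' @return The z-scored `firing_rate_matrix` (`normalized = TRUE`).
#' @export
zscore_rates <- function(frm) {
  stopifnot(inherits(frm, "firing_rate_matrix"))
  if (ncol(frm$rates) < 2) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "need >= 2 bins to z-score", call = sys.call())))
  }
  mu <- rowMeans(frm$rates)
  centered <- frm$rates - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  constant <- sd_pop == 0
  z <- centered / ifelse(constant, 1, sd_pop)
  frm$rates <- z
  frm$normalized <- TRUE
  frm$constant_units <- frm$unit_ids[constant]
  frm
}

#' Pearson correlation matrix between unit rate rows
#'
#' @param frm A (normally z-scored) `firing_rate_matrix`. Constant units
#'   flagged by [zscore_rates()] are excluded.
#' @return Symmetric correlation matrix (unit diagonal) with unit ids as
#'   dimnames.
#' @export
correlation_matrix <- function(frm) {
  stopifnot(inherits(frm, "firing_rate_matrix"))
  keep <- if (is.null(frm$constant_units)) {
    rep(TRUE, length(frm$unit_ids))
  } else {
    !(frm$unit_ids %in% frm$constant_units)
  }
  if (sum(keep) < 2) {
    stop(structure(class = c("retinamech_insufficient_data", "error", "condition"),
                   list(message = "need >= 2 non-constant units", call = sys.call())))
  }
  cc <- stats::cor(t(frm$rates[keep, , drop = FALSE]))
  dimnames(cc) <- list(frm$unit_ids[keep], frm$unit_ids[keep])
  cc
}

#' Cluster units by absolute Pearson correlation
#'
#' Hierarchical agglomerative clustering (average linkage) on the distance
#' `1 - |rho|`, so correlated and anti-correlated units cluster together.
#' The dendrogram is cut at every `k` in `k_range` and the mean silhouette
#' width on the precomputed distance selects `k` (ties go to the smallest
#' `k`). Deterministic.
#'
#' @param corr Correlation matrix from [correlation_matrix()].
#' @param k_range `c(k_min, k_max)` cluster counts to evaluate.
#' @return A `cluster_assignment`: list with `unit_ids`, `labels`,
#'   `k_selected`, `silhouette_by_k`, `linkage_method`.
#' @export
cluster_units <- function(corr, k_range = c(4, 60)) {
  n <- nrow(corr)
  stopifnot(n == ncol(corr))
  d <- as.dist(1 - abs(corr))
  k_min <- k_range[1]; k_max <- k_range[2]
  if (n <= k_min) {
    warning(sprintf("only %d units; truncating k range", n))
    k_min <- max(2L, n - 1L)
  }
  k_max <- min(k_max, n - 1L)
  hc <- hclust(d, method = "average")
  if (max(d) < 1e-12) {
    warning("all units identical under |rho|; returning a single cluster")
    return(structure(list(unit_ids = rownames(corr),
                          labels = rep(1L, n), k_selected = 1L,
                          silhouette_by_k = numeric(0),
                          linkage_method = "average"),
                     class = "cluster_assignment"))
  }
  ks <- seq.int(k_min, k_max)
  sil <- vapply(ks, function(k) {
    labs <- cutree(hc, k = k)
    mean(cluster::silhouette(labs, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- ks
  k_sel <- ks[which.max(sil)]  # which.max takes the first (smallest k) on ties
  structure(list(unit_ids = rownames(corr),
                 labels = unname(cutree(hc, k = k_sel)),
                 k_selected = k_sel,
                 silhouette_by_k = sil,
                 linkage_method = "average"),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment: %d units in %d clusters (avg linkage, 1-|rho|)>\n",
              length(x$labels), x$k_selected))
  if (length(x$silhouette_by_k)) {
    cat(sprintf("  silhouette at k = %d: %.3f\n", x$k_selected,
                x$silhouette_by_k[as.character(x$k_selected)]))
  }
  print(table(cluster = x$labels))
  invisible(x)
}

#' Reorder the basal correlation matrix by indentation-phase clusters
#'
#' Permutes rows/columns of the basal-phase correlation matrix so that the
#' clusters found during the indentation phase are contiguous, and reports
#' the mean within-cluster and between-cluster `|rho|` for both phases
#' (clusters of size 1 are excluded from the within-cluster mean).
#'
#' @param basal_corr Basal-phase correlation matrix (same unit set as the
#'   clustering).
#' @param clusters A `cluster_assignment` from the indentation phase.
#' @param indent_corr Optional indentation-phase correlation matrix for the
#'   phase contrast summary.
#' @return List with `reordered` (permuted basal matrix), `order`, and
#'   `summary` (data.frame: phase, mean within/between `|rho|`).
#' @export
reorder_basal <- function(basal_corr, clusters, indent_corr = NULL) {
  ids <- rownames(basal_corr)
  if (!setequal(ids, clusters$unit_ids) || length(ids) != length(clusters$unit_ids)) {
    stop(structure(class = c("retinamech_alignment_error", "error", "condition"),
                   list(message = "basal matrix and clustering cover different unit sets",
                        call = sys.call())))
  }
  labs <- clusters$labels[match(ids, clusters$unit_ids)]
  ord <- order(labs)
  reordered <- basal_corr[ord, ord]
  phase_summary <- function(cc, labels) {
    a <- abs(cc)
    same <- outer(labels, labels, "==")
    off <- !diag(nrow(a))
    sizes <- table(labels)
    in_big <- labels %in% as.integer(names(sizes)[sizes >= 2])
    within <- mean(a[same & off & outer(in_big, in_big, "&")])
    between <- mean(a[!same])
    c(within = within, between = between)
  }
  sm <- rbind(basal = phase_summary(basal_corr, labs),
              indentation = if (!is.null(indent_corr)) {
                phase_summary(indent_corr[ids, ids], labs)
              } else c(within = NA_real_, between = NA_real_))
  summary <- data.frame(phase = rownames(sm),
                        mean_within_abs_rho = sm[, "within"],
                        mean_between_abs_rho = sm[, "between"],
                        row.names = NULL)
  list(reordered = reordered, order = ord, summary = summary)
}

#' Annotate a recording with stimulation windows
#'
#' Pairs of (start, end) triggers from the indenter are checked for
#' consistency and written into the event list; each onset also defines its
#' basal reference window as the 120 s immediately preceding it (truncated
#' at the recording start with a warning).
#'
#' @param spikes A `spike_train_set`.
#' @param triggers Two-column matrix/data.frame of (start_s, end_s) pairs.
#' @param basal_s Basal window length before each onset, s.
#' @return The `spike_train_set` with updated `events` and a `windows`
#'   element (data.frame: `basal_start_s`, `basal_end_s`, `indent_start_s`,
#'   `indent_end_s`).
#' @export
align_stimulation_window <- function(spikes, triggers, basal_s = 120) {
  stopifnot(inherits(spikes, "spike_train_set"))
  triggers <- as.matrix(triggers)
  bad <- triggers[, 2] <= triggers[, 1] |
    triggers[, 1] < 0 | triggers[, 2] > spikes$duration_s
  if (any(is.na(triggers)) || any(bad)) {
    stop(structure(class = c("retinamech_trigger_error", "error", "condition"),
                   list(message = "triggers must be paired (start < end) and inside the recording",
                        call = sys.call())))
  }
  basal_start <- triggers[, 1] - basal_s
  if (any(basal_start < 0)) {
    warning("basal window truncated at recording start")
    basal_start <- pmax(basal_start, 0)
  }
  windows <- data.frame(basal_start_s = basal_start,
                        basal_end_s = triggers[, 1],
                        indent_start_s = triggers[, 1],
                        indent_end_s = triggers[, 2])
  ev <- rbind(data.frame(kind = "indent_on", time_s = triggers[, 1],
                         depth_um = NA_real_, amplitude_um = NA_real_,
                         frequency_hz = NA_real_),
              data.frame(kind = "indent_off", time_s = triggers[, 2],
                         depth_um = NA_real_, amplitude_um = NA_real_,
                         frequency_hz = NA_real_))
  old <- spikes$events
  if (!is.null(old)) {
    old <- old[!old$kind %in% c("indent_on", "indent_off"), , drop = FALSE]
  }
  spikes$events <- rbind(old, ev)
  spikes$events <- spikes$events[order(spikes$events$time_s), , drop = FALSE]
  spikes$windows <- windows
  spikes
}

#' Per-cluster mean and SEM firing-rate time courses
#'
#' @param frm A z-scored `firing_rate_matrix`.
#' @param clusters A `cluster_assignment` on the same units.
#' @return List (one element per cluster) of data.frames with
#'   `bin_center_s`, `mean_z`, `sem_z`, plus attribute `n_units`. For
#'   single-unit clusters SEM is 0 and the element carries
#'   `flag = "single_unit"`.
#' @export
cluster_timecourse <- function(frm, clusters) {
  stopifnot(inherits(frm, "firing_rate_matrix"))
  idx <- match(clusters$unit_ids, frm$unit_ids)
  if (any(is.na(idx))) {
    stop(structure(class = c("retinamech_alignment_error", "error", "condition"),
                   list(message = "clustered units missing from rate matrix",
                        call = sys.call())))
  }
  lapply(split(idx, clusters$labels), function(rows) {
    x <- frm$rates[rows, , drop = FALSE]
    m <- colMeans(x)
    sem <- if (nrow(x) > 1) apply(x, 2, stats::sd) / sqrt(nrow(x)) else rep(0, ncol(x))
    out <- data.frame(bin_center_s = frm$bin_centers_s, mean_z = m, sem_z = sem)
    attr(out, "n_units") <- nrow(x)
    if (nrow(x) == 1) attr(out, "flag") <- "single_unit"
    out
  })
}
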