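test_that("rate filter is inclusive at the threshold", {
  sts <- make_sts(list(seq(5, 95, length.out = 9),    # 0.09 Hz: dropped
                       seq(5, 95, length.out = 10),   # 0.10 Hz: kept
                       seq(0.5, 99.5, by = 0.5)),     # 2 Hz: kept
                  duration_s = 100)
  kept <- filter_units(sts, 0.1)
  expect_equal(kept$units$unit_id, c(2L, 3L))
  expect_warning(filter_units(make_sts(list(numeric(0)), 100), 0.1),
                 "no units survive")
})

test_that("sliding-window rates count spikes exactly", {
  sts <- make_sts(list(seq(1.05, 2.95, length.out = 20), numeric(0)),
                  duration_s = 10)
  frm <- compute_firing_rate(sts, c(1, 3), window_s = 2, step_s = 0.01)
  # single window fully inside [1, 3]: all 20 spikes -> 10 Hz
  expect_equal(frm$bin_centers_s[1], 2)
  expect_equal(frm$rates[1, 1], 10)
  expect_true(all(frm$rates[2, ] == 0))  # empty unit: all-zero row
  expect_error(compute_firing_rate(sts, c(0, 1), window_s = 2),
               class = "retinamech_insufficient_data")
})

test_that("non-overlapping window counts conserve total spikes", {
  set.seed(4)
  st <- sort(runif(500, 0, 100))
  sts <- make_sts(list(st), duration_s = 100)
  frm <- compute_firing_rate(sts, c(0, 100), window_s = 2, step_s = 2)
  expect_equal(sum(frm$rates[1, ]) * 2, sum(st >= 0 & st < 100))
  # time-averaged rate of a Poisson unit is near its intensity
  lambda <- 500 / 100
  expect_lt(abs(mean(frm$rates[1, ]) - lambda), 3 * sqrt(lambda / 100))
})

test_that("z-scoring uses population SD and flags constant rows", {
  frm <- make_frm(rbind(c(0, 2), c(3, 3)))
  z <- zscore_rates(frm)
  expect_equal(z$rates[1, ], c(-1, 1))       # divisor-n convention
  expect_equal(z$constant_units, 2L)
  expect_false(any(is.nan(z$rates)))
  set.seed(1)
  big <- zscore_rates(make_frm(matrix(rpois(2000, 8), 10)))
  expect_true(all(abs(rowMeans(big$rates)) < 1e-9))
  expect_true(all(abs(sqrt(rowMeans(big$rates^2)) - 1) < 1e-9))
})

test_that("correlation matrix is symmetric PSD with unit diagonal", {
  set.seed(2)
  x <- matrix(rnorm(5 * 400), 5)
  x <- rbind(x, -x[1, ])  # unit 6 is the negation of unit 1
  frm <- zscore_rates(make_frm(x))
  cc <- correlation_matrix(frm)
  expect_equal(diag(cc), stats::setNames(rep(1, 6), 1:6))
  expect_equal(cc[1, 6], -1)
  expect_equal(cc, t(cc))
  expect_true(min(eigen(cc, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)
  expect_true(all(abs(cc) <= 1 + 1e-12))
  expect_error(correlation_matrix(make_frm(matrix(1:4, 1))),
               class = "retinamech_insufficient_data")
})

test_that("anti-correlated groups merge and identical signals fall back", {
  set.seed(3)
  base <- rnorm(1000)
  x <- rbind(base, base, base, -base, -base, -base)
  cc <- correlation_matrix(zscore_rates(make_frm(x)))
  # |rho| ~ 1 everywhere: degenerate, single cluster with warning
  expect_warning(ca <- cluster_units(cc, c(4, 60)))
  expect_equal(ca$k_selected, 1L)
  expect_true(all(ca$labels == 1L))
})

test_that("planted orthogonal clusters are recovered exactly at k = 4", {
  recovered <- vapply(1:5, function(s) {
    set.seed(s)
    sig <- matrix(rnorm(4 * 1500), 4)
    x <- sig[rep(1:4, each = 10), ] + matrix(rnorm(40 * 1500, 0, 0.5), 40)
    cc <- correlation_matrix(zscore_rates(make_frm(x)))
    ca <- cluster_units(cc, c(4, 60))
    tab <- table(rep(1:4, each = 10), ca$labels)
    ca$k_selected == 4 && all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  }, logical(1))
  expect_true(all(recovered))
})

test_that("clustering is invariant to unit input order", {
  set.seed(9)
  sig <- matrix(rnorm(3 * 1200), 3)
  x <- sig[rep(1:3, each = 8), ] + matrix(rnorm(24 * 1200, 0, 0.4), 24)
  cc <- correlation_matrix(zscore_rates(make_frm(x)))
  ca1 <- cluster_units(cc, c(2, 10))
  perm <- sample(nrow(cc))
  cc2 <- cc[perm, perm]
  ca2 <- cluster_units(cc2, c(2, 10))
  # same partition up to relabeling
  l1 <- ca1$labels[perm]
  expect_equal(length(unique(paste(l1, ca2$labels))),
               length(unique(l1)))
  expect_equal(ca1$k_selected, ca2$k_selected)
})

test_that("basal reordering permutes entries and summarizes phases", {
  set.seed(5)
  x <- matrix(rnorm(12 * 800), 12)
  cb <- correlation_matrix(zscore_rates(make_frm(x)))
  ca <- structure(list(unit_ids = rownames(cb), labels = rep(1:3, each = 4),
                       k_selected = 3L), class = "cluster_assignment")
  ro <- reorder_basal(cb, ca, indent_corr = cb)
  expect_equal(sort(as.vector(ro$reordered)), sort(as.vector(cb)))
  expect_equal(ro$summary$mean_within_abs_rho[1], ro$summary$mean_within_abs_rho[2])
  bad <- cb[1:10, 1:10]
  expect_error(reorder_basal(bad, ca), class = "retinamech_alignment_error")
})

test_that("stimulation alignment defines the basal window arithmetic", {
  sts <- make_sts(list(sort(runif(100, 0, 600))), duration_s = 600)
  al <- align_stimulation_window(sts, cbind(200, 260))
  expect_equal(al$windows$basal_start_s, 80)
  expect_equal(al$windows$basal_end_s, 200)
  expect_equal(al$windows$indent_end_s, 260)
  expect_error(align_stimulation_window(sts, cbind(260, 200)),
               class = "retinamech_trigger_error")
  expect_warning(align_stimulation_window(sts, cbind(60, 100)),
                 "truncated")
})

test_that("cluster time courses track the planted response", {
  sc <- make_cluster_scenario(seed = 21)
  aligned <- align_stimulation_window(sc$sts, cbind(120, 180))
  frm <- zscore_rates(compute_firing_rate(aligned, c(120, 190), 2, 0.01))
  ca <- structure(list(unit_ids = frm$unit_ids, labels = sc$truth,
                       k_selected = 4L), class = "cluster_assignment")
  tc <- cluster_timecourse(frm, ca)
  # cluster 1 is onset-excited with ~1 s latency: its mean z peaks early
  peak_t <- tc[["1"]]$bin_center_s[which.max(tc[["1"]]$mean_z)]
  expect_gt(peak_t, 120)
  expect_lt(peak_t, 135)
  # single-unit cluster: SEM zero and flagged
  ca1 <- structure(list(unit_ids = frm$unit_ids,
                        labels = c(1L, rep(2L, length(frm$unit_ids) - 1L)),
                        k_selected = 2L), class = "cluster_assignment")
  tc1 <- cluster_timecourse(frm, ca1)
  expect_true(all(tc1[["1"]]$sem_z == 0))
  expect_equal(attr(tc1[["1"]], "flag"), "single_unit")
})

test_that("responsive clusters among background units concentrate near the probe", {
  # 4 planted clusters of 15 units each, placed near the indentation
  # center, among 300 unmodulated background units
  center <- c(32, 32)
  set.seed(31)
  near <- unique(cbind(pmin(pmax(round(rnorm(120, center[1], 6)), 1), 64),
                       pmin(pmax(round(rnorm(120, center[2], 6)), 1), 64)))[1:60, ]
  far_idx <- sample(setdiff(1:4096, (near[, 2] - 1) * 64 + near[, 1]), 300)
  far <- cbind((far_idx - 1) %% 64 + 1, (far_idx - 1) %/% 64 + 1)
  pos <- rbind(near, far)
  members <- split(1:60, rep(1:4, each = 15))
  pcs <- list(
    planted_cluster(members[[1]], "onset_excited",  latency_s = 1,  duration_s = 8),
    planted_cluster(members[[2]], "onset_excited",  latency_s = 20, duration_s = 8),
    planted_cluster(members[[3]], "onset_excited",  latency_s = 40, duration_s = 8),
    planted_cluster(members[[4]], "offset_excited", latency_s = 1,  duration_s = 8))
  cfg <- retina_config(n_units = 360, unit_positions = pos,
                       cell_types = rep("NC", 360), basal_rates_hz = 5,
                       planted_clusters = pcs, indent_center = center)
  sts <- simulate_spike_trains(cfg, stim = stim_schedule(120, 180),
                               duration_s = 200, seed = 77)
  aligned <- align_stimulation_window(sts, cbind(120, 180))
  ind <- zscore_rates(compute_firing_rate(aligned, c(120, 190), 2, 0.01))
  ca <- cluster_units(correlation_matrix(ind), c(4, 60))
  labs <- ca$labels[match(1:360, as.integer(ca$unit_ids))]
  # each planted cluster is recovered as (the core of) one reported cluster
  planted_labels <- vapply(members, function(m) {
    tab <- table(labs[m])
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  expect_equal(length(unique(planted_labels)), 4)
  for (i in 1:4) expect_gte(mean(labs[members[[i]]] == planted_labels[i]), 0.9)
  # members of responsive clusters sit closer to the probe than average
  d_all <- sqrt((pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2)
  resp_units <- which(labs %in% planted_labels)
  expect_lt(mean(d_all[resp_units]), mean(d_all))
})
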