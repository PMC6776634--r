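test_that("unmodulated units fire at the configured basal rate", {
  cfg <- retina_config(n_units = 60, basal_rates_hz = 5, seed = 1)
  sts <- simulate_spike_trains(cfg, duration_s = 100, seed = 2)
  rates <- lengths(sts$spikes) / sts$duration_s
  se <- sqrt(5 / 100)
  # per-unit z within 3 SE almost always; pooled mean much tighter
  expect_gte(mean(abs(rates - 5) <= 3 * se), 0.95)
  expect_lt(abs(mean(rates) - 5), 3 * se / sqrt(60))
})

test_that("inter-spike intervals are exponential at the configured rate", {
  cfg <- retina_config(n_units = 200, basal_rates_hz = 5, seed = 5)
  sts <- simulate_spike_trains(cfg, duration_s = 100, seed = 6)
  pass <- vapply(sts$spikes, function(st) {
    suppressWarnings(stats::ks.test(diff(st), "pexp", 5)$p.value) >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.95)
})

test_that("planted onset excitation raises the cluster rate by the gain", {
  ratios <- vapply(1:20, function(s) {
    pc <- planted_cluster(1:30, "onset_excited", latency_s = 2,
                         duration_s = 8, gain = 3)
    cfg <- retina_config(n_units = 30, basal_rates_hz = 5,
                         planted_clusters = list(pc), seed = s)
    sts <- simulate_spike_trains(cfg, stim = stim_schedule(50, 80),
                                 duration_s = 100, seed = s + 500)
    # window starts after the per-unit latencies (cluster latency + distance
    # term) have elapsed
    win <- c(50 + 2 + 1.5, 50 + 2 + 8)
    in_win <- mean(vapply(sts$spikes, function(st)
      sum(st >= win[1] & st < win[2]) / diff(win), numeric(1)))
    basal <- mean(vapply(sts$spikes, function(st)
      sum(st < 50) / 50, numeric(1)))
    in_win / basal
  }, numeric(1))
  expect_true(all(ratios >= 2))
})

test_that("spike simulation is deterministic and validates its schedule", {
  cfg <- retina_config(n_units = 20, seed = 3)
  s1 <- simulate_spike_trains(cfg, duration_s = 50, seed = 7)
  s2 <- simulate_spike_trains(cfg, duration_s = 50, seed = 7)
  expect_identical(s1$spikes, s2$spikes)
  expect_true(all(vapply(s1$spikes, function(st) !is.unsorted(st, strictly = TRUE),
                         logical(1))))
  expect_error(simulate_spike_trains(cfg, stim = stim_schedule(40, 60),
                                     duration_s = 50, seed = 1),
               class = "retinamech_invalid_parameter")
  expect_error(stim_schedule(10, 5), class = "retinamech_invalid_parameter")
})

test_that("flash responses follow the cell type", {
  cfg <- retina_config(n_units = 4, cell_types = c("ON", "OFF", "ON_OFF", "NC"),
                       unit_positions = cbind(c(10, 20, 30, 40), 32),
                       basal_rates_hz = 5, flash_gain = 5, seed = 1)
  fl <- flash_schedule(start_s = 5, n_repeats = 30, period_s = 2)
  sts <- simulate_spike_trains(cfg, flashes = fl, duration_s = 130, seed = 9)
  # spike count in the 200 ms after preferred vs non-preferred flashes
  resp <- function(u, color) {
    ons <- fl$time_s[fl$color == color]
    mean(vapply(ons, function(tf)
      sum(sts$spikes[[u]] >= tf & sts$spikes[[u]] < tf + 0.25), numeric(1)))
  }
  expect_gt(resp(1, "white"), 2 * resp(1, "black"))   # ON prefers white
  expect_gt(resp(2, "black"), 2 * resp(2, "white"))   # OFF prefers black
  expect_gt(resp(3, "white"), 1.5 * 5 * 0.25)         # ON_OFF responds to both
  expect_gt(resp(3, "black"), 1.5 * 5 * 0.25)
  expect_lt(resp(4, "white"), 2 * 5 * 0.25)           # NC stays near basal
})

test_that("saturation frames carry the probe shadow exactly", {
  fr <- simulate_saturation_frame(probe_center = c(32, 20),
                                  probe_outline_radius = 6, flip_noise = 0)
  rows <- matrix(1:64, 64, 64)
  cols <- matrix(1:64, 64, 64, byrow = TRUE)
  in_disk <- (rows - 32)^2 + (cols - 20)^2 <= 36
  expect_identical(unclass(fr), !in_disk)
  # degenerate disk: a single shadowed electrode
  fr0 <- simulate_saturation_frame(probe_center = c(10, 10),
                                   probe_outline_radius = 0)
  expect_equal(sum(!fr0), 1)
  expect_false(fr0[10, 10])
  expect_error(simulate_saturation_frame(probe_center = c(200, 10),
                                         probe_outline_radius = 5),
               class = "retinamech_invalid_parameter")
  expect_error(retina_config(10, planted_clusters = list(
    planted_cluster(1:3, "both"), planted_cluster(3:5, "both"))),
    class = "retinamech_invalid_parameter")
})
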