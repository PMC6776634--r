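test_that("contact detection finds the true contact and rejects flat traces", {
  # noise-free: detected within one sample of the true 4.0 s contact
  tr <- simulate_indentation_trace(indentation_protocol("map_sweep"),
                                   sls_tissue_preset(), noise_sd_um = 0, seed = 1)
  ct <- detect_contact_point(tr)
  expect_lte(abs(ct$time_s - attr(tr, "true_contact_time_s")),
             1 / attr(tr, "fs_hz") + 1e-12)
  # flat zero-load trace: no contact
  flat <- tr
  flat$load_un <- 0
  flat$deflection_um <- 0
  expect_error(detect_contact_point(flat), class = "retinamech_no_contact")
})

test_that("contact detection stays within 25 ms under 0.01 uN load noise", {
  # stiff sample indented fast, so the load onset is sharp
  tis <- tabulated_tissue(1, 5e4, 0)
  proto <- indentation_protocol("static", ramp_speed_um_s = 20,
                                target_depth_um = 15, relaxation_s = 1)
  delays <- vapply(1:50, function(s) {
    tr <- simulate_indentation_trace(proto, tis, noise_sd_um = 0.01 / 0.45,
                                     seed = s)
    detect_contact_point(tr)$time_s - attr(tr, "true_contact_time_s")
  }, numeric(1))
  expect_true(all(delays > 0))           # never fires before contact
  expect_true(all(delays <= 0.025))
})

test_that("oscillation fit matches identity, planted values, and the FFT oracle", {
  fs <- 200
  t <- (0:799) / fs
  h <- 5 + 0.3 * sin(2 * pi * 1 * t)
  # identity case: load is a scaled copy of depth
  fit0 <- fit_oscillation(t, h, 3 * h, 1)
  expect_equal(fit0$phase_rad, 0, tolerance = 1e-10)
  expect_equal(fit0$f0_un / fit0$h0_um, 3, tolerance = 1e-10)
  # planted amplitude and phase, noise-free
  F <- 1 + 0.12 * sin(2 * pi * 1 * t + pi / 3)
  fit <- fit_oscillation(t, h, F, 1)
  expect_equal(fit$f0_un, 0.12, tolerance = 1e-6)
  expect_equal(fit$h0_um, 0.3, tolerance = 1e-6)
  expect_equal(fit$phase_rad, pi / 3, tolerance = 1e-6)
  orc <- fft_bin_oracle(F, 1, fs)
  expect_equal(fit$f0_un, orc$amp, tolerance = 1e-6)
  # too-short segment errors
  expect_error(fit_oscillation(t[1:300], h[1:300], F[1:300], 1),
               class = "retinamech_insufficient_data")
})

test_that("phase recovery stays within 0.01 rad at 5 nm deflection noise", {
  fs <- 200
  t <- (0:1999) / fs  # 10 periods at 1 Hz
  err <- vapply(1:100, function(s) {
    set.seed(s)
    h <- 5 + 0.3 * sin(2 * pi * t)
    F <- 1 + 0.12 * sin(2 * pi * t + pi / 3) + 0.45 * rnorm(length(t), 0, 0.005)
    abs(fit_oscillation(t, h, F, 1)$phase_rad - pi / 3)
  }, numeric(1))
  expect_lt(max(err), 0.01)
})

test_that("Hertzian contact geometry matches hand arithmetic", {
  expect_equal(contact_radius(125, 0), 0)
  expect_equal(contact_radius(125, 20), 50)
  expect_equal(contact_area(125, 20), pi * 2500, tolerance = 1e-12)
  expect_equal(contact_radius(57, 15), sqrt(855), tolerance = 1e-12)
  expect_error(contact_radius(125, -1), class = "retinamech_invalid_parameter")
})

test_that("moduli formulas match hand arithmetic and limiting cases", {
  fit <- list(f0_un = 0.12, h0_um = 0.3, phase_rad = pi / 3)  # F0/h0 = 0.4 N/m
  A <- pi * 30^2
  expect_equal(storage_modulus(fit, A), 0.4 * 0.5 / (2 * 30e-6), tolerance = 1e-12)
  expect_equal(loss_modulus(fit, A), 0.4 * (sqrt(3) / 2) / (2 * 30e-6),
               tolerance = 1e-12)
  expect_equal(loss_tangent(storage_modulus(fit, A), loss_modulus(fit, A)),
               tan(pi / 3), tolerance = 1e-12)
  # pure viscous / pure elastic limits
  fit$phase_rad <- pi / 2
  expect_equal(storage_modulus(fit, A), 0, tolerance = 1e-12)
  fit$phase_rad <- 0
  expect_equal(loss_modulus(fit, A), 0)
  expect_equal(loss_tangent(3, 0), 0)
  expect_equal(loss_tangent(5, 5), 1)
  expect_error(loss_tangent(0, 1), class = "retinamech_invalid_parameter")
})

test_that("moduli are invariant to drive scale and scale as 1/sqrt(A)", {
  fit <- list(f0_un = 0.2, h0_um = 0.5, phase_rad = 0.7)
  fit2 <- list(f0_un = 0.4, h0_um = 1.0, phase_rad = 0.7)
  A <- 4000
  expect_equal(storage_modulus(fit, A), storage_modulus(fit2, A))
  expect_equal(loss_modulus(fit, A), loss_modulus(fit2, A))
  expect_equal(storage_modulus(fit, 2 * A), storage_modulus(fit, A) / sqrt(2))
})

test_that("trial pressure and strain match the protocol presets", {
  # 0.3 uN at 20 um depth, R = 125 um
  r2 <- trial_pressure_strain(0.3, 125, 20)
  expect_equal(r2$contact_area_um2, pi * 2500)
  expect_equal(r2$pressure_pa, 0.3e-6 / (pi * 2500e-12), tolerance = 1e-12)
  expect_equal(r2$pressure_pa, 38.2, tolerance = 0.01)
  expect_equal(r2$strain, 0.4)
  # 5 uN at 30 um depth
  r1 <- trial_pressure_strain(5, 125, 30)
  expect_equal(r1$pressure_pa, 424.4, tolerance = 0.001)
  expect_equal(trial_pressure_strain(0, 125, 30)$pressure_pa, 0)
})

test_that("indentation map assembles per-location rows and flags duplicates", {
  tis <- sls_tissue_preset()
  tr1 <- simulate_indentation_trace(indentation_protocol("map_sweep"), tis,
                                    noise_sd_um = 0, seed = 1, x_um = 0)
  map1 <- build_indentation_map(list(tr1))
  expect_equal(nrow(map1), 3)  # one row per frequency
  tr2 <- simulate_indentation_trace(indentation_protocol("map_sweep"), tis,
                                    noise_sd_um = 0, seed = 2, x_um = 50)
  expect_equal(nrow(build_indentation_map(list(tr1, tr2))), 6)
  expect_error(build_indentation_map(list(tr1, tr1)),
               class = "retinamech_duplicate_location")
})

test_that("frequency sweep statistics are calibrated and handle degeneracy", {
  fake_map <- function(values, freqs) {
    data.frame(freq_hz = freqs, k_storage_pa = values, k_loss_pa = values)
  }
  # identical constant groups: H = 0 by convention
  sr <- frequency_sweep_stats(fake_map(rep(1000, 90), rep(c(0.1, 1, 10), each = 30)))
  expect_equal(sr$k_storage$kruskal_h, 0)
  expect_false(sr$k_storage$significant_0.01)
  # strong alternative mimicking the observed stiffening is detected
  set.seed(1)
  med <- rep(c(700, 1200, 1700), each = 30)
  sr2 <- frequency_sweep_stats(fake_map(med * rlnorm(90, 0, 0.1),
                                        rep(c(0.1, 1, 10), each = 30)))
  expect_true(sr2$k_storage$significant_0.0005)
  expect_error(frequency_sweep_stats(fake_map(rnorm(4), c(1, 1, 10, 10))),
               class = "retinamech_insufficient_data")
})
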