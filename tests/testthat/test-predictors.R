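test_that("local density counts with an inclusive Euclidean radius", {
  sts <- make_sts(list(sort(runif(50, 0, 100)), sort(runif(80, 0, 100)),
                       sort(runif(120, 0, 100)), sort(runif(60, 0, 100))),
                  duration_s = 100,
                  rows = c(32, 32, 32, 50),
                  cols = c(33, 36.9, 37, 50))
  # distances from (32, 32): 1, 4.9, 5.0 and far away
  lr <- local_density_rate(sts, c(32, 32), radius = 5)
  expect_equal(lr$d5, 3L)
  expect_equal(lr$r5, mean(c(0.5, 0.8, 1.2)))
  far <- local_density_rate(sts, c(5, 5), radius = 5)
  expect_equal(far$d5, 0L)
  expect_true(is.na(far$r5))
})

test_that("d5 equals a brute-force count on a random layout", {
  cfg <- retina_config(n_units = 150, seed = 4)
  sts <- simulate_spike_trains(cfg, duration_s = 30, seed = 5)
  for (center in list(c(10, 50), c(32, 32), c(60, 3))) {
    brute <- sum(sqrt((cfg$unit_positions[, 1] - center[1])^2 +
                        (cfg$unit_positions[, 2] - center[2])^2) <= 5)
    expect_equal(local_density_rate(sts, center)$d5, brute)
  }
})

test_that("feature table joins mechanics and electrophysiology per trial", {
  sts <- simulate_spike_trains(retina_config(100, seed = 1), duration_s = 60,
                               seed = 2)
  trials <- data.frame(trial_id = 1:2,
                       depth_um = c(20, 30), max_load_un = c(0.3, 5),
                       probe_radius_um = 125,
                       center_row = c(32, 20), center_col = c(32, 40),
                       outcome = c(FALSE, TRUE))
  ft <- build_feature_table(trials, sts)
  expect_s3_class(ft, "trial_feature_table")
  ps <- trial_pressure_strain(0.3, 125, 20)
  expect_equal(ft$pressure_pa[1], ps$pressure_pa)
  expect_equal(ft$strain[1], ps$strain)
  expect_equal(ft$contact_area_um2[1], ps$contact_area_um2)
  expect_true(is.logical(ft$outcome))
  # empty input: empty table, no failure
  expect_equal(nrow(build_feature_table(trials[0, ], sts)), 0)
  dup <- trials; dup$trial_id <- c(1, 1)
  expect_error(build_feature_table(dup, sts),
               class = "retinamech_consistency_error")
  chr <- trials; chr$outcome <- c("a", "b")
  expect_error(build_feature_table(chr, sts),
               class = "retinamech_invalid_parameter")
})

test_that("importances are normalized and order-equivariant", {
  tbl <- make_rule_table(n = 120, seed = 3)
  fi <- feature_importance(tbl, n_repeats = 50, seed = 9)
  expect_true(all(abs(rowSums(fi$per_repeat) - 1) < 1e-9))
  expect_equal(sum(fi$importance$mean_importance), 1, tolerance = 1e-9)
  # permuting feature columns permutes importances identically
  perm <- c(4, 1, 6, 2, 5, 3, 7)
  fi2 <- feature_importance(tbl[, perm], n_repeats = 50, seed = 9)
  m1 <- stats::setNames(fi$importance$mean_importance, fi$importance$feature)
  m2 <- stats::setNames(fi2$importance$mean_importance, fi2$importance$feature)
  expect_equal(m1[sort(names(m1))], m2[sort(names(m2))], tolerance = 1e-12)
})

test_that("duplicating a feature splits its importance rather than inflating it", {
  tbl <- make_rule_table(n = 200, seed = 11)
  fi <- feature_importance(tbl, n_repeats = 200, seed = 13)
  tbl2 <- tbl
  tbl2$pressure_copy <- tbl2$pressure_pa
  fi2 <- feature_importance(tbl2, n_repeats = 200, seed = 13)
  orig <- fi$importance$mean_importance[fi$importance$feature == "pressure_pa"]
  pair <- sum(fi2$importance$mean_importance[
    fi2$importance$feature %in% c("pressure_pa", "pressure_copy")])
  expect_equal(pair, orig, tolerance = 0.1)
})

test_that("outcome noise floors importance under the null", {
  set.seed(21)
  tbl <- make_rule_table(n = 150, seed = 15)
  tbl$outcome <- sample(c(TRUE, FALSE), 150, replace = TRUE)
  fi <- feature_importance(tbl, n_repeats = 300, seed = 17)
  expect_lt(max(fi$importance$mean_importance), 0.5)
})

test_that("degenerate inputs raise typed errors", {
  tbl <- make_rule_table(n = 50)
  one <- tbl; one$outcome <- TRUE
  expect_error(feature_importance(one, 10, 1),
               class = "retinamech_degenerate_outcome")
  expect_error(feature_importance(tbl[1:5, ], 10, 1),
               class = "retinamech_insufficient_data")
})
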