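test_that("sphere volume matches the closed form and rejects bad input", {
  expect_equal(estimated_volume(0), 0)
  expect_equal(estimated_volume(6), 36 * pi)          # = 113.097 mm3
  expect_equal(estimated_volume(3), 4.5 * pi)
  expect_error(estimated_volume(-1), "non-negative")
  expect_error(diameter_from_volume(-5), "non-negative")
  expect_equal(diameter_from_volume(0), 0)
})

test_that("diameter_from_volume is the exact inverse of estimated_volume", {
  expect_equal(diameter_from_volume(estimated_volume(7.5)), 7.5)
  # independent oracle for the 260 mm3 inversion: root-find the forward map
  d260 <- uniroot(function(d) estimated_volume(d) - 260, c(1, 20),
                  tol = 1e-12)$root
  expect_equal(diameter_from_volume(260), d260, tolerance = 1e-9)
  expect_equal(round(diameter_from_volume(260), 2), 7.92)
  # round trip over a volume grid
  v <- 10^seq(-3, 4, length.out = 200)
  expect_equal(estimated_volume(diameter_from_volume(v)), v,
               tolerance = 1e-9)
  # strict monotonicity
  d <- seq(0.1, 30, length.out = 100)
  expect_true(all(diff(estimated_volume(d)) > 0))
})

test_that("outcome classification honours the printed bands and boundaries", {
  cats <- classify_outcome(c(112.9, 113, 260, 260.1))
  expect_equal(as.character(cats),
               c("negative", "indeterminate", "indeterminate", "positive"))
  expect_true(is.ordered(cats))
  expect_error(classify_outcome(0), "positive")
  expect_error(classify_outcome(-3), "positive")
  expect_true(is.na(classify_outcome(NA_real_)))
})

test_that("outcome classification is monotone in volume", {
  v <- sort(exp(runif(300, log(1), log(2000))))
  ranks <- as.integer(classify_outcome(v))
  expect_true(all(diff(ranks) >= 0))
  # EV >= MV implies an EV category at least as severe
  mv <- exp(runif(200, log(5), log(800)))
  ev <- mv * runif(200, 1, 3)
  expect_true(all(as.integer(classify_outcome(ev)) >=
                    as.integer(classify_outcome(mv))))
})

test_that("VDT follows the doubling formula with its symmetries", {
  expect_equal(compute_vdt(100, 200, 365), 365)
  expect_equal(compute_vdt(100, 50, 365), -365)
  expect_equal(compute_vdt(100, 400, 730), 365)  # ln2*730/ln4
  expect_true(is.na(compute_vdt(100, 100, 365)))
  expect_error(compute_vdt(0, 10, 365), "positive")
  expect_error(compute_vdt(10, 10, 0), "positive")

  set.seed(11)
  v1 <- exp(runif(100, 0, 6)); v2 <- exp(runif(100, 0, 6))
  dt <- runif(100, 30, 1000)
  # antisymmetry under swapping scans
  expect_equal(compute_vdt(v1, v2, dt), -compute_vdt(v2, v1, dt))
  # scale invariance
  expect_equal(compute_vdt(3.7 * v1, 3.7 * v2, dt),
               compute_vdt(v1, v2, dt), tolerance = 1e-12)
})

test_that("VDT categorisation applies the band and the non-growth rule", {
  expect_equal(as.character(classify_vdt(c(300, 400, 500, 600, 700))),
               c("probably_malignant", "indeterminate", "indeterminate",
                 "indeterminate", "probably_benign"))
  # shrinking and stable nodules are benign under the default rule
  expect_equal(as.character(classify_vdt(c(-365, 0, NA))),
               rep("probably_benign", 3))
  # the literal "<400" rule sends negative VDTs to probably-malignant
  lit <- screening_thresholds(nongrowth_rule = "literal")
  expect_equal(as.character(classify_vdt(-365, lit)), "probably_malignant")
  expect_equal(as.character(classify_vdt(NA_real_, lit)), "probably_benign")
})

test_that("eligibility filter keeps baseline nodules at or above the floor", {
  obs <- tibble::tibble(
    screenee_id = "s1", nodule_id = c("n1", "n2", "n3", "n4"),
    timepoint = c(0L, 0L, 0L, 1L), days_from_baseline = c(0L, 0L, 0L, 365L),
    max_diameter_mm = c(2.9, 3.0, 10.0, 2.0),
    measured_volume_mm3 = c(10, 15, 500, 9)
  )
  kept <- eligible_baseline(obs)
  expect_equal(kept$nodule_id, c("n2", "n3"))  # 3 mm floor is inclusive
  expect_equal(nrow(eligible_baseline(obs[0, ])), 0)
  all_ok <- obs[obs$max_diameter_mm >= 3 & obs$timepoint == 0, ]
  expect_equal(eligible_baseline(all_ok), tibble::as_tibble(all_ok))
})

test_that("threshold constructor validates its invariants", {
  expect_error(screening_thresholds(neg_max_mm3 = 300, pos_min_mm3 = 260),
               "smaller")
  expect_error(screening_thresholds(vdt_malignant_max_days = 700),
               "smaller")
  expect_error(
    screening_thresholds(interval_months = c(negative = 12,
                                             indeterminate = 12,
                                             positive = 3)),
    "decrease")
})
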