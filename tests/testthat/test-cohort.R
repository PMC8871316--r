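test_that("dominant-nodule selection applies the documented tie-breaks", {
  mk <- function(mv, d, id = paste0("n", seq_along(mv))) tibble::tibble(
    screenee_id = "s1", nodule_id = id, timepoint = 0L,
    days_from_baseline = 0L, max_diameter_mm = d, measured_volume_mm3 = mv
  )
  expect_equal(select_dominant(mk(50, 5))$nodule_id_mv, "n1")
  expect_equal(select_dominant(mk(c(50, 300), c(5, 8)))$nodule_id_mv, "n2")
  # volume tie -> larger diameter wins
  expect_equal(select_dominant(mk(c(200, 200), c(7, 8)))$nodule_id_mv, "n2")
  # full tie -> lexicographically smallest id
  expect_equal(select_dominant(mk(c(200, 200), c(7, 7),
                                  id = c("nB", "nA")))$nodule_id_mv, "nA")
  # by_EV keys on the diameter-derived volume instead
  expect_equal(select_dominant(mk(c(300, 50), c(5, 9)),
                               rule = "by_EV")$nodule_id_ev, "n2")
  expect_error(select_dominant(mk(10, 2.5)), "eligible")
})

test_that("worst_category picks the most severe nodule per measure", {
  # n1: MV 300 (pos), EV from d=5 -> 65 (neg); n2: MV 50 (neg), d=8 -> 268 (pos)
  co <- tibble::tibble(
    screenee_id = "s1", nodule_id = c("n1", "n2"), timepoint = 0L,
    days_from_baseline = 0L, max_diameter_mm = c(5, 8),
    measured_volume_mm3 = c(300, 50)
  )
  dom <- select_dominant(co, rule = "worst_category")
  expect_equal(dom$nodule_id_mv, "n1")
  expect_equal(dom$nodule_id_ev, "n2")
})

test_that("PN-based analysis cross-classifies nodules and VDTs", {
  res <- pn_based_analysis(tiny_cohort())
  expect_equal(res$ldct$n_items, 3)
  # MV cats: neg,pos,ind; EV cats: ind,pos,pos -> 2 discordant, both upward
  expect_equal(res$ldct$n_discordant, 2)
  expect_equal(res$ldct$upward_shift_fraction, 1)
  # two nodules have follow-up: s1/n1 doubles (VDT 365, both measures),
  # s2/n1 shrinks to half (VDT -365 -> probably_benign)
  expect_equal(res$vdt$n_items, 2)
  expect_equal(unname(unclass(res$vdt$table)["probably_malignant",
                                             "probably_malignant"]), 1)
  expect_equal(unname(unclass(res$vdt$table)["probably_benign",
                                             "probably_benign"]), 1)
  expect_equal(res$vdt$n_discordant, 0)
})

test_that("PN-based analysis reproduces fixture tables from per-item records", {
  fix <- fixture_tables()
  co <- cohort_from_fixture(fix$pn_ldct, fix$pn_vdt)
  res <- pn_based_analysis(co)
  expect_equal(unclass(res$ldct$table), unclass(fix$pn_ldct))
  expect_equal(res$ldct$n_items, 2715)
  expect_equal(res$ldct$n_discordant, 1115)
  expect_equal(unclass(res$vdt$table), unclass(fix$pn_vdt))
  expect_equal(res$vdt$n_items, 2311)
  expect_equal(res$vdt$n_discordant, 773)
})

test_that("screenee-based analysis classifies one dominant nodule each", {
  res <- screenee_based_analysis(tiny_cohort())
  # s1 dominant: n2 (MV 300, pos; EV 381.7 pos) concordant;
  # s2 dominant: n1 (MV 120 ind; EV 268 pos) discordant upward
  expect_equal(res$ldct$n_items, 2)
  expect_equal(res$ldct$n_discordant, 1)
  expect_equal(res$ldct$upward_shift_fraction, 1)
  # only s2's dominant nodule has a follow-up; it halves -> benign/benign
  expect_equal(res$vdt$n_items, 1)
  expect_equal(res$vdt$n_discordant, 0)
})

test_that("a concordant single-screenee cohort shows zero discordance", {
  co <- tibble::tibble(
    screenee_id = "s1", nodule_id = "n1", timepoint = 0L,
    days_from_baseline = 0L, max_diameter_mm = 4,
    measured_volume_mm3 = estimated_volume(4)
  )
  res <- screenee_based_analysis(co)
  expect_equal(res$ldct$discordant_fraction, 0)
})

test_that("crosstab summaries satisfy the counting identities", {
  fix <- fixture_tables()
  for (nm in names(fix)) {
    ct <- summarize_crosstab(fix[[nm]],
                             unit = if (grepl("^pn", nm)) "PN" else "screenee",
                             metric = if (grepl("ldct", nm)) "ldct_outcome"
                                      else "vdt_category",
                             increasing_severity = grepl("ldct", nm))
    expect_equal(ct$n_items, sum(fix[[nm]]))
    expect_equal(ct$n_discordant, sum(fix[[nm]]) - sum(diag(fix[[nm]])))
    expect_equal(ct$discordant_fraction, 1 - sum(diag(fix[[nm]])) / sum(fix[[nm]]))
  }
})

test_that("severity shift counts the EV-more-severe triangle", {
  fix <- fixture_tables()
  expect_equal(severity_shift_fraction(fix$screenee_ldct), 727 / 728)
  upper <- contingency_table(matrix(c(10, 0, 4, 20), 2), c("a", "b"))
  expect_equal(severity_shift_fraction(upper), 1)
  sym <- contingency_table(matrix(c(0, 5, 5, 0), 2), c("a", "b"))
  expect_equal(severity_shift_fraction(sym), 0.5)
  # VDT label order runs most-severe-first: the severe triangle flips
  vdt_like <- contingency_table(matrix(c(5, 3, 0, 5), 2,
                                       dimnames = NULL), c("fast", "slow"))
  expect_equal(severity_shift_fraction(vdt_like, increasing_severity = FALSE), 1)
  conc <- contingency_table(diag(c(2, 2)), c("a", "b"))
  expect_warning(out <- severity_shift_fraction(conc), "undefined")
  expect_true(is.na(out))
})

test_that("when EV >= MV everywhere the below-diagonal cells are zero", {
  set.seed(5)
  n <- 400
  mv <- exp(runif(n, log(5), log(700)))
  ev <- mv * runif(n, 1, 2.5)
  co <- tibble::tibble(
    screenee_id = sprintf("s%03d", seq_len(n)), nodule_id = "n1",
    timepoint = 0L, days_from_baseline = 0L,
    max_diameter_mm = diameter_from_volume(ev), measured_volume_mm3 = mv
  )
  tab <- pn_based_analysis(co)$ldct$table
  expect_equal(sum(tab[lower.tri(tab)]), 0)
})

test_that("recall burden follows the interval schedule and is monotone", {
  th <- screening_thresholds()
  expect_equal(recall_burden(rep("negative", 10), th, 36), 10)     # 1 each
  expect_equal(recall_burden("indeterminate", th, 36), 3)          # 12-monthly
  expect_equal(recall_burden("positive", th, 36), 12)              # 3-monthly
  expect_error(recall_burden("unknown", th), "unknown")

  # upward category shift never reduces the scan count
  set.seed(9)
  for (i in 1:10) {
    cats <- sample(outcome_levels(), 30, replace = TRUE)
    idx <- sample(30, 5)
    shifted <- cats
    shifted[idx] <- outcome_levels()[pmin(match(cats[idx],
                                                outcome_levels()) + 1, 3)]
    expect_gte(recall_burden(shifted, th), recall_burden(cats, th))
  }

  cmp <- recall_comparison(c("negative", "indeterminate"),
                           c("indeterminate", "positive"), th, 36)
  expect_equal(cmp$mv_scans, 4)
  expect_equal(cmp$ev_scans, 15)
  expect_equal(cmp$difference, 11)
})
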