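#' Summarise a cross-classification between the two volume measures
#'
#' Wraps a [contingency_table()] of measured-volume (rows) versus
#' estimated-volume (columns) categories with the discordance metrics
#' the cohort analyses report: total items, off-diagonal count and
#' fraction, and the severity-shift fraction among discordant items.
#'
#' @param table A `contingency_table` (rows = MV, columns = EV).
#' @param unit Analysis unit label, `"PN"` or `"screenee"`.
#' @param metric Classification metric label, `"ldct_outcome"` or
#'   `"vdt_category"`.
#' @param increasing_severity `TRUE` when the label order runs from
#'   least to most severe (LDCT outcome), `FALSE` when it runs the other
#'   way (VDT categories are ordered by increasing doubling time, so the
#'   first label is the most severe). Controls which triangle counts as
#'   a shift toward a more severe EV category.
#' @return A `cohort_crosstab` object.
#' @export
summarize_crosstab <- function(table, unit = c("PN", "screenee"),
                               metric = c("ldct_outcome", "vdt_category"),
                               increasing_severity = TRUE) {
  unit <- match.arg(unit)
  metric <- match.arg(metric)
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table)
  n <- sum(table)
  n_disc <- n - sum(diag(table))
  shift <- if (n_disc > 0)
    severity_shift_fraction(table, increasing_severity) else NA_real_
  structure(
    list(unit = unit, metric = metric, table = table,
         n_items = n, n_discordant = n_disc,
         discordant_fraction = if (n > 0) n_disc / n else NA_real_,
         upward_shift_fraction = shift,
         increasing_severity = increasing_severity),
    class = "cohort_crosstab"
  )
}

#' Fraction of discordant items shifted toward a more severe EV category
#'
#' Among the off-diagonal cells of an ordinal MV-versus-EV table,
#' returns the proportion lying on the side where the estimated-volume
#' category is more severe than the measured-volume category (and would
#' therefore trigger an earlier follow-up scan).
#'
#' @inheritParams summarize_crosstab
#' @return A proportion in \[0, 1\]; `NA` with a warning when the table
#'   has no discordant items (the fraction is then undefined).
#' @examples
#' tab <- contingency_table(matrix(c(10, 0, 5, 20), 2), c("neg", "pos"))
#' severity_shift_fraction(tab)
#' @export
severity_shift_fraction <- function(table, increasing_severity = TRUE) {
  if (!inherits(table, "contingency_table"))
    table <- contingency_table(table)
  off <- sum(table) - sum(diag(table))
  if (off == 0) {
    warning("no discordant items: severity shift is undefined", call. = FALSE)
    return(NA_real_)
  }
  severe <- if (increasing_severity) sum(table[upper.tri(table)])
            else sum(table[lower.tri(table)])
  severe / off
}

#' Dominant nodule per screenee
#'
#' Picks, for every screenee with at least one eligible baseline
#' nodule, the nodule that represents them in the screenee-based
#' analysis. Rules:
#' * `by_MV` (default): largest measured volume; ties broken by larger
#'   maximum diameter, then lexicographically smallest `nodule_id`.
#' * `by_EV`: largest estimated volume (i.e. largest diameter); ties by
#'   larger measured volume, then smallest `nodule_id`.
#' * `worst_category`: per measure, the nodule attaining the most severe
#'   outcome category under that measure (so the MV- and EV-dominant
#'   nodules may differ); ties within a category by the corresponding
#'   volume, then diameter, then `nodule_id`.
#'
#' @param cohort A data frame of nodule observations.
#' @param thresholds A [screening_thresholds()] object.
#' @param rule Selection rule, see above.
#' @return A tibble with one row per screenee: `screenee_id`,
#'   `nodule_id_mv` (nodule used for MV-based classification) and
#'   `nodule_id_ev` (for EV-based classification; identical to
#'   `nodule_id_mv` except under `worst_category`).
#' @export
select_dominant <- function(cohort, thresholds = screening_thresholds(),
                            rule = c("by_MV", "by_EV", "worst_category")) {
  rule <- match.arg(rule)
  base <- eligible_baseline(cohort, thresholds)
  if (nrow(base) == 0)
    stop("no eligible baseline nodules in the cohort", call. = FALSE)
  base <- dplyr::mutate(base, ev_mm3 = estimated_volume(.data$max_diameter_mm))

  pick <- function(df, keys) {
    df |>
      dplyr::arrange(!!!keys, .by_group = FALSE) |>
      dplyr::group_by(.data$screenee_id) |>
      dplyr::slice(1) |>
      dplyr::ungroup() |>
      dplyr::select("screenee_id", "nodule_id")
  }

  if (rule == "by_MV") {
    dom <- pick(base, rlang::quos(dplyr::desc(.data$measured_volume_mm3),
                                  dplyr::desc(.data$max_diameter_mm),
                                  .data$nodule_id))
    return(tibble::tibble(screenee_id = dom$screenee_id,
                          nodule_id_mv = dom$nodule_id,
                          nodule_id_ev = dom$nodule_id))
  }
  if (rule == "by_EV") {
    dom <- pick(base, rlang::quos(dplyr::desc(.data$ev_mm3),
                                  dplyr::desc(.data$measured_volume_mm3),
                                  .data$nodule_id))
    return(tibble::tibble(screenee_id = dom$screenee_id,
                          nodule_id_mv = dom$nodule_id,
                          nodule_id_ev = dom$nodule_id))
  }
  # worst_category: most severe category under each measure separately
  base <- dplyr::mutate(
    base,
    mv_rank = as.integer(classify_outcome(.data$measured_volume_mm3, thresholds)),
    ev_rank = as.integer(classify_outcome(.data$ev_mm3, thresholds))
  )
  dom_mv <- pick(base, rlang::quos(dplyr::desc(.data$mv_rank),
                                   dplyr::desc(.data$measured_volume_mm3),
                                   dplyr::desc(.data$max_diameter_mm),
                                   .data$nodule_id))
  dom_ev <- pick(base, rlang::quos(dplyr::desc(.data$ev_rank),
                                   dplyr::desc(.data$ev_mm3),
                                   dplyr::desc(.data$measured_volume_mm3),
                                   .data$nodule_id))
  dplyr::inner_join(
    dplyr::rename(dom_mv, nodule_id_mv = "nodule_id"),
    dplyr::rename(dom_ev, nodule_id_ev = "nodule_id"),
    by = "screenee_id"
  )
}

# baseline/follow-up pairs with both volume measures and VDTs
vdt_pairs <- function(cohort, thresholds) {
  base <- eligible_baseline(cohort, thresholds)
  fu <- cohort |>
    tibble::as_tibble() |>
    dplyr::filter(.data$timepoint > 0, !is.na(.data$measured_volume_mm3),
                  .data$days_from_baseline > 0)
  dplyr::inner_join(base, fu, by = c("screenee_id", "nodule_id"),
                    suffix = c("_t0", "_t1")) |>
    dplyr::mutate(
      mv_vdt = compute_vdt(.data$measured_volume_mm3_t0,
                           .data$measured_volume_mm3_t1,
                           .data$days_from_baseline_t1),
      ev_vdt = compute_vdt(estimated_volume(.data$max_diameter_mm_t0),
                           estimated_volume(.data$max_diameter_mm_t1),
                           .data$days_from_baseline_t1)
    )
}

#' Nodule-level (PN-based) cross-classification
#'
#' Classifies every eligible baseline nodule twice — once from its
#' measured volume (MV), once from the sphere volume estimated from its
#' maximum diameter (EV) — and cross-tabulates the two LDCT outcome
#' assignments. For nodules with a re-measured volume at follow-up it
#' additionally cross-tabulates the VDT categories, where the EV-based
#' VDT uses the estimated volume at *both* timepoints (a purely
#' diameter-driven programme). Nodules without a follow-up measurement
#' are excluded from the VDT denominator.
#'
#' @param cohort A data frame of nodule observations (see
#'   [read_cohort()] for the schema).
#' @param thresholds A [screening_thresholds()] object.
#' @return A `cohort_analysis` object: list with elements `unit`
#'   (`"PN"`), `ldct` and `vdt` (each a [summarize_crosstab()] result;
#'   `vdt` is `NULL` when no nodule has a follow-up measurement). Has a
#'   [tidy()] method.
#' @export
pn_based_analysis <- function(cohort, thresholds = screening_thresholds()) {
  base <- eligible_baseline(cohort, thresholds)
  if (nrow(base) == 0)
    stop("no eligible baseline nodules in the cohort", call. = FALSE)
  mv_cat <- classify_outcome(base$measured_volume_mm3, thresholds)
  ev_cat <- classify_outcome(estimated_volume(base$max_diameter_mm), thresholds)
  ldct <- summarize_crosstab(build_table(mv_cat, ev_cat, outcome_levels()),
                             unit = "PN", metric = "ldct_outcome",
                             increasing_severity = TRUE)
  pairs <- vdt_pairs(cohort, thresholds)
  vdt <- NULL
  if (nrow(pairs) > 0) {
    vdt <- summarize_crosstab(
      build_table(classify_vdt(pairs$mv_vdt, thresholds),
                  classify_vdt(pairs$ev_vdt, thresholds), vdt_levels()),
      unit = "PN", metric = "vdt_category", increasing_severity = FALSE)
  }
  structure(list(unit = "PN", ldct = ldct, vdt = vdt),
            class = "cohort_analysis")
}

#' Screenee-level cross-classification
#'
#' Like [pn_based_analysis()], but with one classification pair per
#' screenee, made on the dominant nodule chosen by [select_dominant()].
#' The VDT block is restricted to screenees whose dominant nodule has a
#' follow-up volume measurement.
#'
#' @inheritParams pn_based_analysis
#' @param rule Dominant-nodule selection rule, see [select_dominant()].
#' @return A `cohort_analysis` object with `unit = "screenee"`.
#' @export
screenee_based_analysis <- function(cohort, thresholds = screening_thresholds(),
                                    rule = c("by_MV", "by_EV", "worst_category")) {
  rule <- match.arg(rule)
  dom <- select_dominant(cohort, thresholds, rule)
  base <- eligible_baseline(cohort, thresholds)

  mv_base <- dplyr::inner_join(dom, base,
                               by = c("screenee_id", nodule_id_mv = "nodule_id"))
  ev_base <- dplyr::inner_join(dom, base,
                               by = c("screenee_id", nodule_id_ev = "nodule_id"))
  mv_cat <- classify_outcome(mv_base$measured_volume_mm3, thresholds)
  ev_cat <- classify_outcome(estimated_volume(ev_base$max_diameter_mm), thresholds)
  ldct <- summarize_crosstab(build_table(mv_cat, ev_cat, outcome_levels()),
                             unit = "screenee", metric = "ldct_outcome",
                             increasing_severity = TRUE)

  pairs <- vdt_pairs(cohort, thresholds)
  vdt <- NULL
  if (nrow(pairs) > 0) {
    mv_fu <- dplyr::inner_join(dom, pairs,
                               by = c("screenee_id", nodule_id_mv = "nodule_id")) |>
      dplyr::select("screenee_id", "mv_vdt")
    ev_fu <- dplyr::inner_join(dom, pairs,
                               by = c("screenee_id", nodule_id_ev = "nodule_id")) |>
      dplyr::select("screenee_id", "ev_vdt")
    both <- dplyr::inner_join(mv_fu, ev_fu, by = "screenee_id")
    if (nrow(both) > 0) {
      vdt <- summarize_crosstab(
        build_table(classify_vdt(both$mv_vdt, thresholds),
                    classify_vdt(both$ev_vdt, thresholds), vdt_levels()),
        unit = "screenee", metric = "vdt_category", increasing_severity = FALSE)
    }
  }
  structure(list(unit = "screenee", rule = rule, ldct = ldct, vdt = vdt),
            class = "cohort_analysis")
}

#' Scheduled follow-up scans over a screening horizon
#'
#' Counts the low-dose CT scans a cohort would receive when every
#' screenee is rescanned at the follow-up interval attached to their
#' outcome category, repeatedly, until the horizon. The baseline scan
#' itself is not counted; with interval \eqn{m} months and horizon
#' \eqn{H} months each screenee receives \eqn{\lfloor H/m \rfloor}
#' scans (a scan falling exactly on the horizon is included).
#'
#' @param categories Outcome categories, one per screenee (factor or
#'   character in `outcome_levels()`).
#' @param thresholds A [screening_thresholds()] object supplying the
#'   interval mapping.
#' @param horizon_months Screening horizon in months.
#' @return Total number of scheduled scans across the cohort.
#' @examples
#' recall_burden(c("negative", "indeterminate"), horizon_months = 36)
#' @export
recall_burden <- function(categories, thresholds = screening_thresholds(),
                          horizon_months = 36) {
  stopifnot(is.numeric(horizon_months), horizon_months > 0)
  categories <- as.character(categories)
  bad <- setdiff(unique(categories), outcome_levels())
  if (length(bad))
    stop("unknown outcome categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  intervals <- thresholds$interval_months[categories]
  sum(floor(horizon_months / intervals + 1e-9))
}

#' Compare MV- and EV-driven recall burden
#'
#' Applies [recall_burden()] to the same screenees under their
#' measured-volume and estimated-volume outcome categories and returns
#' both totals and the difference.
#'
#' @param mv_categories,ev_categories Per-screenee outcome categories
#'   under each measure (equal length).
#' @inheritParams recall_burden
#' @return A one-row tibble: `n_screenees`, `mv_scans`, `ev_scans`,
#'   `difference` (EV minus MV).
#' @export
recall_comparison <- function(mv_categories, ev_categories,
                              thresholds = screening_thresholds(),
                              horizon_months = 36) {
  if (length(mv_categories) != length(ev_categories))
    stop("category vectors must have the same length", call. = FALSE)
  mv <- recall_burden(mv_categories, thresholds, horizon_months)
  ev <- recall_burden(ev_categories, thresholds, horizon_months)
  tibble::tibble(n_screenees = length(mv_categories),
                 mv_scans = mv, ev_scans = ev, difference = ev - mv)
}

#' Tidy a cross-classification summary
#'
#' @param x A `cohort_crosstab` from [summarize_crosstab()], or a
#'   `cohort_analysis` from [pn_based_analysis()] /
#'   [screenee_based_analysis()].
#' @param ... Unused.
#' @return A tibble with one row per unit-metric combination: `unit`,
#'   `metric`, `n`, `n_discordant`, `discordant_fraction`,
#'   `percent_agreement`, `upward_shift_fraction`.
#' @export
tidy.cohort_crosstab <- function(x, ...) {
  tibble::tibble(
    unit = x$unit, metric = x$metric,
    n = x$n_items, n_discordant = x$n_discordant,
    discordant_fraction = x$discordant_fraction,
    percent_agreement = 1 - x$discordant_fraction,
    upward_shift_fraction = x$upward_shift_fraction
  )
}

#' @rdname tidy.cohort_crosstab
#' @export
tidy.cohort_analysis <- function(x, ...) {
  parts <- Filter(Negate(is.null), list(x$ldct, x$vdt))
  dplyr::bind_rows(lapply(parts, tidy.cohort_crosstab))
}

#' @export
print.cohort_crosstab <- function(x, ...) {
  cat(sprintf("%s-based %s cross-classification (MV rows x EV columns)\n",
              x$unit, x$metric))
  print(x$table)
  cat(sprintf("discordant: %d/%d (%.1f%%)",
              as.integer(x$n_discordant), as.integer(x$n_items),
              100 * x$discordant_fraction))
  if (!is.na(x$upward_shift_fraction))
    cat(sprintf("; shifted toward more severe EV category: %.1f%%",
                100 * x$upward_shift_fraction))
  cat("\n")
  invisible(x)
}

#' @export
print.cohort_analysis <- function(x, ...) {
  print(x$ldct)
  if (!is.null(x$vdt)) {
    cat("\n")
    print(x$vdt)
  }
  invisible(x)
}
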