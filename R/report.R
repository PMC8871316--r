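#' End-to-end MV-versus-EV comparison report
#'
#' Runs the full comparison — nodule-level and screenee-level
#' cross-classification, percent agreement, weighted kappa, severity
#' shift, and the recall-burden simulation — either on a cohort of
#' per-nodule observations or on the packaged fixture tables. Cohort
#' mode additionally reports distribution summaries (median and
#' quartiles) of the dominant nodules' MV, EV and both VDTs.
#'
#' @param cohort A cohort tibble (e.g. from [read_cohort()] or
#'   [generate_cohort()]), or `NULL` to analyse the packaged fixture
#'   tables.
#' @param thresholds A [screening_thresholds()] object.
#' @param scheme Kappa weight scheme, see [weighted_kappa()].
#' @param rule Dominant-nodule rule, see [select_dominant()].
#' @param horizon_months Recall-simulation horizon, months.
#' @param verbose Emit the run log as messages as well as storing it.
#' @return A `nodule_report` object: list with elements `meta`
#'   (settings and run log), `crosstabs` (named list of
#'   [summarize_crosstab()] results), `kappa` (named list of
#'   [weighted_kappa()] results), `recall` (tibble from
#'   [recall_comparison()]) and `distributions` (tibble, cohort mode
#'   only). Has [tidy()] and `print()` methods; serialise with
#'   [write_report()].
#' @examples
#' rep <- run_report()  # fixture mode
#' tidy(rep)
#' @export
run_report <- function(cohort = NULL,
                       thresholds = screening_thresholds(),
                       scheme = c("quadratic", "linear", "unweighted"),
                       rule = c("by_MV", "by_EV", "worst_category"),
                       horizon_months = 36,
                       verbose = FALSE) {
  scheme <- match.arg(scheme)
  rule <- match.arg(rule)
  log <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    if (verbose) message(msg)
  }
  say("input: %s", if (is.null(cohort)) "packaged fixture tables"
      else sprintf("cohort with %d observation rows", nrow(cohort)))
  say("thresholds: outcome %g/%g mm3, VDT %g/%g d, min diameter %g mm",
      thresholds$neg_max_mm3, thresholds$pos_min_mm3,
      thresholds$vdt_malignant_max_days, thresholds$vdt_benign_min_days,
      thresholds$min_diameter_mm)
  say("kappa weights: %s; dominance rule: %s; horizon: %g months",
      scheme, rule, horizon_months)

  distributions <- NULL
  if (is.null(cohort)) {
    tabs <- fixture_tables()
    crosstabs <- list(
      pn_ldct = summarize_crosstab(tabs$pn_ldct, "PN", "ldct_outcome", TRUE),
      pn_vdt = summarize_crosstab(tabs$pn_vdt, "PN", "vdt_category", FALSE),
      screenee_ldct = summarize_crosstab(tabs$screenee_ldct, "screenee",
                                         "ldct_outcome", TRUE),
      screenee_vdt = summarize_crosstab(tabs$screenee_vdt, "screenee",
                                        "vdt_category", FALSE)
    )
    # recall burden from the screenee-level LDCT marginals: the schedule
    # depends only on each screenee's category, not on which nodule drove it
    mv_marg <- rowSums(tabs$screenee_ldct)
    ev_marg <- colSums(tabs$screenee_ldct)
    recall <- recall_comparison(rep(outcome_levels(), mv_marg),
                                rep(outcome_levels(), ev_marg),
                                thresholds, horizon_months)
    say("screenees: %d; eligible nodules: %d; nodules with follow-up: %d",
        as.integer(sum(tabs$screenee_ldct)), as.integer(sum(tabs$pn_ldct)),
        as.integer(sum(tabs$pn_vdt)))
  } else {
    base <- eligible_baseline(cohort, thresholds)
    say("eligible baseline nodules: %d of %d baseline rows",
        nrow(base), sum(cohort$timepoint == 0))
    pn <- pn_based_analysis(cohort, thresholds)
    sc <- screenee_based_analysis(cohort, thresholds, rule)
    crosstabs <- list(pn_ldct = pn$ldct, pn_vdt = pn$vdt,
                      screenee_ldct = sc$ldct, screenee_vdt = sc$vdt)
    crosstabs <- Filter(Negate(is.null), crosstabs)
    say("screenees with eligible nodules: %d; nodules with follow-up: %d",
        as.integer(sc$ldct$n_items),
        if (!is.null(pn$vdt)) as.integer(pn$vdt$n_items) else 0L)

    dom <- select_dominant(cohort, thresholds, rule)
    dom_base <- dplyr::inner_join(dom, base,
                                  by = c("screenee_id", nodule_id_mv = "nodule_id"))
    mv_cat <- classify_outcome(dom_base$measured_volume_mm3, thresholds)
    dom_ev <- dplyr::inner_join(dom, base,
                                by = c("screenee_id", nodule_id_ev = "nodule_id"))
    ev_cat <- classify_outcome(estimated_volume(dom_ev$max_diameter_mm),
                               thresholds)
    recall <- recall_comparison(mv_cat, ev_cat, thresholds, horizon_months)

    pairs <- vdt_pairs(cohort, thresholds)
    dom_pairs <- dplyr::inner_join(dom, pairs,
                                   by = c("screenee_id", nodule_id_mv = "nodule_id"))
    q5 <- function(x) {
      x <- x[!is.na(x)]
      if (!length(x)) return(rep(NA_real_, 3))
      stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    }
    distributions <- tibble::tibble(
      quantity = c("dominant_mv_mm3", "dominant_ev_mm3",
                   "dominant_mv_vdt_days", "dominant_ev_vdt_days"),
      q25 = NA_real_, median = NA_real_, q75 = NA_real_
    )
    vals <- list(dom_base$measured_volume_mm3,
                 estimated_volume(dom_ev$max_diameter_mm),
                 dom_pairs$mv_vdt, dom_pairs$ev_vdt)
    for (i in seq_along(vals)) {
      distributions[i, c("q25", "median", "q75")] <- as.list(q5(vals[[i]]))
    }
  }

  kappa <- lapply(crosstabs, function(ct) weighted_kappa(ct$table, scheme))
  say("recall burden over %g months: MV %d scans, EV %d scans (+%d)",
      horizon_months, as.integer(recall$mv_scans),
      as.integer(recall$ev_scans), as.integer(recall$difference))

  structure(
    list(meta = list(source = if (is.null(cohort)) "fixtures" else "cohort",
                     thresholds = thresholds, scheme = scheme, rule = rule,
                     horizon_months = horizon_months, log = log),
         crosstabs = crosstabs, kappa = kappa, recall = recall,
         distributions = distributions),
    class = "nodule_report"
  )
}

#' Tidy a comparison report
#'
#' @param x A `nodule_report` from [run_report()].
#' @param ... Unused.
#' @return A tibble with one row per analysis block: unit, metric,
#'   counts, discordance, percent agreement, kappa and severity shift.
#' @export
tidy.nodule_report <- function(x, ...) {
  rows <- purrr::imap(x$crosstabs, function(ct, name) {
    dplyr::mutate(tidy.cohort_crosstab(ct),
                  analysis = name, kappa = x$kappa[[name]]$kappa,
                  .before = 1)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.nodule_report <- function(x, ...) {
  cat(sprintf("MV vs EV comparison report (%s mode, %s kappa weights)\n\n",
              x$meta$source, x$meta$scheme))
  for (name in names(x$crosstabs)) {
    ct <- x$crosstabs[[name]]
    print(ct)
    cat(sprintf("percent agreement %.1f%%, kappa = %.2f\n\n",
                100 * (1 - ct$discordant_fraction),
                round_half_up(x$kappa[[name]]$kappa, 2)))
  }
  cat(sprintf("Recall burden over %g months: MV %d scans, EV %d scans (difference +%d)\n",
              x$meta$horizon_months, as.integer(x$recall$mv_scans),
              as.integer(x$recall$ev_scans), as.integer(x$recall$difference)))
  if (!is.null(x$distributions)) {
    cat("\nDominant-nodule distribution summaries:\n")
    print(as.data.frame(x$distributions), row.names = FALSE)
  }
  invisible(x)
}

#' Write a machine-readable report
#'
#' Serialises a [run_report()] result to JSON at full precision
#' (tables as labelled count matrices, kappa components, recall totals,
#' distribution summaries and the run log). Identical inputs produce
#' byte-identical files.
#'
#' @param report A `nodule_report`.
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nodule_report"))
  th <- report$meta$thresholds
  payload <- list(
    source = report$meta$source,
    scheme = report$meta$scheme,
    rule = report$meta$rule,
    horizon_months = report$meta$horizon_months,
    thresholds = list(
      neg_max_mm3 = th$neg_max_mm3, pos_min_mm3 = th$pos_min_mm3,
      vdt_malignant_max_days = th$vdt_malignant_max_days,
      vdt_benign_min_days = th$vdt_benign_min_days,
      min_diameter_mm = th$min_diameter_mm,
      interval_months = as.list(th$interval_months),
      nongrowth_rule = th$nongrowth_rule),
    analyses = lapply(stats::setNames(names(report$crosstabs),
                                      names(report$crosstabs)), function(nm) {
      ct <- report$crosstabs[[nm]]
      kp <- report$kappa[[nm]]
      list(unit = ct$unit, metric = ct$metric,
           labels = rownames(ct$table),
           counts = unclass(ct$table),
           n = ct$n_items, n_discordant = ct$n_discordant,
           discordant_fraction = ct$discordant_fraction,
           percent_agreement = 1 - ct$discordant_fraction,
           upward_shift_fraction = ct$upward_shift_fraction,
           kappa = kp$kappa,
           observed_agreement = kp$observed_agreement,
           expected_agreement = kp$expected_agreement)
    }),
    recall = as.list(report$recall),
    distributions = report$distributions,
    log = report$meta$log
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
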