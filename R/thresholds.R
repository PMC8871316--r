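#' Screening decision thresholds
#'
#' Bundles the volume cut-offs that map a nodule volume to a low-dose CT
#' (LDCT) outcome category, the volume-doubling-time (VDT) cut-offs, the
#' minimum diameter for study eligibility, and the follow-up interval
#' attached to each outcome category.
#'
#' The defaults are volumetric management thresholds: a nodule is
#' negative below 113 mm\eqn{^3}, indeterminate in \[113, 260\] mm\eqn{^3}
#' and positive above 260 mm\eqn{^3}; a VDT below 400 days is read as
#' probably malignant, \[400, 600\] days as indeterminate and above 600
#' days as probably benign. Both indeterminate bands are closed on both
#' ends, consistent with the strict inequalities on the outer categories.
#'
#' @param neg_max_mm3 Upper (exclusive) volume bound of the negative
#'   category, mm^3.
#' @param pos_min_mm3 Lower (exclusive) volume bound of the positive
#'   category, mm^3. Must exceed `neg_max_mm3`.
#' @param vdt_malignant_max_days Upper (exclusive) VDT bound of the
#'   probably-malignant category, days.
#' @param vdt_benign_min_days Lower (exclusive) VDT bound of the
#'   probably-benign category, days. Must exceed
#'   `vdt_malignant_max_days`.
#' @param min_diameter_mm Minimum (inclusive) maximum diameter for a
#'   baseline nodule to enter the analysis, mm.
#' @param interval_months Named numeric vector giving the follow-up
#'   interval, in months, for each outcome category (names `negative`,
#'   `indeterminate`, `positive`). Must be strictly decreasing with
#'   severity.
#' @param nongrowth_rule How shrinking or stable nodules (VDT zero,
#'   negative, or undefined) are categorised: `"benign"` (default) sends
#'   them to probably-benign on the ground that shrinkage is not growth;
#'   `"literal"` applies the printed `< 400` rule literally, so a
#'   negative VDT lands in probably-malignant.
#'
#' @return An object of class `screening_thresholds`: a validated list
#'   with the fields above.
#' @examples
#' th <- screening_thresholds()
#' th$neg_max_mm3
#' @export
screening_thresholds <- function(neg_max_mm3 = 113,
                                 pos_min_mm3 = 260,
                                 vdt_malignant_max_days = 400,
                                 vdt_benign_min_days = 600,
                                 min_diameter_mm = 3,
                                 interval_months = c(negative = 36,
                                                     indeterminate = 12,
                                                     positive = 3),
                                 nongrowth_rule = c("benign", "literal")) {
  nongrowth_rule <- match.arg(nongrowth_rule)
  stopifnot(
    is.numeric(neg_max_mm3), length(neg_max_mm3) == 1, neg_max_mm3 > 0,
    is.numeric(pos_min_mm3), length(pos_min_mm3) == 1, pos_min_mm3 > 0,
    is.numeric(vdt_malignant_max_days), vdt_malignant_max_days > 0,
    is.numeric(vdt_benign_min_days), vdt_benign_min_days > 0,
    is.numeric(min_diameter_mm), min_diameter_mm >= 0
  )
  if (neg_max_mm3 >= pos_min_mm3)
    stop("`neg_max_mm3` must be smaller than `pos_min_mm3`", call. = FALSE)
  if (vdt_malignant_max_days >= vdt_benign_min_days)
    stop("`vdt_malignant_max_days` must be smaller than `vdt_benign_min_days`",
         call. = FALSE)
  if (!all(outcome_levels() %in% names(interval_months)))
    stop("`interval_months` must be named for all outcome categories",
         call. = FALSE)
  interval_months <- interval_months[outcome_levels()]
  if (any(diff(interval_months) >= 0))
    stop("follow-up intervals must strictly decrease with category severity",
         call. = FALSE)
  structure(
    list(neg_max_mm3 = neg_max_mm3,
         pos_min_mm3 = pos_min_mm3,
         vdt_malignant_max_days = vdt_malignant_max_days,
         vdt_benign_min_days = vdt_benign_min_days,
         min_diameter_mm = min_diameter_mm,
         interval_months = interval_months,
         nongrowth_rule = nongrowth_rule),
    class = "screening_thresholds"
  )
}

#' @export
print.screening_thresholds <- function(x, ...) {
  cat("Screening thresholds\n")
  cat(sprintf("  LDCT outcome: negative < %g mm3 <= indeterminate <= %g mm3 < positive\n",
              x$neg_max_mm3, x$pos_min_mm3))
  cat(sprintf("  VDT category: prob. malignant < %g d <= indeterminate <= %g d < prob. benign\n",
              x$vdt_malignant_max_days, x$vdt_benign_min_days))
  cat(sprintf("  Eligibility:  max diameter >= %g mm at baseline\n",
              x$min_diameter_mm))
  cat(sprintf("  Intervals:    %s months\n",
              paste(sprintf("%s=%g", names(x$interval_months),
                            x$interval_months), collapse = ", ")))
  cat(sprintf("  Non-growth VDT rule: %s\n", x$nongrowth_rule))
  invisible(x)
}

#' Ordered category labels
#'
#' `outcome_levels()` returns the LDCT outcome categories in increasing
#' order of severity; `vdt_levels()` returns the VDT categories in
#' increasing order of doubling time (so severity *decreases* along the
#' vector: a short VDT is the worrying one).
#'
#' @return A character vector of category labels.
#' @examples
#' outcome_levels()
#' vdt_levels()
#' @export
outcome_levels <- function() c("negative", "indeterminate", "positive")

#' @rdname outcome_levels
#' @export
vdt_levels <- function() c("probably_malignant", "indeterminate", "probably_benign")

# days per month used when converting follow-up intervals to a schedule
DAYS_PER_MONTH <- 30.44
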