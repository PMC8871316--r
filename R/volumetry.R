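#' Sphere volume from maximal diameter
#'
#' Converts a nodule's maximal diameter into its estimated volume (EV)
#' by assuming a spherical shape: \eqn{V = \pi/6 \cdot D^3}. This is the
#' diameter-based stand-in for software-measured volume used throughout
#' the package.
#'
#' @param max_diameter_mm Numeric vector of maximal diameters, mm.
#'   Must be non-negative; `NA` is propagated.
#' @return Numeric vector of estimated volumes, mm^3.
#' @examples
#' estimated_volume(6)   # 36 * pi, right at the 113 mm3 threshold
#' estimated_volume(c(3, 8))
#' @seealso [diameter_from_volume()] for the exact inverse.
#' @export
estimated_volume <- function(max_diameter_mm) {
  stopifnot(is.numeric(max_diameter_mm))
  if (any(max_diameter_mm < 0, na.rm = TRUE))
    stop("diameters must be non-negative", call. = FALSE)
  pi / 6 * max_diameter_mm^3
}

#' Diameter of the sphere with a given volume
#'
#' Exact inverse of [estimated_volume()]: \eqn{D = (6V/\pi)^{1/3}}.
#' Used by the synthetic-cohort generator to derive the diameter a
#' reader would record for a nodule of known estimated volume.
#'
#' @param volume_mm3 Numeric vector of volumes, mm^3. Must be
#'   non-negative; `NA` is propagated.
#' @return Numeric vector of diameters, mm.
#' @examples
#' diameter_from_volume(260)
#' diameter_from_volume(estimated_volume(7.5))  # 7.5
#' @export
diameter_from_volume <- function(volume_mm3) {
  stopifnot(is.numeric(volume_mm3))
  if (any(volume_mm3 < 0, na.rm = TRUE))
    stop("volumes must be non-negative", call. = FALSE)
  (6 * volume_mm3 / pi)^(1 / 3)
}

#' LDCT outcome category from nodule volume
#'
#' Maps a nodule volume to the ordinal screening outcome: negative
#' (below `neg_max_mm3`), indeterminate (the closed band between the two
#' cut-offs) or positive (above `pos_min_mm3`).
#'
#' @param volume_mm3 Numeric vector of volumes, mm^3, strictly positive;
#'   `NA` is propagated.
#' @param thresholds A [screening_thresholds()] object.
#' @return An ordered factor with levels `outcome_levels()`.
#' @examples
#' classify_outcome(c(50, 113, 260, 300))
#' @export
classify_outcome <- function(volume_mm3, thresholds = screening_thresholds()) {
  stopifnot(is.numeric(volume_mm3), inherits(thresholds, "screening_thresholds"))
  if (any(volume_mm3 <= 0, na.rm = TRUE))
    stop("volumes must be strictly positive", call. = FALSE)
  lab <- dplyr::case_when(
    is.na(volume_mm3) ~ NA_character_,
    volume_mm3 < thresholds$neg_max_mm3 ~ "negative",
    volume_mm3 <= thresholds$pos_min_mm3 ~ "indeterminate",
    TRUE ~ "positive"
  )
  factor(lab, levels = outcome_levels(), ordered = TRUE)
}

#' Volume doubling time
#'
#' Computes the volume doubling time (VDT) between two scans,
#' \eqn{VDT = \ln 2 \cdot \Delta T / \ln(V_2 / V_1)} in days. The VDT is
#' negative for a shrinking nodule and undefined (returned as `NA`) for
#' a perfectly stable one (\eqn{V_2 = V_1}), where the formula's
#' denominator vanishes.
#'
#' @param v1_mm3,v2_mm3 Volumes at the first and second scan, mm^3,
#'   strictly positive.
#' @param delta_days Days elapsed between the scans, strictly positive.
#' @return Numeric vector of doubling times in days; `NA` where the
#'   nodule did not change volume (or an input was `NA`).
#' @examples
#' compute_vdt(100, 200, 365)   # doubled in a year: 365
#' compute_vdt(100, 50, 365)    # halved: -365
#' @export
compute_vdt <- function(v1_mm3, v2_mm3, delta_days) {
  stopifnot(is.numeric(v1_mm3), is.numeric(v2_mm3), is.numeric(delta_days))
  if (any(v1_mm3 <= 0, na.rm = TRUE) || any(v2_mm3 <= 0, na.rm = TRUE))
    stop("volumes must be strictly positive", call. = FALSE)
  if (any(delta_days <= 0, na.rm = TRUE))
    stop("`delta_days` must be strictly positive", call. = FALSE)
  ratio <- v2_mm3 / v1_mm3
  out <- log(2) * delta_days / log(ratio)
  out[!is.na(ratio) & ratio == 1] <- NA_real_
  out
}

#' VDT category from doubling time
#'
#' Maps a doubling time to the ordinal growth category: probably
#' malignant (short positive VDT), indeterminate (the closed 400-600 day
#' band) or probably benign (long VDT). Shrinking or stable nodules
#' (non-positive or undefined VDT) are categorised per the thresholds'
#' `nongrowth_rule`: the default reads shrinkage as benign behaviour;
#' the `"literal"` rule applies the `< 400` cut as printed, so negative
#' VDTs land in probably-malignant (undefined VDTs are benign either
#' way: a nodule that did not change is not growing).
#'
#' @param vdt_days Numeric vector of doubling times, days; `NA` means
#'   undefined (no volume change).
#' @param thresholds A [screening_thresholds()] object.
#' @return An ordered factor with levels `vdt_levels()` (ordered by
#'   increasing doubling time, i.e. decreasing severity).
#' @examples
#' classify_vdt(c(300, 500, 700, -365, NA))
#' @export
classify_vdt <- function(vdt_days, thresholds = screening_thresholds()) {
  stopifnot(is.numeric(vdt_days), inherits(thresholds, "screening_thresholds"))
  lo <- thresholds$vdt_malignant_max_days
  hi <- thresholds$vdt_benign_min_days
  lab <- if (thresholds$nongrowth_rule == "benign") {
    dplyr::case_when(
      is.na(vdt_days) ~ "probably_benign",
      vdt_days <= 0 ~ "probably_benign",
      vdt_days < lo ~ "probably_malignant",
      vdt_days <= hi ~ "indeterminate",
      TRUE ~ "probably_benign"
    )
  } else {
    dplyr::case_when(
      is.na(vdt_days) ~ "probably_benign",
      vdt_days < lo ~ "probably_malignant",
      vdt_days <= hi ~ "indeterminate",
      TRUE ~ "probably_benign"
    )
  }
  factor(lab, levels = vdt_levels(), ordered = TRUE)
}

#' Eligible baseline nodules
#'
#' Filters a cohort of nodule observations down to the baseline records
#' that enter the analysis: `timepoint == 0` and maximum diameter at or
#' above the eligibility floor (inclusive, "at least 3 mm" by default).
#'
#' @param observations A data frame of nodule observations with at least
#'   the columns `timepoint` and `max_diameter_mm` (see [read_cohort()]
#'   for the full schema).
#' @param thresholds A [screening_thresholds()] object.
#' @return A tibble with the retained baseline rows.
#' @examples
#' obs <- tibble::tibble(
#'   screenee_id = "s1", nodule_id = c("n1", "n2"), timepoint = 0L,
#'   days_from_baseline = 0L, max_diameter_mm = c(2.9, 3.0),
#'   measured_volume_mm3 = c(10, 15)
#' )
#' eligible_baseline(obs)
#' @export
eligible_baseline <- function(observations, thresholds = screening_thresholds()) {
  stopifnot(is.data.frame(observations),
            inherits(thresholds, "screening_thresholds"))
  dplyr::filter(
    tibble::as_tibble(observations),
    .data$timepoint == 0,
    .data$max_diameter_mm >= thresholds$min_diameter_mm
  )
}
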