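#' Configuration for the synthetic screening cohort
#'
#' Collects the distributional parameters of the cohort generator. The
#' generator emulates the statistical structure the analyses assume —
#' not any individual screenee: a baseline population of solid nodules
#' with lognormal measured volumes, a diameter that over-reads the true
#' size (so the sphere-estimated volume EV exceeds the measured volume
#' MV for almost all nodules), a single follow-up scan with exponential
#' growth for a small malignant fraction, and multiplicative lognormal
#' measurement noise on every scan.
#'
#' Defaults are calibrated so that a generated cohort reproduces the
#' published cohort shape: 1583 screenees carrying ~2715 nodules with
#' baseline MV category marginals near 81/12/7% negative/indeterminate/
#' positive, and ~85% of nodules re-measured at follow-up (see
#' `vignette("nodule-volumetry")` for the calibration).
#'
#' @param n_screenees Number of screenees.
#' @param mean_nodules Mean nodules per screenee; counts are drawn from
#'   a zero-truncated Poisson with this mean (every screenee has at
#'   least one nodule).
#' @param mv_log_median_mm3 Median of the lognormal true-volume
#'   distribution, mm^3.
#' @param mv_log_sigma Log-scale standard deviation of the true-volume
#'   distribution.
#' @param shape_alpha,shape_beta,shape_max Shape-ratio distribution for
#'   `s = MV/EV`: `s = shape_max * Beta(shape_alpha, shape_beta)`. With
#'   the defaults the ratio is almost always below 1 (EV over-reads MV,
#'   as a maximal diameter converted to a sphere must), with < 0.5% of
#'   mass above 1 so that rare MV > EV nodules occur.
#' @param shape_ratio_constant Optional fixed shape ratio overriding the
#'   Beta draw (e.g. `1` makes EV identical to MV, removing all
#'   discordance — useful for pipeline checks).
#' @param followup_fraction Fraction of baseline nodules re-measured at
#'   the follow-up scan.
#' @param delta_days Days between baseline and follow-up.
#' @param malignant_fraction Fraction of followed-up nodules with true
#'   exponential growth.
#' @param true_vdt_median_days,true_vdt_log_sd Lognormal distribution of
#'   the true volume doubling time for growing nodules, days.
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   lognormal measurement noise applied to every observed volume (both
#'   scans; median-unbiased).
#' @param refresh_shape_ratio If `FALSE` (default) the follow-up
#'   diameter is derived through the nodule's baseline shape ratio, so
#'   the ratio cancels and the EV-based VDT equals the MV-based VDT
#'   exactly. If `TRUE` a fresh ratio is drawn at follow-up, emulating
#'   independent diameter re-measurement and producing VDT discordance
#'   between the two measures.
#' @param min_diameter_mm Eligibility floor: generated nodules whose
#'   recorded diameter would fall below it are redrawn. Set to 0 to
#'   disable truncation (e.g. when checking recovery of the volume
#'   distribution itself).
#' @param seed Integer seed; identical config (seed included) gives a
#'   bit-identical cohort.
#' @return A validated `generator_config` object.
#' @export
generator_config <- function(n_screenees = 1583,
                             mean_nodules = 1.72,
                             mv_log_median_mm3 = 30,
                             mv_log_sigma = 1.3,
                             shape_alpha = 5,
                             shape_beta = 3,
                             shape_max = 1.05,
                             shape_ratio_constant = NULL,
                             followup_fraction = 2311 / 2715,
                             delta_days = 365,
                             malignant_fraction = 0.02,
                             true_vdt_median_days = 150,
                             true_vdt_log_sd = 0.5,
                             measurement_cv = 0.15,
                             refresh_shape_ratio = FALSE,
                             min_diameter_mm = 3,
                             seed = 1L) {
  cfg <- list(n_screenees = n_screenees, mean_nodules = mean_nodules,
              mv_log_median_mm3 = mv_log_median_mm3,
              mv_log_sigma = mv_log_sigma,
              shape_alpha = shape_alpha, shape_beta = shape_beta,
              shape_max = shape_max,
              shape_ratio_constant = shape_ratio_constant,
              followup_fraction = followup_fraction,
              delta_days = delta_days,
              malignant_fraction = malignant_fraction,
              true_vdt_median_days = true_vdt_median_days,
              true_vdt_log_sd = true_vdt_log_sd,
              measurement_cv = measurement_cv,
              refresh_shape_ratio = isTRUE(refresh_shape_ratio),
              min_diameter_mm = min_diameter_mm,
              seed = as.integer(seed))
  ok <- is.numeric(cfg$n_screenees) && cfg$n_screenees >= 1 &&
    cfg$mean_nodules >= 1 &&
    cfg$mv_log_median_mm3 > 0 && cfg$mv_log_sigma > 0 &&
    cfg$shape_alpha > 0 && cfg$shape_beta > 0 && cfg$shape_max > 0 &&
    (is.null(cfg$shape_ratio_constant) ||
       (cfg$shape_ratio_constant > 0 && cfg$shape_ratio_constant <= cfg$shape_max)) &&
    cfg$followup_fraction >= 0 && cfg$followup_fraction <= 1 &&
    cfg$delta_days > 0 &&
    cfg$malignant_fraction >= 0 && cfg$malignant_fraction <= 1 &&
    cfg$true_vdt_median_days > 0 && cfg$true_vdt_log_sd >= 0 &&
    cfg$measurement_cv >= 0 && cfg$min_diameter_mm >= 0
  if (!ok)
    stop("invalid generator configuration: proportions must lie in [0, 1] ",
         "and scale parameters must be positive", call. = FALSE)
  # zero-truncated Poisson rate with the requested mean, solved once here
  cfg$ztp_lambda <- if (cfg$mean_nodules == 1) 0 else
    stats::uniroot(function(l) l / (1 - exp(-l)) - cfg$mean_nodules,
                   c(1e-8, 4 * cfg$mean_nodules))$root
  structure(cfg, class = "generator_config")
}

# inverse-CDF draw from a zero-truncated Poisson (lambda 0 -> all ones)
rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  p0 <- stats::ppois(0, lambda)
  stats::qpois(p0 + stats::runif(n) * (1 - p0), lambda)
}

# lognormal multiplicative noise, median 1, coefficient of variation cv
rnoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  stats::rlnorm(n, 0, sqrt(log(1 + cv^2)))
}

draw_shape_ratio <- function(n, config) {
  if (!is.null(config$shape_ratio_constant))
    rep(config$shape_ratio_constant, n)
  else
    config$shape_max * stats::rbeta(n, config$shape_alpha, config$shape_beta)
}

#' Generate the baseline round of a synthetic screening cohort
#'
#' Draws, per nodule: a true volume from the lognormal, a shape ratio
#' `s = MV/EV`, and measurement noise; the observed measured volume is
#' the noisy true volume, the estimated volume is `MV/s`, and the
#' recorded maximum diameter is the diameter of the EV sphere. Nodules
#' whose diameter falls below the eligibility floor are rejected and
#' redrawn, so the emitted cohort is entirely eligible.
#'
#' @param config A [generator_config()].
#' @return A tibble of baseline nodule observations (`timepoint = 0`)
#'   in the standard cohort schema, plus generator-internal columns
#'   `.true_volume_mm3` and `.shape_ratio` that [generate_followup()]
#'   consumes ([write_cohort()] drops them).
#' @examples
#' generate_baseline(generator_config(n_screenees = 5, seed = 42))
#' @export
generate_baseline <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n_per <- rztpois(config$n_screenees, config$ztp_lambda)
  n <- sum(n_per)
  screenee <- rep(sprintf("S%05d", seq_len(config$n_screenees)), n_per)
  nodule <- sprintf("N%d", unlist(lapply(n_per, seq_len), use.names = FALSE))

  true_v <- mv <- s <- d <- rep(NA_real_, n)
  todo <- seq_len(n)
  while (length(todo)) {
    m <- length(todo)
    tv <- stats::rlnorm(m, log(config$mv_log_median_mm3), config$mv_log_sigma)
    obs <- tv * rnoise(m, config$measurement_cv)
    sr <- draw_shape_ratio(m, config)
    dd <- diameter_from_volume(obs / sr)
    ok <- dd >= config$min_diameter_mm
    idx <- todo[ok]
    true_v[idx] <- tv[ok]; mv[idx] <- obs[ok]; s[idx] <- sr[ok]; d[idx] <- dd[ok]
    todo <- todo[!ok]
  }
  tibble::tibble(
    screenee_id = screenee, nodule_id = nodule,
    timepoint = 0L, days_from_baseline = 0L,
    max_diameter_mm = d, measured_volume_mm3 = mv,
    .true_volume_mm3 = true_v, .shape_ratio = s
  )
}

#' Generate the follow-up round for a synthetic baseline
#'
#' Selects a fraction of the baseline nodules for re-measurement. A
#' small malignant fraction grows exponentially,
#' \eqn{V(t) = V_0 \cdot 2^{\Delta t / VDT}}, with a lognormal true
#' doubling time; the remainder keep their true volume. Each follow-up
#' observation is the evolved true volume times fresh multiplicative
#' measurement noise; the follow-up diameter is derived through the
#' nodule's own (persistent) shape ratio.
#'
#' Uses its own seed substream (`config$seed + 1`), so
#' baseline + follow-up are jointly reproducible from the config alone.
#'
#' @param baseline A baseline tibble from [generate_baseline()] (must
#'   retain the `.true_volume_mm3` and `.shape_ratio` columns).
#' @inheritParams generate_baseline
#' @return A tibble of follow-up observations (`timepoint = 1`) for the
#'   re-measured nodules, same schema as the baseline plus a logical
#'   `.is_malignant` column.
#' @export
generate_followup <- function(baseline, config = generator_config()) {
  stopifnot(inherits(config, "generator_config"),
            all(c(".true_volume_mm3", ".shape_ratio") %in% names(baseline)))
  set.seed(config$seed + 1L)
  n <- nrow(baseline)
  keep <- stats::runif(n) < config$followup_fraction
  fu <- baseline[keep, , drop = FALSE]
  m <- nrow(fu)
  if (m == 0) return(fu[0, ])
  malignant <- stats::runif(m) < config$malignant_fraction
  vdt <- stats::rlnorm(m, log(config$true_vdt_median_days),
                       config$true_vdt_log_sd)
  growth <- ifelse(malignant, 2^(config$delta_days / vdt), 1)
  true_v <- fu$.true_volume_mm3 * growth
  obs <- true_v * rnoise(m, config$measurement_cv)
  s2 <- if (config$refresh_shape_ratio) draw_shape_ratio(m, config)
        else fu$.shape_ratio
  tibble::tibble(
    screenee_id = fu$screenee_id, nodule_id = fu$nodule_id,
    timepoint = 1L, days_from_baseline = as.integer(config$delta_days),
    max_diameter_mm = diameter_from_volume(obs / s2),
    measured_volume_mm3 = obs,
    .true_volume_mm3 = true_v, .shape_ratio = s2,
    .is_malignant = malignant
  )
}

#' Generate a full two-round synthetic cohort
#'
#' Convenience wrapper: [generate_baseline()] followed by
#' [generate_followup()], rows bound together.
#'
#' @inheritParams generate_baseline
#' @return A tibble with baseline and follow-up observations.
#' @examples
#' cohort <- generate_cohort(generator_config(n_screenees = 20, seed = 7))
#' dplyr::count(cohort, timepoint)
#' @export
generate_cohort <- function(config = generator_config()) {
  base <- generate_baseline(config)
  dplyr::bind_rows(base, generate_followup(base, config))
}
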