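#' Plot a cross-classification table
#'
#' Tile plot of an MV-versus-EV contingency table with cell counts.
#'
#' @param object A [contingency_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' ggplot2::autoplot(fixture_tables()$pn_ldct)
#' @export
autoplot.contingency_table <- function(object, ...) {
  df <- tidy.contingency_table(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col,
                                   y = factor(.data$row,
                                              levels = rev(levels(.data$row))),
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey60") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 guide = "none") +
    ggplot2::labs(x = "EV category", y = "MV category") +
    ggplot2::theme_minimal()
}

#' Box plot of measured versus estimated volume
#'
#' Side-by-side box plots of the dominant nodules' measured and
#' estimated volumes, with the outcome thresholds drawn as horizontal
#' lines; the companion `plot_vdt_box()` shows the two VDT
#' distributions with the VDT cut-offs.
#'
#' @param cohort A cohort tibble.
#' @param thresholds A [screening_thresholds()] object.
#' @param rule Dominant-nodule rule, see [select_dominant()].
#' @param limits Optional y-axis range used to trim extreme values from
#'   display (values outside are dropped from the plot, not the data).
#' @return A ggplot object.
#' @export
plot_volume_box <- function(cohort, thresholds = screening_thresholds(),
                            rule = "by_MV", limits = c(3, 500)) {
  dom <- select_dominant(cohort, thresholds, rule)
  base <- eligible_baseline(cohort, thresholds)
  mv <- dplyr::inner_join(dom, base,
                          by = c("screenee_id", nodule_id_mv = "nodule_id"))
  ev <- dplyr::inner_join(dom, base,
                          by = c("screenee_id", nodule_id_ev = "nodule_id"))
  df <- dplyr::bind_rows(
    tibble::tibble(measure = "MV", volume = mv$measured_volume_mm3),
    tibble::tibble(measure = "EV",
                   volume = estimated_volume(ev$max_diameter_mm))
  )
  if (!is.null(limits))
    df <- dplyr::filter(df, .data$volume >= limits[1],
                        .data$volume <= limits[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$volume)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = c(thresholds$neg_max_mm3,
                                       thresholds$pos_min_mm3),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "volume (mm³)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_volume_box
#' @export
plot_vdt_box <- function(cohort, thresholds = screening_thresholds(),
                         rule = "by_MV", limits = c(-1000, 1000)) {
  dom <- select_dominant(cohort, thresholds, rule)
  pairs <- vdt_pairs(cohort, thresholds)
  mv <- dplyr::inner_join(dom, pairs,
                          by = c("screenee_id", nodule_id_mv = "nodule_id"))
  ev <- dplyr::inner_join(dom, pairs,
                          by = c("screenee_id", nodule_id_ev = "nodule_id"))
  df <- dplyr::bind_rows(
    tibble::tibble(measure = "MV VDT", vdt = mv$mv_vdt),
    tibble::tibble(measure = "EV VDT", vdt = ev$ev_vdt)
  )
  df <- dplyr::filter(df, !is.na(.data$vdt))
  if (!is.null(limits))
    df <- dplyr::filter(df, .data$vdt >= limits[1], .data$vdt <= limits[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$measure, y = .data$vdt)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = c(thresholds$vdt_malignant_max_days,
                                       thresholds$vdt_benign_min_days),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = NULL, y = "volume doubling time (days)") +
    ggplot2::theme_minimal()
}
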