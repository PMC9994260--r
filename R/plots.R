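#' Plot transcriptome-wide mismatch-class rates
#'
#' One point (or line, across timepoints) per substitution class, with the
#' A>G editing class emphasised — the transcriptome-wide view in which
#' genuine A-to-I editing shows up as an elevated A>G rate over the
#' sequencing-error floor.
#'
#' @param rates A [transcriptome_rates()] tibble, optionally with
#'   `timepoint` and/or `sample_id` columns (e.g. bound over samples).
#' @return A ggplot object.
#' @export
plot_class_rates <- function(rates) {
  rates <- as_tibble(rates)
  rates$is_ag <- rates$class == "A>G"
  if ("timepoint" %in% names(rates)) {
    p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$timepoint,
                                             y = .data$rate,
                                             group = .data$class,
                                             colour = .data$is_ag)) +
      ggplot2::geom_line(alpha = 0.6) +
      ggplot2::geom_point() +
      ggplot2::labs(x = "time from onset of infection (min)")
  } else {
    p <- ggplot2::ggplot(rates, ggplot2::aes(x = .data$class, y = .data$rate,
                                             fill = .data$is_ag)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "mismatch class")
  }
  p +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey50"),
                                 aesthetics = c("colour", "fill"),
                                 guide = "none") +
    ggplot2::labs(y = "mismatch rate at expressed positions") +
    ggplot2::theme_minimal() +
    (if ("sample_id" %in% names(rates))
      ggplot2::facet_wrap(ggplot2::vars(.data$sample_id)) else NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a condition comparison
#'
#' Per-site editing fraction in treatment against control, faceted by
#' timepoint; called sites highlighted.
#'
#' @param object An `edit_comparison`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.edit_comparison <- function(object, ...) {
  sites <- object$sites
  sites$called <- !is.na(sites$called_edited) & sites$called_edited
  ggplot2::ggplot(sites, ggplot2::aes(x = .data$f_control,
                                      y = .data$f_treatment,
                                      colour = .data$called)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey70") +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#c0392b",
                                            `FALSE` = "grey40"),
                                 name = "called edited") +
    ggplot2::facet_wrap(ggplot2::vars(.data$timepoint)) +
    ggplot2::labs(x = "editing fraction, control",
                  y = "editing fraction, treatment") +
    ggplot2::theme_minimal()
}

#' Plot a targeted-locus report
#'
#' Editing fraction per locus, optionally across samples/timepoints.
#'
#' @param report A [targeted_report()] tibble.
#' @return A ggplot object.
#' @export
plot_loci <- function(report) {
  report <- filter(as_tibble(report), .data$status == "ok")
  x_var <- if ("timepoint" %in% names(report)) "timepoint" else "label"
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data[[x_var]], y = .data$f))
  if (x_var == "timepoint") {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$label)) +
      ggplot2::geom_point() +
      ggplot2::facet_wrap(ggplot2::vars(.data$label)) +
      ggplot2::labs(x = "time from onset of infection (min)")
  } else {
    p <- p + ggplot2::geom_col() + ggplot2::labs(x = "locus")
  }
  p + ggplot2::labs(y = "A>G editing fraction") + ggplot2::theme_minimal()
}
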