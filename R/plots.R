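# ggplot2 displays for the main result types.

#' Plot the top extracted occupations
#'
#' Horizontal bar chart of patient-level occupation counts from
#' [top_occupations()].
#'
#' @param profiles An `occ_profiles` tibble.
#' @param k Number of occupations to show.
#' @return A ggplot object.
#' @export
plot_top_occupations <- function(profiles, k = 10L) {
  tab <- top_occupations(profiles, k)
  ggplot2::ggplot(tab, ggplot2::aes(
    x = .data$pct_patients,
    y = stats::reorder(.data$label, .data$pct_patients)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "% of patients with the occupation extracted", y = NULL,
      title = "Most frequently extracted patient occupations"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occ_associations <- function(object, model = "fully_adjusted", ...) {
  dat <- dplyr::filter(as_tibble(object), .data$model == .env$model,
                       !is.na(.data$or)) |>
    mutate(label = paste(.data$variable, .data$level, sep = ": "))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$or, y = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Odds ratio (log scale)", y = NULL,
      title = sprintf("Predictors of occupation recording (%s)", model)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.occ_eval <- function(object, ...) {
  dat <- tidyr::pivot_longer(
    as_tibble(object)[c("precision", "recall")],
    cols = dplyr::everything(), names_to = "metric"
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(width = 0.5, fill = "grey40") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("Extraction performance (%s, %s)",
                      object$mode, object$scope)
    ) +
    ggplot2::theme_minimal()
}
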