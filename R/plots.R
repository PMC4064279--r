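#' Plot a power grid
#'
#' Displays Monte-Carlo power against the grid dimension that varies
#' (artists or days), one line per value of the other dimension, with
#' pointwise 95% Monte-Carlo intervals; engines are shown in separate
#' panels when both are present.
#'
#' @param object A power table from [power_grid()] or [estimate_power()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.injury_power_grid <- function(object, ...) {
  stopifnot(nrow(object) > 0)
  x_var <- if (dplyr::n_distinct(object$n_artists) > 1) "n_artists"
           else "n_days"
  group_var <- setdiff(c("n_artists", "n_days"), x_var)
  dat <- dplyr::mutate(
    tibble::as_tibble(object),
    .group = factor(.data[[group_var]]),
    .lo = pmax(0, .data$power - 1.96 * .data$mc_stderr),
    .hi = pmin(1, .data$power + 1.96 * .data$mc_stderr)
  )
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data[[x_var]], y = .data$power,
                 colour = .data$.group, group = .data$.group)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$.lo, ymax = .data$.hi), size = 0.3
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = gsub("_", " ", x_var),
      y = "Monte-Carlo power",
      colour = gsub("_", " ", group_var)
    ) +
    ggplot2::theme_minimal()
  if (dplyr::n_distinct(object$engine) > 1) {
    p <- p + ggplot2::facet_wrap(~engine)
  }
  p
}

#' Plot a matched-design sample-size table
#'
#' Required cases against the within-person exposure correlation, with
#' variable labels when present -- the planning view of how exposure
#' stability inflates the case requirement of the nested case-crossover
#' design.
#'
#' @param object A table from [required_cases_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.matched_size_table <- function(object, ...) {
  stopifnot(nrow(object) > 0)
  dat <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(
    dat, ggplot2::aes(x = .data$phi, y = .data$required_cases)
  ) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "within-person exposure correlation (ICC)",
      y = "required cases (injuries)"
    ) +
    ggplot2::theme_minimal()
  if ("variable" %in% names(dat)) {
    p <- p + ggplot2::geom_text(
      ggplot2::aes(label = .data$variable), hjust = -0.1, vjust = 0.5,
      size = 3, check_overlap = TRUE
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
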