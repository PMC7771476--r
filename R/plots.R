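#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot world price paths of a trajectory
#'
#' @param object A `pe_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pe_trajectory <- function(object, ...) {
  prices <- tidy(object) |>
    dplyr::distinct(.data$year, .data$commodity, .data$world_price)
  ggplot2::ggplot(prices,
                  ggplot2::aes(.data$year, .data$world_price,
                               colour = .data$commodity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "world price (US$/t)", colour = NULL,
                  title = attr(object, "pathway")) +
    ggplot2::theme_minimal()
}

#' Plot the adoption paths of a shock
#'
#' @param object A `pe_shock`.
#' @param ... Unused.
#' @return A ggplot of the adopted area share per target region over time.
#' @export
autoplot.pe_shock <- function(object, ...) {
  ggplot2::ggplot(object$table,
                  ggplot2::aes(.data$year, .data$adoption,
                               colour = .data$region)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "year", y = "adopted area share", colour = NULL,
                  title = object$tech$name) +
    ggplot2::theme_minimal()
}

#' Plot net-benefit NPVs of a study
#'
#' @param object A `pe_study`.
#' @param ... Unused.
#' @return A ggplot of net-benefit NPVs by technology and scenario, faceted
#'   by aggregation.
#' @export
autoplot.pe_study <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$technology, .data$net_npv,
                               fill = .data$pathway)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~aggregation) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "net benefits, NPV (million US$)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
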