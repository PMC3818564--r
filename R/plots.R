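# ggplot2 displays for the main result types.

#' Plot a phylogenetic-signal battery
#'
#' Dot plot of the signal estimates by trait, faceted by statistic, with the
#' no-signal reference lines (lambda = 0, D = 1) and the Brownian reference
#' for D (D = 0).
#'
#' @param object A `signal_battery` tibble.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.signal_battery <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$estimate))
  refs <- dplyr::bind_rows(
    tibble::tibble(statistic = "lambda", ref = 0, kind = "no signal"),
    tibble::tibble(statistic = "D", ref = 1, kind = "no signal"),
    tibble::tibble(statistic = "D", ref = 0, kind = "Brownian"))
  refs <- dplyr::semi_join(refs, df, by = "statistic")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$trait)) +
    ggplot2::geom_vline(data = refs,
                        ggplot2::aes(xintercept = .data$ref,
                                     linetype = .data$kind),
                        colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant),
                        size = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$statistic), scales = "free") +
    ggplot2::labs(x = "estimate", y = NULL, colour = "significant",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PGLS model battery
#'
#' AIC improvement over the null model per battery entry, with the
#' conventional 2-unit support threshold marked.
#'
#' @param object A `model_battery` tibble.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.model_battery <- function(object, ...) {
  df <- dplyr::filter(object, .data$model != "(null)",
                      !is.na(.data$delta_aic))
  df <- dplyr::distinct(df, .data$model, .keep_all = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_aic,
                                   y = stats::reorder(.data$model,
                                                      .data$delta_aic))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey30") +
    ggplot2::geom_vline(xintercept = 2, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "AIC improvement over null", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a PGLS fit
#'
#' Observed versus fitted values with the 1:1 line.
#'
#' @param object A `pgls_fit` object.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  df <- tibble::tibble(fitted = unname(object$fitted),
                       observed = unname(object$y))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "fitted", y = "observed",
                  title = deparse(object$formula)) +
    ggplot2::theme_minimal()
}
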