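# ggplot2 diagnostics.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sparse CCA fit
#'
#' `type = "weights"`: stem plot of the canonical weights by feature
#' index, faceted by block and component — planted or selected variable
#' blocks show up as spikes. `type = "cpev"`: plain vs adjusted cumulative
#' explained variance across components; a plateau in the adjusted curve
#' suggests the remaining components repeat earlier information.
#'
#' @param object an [scca_fit()].
#' @param type `"weights"` or `"cpev"`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scca_fit <- function(object, type = c("weights", "cpev"), ...) {
  type <- match.arg(type)
  if (type == "weights") {
    dat <- tidy.scca_fit(object, all = FALSE)
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, xend = .data$index,
                                      y = 0, yend = .data$weight)) +
      ggplot2::geom_segment() +
      ggplot2::facet_grid(component ~ dataset, scales = "free_x",
                          labeller = ggplot2::label_both) +
      ggplot2::labs(x = "feature index", y = "canonical weight") +
      ggplot2::theme_minimal()
  } else {
    dat <- tidyr::pivot_longer(
      tibble::tibble(component = seq_len(object$k),
                     cpev = object$ev_1$cpev,
                     cpev_adjusted = object$ev_1$cpev_adj),
      cols = c("cpev", "cpev_adjusted"),
      names_to = "measure", values_to = "value")
    ggplot2::ggplot(dat, ggplot2::aes(x = .data$component, y = .data$value,
                                      colour = .data$measure)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(x = "component", y = "cumulative explained variance") +
      ggplot2::theme_minimal()
  }
}

#' Plot permutation null distributions
#'
#' Histograms of the null statistic per component with the observed value
#' as a vertical line.
#'
#' @param object an [scca_perm_test()] result with stored null draws.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.scca_perm <- function(object, ...) {
  if (is.null(object$null_draws)) {
    stop("null draws were not kept; rerun with keep_null = TRUE", call. = FALSE)
  }
  nulls <- tidyr::unnest(
    tibble::tibble(component = object$component,
                   null = object$null_draws),
    cols = "null")
  obs <- tibble::tibble(component = object$component,
                        observed = object$observed)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(data = obs,
                        ggplot2::aes(xintercept = .data$observed),
                        colour = "red") +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "statistic", y = "count") +
    ggplot2::theme_minimal()
}
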