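#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fitted mixture of GLM regressions
#'
#' Scatter of the response against one covariate, points coloured by MAP
#' component, overlaid with the component mean curves.
#'
#' @param object A `"mixglm"` fit.
#' @param covariate Name of the covariate on the x-axis (defaults to the
#'   first one).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixglm
#' @export
autoplot.mixglm <- function(object, covariate = colnames(object$X)[1], ...) {
  if (is.null(covariate) || !covariate %in% colnames(object$X)) {
    stop("covariate not found in the fit", call. = FALSE)
  }
  df <- tibble::tibble(x = object$X[, covariate], y = object$y,
                       component = factor(object$map_labels))
  lines <- purrr::map_dfr(seq_len(object$k), function(j) {
    tibble::tibble(x = df$x, mu = object$fitted_means[, j],
                   component = factor(j, levels = levels(df$component)))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$component)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = lines,
                       ggplot2::aes(y = .data$mu, group = .data$component)) +
    ggplot2::labs(x = covariate, y = "response", colour = "component") +
    ggplot2::theme_minimal()
}

#' Plot a deviance decomposition
#'
#' Stacked bar of the normalized shares of the total deviance: between
#' (NBD), explained-within (NEWD) and residual-within (NRWD).
#'
#' @param object A `"mixglm_deviance"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mixglm_deviance
#' @export
autoplot.mixglm_deviance <- function(object, ...) {
  df <- tibble::tibble(
    share = factor(c("NBD", "NEWD", "NRWD"), levels = c("NRWD", "NEWD", "NBD")),
    value = c(object$normalized$NBD, object$normalized$NEWD,
              object$normalized$NRWD)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = "total deviance", y = .data$value,
                                   fill = .data$share)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "share of total deviance", fill = NULL) +
    ggplot2::theme_minimal()
}
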