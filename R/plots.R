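#' Heatmap of a connectivity matrix
#'
#' Upper triangle shows the epoch-averaged |Pearson r|, lower triangle the
#' binarized edges (when available), channels ordered as in the montage.
#'
#' @param object a `connectivity_result`
#' @param ... unused
#' @return a ggplot
#' @method autoplot connectivity_result
#' @export
autoplot.connectivity_result <- function(object, ...) {
  C <- length(object$channels)
  W <- object$weighted
  idx <- expand.grid(i = seq_len(C), j = seq_len(C))
  val <- W[cbind(idx$i, idx$j)]
  if (!is.null(object$binary)) {
    lower <- idx$i > idx$j
    val[lower] <- object$binary[cbind(idx$i[lower], idx$j[lower])]
  }
  d <- tibble(
    from = factor(object$channels[idx$i], levels = object$channels),
    to = factor(object$channels[idx$j], levels = rev(object$channels)),
    value = val
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$from, y = .data$to, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "|r| / edge") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Connectivity (%d epochs)", object$n_epochs_used)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Posterior mean degree per Group x Session cell
#'
#' Point = posterior median of the average marginal prediction; interval =
#' 89% HDI.
#'
#' @param object a `marginal_predictions`
#' @param hdi_mass interval mass
#' @param ... unused
#' @return a ggplot
#' @method autoplot marginal_predictions
#' @export
autoplot.marginal_predictions <- function(object, hdi_mass = 0.89, ...) {
  summ <- object |>
    dplyr::group_by(.data$group, .data$session) |>
    dplyr::summarise(
      median = median(.data$.prediction),
      low = hdi(.data$.prediction, hdi_mass)[1],
      high = hdi(.data$.prediction, hdi_mass)[2],
      .groups = "drop"
    )
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$session, y = .data$median,
                                     colour = .data$group, group = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$low, ymax = .data$high),
                             position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = NULL, y = "posterior mean degree") +
    ggplot2::theme_minimal()
}

#' Pairwise difference distributions against the ROPE
#'
#' Point-intervals are the median and 89% HDI of each difference
#' distribution; the shaded band is the region of practical equivalence.
#'
#' @param object a `pairwise_comparisons` completed by [rope_decision()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot pairwise_comparisons
#' @export
autoplot.pairwise_comparisons <- function(object, ...) {
  if (is.null(object$median)) stop_param("run rope_decision() first")
  d <- tidy.pairwise_comparisons(object)
  d$label <- paste(d$within, d$contrast, sep = ": ")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median, y = .data$label,
                                  colour = .data$decision)) +
    ggplot2::annotate("rect", xmin = d$rope_low[1], xmax = d$rope_high[1],
                      ymin = -Inf, ymax = Inf, alpha = 0.15) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$hdi_low, xmax = .data$hdi_high)) +
    ggplot2::labs(x = expression(Delta ~ "degree"), y = NULL) +
    ggplot2::theme_minimal()
}
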