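#' Plot a mean allocation trajectory
#'
#' @param object A `linkbar_trajectory` from [allocation_trajectory()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linkbar_trajectory
#' @export
autoplot.linkbar_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$mean_prob,
                                       colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Patient recruitment index", y = "Mean allocation probability",
      colour = NULL,
      title = sprintf("%s design, profile %s",
                      attr(object, "design"),
                      profile_table()$key[attr(object, "profile")])
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a power sweep
#'
#' @param object A `linkbar_sweep` from [prevalence_sweep()] or
#'   [sensitivity_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot linkbar_sweep
#' @export
autoplot.linkbar_sweep <- function(object, ...) {
  if ("prevalence" %in% names(object)) {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$prevalence,
                                              y = .data$power,
                                              colour = .data$design)) +
      ggplot2::labs(x = "Prevalence of B1", y = "Power (T1 in B1-positive)")
  } else {
    p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$value,
                                              y = .data$power,
                                              colour = .data$hypothesis)) +
      ggplot2::labs(x = unique(object$axis), y = "Power")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' @export
plot.linkbar_trajectory <- function(x, ...) print(autoplot.linkbar_trajectory(x, ...))

#' @export
plot.linkbar_sweep <- function(x, ...) print(autoplot.linkbar_sweep(x, ...))
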