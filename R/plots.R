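# ggplot2 convenience plots for each result type.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot consistency_shares
#' @export
autoplot.consistency_shares <- function(object, ...) {
  ggplot2::ggplot(object$classes,
                  ggplot2::aes(x = .data$class, y = .data$share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$share)),
                       vjust = -0.3, size = 3) +
    ggplot2::labs(
      x = NULL, y = "Share of panel",
      title = paste("Consistency of", object$regime, "vaccination attitudes"),
      subtitle = paste0("n = ", object$n)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}

#' @method autoplot switching_table
#' @export
autoplot.switching_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$destination, y = .data$share)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(
      x = paste("Category in wave", attr(object, "to_wave")),
      y = "Share of origin group",
      title = paste0("Where the ", attr(object, "conditioned_on"),
                     " of wave ", attr(object, "from_wave"), " went"),
      subtitle = paste0(attr(object, "regime"), " regime, n = ",
                        attr(object, "n_origin"))) +
    ggplot2::theme_minimal()
}

#' @method autoplot transition_matrix
#' @export
autoplot.transition_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$probability)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$probability)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "To state", y = "From state",
                  title = "Attitude transition probabilities") +
    ggplot2::theme_minimal()
}

#' @method autoplot attitude_model
#' @export
autoplot.attitude_model <- function(object, ...) {
  df <- dplyr::filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::labs(
      x = "Standardised coefficient (95% CI)", y = NULL,
      title = paste("Predictors of", gsub("_", " ", object$outcome)),
      subtitle = sprintf("%s regime, %s, Tjur's R2 = %.3f, n = %d",
                         object$regime, object$estimator, object$tjur_r2,
                         object$n)) +
    ggplot2::theme_minimal()
}

#' Plot a projected attitude trajectory
#'
#' Line plot of [project_chain()] output: one line per state across
#' projection steps.
#'
#' @param projection Tibble returned by [project_chain()].
#' @return A ggplot object.
#' @export
plot_projection <- function(projection) {
  long <- tidyr::pivot_longer(projection, -"step",
                              names_to = "state", values_to = "probability")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$probability,
                                     colour = .data$state)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Projection step (waves ahead)", y = "Probability",
                  title = "Projected attitude distribution",
                  colour = "State") +
    ggplot2::theme_minimal()
}
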