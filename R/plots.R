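#' Plot a per-pair count series
#'
#' Bar chart of the bidirectional disector counts per section pair in
#' cutting order — the series whose smoothness drives the systematic
#' sampling variance ([var_surs()]).
#'
#' @param object A `count_table` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot count_table
#' @export
autoplot.count_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  if (!"q" %in% names(df)) df$q <- df$q_forward + df$q_reverse
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair_index, y = .data$q)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "disector pair (cutting order)",
                  y = expression(Q[i]^"-"),
                  title = "Per-pair disector counts") +
    ggplot2::theme_minimal()
}

#' Plot a simulated lesion cohort
#'
#' Scatter of amphetamine-induced rotations against the estimated
#' ipsilateral neuron number, the association a rank correlation test is run
#' on ([rank_correlation()]).
#'
#' @param object A [generate_lesion_cohort()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lesion_cohort
#' @export
autoplot.lesion_cohort <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_ipsi,
                                       y = .data$rotations_amphetamine)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "ipsilateral number estimate",
                  y = "amphetamine rotations (net turns / 15 min)",
                  title = "Behavioural asymmetry vs neuron loss") +
    ggplot2::theme_minimal()
}

#' Plot a phantom in cross-section
#'
#' Projects the particle centres of a phantom onto the plane perpendicular
#' to the chosen cutting axis, with point size proportional to particle
#' radius.
#'
#' @param object A [generate_phantom()] phantom.
#' @param axis Cutting axis whose plane is shown (default `"x"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phantom
#' @export
autoplot.phantom <- function(object, axis = "x", ...) {
  cols <- axis_cols(axis)
  df <- tibble::tibble(u = object$particles[[cols[["u"]]]],
                       v = object$particles[[cols[["v"]]]],
                       r = object$particles$r)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$u, y = .data$v, size = .data$r)) +
    ggplot2::geom_point(alpha = 0.4, colour = "steelblue") +
    ggplot2::scale_size_continuous(range = c(0.2, 2)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (um)", cols[["u"]]),
                  y = sprintf("%s (um)", cols[["v"]]),
                  size = "radius (um)",
                  title = sprintf("Phantom cross-section (n = %d)", object$true_n)) +
    ggplot2::theme_minimal()
}
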