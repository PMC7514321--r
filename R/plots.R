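# ggplot2 visualisations of result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a composition table
#'
#' Bar chart of the irreducible cause and effect information of every subset,
#' faceted by direction — a graphical analogue of the per-subset phi table.
#'
#' @param object A `composition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.composition <- function(object, ...) {
  tab <- object$table
  tab$subset <- factor(tab$subset, levels = unique(tab$subset))
  tab$direction <- factor(tab$direction, levels = c("cause", "effect"),
                          labels = c("phi[C]", "phi[E]"))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$subset, y = .data$phi)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~direction, ncol = 1,
                        labeller = ggplot2::label_parsed) +
    ggplot2::labs(
      x = "mechanism (subset in its current state)",
      y = "irreducible information (bits)",
      title = sprintf("Causal composition of state %s", object$state_label)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sweep table
#'
#' Scatter of system-level integrated information against total compositional
#' intrinsic information across a collection of systems, coloured by system
#' class (probabilistic, deterministic, reversible, ergodic-reversible).
#'
#' @param object A tibble from [sweep_systems()] containing `total_phi` and
#'   `big_phi` columns.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_sweep <- function(object, ...) {
  stopifnot(all(c("total_phi", "big_phi") %in% names(object)))
  cls <- ifelse(!object$deterministic, "probabilistic",
         ifelse(object$ergodic, "ergodic-reversible",
         ifelse(object$reversible, "reversible", "deterministic")))
  df <- dplyr::mutate(object, class = cls)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total_phi, y = .data$big_phi,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = expression(sum(phi[C]) + sum(phi[E]) ~ "(bits)"),
      y = expression(Phi ~ "(bits)"),
      colour = "system class"
    ) +
    ggplot2::theme_minimal()
}
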