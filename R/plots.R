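# ggplot2 views of the analysis results.

#' Plot reaction importances against class correlation
#'
#' Scatter of each reaction's Spearman correlation with the phenotype
#' (x) against its position in the importance ranking, point size
#' proportional to forest importance and color by subsystem — the
#' standard overview of which flux alterations discriminate the two
#' metabolic states.
#'
#' @param object An `importance_ledger`.
#' @param top_n Reactions to show (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.importance_ledger <- function(object, top_n = 30, ...) {
  df <- utils::head(object$reactions, top_n)
  df$reaction_id <- factor(df$reaction_id, levels = rev(df$reaction_id))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rho, y = .data$reaction_id,
    size = .data$importance, color = .data$subsystem
  )) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey60") +
    ggplot2::geom_point(alpha = 0.85) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(
      x = "Spearman correlation with phenotype",
      y = NULL, size = "importance", color = "pathway",
      title = "Discriminative metabolic reactions"
    ) +
    ggplot2::theme_minimal()
}

#' Per-class flux density for one reaction
#'
#' Kernel density estimates of a reaction's imputed flux in each class,
#' with dashed lines at class means — the per-reaction view used to
#' inspect direction and magnitude of a flux shift between states.
#'
#' @param fm Imputed `feature_matrix`.
#' @param reaction_id Reaction to plot.
#' @return A ggplot object.
#' @export
plot_flux_density <- function(fm, reaction_id) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!reaction_id %in% colnames(fm$values)) {
    stop("unknown reaction: ", reaction_id, call. = FALSE)
  }
  df <- tibble::tibble(
    label = fm$samples$label,
    flux = fm$values[, reaction_id]
  )
  means <- dplyr::summarise(dplyr::group_by(df, .data$label),
                            m = mean(.data$flux), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$flux, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.45, color = NA) +
    ggplot2::geom_vline(
      data = means,
      ggplot2::aes(xintercept = .data$m, color = .data$label),
      linetype = 2
    ) +
    ggplot2::labs(x = "flux (model units)", y = "density",
                  title = reaction_id) +
    ggplot2::theme_minimal()
}

#' Rolling flux and activity-ratio plot for one reaction
#'
#' Two stacked panels over sample position per class: the trailing
#' rolling-mean flux and the windowed activity ratio (fraction of
#' samples with nonzero flux).
#'
#' @param activity Output of [flux_activity_summary()].
#' @return A ggplot object (facetted).
#' @export
plot_flux_activity <- function(activity) {
  df <- tidyr::pivot_longer(
    activity, c("rolling_mean", "activity_ratio"),
    names_to = "panel", values_to = "value"
  )
  df$panel <- factor(df$panel, levels = c("rolling_mean", "activity_ratio"),
                     labels = c("rolling mean flux", "activity ratio"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$value, color = .data$label
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "sample position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Filtration waterfall plot
#'
#' Candidate counts entering and surviving each filtration stage.
#'
#' @param report The three-row report tibble from [run_filtration()].
#' @return A ggplot object.
#' @export
plot_filtration <- function(report) {
  df <- tibble::tibble(
    stage = factor(report$stage, levels = report$stage),
    n_in = report$n_in,
    n_out = report$n_out
  )
  df <- tidyr::pivot_longer(df, c("n_in", "n_out"),
                            names_to = "when", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$stage, y = .data$n, fill = .data$when
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "candidate models",
                  title = "Biological filtration of synthetic models") +
    ggplot2::theme_minimal()
}
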