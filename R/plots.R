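#' Plot the distribution of the four topological features
#'
#' Histograms of degree, betweenness, closeness and core number with the
#' feature medians (dashed) and, optionally, the stage-B thresholds they
#' define.
#'
#' @param object A [topology_profile()].
#' @param bins Histogram bins.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.topology_profile <- function(object, bins = 30, ...) {
  med <- attr(object, "medians")
  long <- tidyr::pivot_longer(tidy(object), -"id",
                              names_to = "feature", values_to = "value")
  med_df <- tibble::tibble(feature = names(med), median = unname(med))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey35") +
    ggplot2::geom_vline(data = med_df,
                        ggplot2::aes(xintercept = .data$median),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::facet_wrap(~feature, scales = "free") +
    ggplot2::labs(x = NULL, y = "nodes",
                  title = "Topological features (dashed: median)") +
    ggplot2::theme_minimal()
}

#' Dot plot of pathway over-representation results
#'
#' Pathways ordered by significance; point size is the overlap `k`, colour
#' the BH q-value.
#'
#' @param object An [run_ora()] result.
#' @param top Show at most this many pathways.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.ora_result <- function(object, top = 20, ...) {
  df <- utils::head(tibble::as_tibble(unclass(object)), top)
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "No enriched pathways") +
             ggplot2::theme_void())
  }
  df$set_id <- factor(df$set_id, levels = rev(df$set_id))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_value), y = .data$set_id,
                                   size = .data$k, colour = .data$q_value)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient(low = "firebrick", high = "steelblue") +
    ggplot2::labs(x = expression(-log[10](p)), y = NULL, size = "overlap",
                  colour = "q (BH)", title = "Pathway over-representation") +
    ggplot2::theme_minimal()
}

#' Bar chart of Venn region sizes
#'
#' One bar per non-empty disjoint region of the labelled sets (an
#' UpSet-style summary that stays readable for four sets).
#'
#' @param partition A [venn_partition()].
#' @return A ggplot.
#' @export
plot_venn <- function(partition) {
  stopifnot(inherits(partition, "venn_partition"))
  df <- tibble::tibble(region = partition$region, count = partition$count,
                       n_labels = partition$n_labels)
  df$region <- factor(df$region, levels = df$region[order(df$n_labels,
                                                          -df$count)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$count,
                                   fill = factor(.data$n_labels))) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.3,
                       size = 3) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = 1) +
    ggplot2::labs(x = NULL, y = "symbols", fill = "sets",
                  title = "Disjoint membership regions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Degree summary of a docking network
#'
#' Horizontal bars of per-node degree, split by role, for the retained
#' target-compound network.
#'
#' @param object A `docking_report` (from [build_docking_network()]).
#' @param top Show at most this many nodes per role.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.docking_report <- function(object, top = 15, ...) {
  df <- object$degrees |>
    dplyr::group_by(.data$role) |>
    dplyr::slice_max(.data$degree, n = top, with_ties = FALSE) |>
    dplyr::ungroup()
  if (nrow(df) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::labs(title = "Empty docking network") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree,
                                   y = stats::reorder(.data$id, .data$degree))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~role, scales = "free_y") +
    ggplot2::labs(x = "degree (retained docking pairs)", y = NULL,
                  title = "Target-compound docking network") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
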