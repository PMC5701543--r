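#' Median filter for docking scores
#'
#' A docked (compound, target) pair is called a strong binder when its score
#' is strictly greater than the median of *all* docking scores in the input
#' table. The median is the same linear-interpolated median used for the
#' topological features and is data-derived, never hard-coded. Duplicate
#' pairs collapse to their maximum score (best pose) before the median is
#' computed, so the filter is a pure function of the deduplicated table; it
#' is also scale-invariant (rescaling all scores by a positive constant
#' leaves the retained set unchanged).
#'
#' @param records Data frame with columns `compound_id`, `target_symbol`,
#'   `score` (finite).
#' @return A list with `retained` (tibble of rows with `score > median`),
#'   `median` and `n_input` (deduplicated input size).
#' @examples
#' filter_by_median(data.frame(compound_id = "c", target_symbol = c("A", "B", "C"),
#'                             score = c(1, 2, 3)))
#' @export
filter_by_median <- function(records) {
  records <- tibble::as_tibble(records)
  require_columns(records, c("compound_id", "target_symbol", "score"),
                  "docking records")
  if (nrow(records) == 0) abort("filter_by_median: empty input.")
  if (anyNA(records$score) || any(!is.finite(records$score))) {
    abort("filter_by_median: scores must be finite.")
  }
  records$target_symbol <- normalize_symbol(records$target_symbol)
  records <- records |>
    dplyr::group_by(.data$compound_id, .data$target_symbol) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop")
  med <- feature_median(records$score)
  retained <- records[records$score > med, , drop = FALSE]
  retained <- retained[order(retained$compound_id, retained$target_symbol), ]
  list(retained = retained, median = med, n_input = nrow(records))
}

#' Target-compound network from retained docking pairs
#'
#' Builds the bipartite target-compound network whose edges are the docking
#' pairs that survived the median filter, with the score kept as an edge
#' attribute, and summarises it: node counts by role, per-node degrees and
#' the best-scoring pair.
#'
#' @param retained Tibble of retained docking records (`compound_id`,
#'   `target_symbol`, `score`), deduplicated.
#' @return A list with `network` (an [interaction_network()]) and `report`
#'   (class `docking_report`: `n_edges`, `n_targets`, `n_compounds`,
#'   `degrees` tibble, `best_pair` one-row tibble).
#' @examples
#' ret <- data.frame(compound_id = c("c1", "c2", "c1"),
#'                   target_symbol = c("T1", "T1", "T2"),
#'                   score = c(90, 95, 91))
#' build_docking_network(ret)$report$best_pair
#' @export
build_docking_network <- function(retained) {
  retained <- tibble::as_tibble(retained)
  if (nrow(retained) == 0) {
    net <- interaction_network(tibble::tibble(id = character(),
                                              role = character()))
    report <- structure(list(n_edges = 0L, n_targets = 0L, n_compounds = 0L,
                             degrees = tibble::tibble(id = character(),
                                                      role = character(),
                                                      degree = integer()),
                             best_pair = NULL),
                        class = "docking_report")
    return(list(network = net, report = report))
  }
  require_columns(retained, c("compound_id", "target_symbol", "score"),
                  "retained docking records")
  net <- bipartite_network(
    retained[, c("compound_id", "target_symbol", "score")],
    left_role = "compound", right_role = "protein", relation = "ct")
  deg <- node_degree(net) |>
    dplyr::left_join(net$nodes[, c("id", "role")], by = "id") |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$id)
  best <- retained[which.max(retained$score), , drop = FALSE]
  report <- structure(
    list(n_edges = n_edges(net),
         n_targets = sum(net$nodes$role == "protein"),
         n_compounds = sum(net$nodes$role == "compound"),
         degrees = deg[, c("id", "role", "degree")],
         best_pair = best),
    class = "docking_report")
  list(network = net, report = report)
}

#' @export
print.docking_report <- function(x, ...) {
  cat("<docking_report> ", x$n_edges, " retained pairs; ",
      x$n_targets + x$n_compounds, " nodes (", x$n_targets, " targets, ",
      x$n_compounds, " compounds)\n", sep = "")
  if (!is.null(x$best_pair)) {
    cat("  best pair: ", x$best_pair$compound_id, " - ",
        x$best_pair$target_symbol, " (score ",
        format(x$best_pair$score), ")\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.docking_report <- function(x, ...) {
  tibble::tibble(n_edges = x$n_edges, n_targets = x$n_targets,
                 n_compounds = x$n_compounds,
                 best_score = if (is.null(x$best_pair)) NA_real_ else x$best_pair$score)
}

#' Full docking analysis
#'
#' Convenience wrapper: median filter followed by network construction.
#'
#' @inheritParams filter_by_median
#' @return A list with `retained`, `median`, `n_input`, `network`, `report`.
#' @export
docking_analysis <- function(records) {
  filt <- filter_by_median(records)
  dn <- build_docking_network(filt$retained)
  c(filt, dn)
}
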