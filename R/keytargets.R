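#' Two-stage median-threshold identification of key targets
#'
#' The network is simplified in two stages. Stage A deletes every node whose
#' degree is less than `multiplier` times the median degree of all nodes
#' (default 2-fold; ties at exactly the threshold are kept) and rebuilds the
#' network as the induced subgraph on the survivors — the hub network. Stage
#' B recomputes all four topological features *on that hub network* and
#' retains the nodes that are strictly greater than the corresponding median
#' of every feature: degree, betweenness, closeness and core number. The
#' survivors are the key targets.
#'
#' Both stages recompute features from scratch on their own input network;
#' nothing is cached across stages. An all-nodes-removed outcome is not an
#' error: the empty network is returned with a warning flag in the report.
#'
#' @param net An [interaction_network()] with at least one node.
#' @param multiplier Stage-A degree threshold as a multiple of the median
#'   degree (default 2).
#' @return `stage_a_filter()`: a list with `network` (the hub network) and
#'   `report` (a `filter_report`). `stage_b_filter()`: a list with
#'   `key_targets` (character vector of node ids) and `report`.
#'   `key_target_pipeline()` chains the two and also returns the key-target
#'   induced network.
#' @examples
#' # two hubs joined, five leaves each: only the hubs survive stage A
#' hubs <- data.frame(from = c("u", rep("u", 5), rep("v", 5)),
#'                    to = c("v", paste0("l", 1:5), paste0("m", 1:5)))
#' net <- interaction_network(
#'   data.frame(id = unique(unlist(hubs)), role = "protein"), hubs)
#' stage_a_filter(net)$report$retained
#' @export
stage_a_filter <- function(net, multiplier = 2) {
  stopifnot(is_interaction_network(net))
  if (n_nodes(net) == 0) abort("stage_a_filter: network has no nodes.")
  if (!is.numeric(multiplier) || multiplier <= 0) {
    abort("`multiplier` must be a positive number.")
  }
  deg <- node_degree(net)
  med <- feature_median(deg$degree)
  threshold <- multiplier * med
  retained <- deg$id[deg$degree >= threshold]
  out <- induced_subgraph(net, retained)
  emptied <- length(retained) == 0
  if (emptied) warn("stage_a_filter: threshold removed every node.")
  report <- new_filter_report(
    stage = "A", n_in = n_nodes(net), m_in = n_edges(net),
    thresholds = c(degree = threshold), medians = c(degree = med),
    retained = retained, n_out = n_nodes(out), m_out = n_edges(out),
    emptied = emptied)
  list(network = out, report = report)
}

#' @rdname stage_a_filter
#' @export
stage_b_filter <- function(net) {
  stopifnot(is_interaction_network(net))
  if (n_nodes(net) == 0) abort("stage_b_filter: network has no nodes.")
  prof <- topology_profile(net)
  med <- attr(prof, "medians")
  keep <- prof$degree > med[["degree"]] &
    prof$betweenness > med[["betweenness"]] &
    prof$closeness > med[["closeness"]] &
    prof$kcore > med[["kcore"]]
  retained <- prof$id[keep]
  emptied <- length(retained) == 0
  if (emptied) warn("stage_b_filter: no node exceeds all four medians.")
  report <- new_filter_report(
    stage = "B", n_in = n_nodes(net), m_in = n_edges(net),
    thresholds = med, medians = med, retained = retained,
    n_out = length(retained),
    m_out = if (emptied) 0L else n_edges(induced_subgraph(net, retained)),
    emptied = emptied)
  list(key_targets = retained, report = report, profile = prof)
}

#' @rdname stage_a_filter
#' @export
key_target_pipeline <- function(net, multiplier = 2) {
  a <- stage_a_filter(net, multiplier)
  if (n_nodes(a$network) == 0) {
    return(list(hub_network = a$network, key_targets = character(),
                key_network = a$network,
                reports = list(stage_a = a$report, stage_b = NULL)))
  }
  b <- stage_b_filter(a$network)
  key_net <- induced_subgraph(a$network, b$key_targets)
  list(hub_network = a$network, key_targets = b$key_targets,
       key_network = key_net, hub_profile = b$profile,
       reports = list(stage_a = a$report, stage_b = b$report))
}

new_filter_report <- function(stage, n_in, m_in, thresholds, medians,
                              retained, n_out, m_out, emptied) {
  structure(list(stage = stage, n_in = n_in, m_in = m_in,
                 thresholds = thresholds, medians = medians,
                 retained = retained, n_out = n_out, m_out = m_out,
                 emptied = emptied),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> stage ", x$stage, ": ", x$n_in, " nodes / ", x$m_in,
      " edges -> ", x$n_out, " nodes / ", x$m_out, " edges\n", sep = "")
  cat("  thresholds: ",
      paste(names(x$thresholds), signif(x$thresholds, 6), sep = " ",
            collapse = ", "), "\n", sep = "")
  if (x$emptied) cat("  warning: stage removed every node\n")
  invisible(x)
}

#' @export
glance.filter_report <- function(x, ...) {
  tibble::tibble(stage = x$stage, n_in = x$n_in, m_in = x$m_in,
                 n_out = x$n_out, m_out = x$m_out, emptied = x$emptied)
}

#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(stage = x$stage, feature = names(x$thresholds),
                 median = unname(x$medians[names(x$thresholds)]),
                 threshold = unname(x$thresholds))
}

#' Venn partition of labelled sets
#'
#' Decomposes 2-4 labelled sets (e.g. putative targets and per-disease
#' therapeutic targets) into their disjoint membership regions: each element
#' of the union is assigned to exactly one region named by the
#' `&`-joined labels of the sets containing it.
#'
#' @param sets Named list of 2 or more character vectors; names must be
#'   unique and must not contain `"&"`.
#' @return A tibble of class `venn_partition` with one row per non-empty
#'   region: `region` (label string such as `"PT&HT"`), `n_labels`, `count`
#'   and `symbols` (list-column).
#' @examples
#' vp <- venn_partition(list(A = c("1", "2"), B = c("2", "3")))
#' vp
#' venn_overlap(vp, c("A", "B"))
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || length(sets) < 2) abort("Need at least 2 labelled sets.")
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(!nzchar(labels))) {
    abort("Set labels must be unique and non-empty.")
  }
  if (any(grepl("&", labels, fixed = TRUE))) abort("Labels must not contain '&'.")
  sets <- lapply(sets, function(s) unique(normalize_symbol(s)))
  universe <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  region <- apply(membership, 1, function(m) paste(labels[m], collapse = "&"))
  out <- tibble::tibble(symbol = universe, region = region) |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(count = dplyr::n(), symbols = list(.data$symbol),
                     .groups = "drop")
  out$n_labels <- lengths(strsplit(out$region, "&", fixed = TRUE))
  out <- out[order(out$n_labels, out$region), c("region", "n_labels", "count", "symbols")]
  structure(out, labels = labels,
            class = c("venn_partition", class(out)))
}

#' @rdname venn_partition
#' @param partition A `venn_partition`.
#' @param which Character vector of labels; `venn_overlap()` sums the counts
#'   of every region containing *all* of them.
#' @export
venn_overlap <- function(partition, which) {
  stopifnot(inherits(partition, "venn_partition"))
  labels <- attr(partition, "labels")
  unknown <- setdiff(which, labels)
  if (length(unknown)) abort(paste0("Unknown labels: ", paste(unknown, collapse = ", ")))
  parts <- strsplit(partition$region, "&", fixed = TRUE)
  hit <- vapply(parts, function(p) all(which %in% p), logical(1))
  sum(partition$count[hit])
}

#' @rdname venn_partition
#' @export
venn_region <- function(partition, which) {
  stopifnot(inherits(partition, "venn_partition"))
  key <- paste(sort(which), collapse = "|")
  parts <- vapply(strsplit(partition$region, "&", fixed = TRUE),
                  function(p) paste(sort(p), collapse = "|"), "")
  hit <- which(parts == key)
  if (!length(hit)) character() else sort(partition$symbols[[hit]])
}
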