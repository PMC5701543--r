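#' Heterogeneous interaction networks
#'
#' An `interaction_network` is an undirected simple graph with typed,
#' annotated nodes. It is the common container for every network this
#' package builds: the compound-putative target-therapeutic target network,
#' its filtered subnetworks, and the bipartite pathway-target and
#' target-compound networks.
#'
#' Nodes live in a tibble with at least columns `id` (character, unique) and
#' `role` (e.g. `"protein"`, `"compound"`, `"pathway"`, `"disease-source"`);
#' any further columns are annotations (putative-target flag, per-disease
#' membership flags, ...). Edges live in a tibble with columns `from`, `to`
#' and `relation` (`"pp"` protein-protein, `"ct"` compound-target, `"dt"`
#' disease-target, `"pt"` pathway-target). Edges are canonicalised so that
#' `from <= to`; self-loops and parallel edges are rejected.
#'
#' @param nodes Data frame with columns `id`, `role` and optional annotation
#'   columns.
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `relation` (default `"pp"`). May have extra columns (e.g. a docking
#'   `score`).
#' @return An `interaction_network` object: a list with tibbles `nodes` and
#'   `edges`.
#' @examples
#' net <- interaction_network(
#'   nodes = data.frame(id = c("A", "B", "C"), role = "protein"),
#'   edges = data.frame(from = c("A", "B"), to = c("B", "C"))
#' )
#' net
#' @export
interaction_network <- function(nodes, edges = NULL) {
  nodes <- tibble::as_tibble(nodes)
  if (!"id" %in% names(nodes)) abort("`nodes` must have an `id` column.")
  nodes$id <- as.character(nodes$id)
  if (!"role" %in% names(nodes)) nodes$role <- "protein"
  if (anyNA(nodes$id) || any(!nzchar(nodes$id))) {
    abort("Node ids must be non-empty and non-missing.")
  }
  if (anyDuplicated(nodes$id)) {
    dup <- unique(nodes$id[duplicated(nodes$id)])
    abort(paste0("Duplicate node ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            relation = character())
  }
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    abort("`edges` must have `from` and `to` columns.")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"relation" %in% names(edges)) edges$relation <- rep("pp", nrow(edges))
  edges <- canonicalise_edges(edges)
  if (any(edges$from == edges$to)) abort("Self-loops are not allowed.")
  key <- paste(edges$from, edges$to)
  if (anyDuplicated(key)) abort("Parallel edges are not allowed.")
  missing_ep <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(missing_ep)) {
    abort(paste0("Edge endpoints absent from node table: ",
                 paste(head(missing_ep, 5), collapse = ", ")))
  }
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

canonicalise_edges <- function(edges) {
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges[order(edges$from, edges$to), , drop = FALSE]
}

#' @export
print.interaction_network <- function(x, ...) {
  roles <- table(x$nodes$role)
  cat("<interaction_network> ", nrow(x$nodes), " nodes (",
      paste(names(roles), unname(roles), sep = ": ", collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' @rdname interaction_network
#' @param net,x An `interaction_network`.
#' @export
net_nodes <- function(net) net$nodes

#' @rdname interaction_network
#' @export
net_edges <- function(net) net$edges

#' @rdname interaction_network
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname interaction_network
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname interaction_network
#' @export
is_interaction_network <- function(x) inherits(x, "interaction_network")

#' Assemble the compound-target-disease interaction network
#'
#' Builds the heterogeneous network at the heart of the analysis: its protein
#' nodes are the union of the putative targets of the compounds and the known
#' therapeutic targets of the diseases, and its protein-protein edges are the
#' input PPI restricted to that node set (the network is target-anchored:
#' interactions between two non-target proteins are excluded). Each protein
#' node is annotated with a putative-target flag and one logical membership
#' column per disease. Self-loops and duplicate PPI rows are dropped and
#' counted.
#'
#' With `include_source_nodes = TRUE` the compound nodes (edges `"ct"` to
#' their putative targets) and one source node per disease (edges `"dt"` to
#' its targets) are attached as well. These extra nodes are a visualisation
#' device; topological features for the key-target filter are computed on the
#' protein-only network (the default).
#'
#' @param associations Data frame of compound-target predictions with columns
#'   `compound_id` and `target_symbol` (see [read_target_associations()]).
#' @param disease_targets Data frame of known therapeutic targets with
#'   columns `disease_id` and `target_symbol` (see
#'   [dedupe_disease_targets()]); may be `NULL`.
#' @param ppi Data frame of protein-protein interactions with columns `from`
#'   and `to` (gene symbols).
#' @param include_source_nodes Attach compound and disease-source nodes?
#'   Default `FALSE`.
#' @param quiet Suppress the dropped-edge message.
#' @return An `interaction_network`. The number of PPI rows dropped
#'   (self-loops, duplicates, edges leaving the target set) is stored in
#'   attribute `"dropped_ppi"`.
#' @examples
#' assoc <- data.frame(compound_id = "c1", target_symbol = c("A", "B", "C"))
#' dis <- data.frame(disease_id = "T2D", target_symbol = c("C", "D"))
#' ppi <- data.frame(from = c("A", "C", "D"), to = c("B", "D", "E"))
#' net <- assemble_network(assoc, dis, ppi)
#' net_edges(net) # E is not a target: edge D-E dropped
#' @export
assemble_network <- function(associations, disease_targets, ppi,
                             include_source_nodes = FALSE, quiet = FALSE) {
  associations <- tibble::as_tibble(associations)
  associations$target_symbol <- normalize_symbol(associations$target_symbol)
  putative <- sort(unique(associations$target_symbol))
  if (is.null(disease_targets) || nrow(tibble::as_tibble(disease_targets)) == 0) {
    disease_targets <- tibble::tibble(disease_id = character(),
                                      target_symbol = character())
  }
  disease_targets <- tibble::as_tibble(disease_targets)
  disease_targets$target_symbol <- normalize_symbol(disease_targets$target_symbol)
  diseases <- sort(unique(disease_targets$disease_id))

  proteins <- sort(unique(c(putative, disease_targets$target_symbol)))
  if (!length(proteins)) abort("No protein nodes: empty putative and disease target sets.")

  nodes <- tibble::tibble(id = proteins, role = "protein",
                          putative = proteins %in% putative)
  for (d in diseases) {
    nodes[[d]] <- proteins %in%
      disease_targets$target_symbol[disease_targets$disease_id == d]
  }

  ppi <- tibble::as_tibble(ppi)
  n_raw <- nrow(ppi)
  ppi$from <- normalize_symbol(ppi$from)
  ppi$to <- normalize_symbol(ppi$to)
  ppi <- ppi[ppi$from != ppi$to, c("from", "to")]
  ppi <- ppi[ppi$from %in% proteins & ppi$to %in% proteins, , drop = FALSE]
  ppi <- canonicalise_edges(cbind(ppi, relation = rep("pp", nrow(ppi))))
  ppi <- dplyr::distinct(tibble::as_tibble(ppi))
  dropped <- n_raw - nrow(ppi)
  if (dropped > 0 && !quiet) {
    inform(paste0("assemble_network: dropped ", dropped,
                  " PPI rows (self-loops, duplicates, or non-target endpoints)."))
  }

  if (include_source_nodes) {
    associations <- dplyr::distinct(associations[, c("compound_id", "target_symbol")])
    compounds <- sort(unique(associations$compound_id))
    extra <- tibble::tibble(id = c(compounds, diseases),
                            role = rep(c("compound", "disease-source"),
                                       c(length(compounds), length(diseases))),
                            putative = FALSE)
    for (d in diseases) extra[[d]] <- FALSE
    nodes <- dplyr::bind_rows(nodes, extra)
    ct <- tibble::tibble(from = associations$compound_id,
                         to = associations$target_symbol, relation = "ct")
    dt <- tibble::tibble(from = disease_targets$disease_id,
                         to = disease_targets$target_symbol, relation = "dt")
    dt <- dplyr::distinct(dt)
    ppi <- dplyr::bind_rows(ppi, ct, dt)
  }

  net <- interaction_network(nodes, ppi)
  attr(net, "dropped_ppi") <- dropped
  net
}

#' Induced subgraph of an interaction network
#'
#' Restricts a network to a set of node ids: the result keeps exactly those
#' nodes (annotations preserved) and every edge whose two endpoints are both
#' kept. This is the "use the retained nodes to rebuild the network" step of
#' the median-threshold simplification.
#'
#' @param net An `interaction_network`.
#' @param ids Character vector of node ids, all present in `net`.
#' @return An `interaction_network`.
#' @examples
#' tri <- interaction_network(data.frame(id = c("a", "b", "c"), role = "protein"),
#'                            data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
#' induced_subgraph(tri, c("a", "b"))
#' @export
induced_subgraph <- function(net, ids) {
  stopifnot(is_interaction_network(net))
  ids <- unique(as.character(ids))
  unknown <- setdiff(ids, net$nodes$id)
  if (length(unknown)) {
    abort(paste0("Unknown node ids: ", paste(head(unknown, 5), collapse = ", ")))
  }
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  edges <- net$edges[net$edges$from %in% ids & net$edges$to %in% ids, , drop = FALSE]
  interaction_network(nodes, edges)
}

#' Build a bipartite network from id pairs
#'
#' Turns a deduplicated table of (left, right) pairs into a bipartite
#' `interaction_network` with role-tagged node classes: the pathway-target
#' network and the target-compound docking network are built this way.
#'
#' @param pairs Data frame whose first two columns are the left and right ids
#'   of each edge; extra columns (e.g. a docking `score`) are kept as edge
#'   attributes.
#' @param left_role,right_role Role tags for the two node classes.
#' @param relation Relation tag for the edges.
#' @return An `interaction_network` whose node roles 2-colour the graph.
#' @examples
#' bipartite_network(data.frame(compound = c("c1", "c1", "c2"),
#'                              target = c("T1", "T2", "T1")),
#'                   left_role = "compound", right_role = "protein")
#' @export
bipartite_network <- function(pairs, left_role = "compound",
                              right_role = "protein", relation = "ct") {
  pairs <- tibble::as_tibble(pairs)
  if (ncol(pairs) < 2) abort("`pairs` needs at least two columns.")
  left <- as.character(pairs[[1]])
  right <- as.character(pairs[[2]])
  if (any(left == right)) {
    abort("A pair's two ids are equal; left and right namespaces must be disjoint.")
  }
  if (length(intersect(left, right))) {
    abort("Left and right id sets overlap; bipartiteness would fail.")
  }
  key <- paste(left, right)
  if (anyDuplicated(key)) {
    keep <- !duplicated(key)
    pairs <- pairs[keep, , drop = FALSE]
    left <- left[keep]; right <- right[keep]
  }
  nodes <- tibble::tibble(
    id = c(sort(unique(left)), sort(unique(right))),
    role = rep(c(left_role, right_role),
               c(length(unique(left)), length(unique(right)))))
  edges <- tibble::tibble(from = left, to = right, relation = relation)
  extra <- pairs[, -(1:2), drop = FALSE]
  if (ncol(extra)) edges <- dplyr::bind_cols(edges, extra)
  interaction_network(nodes, edges)
}
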