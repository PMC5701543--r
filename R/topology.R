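#' @keywords internal
#' Build an index-based adjacency list for a network.
#' Returns list(ids, adj) where adj[[i]] is an integer vector of neighbours.
#' @noRd
adjacency_list <- function(net) {
  ids <- net$nodes$id
  idx <- setNames(seq_along(ids), ids)
  adj <- vector("list", length(ids))
  for (i in seq_along(adj)) adj[[i]] <- integer()
  if (nrow(net$edges)) {
    f <- idx[net$edges$from]
    t <- idx[net$edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  list(ids = ids, adj = adj)
}

#' Topological features of an interaction network
#'
#' The four per-node features used by the key-target filter, each computed
#' from first principles on the undirected, unweighted, simple graph:
#'
#' * **degree** — number of incident edges;
#' * **betweenness** — Brandes' algorithm; unnormalised, each unordered pair
#'   \{s, t\} counted once: for node v,
#'   \eqn{\sum_{\{s,t\}, s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}}, where
#'   \eqn{\sigma_{st}} counts shortest s-t paths (disconnected pairs
#'   contribute 0);
#' * **closeness** — inverse of the sum of shortest-path distances to the
#'   nodes *reachable* from v (so disconnected components are handled
#'   per-component); a node with no neighbours has closeness 0 by convention;
#' * **core number** — the largest k such that the node belongs to a maximal
#'   subgraph of minimum degree at least k, by iterative peeling.
#'
#' @param net An [interaction_network()].
#' @return A tibble with columns `id` and the feature value(s).
#' @examples
#' path3 <- interaction_network(data.frame(id = c("a", "b", "c"), role = "protein"),
#'                              data.frame(from = c("a", "b"), to = c("b", "c")))
#' node_betweenness(path3) # the interior node carries the single a-c pair
#' @name topology-features
NULL

#' @rdname topology-features
#' @export
node_degree <- function(net) {
  stopifnot(is_interaction_network(net))
  deg <- setNames(integer(n_nodes(net)), net$nodes$id)
  if (n_edges(net)) {
    tab <- table(c(net$edges$from, net$edges$to))
    deg[names(tab)] <- as.integer(tab)
  }
  tibble::tibble(id = names(deg), degree = unname(deg))
}

#' @rdname topology-features
#' @export
node_betweenness <- function(net) {
  stopifnot(is_interaction_network(net))
  al <- adjacency_list(net)
  n <- length(al$ids)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    # Brandes: BFS from s, then back-propagate pair dependencies
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    order_visited <- integer(0)
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- c(s)
    qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      order_visited <- c(order_visited, v)
      for (w in al$adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  # each unordered pair was accumulated from both endpoints
  tibble::tibble(id = al$ids, betweenness = cb / 2)
}

#' @rdname topology-features
#' @export
node_closeness <- function(net) {
  stopifnot(is_interaction_network(net))
  al <- adjacency_list(net)
  n <- length(al$ids)
  clo <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    dist[s] <- 0L
    queue <- c(s); qi <- 1L
    while (qi <= length(queue)) {
      v <- queue[qi]; qi <- qi + 1L
      for (w in al$adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    total <- sum(dist[dist > 0L])
    clo[s] <- if (total > 0) 1 / total else 0
  }
  tibble::tibble(id = al$ids, closeness = clo)
}

#' @rdname topology-features
#' @export
node_coreness <- function(net) {
  stopifnot(is_interaction_network(net))
  al <- adjacency_list(net)
  n <- length(al$ids)
  deg <- lengths(al$adj)
  core <- integer(n)
  remaining <- rep(TRUE, n)
  k <- 0L
  for (step in seq_len(n)) {
    cand <- which(remaining)
    v <- cand[which.min(deg[cand])]
    k <- max(k, deg[v])
    core[v] <- k
    remaining[v] <- FALSE
    for (w in al$adj[[v]]) if (remaining[w]) deg[w] <- deg[w] - 1L
  }
  tibble::tibble(id = al$ids, kcore = core)
}

#' Median of a feature vector
#'
#' The linear-interpolated sample median (the mean of the two middle order
#' statistics for even n), applied uniformly to all four topological features
#' and to docking scores.
#'
#' @param values Non-empty numeric vector.
#' @return A single number.
#' @examples
#' feature_median(c(1, 2, 3, 4)) # 2.5
#' @export
feature_median <- function(values) {
  if (length(values) == 0) abort("feature_median: empty input.")
  if (anyNA(values)) abort("feature_median: missing values.")
  median(as.numeric(values))
}

#' Per-node topology profile with feature medians
#'
#' Computes all four topological features of every node and the per-feature
#' medians, the quantities the two-stage key-target filter thresholds on.
#'
#' @param net An [interaction_network()] with at least one node.
#' @return A tibble of class `topology_profile` with columns `id`, `degree`,
#'   `betweenness`, `closeness`, `kcore`; the named numeric vector of feature
#'   medians is in attribute `"medians"` and is returned by [glance()].
#' @examples
#' ring <- interaction_network(
#'   data.frame(id = letters[1:4], role = "protein"),
#'   data.frame(from = c("a", "b", "c", "a"), to = c("b", "c", "d", "d")))
#' prof <- topology_profile(ring)
#' glance(prof)
#' @export
topology_profile <- function(net) {
  stopifnot(is_interaction_network(net))
  if (n_nodes(net) == 0) abort("topology_profile: network has no nodes.")
  prof <- node_degree(net) |>
    dplyr::left_join(node_betweenness(net), by = "id") |>
    dplyr::left_join(node_closeness(net), by = "id") |>
    dplyr::left_join(node_coreness(net), by = "id")
  medians <- vapply(prof[c("degree", "betweenness", "closeness", "kcore")],
                    feature_median, numeric(1))
  structure(prof, medians = medians,
            class = c("topology_profile", class(prof)))
}

#' @export
glance.topology_profile <- function(x, ...) {
  m <- attr(x, "medians")
  tibble::tibble(n_nodes = nrow(x),
                 median_degree = m[["degree"]],
                 median_betweenness = m[["betweenness"]],
                 median_closeness = m[["closeness"]],
                 median_kcore = m[["kcore"]])
}

#' @export
tidy.topology_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Write a topology profile as TSV
#'
#' @param profile A [topology_profile()].
#' @param path Output TSV (columns id, degree, betweenness, closeness, kcore).
#' @export
write_topology_profile <- function(profile, path) {
  readr::write_tsv(tidy(profile), path, progress = FALSE)
  invisible(path)
}
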