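# Independent brute-force oracles and small-graph helpers.
# These deliberately avoid the package's BFS/peeling code paths:
# betweenness/closeness come from exhaustive simple-path enumeration and
# Floyd-Warshall, core numbers from an all-subgraphs minimum-degree search.

`%||%` <- function(x, y) if (is.null(x)) y else x

make_net <- function(edges, ids = NULL) {
  edges <- as.data.frame(edges)
  names(edges)[1:2] <- c("from", "to")
  if (is.null(ids)) ids <- sort(unique(c(edges$from, edges$to)))
  interaction_network(data.frame(id = ids, role = "protein"), edges)
}

random_er_net <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p
  edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2])
  interaction_network(data.frame(id = ids, role = "protein"), edges)
}

net_adj_matrix <- function(net) {
  ids <- net_nodes(net)$id
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net_edges(net)
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- TRUE
    A[cbind(e$to, e$from)] <- TRUE
  }
  A
}

# all simple paths between two nodes, by exhaustive DFS
all_simple_paths_bf <- function(A, s, t) {
  out <- list()
  recurse <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    for (w in which(A[v, ])) if (!w %in% path) recurse(c(path, w))
  }
  recurse(s)
  out
}

brute_betweenness <- function(net) {
  A <- net_adj_matrix(net)
  n <- nrow(A)
  cb <- setNames(numeric(n), rownames(A))
  if (n < 3) return(cb)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_simple_paths_bf(A, s, t)
    if (!length(paths)) next
    lens <- lengths(paths)
    shortest <- paths[lens == min(lens)]
    for (p in shortest) {
      interior <- p[-c(1, length(p))]
      cb[interior] <- cb[interior] + 1 / length(shortest)
    }
  }
  cb
}

# Floyd-Warshall distances
brute_distances <- function(net) {
  A <- net_adj_matrix(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  diag(D) <- 0
  D[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  D
}

brute_closeness <- function(net) {
  D <- brute_distances(net)
  apply(D, 1, function(d) {
    s <- sum(d[is.finite(d) & d > 0])
    if (s > 0) 1 / s else 0
  })
}

# core number: max over all vertex subsets containing v of the induced
# subgraph's minimum degree
brute_coreness <- function(net) {
  A <- net_adj_matrix(net)
  n <- nrow(A)
  core <- setNames(integer(n), rownames(A))
  for (mask in seq_len(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) < 2) next
    sub <- A[members, members, drop = FALSE]
    mindeg <- min(rowSums(sub))
    core[members] <- pmax(core[members], mindeg)
  }
  core
}

# hypergeometric upper tail by enumerating every size-n draw from the universe
brute_hyper_tail <- function(k, K, n, N) {
  draws <- combn(N, n)
  hits <- colSums(draws <= K) # items 1..K are the annotated ones
  mean(hits >= k)
}
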