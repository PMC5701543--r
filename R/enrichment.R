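#' Hypergeometric upper-tail probability
#'
#' The over-representation p-value: the probability of seeing `k` or more
#' annotated genes when drawing `n` genes without replacement from a universe
#' of `N` genes of which `K` are annotated,
#' \eqn{P(X \ge k) = \sum_{j \ge k} \binom{K}{j}\binom{N-K}{n-j} / \binom{N}{n}}.
#' Terms are evaluated in log-space (via `lchoose`) and summed from the tail
#' for numerical stability; `k = 0` returns exactly 1.
#'
#' @param k Observed overlap (vectorised).
#' @param K Annotated genes in the universe.
#' @param n Query size (genes drawn).
#' @param N Universe size.
#' @return Probabilities in (0, 1].
#' @examples
#' hypergeom_upper_tail(5, 5, 5, 10) # 1 / choose(10, 5)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(K, n, N) < 0) || K > N || n > N) abort("Inconsistent counts.")
  vapply(k, function(ki) {
    if (ki < 0 || ki > min(n, K)) {
      if (ki > min(n, K)) abort("k exceeds min(n, K).")
      abort("k must be non-negative.")
    }
    if (ki == 0) return(1)
    j <- ki:min(n, K)
    lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]):
#' order-preserving and clipped to 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.04))
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Hypergeometric over-representation analysis
#'
#' Tests a query gene list (here, the key targets) against each set of a
#' gene-set collection. For each set, `k` is the overlap of the query with
#' the set, `K` the set size within the universe, `n` the query size within
#' the universe and `N` the universe size; the p-value is the hypergeometric
#' upper tail. Benjamini-Hochberg q-values are computed across all sets with
#' `k >= 1` and reported alongside, but the significance filter follows the
#' raw p-value cut-off (`p < alpha`), the criterion used to call a pathway
#' enriched.
#'
#' The default universe is the union of all genes annotated in the
#' collection; pass an explicit background to override. Sets with no overlap
#' are omitted (they carry no network edges). Results are sorted by p-value,
#' ties broken by set id.
#'
#' @param query Character vector of gene symbols.
#' @param collection Named list of gene sets, as from [read_gmt()].
#' @param universe Optional character vector of background genes.
#' @param alpha Raw-p significance cut-off (default 0.05). Use `alpha = 1`
#'   (or slightly above) to keep every overlapping set.
#' @return A tibble of class `ora_result`: `set_id`, `description`, `k`,
#'   `K`, `n`, `N`, `p_value`, `q_value`, `overlap` (list-column of symbols).
#' @examples
#' sets <- list(S1 = c("A", "B", "C"), S2 = c("D", "E"))
#' attr(sets, "description") <- c(S1 = "first", S2 = "second")
#' run_ora(c("A", "B"), sets, universe = LETTERS, alpha = 1)
#' @export
run_ora <- function(query, collection, universe = NULL, alpha = 0.05) {
  if (!length(collection)) abort("Empty gene-set collection.")
  query <- unique(normalize_symbol(query))
  if (!length(query)) abort("Empty query.")
  sets <- lapply(collection, function(s) unique(normalize_symbol(s)))
  desc <- attr(collection, "description") %||%
    setNames(names(sets), names(sets))
  if (is.null(universe)) {
    universe <- sort(unique(unlist(sets)))
  } else {
    universe <- unique(normalize_symbol(universe))
  }
  N <- length(universe)
  query_u <- intersect(query, universe)
  n <- length(query_u)
  rows <- purrr::map(names(sets), function(id) {
    set_u <- intersect(sets[[id]], universe)
    ov <- sort(intersect(query_u, set_u))
    k <- length(ov)
    if (k == 0) return(NULL)
    tibble::tibble(set_id = id, description = unname(desc[[id]] %||% id),
                   k = k, K = length(set_u), n = n, N = N,
                   p_value = hypergeom_upper_tail(k, length(set_u), n, N),
                   overlap = list(ov))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(set_id = character(), description = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p_value = numeric(),
                          q_value = numeric(), overlap = list())
    return(structure(out, class = c("ora_result", class(out))))
  }
  out$q_value <- bh_adjust(out$p_value)
  # alpha = 1 means "keep every overlapping set", including exact p = 1
  out <- out[out$p_value < alpha | alpha >= 1, , drop = FALSE]
  out <- out[order(out$p_value, out$set_id),
             c("set_id", "description", "k", "K", "n", "N",
               "p_value", "q_value", "overlap")]
  structure(out, class = c("ora_result", class(out)))
}

#' @export
glance.ora_result <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x),
                 n_significant_q = sum(x$q_value < 0.05),
                 min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}

#' @export
tidy.ora_result <- function(x, ...) {
  out <- tibble::as_tibble(unclass(x))
  out$overlap <- vapply(out$overlap, paste, "", collapse = ",")
  out
}

#' Write an ORA result table as TSV
#'
#' Columns: set_id, description, k, K, n, N, p_value, q_value, overlap
#' (comma-joined symbols).
#'
#' @param results An [run_ora()] result.
#' @param path Output TSV.
#' @export
write_ora_table <- function(results, path) {
  readr::write_tsv(tidy(results), path, progress = FALSE)
  invisible(path)
}

#' Pathway-target bipartite network
#'
#' Connects each enriched pathway to its overlap genes: one edge per
#' (pathway, gene) overlap pair, so the edge count equals the summed overlap
#' sizes. The network's own topology profile (degree, betweenness,
#' closeness, core number, with medians) is computed on it.
#'
#' @param results An [run_ora()] result with its `overlap` list-column.
#' @return A list with `network` (an [interaction_network()], roles
#'   `"pathway"` and `"protein"`) and `profile` (a [topology_profile()], or
#'   `NULL` for an empty result).
#' @export
pathway_target_network <- function(results) {
  stopifnot(inherits(results, "ora_result") || is.data.frame(results))
  if (nrow(results) == 0) {
    net <- interaction_network(tibble::tibble(id = character(),
                                              role = character()))
    return(list(network = net, profile = NULL))
  }
  pairs <- tidyr::unnest(
    tibble::tibble(pathway = results$set_id, gene = results$overlap),
    "gene")
  net <- bipartite_network(pairs, left_role = "pathway",
                           right_role = "protein", relation = "pt")
  list(network = net, profile = topology_profile(net))
}
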