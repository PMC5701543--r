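#' Normalise gene symbols
#'
#' Gene symbols are uppercased and whitespace-trimmed. No alias resolution is
#' attempted; normalisation is idempotent and order-independent.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of normalised symbols.
#' @examples
#' normalize_symbol(c(" abcA1 ", "pparg"))
#' @export
normalize_symbol <- function(x) toupper(trimws(as.character(x)))

read_tsv_quiet <- function(path, ...) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE, ...)
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0(path, ": missing mandatory column(s) ",
                 paste(missing, collapse = ", ")))
  }
}

remap_columns <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  for (canonical in names(col_map)) {
    src <- col_map[[canonical]]
    if (src %in% names(df)) names(df)[names(df) == src] <- canonical
  }
  df
}

#' Read a compound table
#'
#' One row per composite compound of the herb: an opaque compound id (for
#' example a UNPD accession), a display name, and optionally a SMILES
#' structure string.
#'
#' @param path TSV file with a header.
#' @param col_map Optional named list mapping canonical column names
#'   (`compound_id`, `name`, `smiles`) to the file's column names.
#' @return A tibble with columns `compound_id`, `name` and (if present)
#'   `smiles`.
#' @export
read_compound_table <- function(path, col_map = NULL) {
  df <- remap_columns(read_tsv_quiet(path), col_map)
  require_columns(df, c("compound_id", "name"), path)
  df$compound_id <- trimws(as.character(df$compound_id))
  if (any(!nzchar(df$compound_id))) abort(paste0(path, ": empty compound_id."))
  if (anyDuplicated(df$compound_id)) abort(paste0(path, ": duplicate compound_id."))
  keep <- intersect(c("compound_id", "name", "smiles"), names(df))
  tibble::as_tibble(df[, keep, drop = FALSE])
}

#' Read compound-target association predictions
#'
#' One row per predicted (compound, putative target) pair. Target symbols are
#' normalised and duplicate pairs are collapsed; when duplicates carry
#' conflicting prediction scores the maximum is kept (a best-evidence rule).
#'
#' @param path TSV file with a header.
#' @param col_map Optional named list mapping canonical names (`compound_id`,
#'   `target_symbol`, `score`) to the file's column names.
#' @param quiet Suppress the duplicate-count message.
#' @return A tibble with columns `compound_id`, `target_symbol` and (if
#'   present) `score`, unique on (compound_id, target_symbol). The number of
#'   collapsed duplicate rows is stored in attribute `"duplicates"`.
#' @export
read_target_associations <- function(path, col_map = NULL, quiet = FALSE) {
  df <- remap_columns(read_tsv_quiet(path), col_map)
  require_columns(df, c("compound_id", "target_symbol"), path)
  dedupe_pairs(df, path, quiet, score_required = FALSE)
}

#' Read a docking-score table
#'
#' One row per docked (compound, target) pair with its docking score (for
#' example a LibDock score; dimensionless, higher = stronger predicted
#' binding). Duplicate pairs collapse to the maximum score (docking is a
#' best-pose score) before any downstream median computation.
#'
#' @inheritParams read_target_associations
#' @return A tibble with columns `compound_id`, `target_symbol`, `score`,
#'   unique on (compound_id, target_symbol), all scores finite.
#' @export
read_docking_table <- function(path, col_map = NULL, quiet = FALSE) {
  df <- remap_columns(read_tsv_quiet(path), col_map)
  require_columns(df, c("compound_id", "target_symbol", "score"), path)
  df$score <- suppressWarnings(as.numeric(df$score))
  if (anyNA(df$score) || any(!is.finite(df$score))) {
    abort(paste0(path, ": non-numeric or non-finite docking score."))
  }
  dedupe_pairs(df, path, quiet, score_required = TRUE)
}

dedupe_pairs <- function(df, path, quiet, score_required) {
  df$compound_id <- trimws(as.character(df$compound_id))
  df$target_symbol <- normalize_symbol(df$target_symbol)
  n_raw <- nrow(df)
  has_score <- "score" %in% names(df)
  if (has_score) {
    df <- df |>
      dplyr::group_by(.data$compound_id, .data$target_symbol) |>
      dplyr::summarise(score = max(.data$score), .groups = "drop")
  } else {
    df <- dplyr::distinct(df[, c("compound_id", "target_symbol")])
  }
  dups <- n_raw - nrow(df)
  if (dups > 0 && !quiet) {
    inform(paste0(path, ": collapsed ", dups, " duplicate row(s)."))
  }
  keep <- c("compound_id", "target_symbol", if (has_score) "score")
  out <- tibble::as_tibble(df[order(df$compound_id, df$target_symbol), keep])
  attr(out, "duplicates") <- dups
  out
}

#' Read known therapeutic-target lists
#'
#' One row per (disease, target) assertion, optionally with a provenance tag
#' (for example DrugBank or OMIM). Symbols are normalised; use
#' [dedupe_disease_targets()] to collapse redundant assertions into one
#' unique symbol set per disease.
#'
#' @param path TSV file with a header.
#' @param col_map Optional named list mapping canonical names (`disease_id`,
#'   `target_symbol`, `source`) to the file's column names.
#' @return A tibble with columns `disease_id`, `target_symbol` and (if
#'   present) `source`.
#' @export
read_disease_targets <- function(path, col_map = NULL) {
  df <- remap_columns(read_tsv_quiet(path), col_map)
  require_columns(df, c("disease_id", "target_symbol"), path)
  df$disease_id <- trimws(as.character(df$disease_id))
  df$target_symbol <- normalize_symbol(df$target_symbol)
  keep <- intersect(c("disease_id", "target_symbol", "source"), names(df))
  tibble::as_tibble(df[, keep, drop = FALSE])
}

#' Deduplicate disease-target assertions
#'
#' Known therapeutic targets are typically merged from several databases
#' (DrugBank, OMIM, ...) that list overlapping genes. This collapses the raw
#' assertions to one unique, normalised symbol set per disease — a plain set
#' union across sources — and reports the per-disease counts.
#'
#' @param raw Data frame with columns `disease_id` and `target_symbol`.
#' @param quiet Suppress the per-disease count message.
#' @return A tibble with columns `disease_id`, `target_symbol`, unique per
#'   disease; per-disease counts in attribute `"counts"` (named integer).
#' @examples
#' dedupe_disease_targets(
#'   data.frame(disease_id = "T2D", target_symbol = c("PPARG", "pparg")))
#' @export
dedupe_disease_targets <- function(raw, quiet = FALSE) {
  raw <- tibble::as_tibble(raw)
  if (nrow(raw) == 0) {
    warn("dedupe_disease_targets: empty input; returning empty set.")
    out <- tibble::tibble(disease_id = character(), target_symbol = character())
    attr(out, "counts") <- integer()
    return(out)
  }
  require_columns(raw, c("disease_id", "target_symbol"), "disease targets")
  raw$target_symbol <- normalize_symbol(raw$target_symbol)
  out <- dplyr::distinct(raw[, c("disease_id", "target_symbol")])
  out <- out[order(out$disease_id, out$target_symbol), ]
  counts <- table(out$disease_id)
  counts <- setNames(as.integer(counts), names(counts))
  if (!quiet) {
    inform(paste0("Deduplicated therapeutic targets: ",
                  paste(names(counts), counts, sep = " = ", collapse = ", ")))
  }
  attr(out, "counts") <- counts
  out
}

#' Read and write gene-set collections (GMT)
#'
#' The GMT dialect is the tab-separated Broad layout: one set per line,
#' `set_id TAB description TAB gene TAB gene ...`. Gene symbols are
#' normalised on read; duplicate genes within a set collapse; duplicate set
#' ids are an error.
#'
#' @param path GMT file.
#' @return `read_gmt()`: a named list of character vectors (the sets), with
#'   a named character vector of descriptions in attribute `"description"`.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("S1\tfirst set\tA\tB", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad)) {
    abort(paste0(path, ": line ", bad[1], " has fewer than 3 tab-separated fields."))
  }
  ids <- vapply(fields, `[[`, "", 1)
  if (anyDuplicated(ids)) {
    abort(paste0(path, ": duplicate set id ", ids[duplicated(ids)][1], "."))
  }
  desc <- setNames(vapply(fields, `[[`, "", 2), ids)
  sets <- lapply(fields, function(f) unique(normalize_symbol(f[-(1:2)])))
  names(sets) <- ids
  if (any(lengths(sets) == 0)) abort(paste0(path, ": empty gene set."))
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets Named list of character vectors, optionally with a
#'   `"description"` attribute.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||% setNames(names(sets), names(sets))
  lines <- vapply(names(sets), function(id) {
    paste(c(id, unname(desc[[id]]), sets[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export and import interaction networks
#'
#' Three exchange formats are supported. `"sif"` is the simple-interaction
#' format of Cytoscape-class viewers: one `from relation to` line per edge
#' and a bare-id line per isolated node; node annotations are not
#' representable in SIF. `"graphml"` preserves nodes, edges, relations and
#' all node annotation columns with their types. `"tsv"` writes the edge
#' table to `path` and the node table (with annotations) to
#' `sub("\\\\.tsv$", ".nodes.tsv", path)`.
#'
#' Every writer emits UTF-8 with LF line endings, and
#' `read_network(write_network(net, p, fmt), fmt)` reproduces the node set,
#' edge set and (except for SIF) the node annotations.
#'
#' @param net An [interaction_network()].
#' @param path Output file.
#' @param format One of `"sif"`, `"graphml"`, `"tsv"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns an `interaction_network`.
#' @export
write_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(is_interaction_network(net))
  format <- match.arg(format)
  switch(format,
    sif = write_sif(net, path),
    graphml = write_graphml(net, path),
    tsv = write_net_tsv(net, path))
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("sif", "graphml", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  switch(format,
    sif = read_sif(path),
    graphml = read_graphml(path),
    tsv = read_net_tsv(path))
}

write_sif <- function(net, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  e <- net$edges
  lines <- character()
  if (nrow(e)) lines <- paste(e$from, e$relation, e$to, sep = "\t")
  isolated <- setdiff(net$nodes$id, c(e$from, e$to))
  lines <- c(lines, isolated)
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
}

read_sif <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  single <- lengths(fields) == 1
  bad <- !single & lengths(fields) != 3
  if (any(bad)) abort(paste0(path, ": SIF line ", which(bad)[1], " malformed."))
  edges <- do.call(rbind, fields[!single])
  if (is.null(edges)) {
    edges <- tibble::tibble(from = character(), to = character(),
                            relation = character())
  } else {
    edges <- tibble::tibble(from = edges[, 1], relation = edges[, 2],
                            to = edges[, 3])
  }
  ids <- unique(c(edges$from, edges$to, unlist(fields[single])))
  interaction_network(tibble::tibble(id = sort(ids), role = "protein"), edges)
}

graphml_type <- function(x) {
  if (is.logical(x)) "boolean"
  else if (is.integer(x)) "int"
  else if (is.numeric(x)) "double"
  else "string"
}

write_graphml <- function(net, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  attr_cols <- setdiff(names(net$nodes), "id")
  for (i in seq_along(attr_cols)) {
    xml2::xml_add_child(doc, "key", id = paste0("n", i), `for` = "node",
                        attr.name = attr_cols[i],
                        attr.type = graphml_type(net$nodes[[attr_cols[i]]]))
  }
  xml2::xml_add_child(doc, "key", id = "e1", `for` = "edge",
                      attr.name = "relation", attr.type = "string")
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  for (r in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$id[r])
    for (i in seq_along(attr_cols)) {
      val <- net$nodes[[attr_cols[i]]][r]
      d <- xml2::xml_add_child(nd, "data", key = paste0("n", i))
      xml2::xml_text(d) <- if (is.logical(val)) tolower(as.character(val)) else
        format(val, scientific = FALSE, trim = TRUE)
    }
  }
  for (r in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(g, "edge", source = net$edges$from[r],
                              target = net$edges$to[r])
    d <- xml2::xml_add_child(ed, "data", key = "e1")
    xml2::xml_text(d) <- net$edges$relation[r]
  }
  xml2::write_xml(doc, path)
}

read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, "./key")
  key_name <- setNames(xml2::xml_attr(keys, "attr.name"), xml2::xml_attr(keys, "id"))
  key_type <- setNames(xml2::xml_attr(keys, "attr.type"), xml2::xml_attr(keys, "id"))
  node_els <- xml2::xml_find_all(doc, "./graph/node")
  ids <- xml2::xml_attr(node_els, "id")
  nodes <- tibble::tibble(id = ids)
  node_keys <- names(key_name)[xml2::xml_attr(keys, "for") == "node"]
  for (k in node_keys) {
    raw <- vapply(node_els, function(el) {
      d <- xml2::xml_find_first(el, paste0("./data[@key='", k, "']"))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }, "")
    nodes[[key_name[[k]]]] <- switch(key_type[[k]],
      boolean = raw == "true",
      int = as.integer(raw),
      double = as.numeric(raw),
      raw)
  }
  edge_els <- xml2::xml_find_all(doc, "./graph/edge")
  rel <- vapply(edge_els, function(el) {
    d <- xml2::xml_find_first(el, "./data")
    if (inherits(d, "xml_missing")) "pp" else xml2::xml_text(d)
  }, "")
  edges <- tibble::tibble(from = xml2::xml_attr(edge_els, "source"),
                          to = xml2::xml_attr(edge_els, "target"),
                          relation = rel)
  if (!"role" %in% names(nodes)) nodes$role <- "protein"
  interaction_network(nodes, edges)
}

nodes_tsv_path <- function(path) {
  if (grepl("\\.tsv$", path)) sub("\\.tsv$", ".nodes.tsv", path)
  else paste0(path, ".nodes.tsv")
}

write_net_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path, progress = FALSE)
  readr::write_tsv(net$nodes, nodes_tsv_path(path), progress = FALSE)
}

read_net_tsv <- function(path) {
  edges <- read_tsv_quiet(path, col_types = readr::cols(
    from = "c", to = "c", relation = "c", .default = readr::col_guess()))
  nodes <- read_tsv_quiet(nodes_tsv_path(path))
  nodes$id <- as.character(nodes$id)
  if (nrow(edges) == 0) edges <- NULL
  interaction_network(nodes, edges)
}
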