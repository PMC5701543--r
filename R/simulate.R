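#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single integer.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive child seeds from a master seed so each synthetic table is
#' individually reproducible.
#' @noRd
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

gene_token <- function(i) sprintf("G%06d", i)
compound_token <- function(i) sprintf("CPD%04d", i)

#' Simulate a scale-free PPI edge list
#'
#' Preferential-attachment (Barabási-Albert) graph: connected, with the
#' heavy-tailed degree distribution typical of merged protein-protein
#' interaction snapshots. Generation is delegated to
#' [igraph::sample_pa()]; the result is deterministic per seed.
#'
#' @param n Number of proteins (>= 2).
#' @param attachment Edges added per incoming node (>= 1).
#' @param seed Integer seed.
#' @param ids Optional character vector of `n` node names; defaults to
#'   `G000001`-style tokens.
#' @return A tibble with columns `from`, `to`.
#' @export
simulate_ppi <- function(n, attachment = 2, seed = 1, ids = NULL) {
  if (!is.numeric(n) || n < 2) abort("`n` must be >= 2.")
  if (!is.numeric(attachment) || attachment < 1) abort("`attachment` must be >= 1.")
  if (is.null(ids)) ids <- gene_token(seq_len(n))
  if (length(ids) != n) abort("`ids` must have length n.")
  el <- with_seed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = attachment, directed = FALSE)
    igraph::as_edgelist(g, names = FALSE)
  })
  tibble::tibble(from = ids[el[, 1]], to = ids[el[, 2]])
}

#' Simulate labelled sets with a planted Venn structure
#'
#' Generates labelled symbol sets (for example putative targets and three
#' disease target lists) whose Venn partition equals a planted region
#' specification exactly: `region_spec` is a named integer vector whose
#' names are `&`-joined label combinations (`"PT"`, `"PT&HT"`,
#' `"PT&T2D&HT&HL"`, ...) and whose values are the region sizes. Symbols are
#' synthesised as disjoint `G`-tokens, so ground truth is known per region.
#'
#' @param region_spec Named integer vector of disjoint region sizes.
#' @param seed Integer seed (shuffles which symbols land in which region).
#' @param start_index First integer used for symbol tokens.
#' @return A list with `sets` (named list of character vectors, one per
#'   label), `regions` (tibble `region`, `count`, `symbols` — the ground
#'   truth), and `membership` (long tibble `label`, `symbol`).
#' @examples
#' sim <- simulate_overlap_sets(c(A = 3, B = 2, `A&B` = 1), seed = 7)
#' lengths(sim$sets)
#' @export
simulate_overlap_sets <- function(region_spec, seed = 1, start_index = 1L) {
  if (is.null(names(region_spec)) || any(!nzchar(names(region_spec)))) {
    abort("`region_spec` must be a named vector.")
  }
  if (anyDuplicated(names(region_spec))) abort("Duplicate region names.")
  if (any(region_spec < 0)) abort("Region sizes must be non-negative.")
  region_spec <- region_spec[region_spec > 0]
  total <- sum(region_spec)
  symbols <- with_seed(seed, sample(gene_token(seq.int(start_index,
                                                       start_index + total - 1L))))
  labels <- unique(unlist(strsplit(names(region_spec), "&", fixed = TRUE)))
  idx <- 0L
  regions <- tibble::tibble(region = names(region_spec),
                            count = as.integer(region_spec),
                            symbols = vector("list", length(region_spec)))
  sets <- setNames(rep(list(character()), length(labels)), labels)
  for (r in seq_along(region_spec)) {
    sym <- symbols[idx + seq_len(region_spec[[r]])]
    idx <- idx + region_spec[[r]]
    regions$symbols[[r]] <- sort(sym)
    for (lb in strsplit(regions$region[r], "&", fixed = TRUE)[[1]]) {
      sets[[lb]] <- c(sets[[lb]], sym)
    }
  }
  sets <- lapply(sets, sort)
  list(sets = sets, regions = regions,
       membership = tidyr::unnest(
         tibble::tibble(label = names(sets), symbol = unname(sets)), "symbol"))
}

#' Planted Venn specification mirroring the study's set sizes
#'
#' Region sizes chosen so the four sets have 97 putative targets (PT) and
#' 59, 279 and 20 therapeutic targets for T2D, HT and HL, with 13 putative
#' targets shared with at least one disease: PT&HT 8, PT&HL 1, one symbol in
#' each of PT&T2D&HT, PT&T2D&HL, PT&HT&HL, and one symbol in all four.
#'
#' @return Named integer vector usable with [simulate_overlap_sets()].
#' @export
default_region_spec <- function() {
  c(PT = 84L, T2D = 56L, HT = 268L, HL = 16L,
    `PT&HT` = 8L, `PT&HL` = 1L,
    `PT&T2D&HT` = 1L, `PT&T2D&HL` = 1L, `PT&HT&HL` = 1L,
    `PT&T2D&HT&HL` = 1L)
}

#' Simulate a pathway collection with one planted enriched set
#'
#' Decoy sets are drawn uniformly from the universe; the planted set
#' contains `round(planted_fraction * length(planted_query))` genes of the
#' planted query plus uniform filler, so at fraction 1 it is fully enriched
#' for the query and at the background rate it is indistinguishable from a
#' decoy.
#'
#' @param universe Character vector of background genes.
#' @param planted_query Character vector (e.g. the planted key targets).
#' @param n_sets Number of sets including the planted one.
#' @param size_range Length-2 integer vector of set sizes (uniform).
#' @param planted_fraction Fraction of the query planted into the set.
#' @param seed Integer seed.
#' @return A list with `collection` (named list with `description`
#'   attribute, GMT-compatible) and `planted_set_id`.
#' @export
simulate_pathways <- function(universe, planted_query, n_sets = 50,
                              size_range = c(10, 60), planted_fraction = 1,
                              seed = 1) {
  if (planted_fraction < 0 || planted_fraction > 1) {
    abort("`planted_fraction` must be in [0, 1].")
  }
  if (n_sets < 1) abort("`n_sets` must be >= 1.")
  universe <- unique(normalize_symbol(universe))
  planted_query <- unique(normalize_symbol(planted_query))
  if (!all(planted_query %in% universe)) {
    abort("`planted_query` must be contained in `universe`.")
  }
  if (max(size_range) > length(universe)) abort("Set sizes exceed universe.")
  with_seed(seed, {
    ids <- sprintf("PATH%03d", seq_len(n_sets))
    planted_id <- ids[1]
    sizes <- sample(seq.int(size_range[1], size_range[2]), n_sets,
                    replace = TRUE)
    n_in <- round(planted_fraction * length(planted_query))
    sizes[1] <- max(sizes[1], n_in)
    planted <- sample(planted_query, n_in)
    filler <- sample(setdiff(universe, planted), sizes[1] - n_in)
    sets <- vector("list", n_sets)
    sets[[1]] <- sort(c(planted, filler))
    for (i in seq_len(n_sets)[-1]) sets[[i]] <- sort(sample(universe, sizes[i]))
    names(sets) <- ids
    attr(sets, "description") <- setNames(
      c("planted pathway", sprintf("decoy pathway %d", seq_len(n_sets - 1))),
      ids)
    list(collection = sets, planted_set_id = planted_id)
  })
}

#' Simulate docking scores for compound-target pairs
#'
#' One Gaussian score per pair, seeded; the distribution's median equals
#' `mean`, so roughly half of a large table survives the median filter and
#' for an odd number of distinct scores exactly `(n - 1) / 2` do.
#'
#' @param pairs Data frame with columns `compound_id`, `target_symbol`.
#' @param mean,sd Score distribution parameters (`sd > 0`).
#' @param seed Integer seed.
#' @return A tibble with columns `compound_id`, `target_symbol`, `score`.
#' @export
simulate_docking_scores <- function(pairs, mean = 86, sd = 25, seed = 1) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty.")
  if (sd <= 0) abort("`sd` must be positive.")
  require_columns(pairs, c("compound_id", "target_symbol"), "pairs")
  scores <- with_seed(seed, rnorm(nrow(pairs), mean, sd))
  tibble::tibble(compound_id = pairs$compound_id,
                 target_symbol = pairs$target_symbol,
                 score = round(scores, 3))
}

#' Simulate a PPI network with planted hub targets
#'
#' A designed three-tier topology with known ground truth for the two-stage
#' key-target filter: `n_hubs` hub nodes forming a clique, each additionally
#' tied to mid-tier nodes; `n_mids` mid-tier nodes arranged in a cycle, each
#' tied to exactly two hubs (balanced round-robin); and `n_pendants`
#' degree-1 leaf nodes hanging off random mid-tier nodes. Pendants keep the
#' network-wide median degree at 1, so stage A (degree >= 2x median) retains
#' exactly the hub + mid tier; within that hub network every mid-tier node
#' has degree equal to the median (failing the strict stage-B test) while
#' hubs strictly exceed all four feature medians. The planted hubs are
#' therefore the exact key-target set.
#'
#' @param n_hubs Number of planted hubs (>= 6, so the hub clique's core
#'   number exceeds the mid-tier core).
#' @param n_mids Number of mid-tier nodes (>= `n_hubs + 2`, so the stage-B
#'   medians are mid-tier values).
#' @param n_pendants Number of leaves (>= `n_hubs + n_mids + 2`, so the
#'   network-wide median degree is 1).
#' @param seed Integer seed (shuffles which ids play which role).
#' @param ids Optional character vector of node names (length
#'   `n_hubs + n_mids + n_pendants`); defaults to `G`-tokens.
#' @return A list with `edges` (tibble `from`, `to`), `hubs`, `mids`,
#'   `pendants` (character vectors of ids).
#' @export
simulate_hub_network <- function(n_hubs = 7, n_mids = 12, n_pendants = 25,
                                 seed = 1, ids = NULL) {
  if (n_hubs < 6) abort("`n_hubs` must be >= 6.")
  if (n_mids < n_hubs + 2) abort("`n_mids` must be >= n_hubs + 2.")
  if (n_pendants < n_hubs + n_mids + 2) {
    abort("`n_pendants` must be >= n_hubs + n_mids + 2.")
  }
  n <- n_hubs + n_mids + n_pendants
  if (is.null(ids)) ids <- gene_token(seq_len(n))
  if (length(ids) != n) abort("`ids` must have length n_hubs + n_mids + n_pendants.")
  with_seed(seed, {
    ids <- sample(ids)
    hubs <- ids[seq_len(n_hubs)]
    mids <- ids[n_hubs + seq_len(n_mids)]
    pendants <- ids[n_hubs + n_mids + seq_len(n_pendants)]
    hub_pairs <- t(utils::combn(hubs, 2))
    cycle <- cbind(mids, c(mids[-1], mids[1]))
    # balanced round-robin: mid i ties to hubs i and i + floor(H/2) (mod H)
    h1 <- ((seq_len(n_mids) - 1L) %% n_hubs) + 1L
    h2 <- ((seq_len(n_mids) - 1L + n_hubs %/% 2L) %% n_hubs) + 1L
    mid_hub <- cbind(rep(mids, 2), hubs[c(h1, h2)])
    leaf <- cbind(pendants, sample(mids, n_pendants, replace = TRUE))
    edges <- rbind(hub_pairs, cycle, mid_hub, leaf)
    list(edges = tibble::tibble(from = edges[, 1], to = edges[, 2]),
         hubs = sort(hubs), mids = sort(mids), pendants = sort(pendants))
  })
}

#' Simulate a complete synthetic input bundle
#'
#' Generates every input of the pipeline with planted ground truth for every
#' downstream stage, at the study conditions the analysis assumes by
#' default: 20 composite compounds with 97 putative targets; therapeutic
#' target lists of 59, 279 and 20 symbols for T2D, HT and HL with the
#' planted Venn regions of [default_region_spec()]; a PPI with
#' `n_hubs` planted hub targets ([simulate_hub_network()]) plus a few decoy
#' genes outside the target universe; a pathway collection whose first set
#' is planted around the hubs; and Gaussian docking scores (median at
#' `docking_mean`) for every compound x hub pair. A single master seed fans
#' out to fixed per-table child seeds, so each table is individually
#' reproducible and the whole bundle is byte-stable per seed.
#'
#' The raw disease-target table deliberately contains redundant rows
#' (DrugBank/OMIM double listings and case variants) so that
#' [dedupe_disease_targets()] has real work to do; the deduplicated counts
#' equal the planted set sizes.
#'
#' @param seed Master integer seed.
#' @param n_compounds Number of compounds.
#' @param region_spec Planted Venn region sizes (named vector).
#' @param n_hubs,n_mids Planted hub-network tiers; every remaining protein
#'   becomes a pendant.
#' @param n_pathways,pathway_size_range Pathway collection shape.
#' @param docking_mean,docking_sd Docking-score distribution.
#' @param n_decoy_genes Non-target genes wired into the raw PPI (their edges
#'   must be dropped at assembly).
#' @return A list of class `synthetic_bundle`: `compounds`, `associations`,
#'   `disease_targets` (raw, with redundancies), `ppi`, `pathways`,
#'   `docking`, and `ground_truth` (hubs, regions, planted pathway id,
#'   docking parameters, seed).
#' @export
simulate_bundle <- function(seed = 1,
                            n_compounds = 20,
                            region_spec = default_region_spec(),
                            n_hubs = 7, n_mids = 12,
                            n_pathways = 50,
                            pathway_size_range = c(10, 60),
                            docking_mean = 86, docking_sd = 25,
                            n_decoy_genes = 10) {
  cs <- child_seeds(seed, 8)

  ov <- simulate_overlap_sets(region_spec, seed = cs[1])
  pt <- ov$sets[["PT"]]
  disease_labels <- setdiff(names(ov$sets), "PT")
  proteins <- sort(unique(unlist(ov$sets)))

  compounds <- tibble::tibble(
    compound_id = compound_token(seq_len(n_compounds)),
    name = sprintf("compound-%02d", seq_len(n_compounds)),
    smiles = NA_character_)

  associations <- with_seed(cs[2], {
    rows <- lapply(pt, function(sym) {
      k <- sample(1:3, 1)
      tibble::tibble(compound_id = sample(compounds$compound_id, k),
                     target_symbol = sym)
    })
    out <- dplyr::bind_rows(rows)
    orphan <- setdiff(compounds$compound_id, out$compound_id)
    if (length(orphan)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        compound_id = orphan, target_symbol = sample(pt, length(orphan),
                                                     replace = TRUE)))
    }
    dplyr::distinct(out[order(out$compound_id, out$target_symbol), ])
  })

  disease_targets <- with_seed(cs[3], {
    rows <- lapply(disease_labels, function(d) {
      sym <- ov$sets[[d]]
      src <- sample(c("DrugBank", "OMIM"), length(sym), replace = TRUE)
      base <- tibble::tibble(disease_id = d, target_symbol = sym, source = src)
      # redundancies: ~15% double-listed in the other source, some lower-case
      dup <- base[sample.int(nrow(base), max(1, round(0.15 * nrow(base)))), ]
      dup$source <- ifelse(dup$source == "DrugBank", "OMIM", "DrugBank")
      dup$target_symbol <- ifelse(seq_len(nrow(dup)) %% 2 == 0,
                                  tolower(dup$target_symbol),
                                  dup$target_symbol)
      dplyr::bind_rows(base, dup)
    })
    out <- dplyr::bind_rows(rows)
    out[sample.int(nrow(out)), ]
  })

  n_pendants <- length(proteins) - n_hubs - n_mids
  hubnet <- simulate_hub_network(n_hubs = n_hubs, n_mids = n_mids,
                                 n_pendants = n_pendants, seed = cs[4],
                                 ids = proteins)
  decoys <- sprintf("X%04d", seq_len(n_decoy_genes))
  decoy_edges <- with_seed(cs[5], tibble::tibble(
    from = decoys, to = sample(hubnet$mids, n_decoy_genes, replace = TRUE)))
  ppi <- dplyr::bind_rows(hubnet$edges, decoy_edges)
  ppi <- with_seed(cs[5], ppi[sample.int(nrow(ppi)), ])

  pathway_universe <- sort(unique(c(
    proteins, gene_token(seq.int(700001, 700000 + 400)))))
  pw <- simulate_pathways(pathway_universe, planted_query = hubnet$hubs,
                          n_sets = n_pathways,
                          size_range = pathway_size_range,
                          planted_fraction = 1, seed = cs[6])

  pairs <- tidyr::expand_grid(compound_id = compounds$compound_id,
                              target_symbol = hubnet$hubs)
  docking <- simulate_docking_scores(pairs, mean = docking_mean,
                                     sd = docking_sd, seed = cs[7])

  structure(list(
    compounds = compounds,
    associations = associations,
    disease_targets = disease_targets,
    ppi = ppi,
    pathways = pw$collection,
    docking = docking,
    ground_truth = list(
      seed = seed,
      hubs = hubnet$hubs, mids = hubnet$mids, pendants = hubnet$pendants,
      regions = ov$regions,
      set_sizes = lengths(ov$sets),
      planted_pathway = pw$planted_set_id,
      docking_mean = docking_mean, docking_sd = docking_sd)),
    class = "synthetic_bundle")
}

#' Write a synthetic bundle to a directory
#'
#' Emits the TSV/GMT files the pipeline readers consume, plus
#' `ground_truth.json`.
#'
#' @param bundle A [simulate_bundle()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(bundle$compounds, file.path(dir, "compounds.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$associations, file.path(dir, "associations.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$disease_targets,
                   file.path(dir, "disease_targets.tsv"), progress = FALSE)
  readr::write_tsv(bundle$ppi, file.path(dir, "ppi.tsv"), progress = FALSE)
  write_gmt(bundle$pathways, file.path(dir, "pathways.gmt"))
  readr::write_tsv(bundle$docking, file.path(dir, "docking.tsv"),
                   progress = FALSE)
  gt <- bundle$ground_truth
  gt$regions <- lapply(seq_len(nrow(gt$regions)), function(i) {
    list(region = gt$regions$region[i], count = gt$regions$count[i],
         symbols = gt$regions$symbols[[i]])
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
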