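pipeline_defaults <- function() {
  list(stage_a_multiplier = 2.0, alpha = 0.05,
       include_source_nodes = FALSE, outdir = NULL, seed = 1L)
}

pipeline_input_keys <- c("compounds", "associations", "disease_targets",
                         "ppi", "pathways", "docking")

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent named list), applies
#' defaults and rejects unknown keys. Recognised keys:
#'
#' * `inputs`: named paths — `associations` and `ppi` are mandatory;
#'   `compounds`, `disease_targets`, `pathways` (GMT) and `docking` are
#'   optional (their stages are skipped when absent);
#' * `stage_a_multiplier` (default 2.0 — the 2-fold-median degree cut);
#' * `alpha` (default 0.05 — the raw-p enrichment cut-off);
#' * `include_source_nodes` (default false);
#' * `outdir` (default: no files written, results returned only);
#' * `seed` (recorded in the run report; the pipeline itself is
#'   deterministic).
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("Config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a YAML path or a named list.")
  known <- c("inputs", names(pipeline_defaults()))
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(pipeline_defaults(), config[setdiff(names(config), "inputs")])
  inputs <- config$inputs %||% list()
  unknown_in <- setdiff(names(inputs), pipeline_input_keys)
  if (length(unknown_in)) {
    abort(paste0("Unknown input key(s): ", paste(unknown_in, collapse = ", ")))
  }
  for (req in c("associations", "ppi")) {
    if (is.null(inputs[[req]])) abort(paste0("`inputs$", req, "` is required."))
  }
  for (k in names(inputs)) {
    if (!file.exists(inputs[[k]])) {
      abort(paste0("Input file not found (", k, "): ", inputs[[k]]))
    }
  }
  if (!is.numeric(cfg$stage_a_multiplier) || cfg$stage_a_multiplier <= 0) {
    abort("`stage_a_multiplier` must be a positive number.")
  }
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha > 1) {
    abort("`alpha` must lie in (0, 1].")
  }
  if (!is.logical(cfg$include_source_nodes)) {
    abort("`include_source_nodes` must be true/false.")
  }
  cfg$inputs <- inputs
  structure(cfg, class = "pipeline_config")
}

#' Run the full network-pharmacology pipeline
#'
#' Orchestrates every stage on file inputs: read and normalise the tables,
#' deduplicate the therapeutic-target lists, assemble the
#' compound-target-disease network, profile its topology, run the two-stage
#' median-threshold key-target filter, partition the putative and disease
#' target sets into Venn regions, test the key targets for pathway
#' over-representation and build the pathway-target network, and filter the
#' docking table at its score median to build the target-compound network.
#'
#' When `outdir` is set, every stage's artefacts are written there (TSV
#' tables, SIF + GraphML networks, and a machine-readable `report.json`
#' summarising every count and threshold); the pipeline is deterministic, so
#' identical inputs and config give identical outputs. Empty stage outputs
#' (e.g. no key targets) raise a warning and the remaining stages are
#' skipped gracefully, not an error.
#'
#' @param config A YAML path, named list, or [validate_config()] result.
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_report`; see the `summary` element for
#'   the flat count/threshold record written to `report.json`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else validate_config(config)
  say <- function(...) if (!quiet) inform(paste0("[netpharm] ", ...))
  inp <- cfg$inputs

  assoc <- read_target_associations(inp$associations, quiet = quiet)
  say("associations: ", nrow(assoc), " unique compound-target pairs, ",
      length(unique(assoc$target_symbol)), " putative targets")
  disease_raw <- if (!is.null(inp$disease_targets)) {
    read_disease_targets(inp$disease_targets)
  } else NULL
  disease <- if (!is.null(disease_raw)) {
    dedupe_disease_targets(disease_raw, quiet = quiet)
  } else NULL
  ppi <- read_tsv_quiet(inp$ppi)
  require_columns(ppi, c("from", "to"), inp$ppi)

  net <- assemble_network(assoc, disease, ppi,
                          include_source_nodes = cfg$include_source_nodes,
                          quiet = quiet)
  say("network: ", n_nodes(net), " nodes, ", n_edges(net), " edges")
  profile_full <- topology_profile(net)

  ktp <- key_target_pipeline(net, multiplier = cfg$stage_a_multiplier)
  say("stage A: ", n_nodes(ktp$hub_network), " nodes, ",
      n_edges(ktp$hub_network), " edges; stage B: ",
      length(ktp$key_targets), " key targets")

  venn <- NULL
  if (!is.null(disease) && nrow(disease)) {
    sets <- c(list(PT = unique(assoc$target_symbol)),
              split(disease$target_symbol, disease$disease_id))
    venn <- venn_partition(sets)
  }

  ora <- NULL; ptn <- NULL
  if (!is.null(inp$pathways)) {
    gmt <- read_gmt(inp$pathways)
    if (length(ktp$key_targets)) {
      ora <- run_ora(ktp$key_targets, gmt, alpha = cfg$alpha)
      ptn <- pathway_target_network(ora)
      say("enrichment: ", nrow(ora), " pathways at p < ", cfg$alpha,
          "; pathway-target network: ", n_nodes(ptn$network), " nodes, ",
          n_edges(ptn$network), " edges")
    } else {
      warn("run_pipeline: no key targets; enrichment skipped.")
    }
  }

  dock <- NULL
  if (!is.null(inp$docking)) {
    dock <- docking_analysis(read_docking_table(inp$docking, quiet = quiet))
    say("docking: median ", signif(dock$median, 6), "; ",
        nrow(dock$retained), " of ", dock$n_input, " pairs retained")
  }

  summary <- build_summary(cfg, assoc, disease, net, profile_full, ktp,
                           venn, ora, ptn, dock)
  report <- structure(
    list(config = cfg, summary = summary, network = net,
         profile = profile_full, hub_network = ktp$hub_network,
         hub_profile = ktp$hub_profile, key_targets = ktp$key_targets,
         key_network = ktp$key_network, filter_reports = ktp$reports,
         venn = venn, ora = ora, pathway_target = ptn, docking = dock),
    class = "pipeline_report")
  if (!is.null(cfg$outdir)) write_pipeline_outputs(report, cfg$outdir)
  report
}

build_summary <- function(cfg, assoc, disease, net, profile_full, ktp,
                          venn, ora, ptn, dock) {
  med_full <- attr(profile_full, "medians")
  s <- list(
    n_putative_targets = length(unique(assoc$target_symbol)),
    n_compounds = length(unique(assoc$compound_id)),
    disease_target_counts = if (!is.null(disease)) {
      as.list(attr(disease, "counts"))
    } else NULL,
    network = list(nodes = n_nodes(net), edges = n_edges(net)),
    full_network_medians = as.list(med_full),
    stage_a = list(threshold = unname(ktp$reports$stage_a$thresholds["degree"]),
                   nodes = ktp$reports$stage_a$n_out,
                   edges = ktp$reports$stage_a$m_out),
    stage_b = if (!is.null(ktp$reports$stage_b)) {
      list(medians = as.list(ktp$reports$stage_b$medians),
           key_targets = length(ktp$key_targets))
    } else NULL,
    key_targets = ktp$key_targets,
    key_network = list(nodes = n_nodes(ktp$key_network),
                       edges = n_edges(ktp$key_network)),
    stage_a_multiplier = cfg$stage_a_multiplier,
    alpha = cfg$alpha,
    seed = cfg$seed)
  if (!is.null(venn)) {
    s$venn_regions <- setNames(as.list(venn$count), venn$region)
  }
  if (!is.null(ora)) {
    s$enrichment <- list(significant_pathways = nrow(ora))
  }
  if (!is.null(ptn) && !is.null(ptn$profile)) {
    s$pathway_target_network <- list(
      nodes = n_nodes(ptn$network), edges = n_edges(ptn$network),
      n_pathways = sum(ptn$network$nodes$role == "pathway"),
      n_targets = sum(ptn$network$nodes$role == "protein"),
      medians = as.list(attr(ptn$profile, "medians")))
  }
  if (!is.null(dock)) {
    s$docking <- list(
      n_input = dock$n_input, median = dock$median,
      n_retained = nrow(dock$retained),
      network = list(nodes = n_nodes(dock$network),
                     edges = dock$report$n_edges,
                     n_targets = dock$report$n_targets,
                     n_compounds = dock$report$n_compounds),
      best_pair = if (!is.null(dock$report$best_pair)) {
        as.list(dock$report$best_pair)
      } else NULL)
  }
  s
}

write_pipeline_outputs <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  write_network(report$network, p("network.sif"), "sif")
  write_network(report$network, p("network.graphml"), "graphml")
  write_topology_profile(report$profile, p("topology_full.tsv"))
  write_network(report$hub_network, p("hub_network.sif"), "sif")
  if (!is.null(report$hub_profile)) {
    write_topology_profile(report$hub_profile, p("topology_hub.tsv"))
  }
  writeLines(report$key_targets, p("key_targets.txt"))
  write_network(report$key_network, p("key_network.sif"), "sif")
  write_network(report$key_network, p("key_network.graphml"), "graphml")
  if (!is.null(report$venn)) {
    venn_tbl <- tibble::tibble(
      region = report$venn$region, count = report$venn$count,
      symbols = vapply(report$venn$symbols, paste, "", collapse = ","))
    readr::write_tsv(venn_tbl, p("venn_regions.tsv"), progress = FALSE)
  }
  if (!is.null(report$ora)) write_ora_table(report$ora, p("enrichment.tsv"))
  if (!is.null(report$pathway_target) &&
      n_nodes(report$pathway_target$network) > 0) {
    write_network(report$pathway_target$network,
                  p("pathway_target_network.graphml"), "graphml")
    write_topology_profile(report$pathway_target$profile,
                           p("topology_pathway_target.tsv"))
  }
  if (!is.null(report$docking)) {
    readr::write_tsv(report$docking$retained, p("docking_retained.tsv"),
                     progress = FALSE)
    if (n_nodes(report$docking$network) > 0) {
      write_network(report$docking$network,
                    p("docking_network.graphml"), "graphml")
    }
  }
  jsonlite::write_json(report$summary, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  s <- x$summary
  cat("<pipeline_report>\n")
  cat("  putative targets: ", s$n_putative_targets, " (",
      s$n_compounds, " compounds)\n", sep = "")
  cat("  network: ", s$network$nodes, " nodes / ", s$network$edges,
      " edges\n", sep = "")
  cat("  stage A (degree >= ", s$stage_a$threshold, "): ", s$stage_a$nodes,
      " nodes / ", s$stage_a$edges, " edges\n", sep = "")
  cat("  key targets: ", length(x$key_targets), "\n", sep = "")
  if (!is.null(s$enrichment)) {
    cat("  enriched pathways (p < ", s$alpha, "): ",
        s$enrichment$significant_pathways, "\n", sep = "")
  }
  if (!is.null(s$docking)) {
    cat("  docking: ", s$docking$n_retained, "/", s$docking$n_input,
        " pairs above median ", signif(s$docking$median, 6), "\n", sep = "")
  }
  invisible(x)
}

#' @export
glance.pipeline_report <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    n_putative = s$n_putative_targets,
    network_nodes = s$network$nodes, network_edges = s$network$edges,
    hub_nodes = s$stage_a$nodes, hub_edges = s$stage_a$edges,
    n_key_targets = length(x$key_targets),
    n_enriched_pathways = s$enrichment$significant_pathways %||% NA_integer_,
    docking_retained = s$docking$n_retained %||% NA_integer_)
}
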