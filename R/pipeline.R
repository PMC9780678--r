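#' Run the screening pipeline end-to-end
#'
#' Executes the full in-silico screen from one configuration: library
#' ingestion (or synthetic simulation), the three-stage curation cascade
#' (class exclusion, inorganic/water removal, molecular-weight cut-off),
#' descriptor computation, cumulative rule scoring, top-k selection,
#' multi-tool target-vote aggregation and network export. Identical
#' configuration and seed give byte-identical reports and artifacts.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' sections `seed`, either `simulate` (passed to [library_config()]) or
#' `inputs` (file paths: `compounds`, optional `format`, optional
#' `descriptors`, optional `admet`, optional `predictions` entries with
#' `tool_id`, `path` and `covered_targets`), and optional `filters`
#' (`excluded_classes`, `min_mw`), `scoring` (`ruleset` path, `top_k`),
#' `descriptors` (`hbond_convention`), `targets` (`of_interest`, `top_k`,
#' `min_votes`, `unknown_universe`). Relative paths are resolved against
#' the configuration file's directory. Unknown section names raise a
#' configuration error before anything runs.
#'
#' @param config Path to a YAML configuration file, or a list.
#' @param out_dir Optional output directory; when given, the JSON report,
#'   scorecard CSV, edge-list TSV and GraphML network are written there.
#' @return An object of class `screening_report` (see
#'   [print.screening_report()]): stage reports, the active ruleset, the
#'   ranked top-k table, the consensus vote table, network summary, seed
#'   and version stamps.
#' @export
run_screening <- function(config, out_dir = NULL) {
  base_dir <- "."
  if (is.character(config) && length(config) == 1L) {
    base_dir <- dirname(config)
    config <- yaml::read_yaml(config)
  }
  known <- c("seed", "simulate", "inputs", "filters", "scoring",
             "descriptors", "targets")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop("unknown configuration section(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    stop("configuration needs either a 'simulate' or an 'inputs' section",
         call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  filters <- config$filters
  excluded_classes <- filters$excluded_classes
  if (is.null(excluded_classes)) {
    excluded_classes <- c("triacylglycerol", "diacylglycerol",
                          "phosphatidylethanolamine")
  } else {
    excluded_classes <- unlist(excluded_classes)
  }
  min_mw <- if (is.null(filters$min_mw)) 100 else as.numeric(filters$min_mw)
  top_k <- if (is.null(config$scoring$top_k)) 10 else
    as.integer(config$scoring$top_k)
  ruleset <- if (is.null(config$scoring$ruleset)) default_ruleset() else
    read_ruleset(resolve_path(config$scoring$ruleset, base_dir))
  hbond <- if (is.null(config$descriptors$hbond_convention)) "lipinski" else
    config$descriptors$hbond_convention
  tgt <- config$targets
  targets_of_interest <- if (is.null(tgt$of_interest)) default_targets() else
    unlist(tgt$of_interest)
  target_topk <- if (is.null(tgt$top_k)) 20 else as.integer(tgt$top_k)
  min_votes <- if (is.null(tgt$min_votes)) 1 else as.integer(tgt$min_votes)
  unknown_universe <- if (is.null(tgt$unknown_universe)) "error" else
    tgt$unknown_universe

  written <- character(0)
  on_fail <- function(stage) {
    function(e) {
      unlink(written)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  }

  # --- acquire inputs -------------------------------------------------
  sim <- NULL
  predictions <- NULL
  manifests <- NULL
  tryCatch({
    if (!is.null(config$simulate)) {
      simargs <- config$simulate
      libcfg <- library_config(
        n_compounds = if (is.null(simargs$n_compounds)) 200 else
          as.integer(simargs$n_compounds),
        n_planted = if (is.null(simargs$n_planted)) 10 else
          as.integer(simargs$n_planted),
        seed = seed)
      sim <- generate_library(libcfg, ruleset = ruleset,
                              excluded_classes = excluded_classes)
      compounds <- sim$compounds
      descriptors <- sim$descriptors
      admet <- sim$admet
      actives <- sim$truth$compound_id[sim$truth$is_active]
      true_pairs <- expand.grid(compound_id = actives,
                                target_id = targets_of_interest,
                                KEEP.OUT.ATTRS = FALSE,
                                stringsAsFactors = FALSE)
      psim <- generate_predictions(
        predictor_sim_config(topk = target_topk, seed = seed),
        true_pairs, decoy_targets = character(0))
      predictions <- psim$predictions
      manifests <- psim$manifests
    } else {
      inp <- config$inputs
      compounds <- read_compound_table(
        resolve_path(inp$compounds, base_dir),
        format = if (is.null(inp$format)) "auto" else inp$format)
      descriptors <- if (!is.null(inp$descriptors)) {
        utils::read.csv(resolve_path(inp$descriptors, base_dir),
                        stringsAsFactors = FALSE)
      } else {
        compute_descriptor_table(compounds$smiles, compounds$compound_id,
                                 hbond_convention = hbond)
      }
      admet <- if (!is.null(inp$admet)) {
        load_admet_table(resolve_path(inp$admet, base_dir))
      } else NULL
      if (!is.null(inp$predictions)) {
        recs <- list()
        manifests <- list()
        for (entry in inp$predictions) {
          recs[[length(recs) + 1L]] <- load_predictions(
            resolve_path(entry$path, base_dir), entry$tool_id,
            column_map = entry$column_map)
          manifests[[length(manifests) + 1L]] <- tool_manifest(
            entry$tool_id,
            if (is.null(entry$covered_targets)) NULL else
              unlist(entry$covered_targets))
        }
        predictions <- do.call(rbind, recs)
      }
    }
  }, error = on_fail("input"))

  # --- curation cascade ----------------------------------------------
  stages <- list()
  tryCatch({
    s1 <- filter_by_class(compounds, excluded_classes)
    s2 <- filter_inorganic(s1$records)
    s3 <- filter_by_molecular_weight(s2$records, descriptors,
                                     min_mw = min_mw)
    stages <- list(s1$report, s2$report, s3$report)
    kept <- s3$records
  }, error = on_fail("curation"))

  # --- scoring and selection -----------------------------------------
  tryCatch({
    scorable <- kept$compound_id[vapply(kept$parse_ok, isTRUE, logical(1))]
    scorecards <- evaluate_scorecards(descriptors, admet, ruleset,
                                      compound_ids = scorable)
    top <- rank_and_select(scorecards, k = top_k)
  }, error = on_fail("scoring"))

  # --- target aggregation --------------------------------------------
  votematrix <- NULL
  network <- NULL
  tryCatch({
    if (!is.null(predictions) && nrow(predictions) > 0L) {
      sel <- predictions[predictions$compound_id %in% top$compound_id, ,
                         drop = FALSE]
      sel <- apply_topk(sel, k = target_topk)
      votematrix <- assign_vote_states(
        sel, manifests, targets_of_interest = targets_of_interest,
        compounds = sort(top$compound_id),
        unknown_universe = unknown_universe)
      network <- build_network(votematrix, min_votes = min_votes)
    }
  }, error = on_fail("target_aggregation"))

  # --- report and artifacts ------------------------------------------
  report <- structure(list(
    seed = seed,
    package_version = as.character(utils::packageVersion("foodscreen")),
    stages = lapply(stages, unclass),
    ruleset = as.data.frame(ruleset),
    n_scored = nrow(scorecards),
    top = top[, c("compound_id", "raw_score", "max_possible",
                  "normalized_score", "rank")],
    consensus = if (!is.null(votematrix)) consensus_votes(votematrix) else
      NULL,
    network = if (!is.null(network)) {
      list(n_nodes = igraph::vcount(network),
           n_edges = igraph::ecount(network),
           edge_list_file = "edge_list.tsv",
           graphml_file = "network.graphml")
    } else NULL
  ), class = "screening_report")

  result <- structure(list(report = report, scorecards = scorecards,
                           top = top, votematrix = votematrix,
                           network = network, stages = stages,
                           library = compounds, simulation = sim),
                      class = "screening_result")

  if (!is.null(out_dir)) {
    tryCatch({
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      rp <- file.path(out_dir, "report.json")
      write_report_json(report, rp)
      written <- c(written, rp)
      sp <- file.path(out_dir, "scorecards.csv")
      write_scorecards(scorecards, sp)
      written <- c(written, sp)
      if (!is.null(network)) {
        ep <- file.path(out_dir, "edge_list.tsv")
        gp <- file.path(out_dir, "network.graphml")
        export_network(network, ep, gp)
        written <- c(written, ep, gp)
      }
    }, error = on_fail("export"))
  }
  result
}

resolve_path <- function(path, base_dir) {
  if (is.null(path)) return(NULL)
  if (grepl("^(/|[A-Za-z]:)", path)) path else file.path(base_dir, path)
}

write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = 10, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report> seed", x$seed, "\n")
  for (s in x$stages) {
    cat(sprintf("  %-18s %4d -> %4d\n", s$stage_name, s$n_in, s$n_out))
  }
  cat("  scored:", x$n_scored, "| selected:", nrow(x$top), "\n")
  if (!is.null(x$network)) {
    cat("  network:", x$network$n_nodes, "nodes,",
        x$network$n_edges, "edges\n")
  }
  invisible(x)
}

#' @export
print.screening_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
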