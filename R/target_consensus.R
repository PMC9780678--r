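#' Default protein targets of interest
#'
#' UniProt accessions of the three neurodegeneration targets used for
#' consensus voting: P05067 (amyloid-beta precursor protein, source of the
#' A-beta 1-42 peptide), P22303 (acetylcholinesterase) and P42574
#' (caspase-3).
#'
#' @return Character vector of UniProt accessions.
#' @export
default_targets <- function() c("P05067", "P22303", "P42574")

#' Load a ranked target-prediction hit list for one tool
#'
#' Adapter for the tabular exports of ligand-based target prediction
#' services. Each row is one (compound, target) prediction. When the file
#' carries explicit ranks they are preserved; otherwise ranks are derived
#' per compound from the score column (descending), ties broken by
#' `target_id` so the ordering is deterministic.
#'
#' @param path Path to a CSV/TSV file.
#' @param tool_id Identifier of the predicting tool.
#' @param column_map Optional named list mapping the expected fields
#'   (`compound_id`, `target_id`, `rank`, `score`) to the file's column
#'   names.
#' @return A `data.frame` with columns `tool_id`, `compound_id`,
#'   `target_id`, `rank`, `score`, `in_topk` (`NA` until
#'   [apply_topk()] is called).
#' @export
load_predictions <- function(path, tool_id, column_map = NULL) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  cmap <- as.list(column_map)
  col_of <- function(field) {
    if (!is.null(cmap[[field]])) cmap[[field]] else field
  }
  for (field in c("compound_id", "target_id")) {
    if (!col_of(field) %in% names(tab)) {
      stop("column '", col_of(field), "' (", field, ") missing from ", path,
           call. = FALSE)
    }
  }
  has_rank <- col_of("rank") %in% names(tab)
  has_score <- col_of("score") %in% names(tab)
  if (!has_rank && !has_score) {
    stop("prediction table needs a 'rank' or a 'score' column: ", path,
         call. = FALSE)
  }
  rec <- data.frame(
    tool_id = tool_id,
    compound_id = as.character(tab[[col_of("compound_id")]]),
    target_id = as.character(tab[[col_of("target_id")]]),
    rank = if (has_rank) as.integer(tab[[col_of("rank")]]) else NA_integer_,
    score = if (has_score) as.numeric(tab[[col_of("score")]]) else NA_real_,
    stringsAsFactors = FALSE
  )
  key <- paste(rec$compound_id, rec$target_id)
  if (anyDuplicated(key)) {
    stop("duplicate (compound, target) prediction: ",
         paste(unique(key[duplicated(key)]), collapse = "; "), call. = FALSE)
  }
  if (!has_rank) {
    rec <- rec[order(rec$compound_id, -rec$score, rec$target_id), ,
               drop = FALSE]
    rec$rank <- stats::ave(seq_len(nrow(rec)), rec$compound_id,
                           FUN = seq_along)
  }
  rec$in_topk <- NA
  rownames(rec) <- NULL
  rec
}

#' Flag predictions inside the per-tool retention window
#'
#' Marks each prediction as inside (`in_topk = TRUE`) or beyond the first
#' `k` hits of its tool's ranked list. No record is dropped: hits beyond
#' the window must stay distinguishable from targets the tool never
#' returned.
#'
#' @param records Prediction records from [load_predictions()].
#' @param k Retention cut-off (default 20, a deliberately loose threshold
#'   for a rough first-pass prediction).
#' @return The records with `in_topk` filled.
#' @export
apply_topk <- function(records, k = 20) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive count", call. = FALSE)
  }
  if (any(is.na(records$rank))) {
    stop("ranks must be assigned before apply_topk()", call. = FALSE)
  }
  records$in_topk <- records$rank <= k
  records
}

#' Declare which targets a prediction tool covers
#'
#' @param tool_id Tool identifier.
#' @param covered_targets Character vector of UniProt accessions the tool
#'   can in principle return, or `NULL` when the tool's target universe is
#'   unknown.
#' @return A list of class `tool_manifest`.
#' @export
tool_manifest <- function(tool_id, covered_targets = NULL) {
  structure(list(tool_id = tool_id,
                 covered_targets = if (is.null(covered_targets)) NULL else
                   as.character(covered_targets)),
            class = "tool_manifest")
}

#' Assign the four per-tool vote states
#'
#' For every (compound, target, tool) triple the state is one of: `hit`
#' (the tool returned the target within the retention window),
#' `hit_beyond_topk` (returned, but outside the window), `no_hit` (the
#' tool covers the target but did not return it) and `not_covered` (the
#' target is outside the tool's universe). The consensus vote for a
#' (compound, target) pair is the number of tools in state `hit`.
#'
#' Tools with an unknown target universe cannot distinguish `no_hit` from
#' `not_covered` for absent targets; by default that raises an error, and
#' `unknown_universe` selects an explicit fallback instead.
#'
#' @param records Prediction records after [apply_topk()].
#' @param manifests List of [tool_manifest()] objects, one per tool in
#'   `records`.
#' @param targets_of_interest Targets to vote on; default
#'   [default_targets()].
#' @param compounds Compounds to vote on; defaults to all compounds in
#'   `records`.
#' @param unknown_universe What to do for an absent target of a tool whose
#'   universe is unknown: `"error"` (default), `"not_covered"`, `"no_hit"`.
#' @return A list of class `vote_matrix`: `states` (long data frame of
#'   per-tool states), `consensus` (per-pair vote counts), `tools`,
#'   `targets`, `compounds`.
#' @export
assign_vote_states <- function(records, manifests,
                               targets_of_interest = default_targets(),
                               compounds = NULL,
                               unknown_universe = c("error", "not_covered",
                                                    "no_hit")) {
  unknown_universe <- match.arg(unknown_universe)
  if (any(is.na(records$in_topk))) {
    stop("run apply_topk() before assigning vote states", call. = FALSE)
  }
  if (inherits(manifests, "tool_manifest")) manifests <- list(manifests)
  man_ids <- vapply(manifests, `[[`, character(1), "tool_id")
  names(manifests) <- man_ids
  tools <- sort(unique(c(records$tool_id, man_ids)))
  missing_man <- setdiff(unique(records$tool_id), man_ids)
  if (length(missing_man)) {
    stop("no manifest for tool(s): ", paste(missing_man, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(compounds)) compounds <- sort(unique(records$compound_id))

  grid <- expand.grid(compound_id = compounds,
                      target_id = targets_of_interest,
                      tool_id = tools,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rec_key <- paste(records$compound_id, records$target_id, records$tool_id)
  idx <- match(paste(grid$compound_id, grid$target_id, grid$tool_id), rec_key)

  grid$state <- vapply(seq_len(nrow(grid)), function(i) {
    man <- manifests[[grid$tool_id[i]]]
    covered <- if (is.null(man$covered_targets)) NA else
      grid$target_id[i] %in% man$covered_targets
    if (isFALSE(covered)) return("not_covered")
    j <- idx[i]
    if (!is.na(j)) {
      return(if (records$in_topk[j]) "hit" else "hit_beyond_topk")
    }
    if (is.na(covered)) {
      if (unknown_universe == "error") {
        stop("tool '", grid$tool_id[i], "' has an unknown target universe; ",
             "cannot distinguish no_hit from not_covered for target ",
             grid$target_id[i],
             " (set unknown_universe to override)", call. = FALSE)
      }
      return(unknown_universe)
    }
    "no_hit"
  }, character(1))

  agg <- stats::aggregate(state ~ compound_id + target_id, data = grid,
                          FUN = function(s) sum(s == "hit"))
  names(agg)[names(agg) == "state"] <- "votes"
  agg <- agg[order(agg$compound_id, agg$target_id), , drop = FALSE]
  rownames(agg) <- NULL

  structure(list(states = grid, consensus = agg, tools = tools,
                 targets = targets_of_interest, compounds = compounds),
            class = "vote_matrix")
}

#' @export
print.vote_matrix <- function(x, ...) {
  cat(sprintf("<vote_matrix> %d compounds x %d targets x %d tools\n",
              length(x$compounds), length(x$targets), length(x$tools)))
  print(utils::head(x$consensus, 10))
  invisible(x)
}

#' Consensus vote counts
#'
#' @param votematrix A `vote_matrix` from [assign_vote_states()].
#' @return Data frame `compound_id`, `target_id`, `votes`.
#' @export
consensus_votes <- function(votematrix) votematrix$consensus

#' Build the compound-target interaction network
#'
#' Bipartite graph with compound and target nodes; an edge is drawn for
#' every (compound, target) pair reaching at least `min_votes` consensus
#' votes, weighted by the vote count and annotated with the per-tool
#' states.
#'
#' @param votematrix A `vote_matrix`.
#' @param min_votes Minimum consensus votes for an edge (default 1).
#' @return An [igraph::graph] with vertex attribute `type` (`FALSE` =
#'   compound, `TRUE` = target) and edge attributes `votes` and
#'   `tool_states`.
#' @export
build_network <- function(votematrix, min_votes = 1) {
  cons <- votematrix$consensus
  edges <- cons[cons$votes >= min_votes, , drop = FALSE]
  st <- votematrix$states
  edges$tool_states <- vapply(seq_len(nrow(edges)), function(i) {
    sel <- st$compound_id == edges$compound_id[i] &
      st$target_id == edges$target_id[i]
    sub <- st[sel, , drop = FALSE]
    sub <- sub[order(sub$tool_id), , drop = FALSE]
    paste(paste0(sub$tool_id, "=", sub$state), collapse = ";")
  }, character(1))

  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(votematrix$compounds),
                            name = votematrix$compounds, type = FALSE,
                            kind = "compound")
  g <- igraph::add_vertices(g, length(votematrix$targets),
                            name = votematrix$targets, type = TRUE,
                            kind = "target")
  if (nrow(edges)) {
    pairs <- rbind(edges$compound_id, edges$target_id)
    g <- igraph::add_edges(g, as.vector(pairs), votes = edges$votes,
                           tool_states = edges$tool_states)
  }
  g
}

#' Export the interaction network
#'
#' Writes a deterministic edge-list TSV (`compound_id`, `target_id`,
#' `votes`, `tool_states`, sorted by compound then target) and optionally
#' a GraphML file.
#'
#' @param network An igraph object from [build_network()].
#' @param edge_list_path Path for the TSV edge list.
#' @param graphml_path Optional path for a GraphML export.
#' @return Invisibly, the edge-list data frame.
#' @export
export_network <- function(network, edge_list_path, graphml_path = NULL) {
  if (igraph::ecount(network) > 0) {
    ends <- igraph::as_edgelist(network)
    df <- data.frame(compound_id = ends[, 1L], target_id = ends[, 2L],
                     votes = igraph::E(network)$votes,
                     tool_states = igraph::E(network)$tool_states,
                     stringsAsFactors = FALSE)
    df <- df[order(df$compound_id, df$target_id), , drop = FALSE]
  } else {
    df <- data.frame(compound_id = character(0), target_id = character(0),
                     votes = integer(0), tool_states = character(0))
  }
  utils::write.table(df, edge_list_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (!is.null(graphml_path)) {
    igraph::write_graph(network, graphml_path, format = "graphml")
  }
  invisible(df)
}
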