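#' ADMET endpoint vocabulary
#'
#' The eight toxicity endpoints consumed by the default scoring rules:
#' hERG potassium-channel blockade, human hepatotoxicity (H-HT), Ames
#' bacterial mutagenicity, rat oral acute toxicity (ROA), carcinogenicity,
#' respiratory toxicity, and the non-genotoxic / genotoxic carcinogenicity
#' calls. Values are probabilities of a positive (toxic) prediction.
#'
#' @return Character vector of endpoint names.
#' @export
admet_endpoints <- function() {
  c("hERG", "H-HT", "Ames", "ROA", "Carcinogenicity", "Respiratory",
    "Non-Genotoxic_Carcinogenicity", "Genotoxic_Carcinogenicity_Mutagenicity")
}

#' Load an ADMET endpoint prediction table
#'
#' Adapter for ADMETlab-style exports: a CSV/TSV with one row per compound
#' and one column per endpoint, each value the predicted probability of a
#' positive (toxic) outcome in \[0, 1\]. Endpoints absent from the file are
#' marked unavailable (`NA`) in the returned profiles, and the
#' corresponding rules become not-evaluable at scoring time.
#'
#' @param path Path to the table. Separator inferred from the extension
#'   (`.tsv` = tab, otherwise comma).
#' @param column_map Optional named list/vector mapping endpoint names (and
#'   optionally `compound_id`) to the column names used in the file.
#'   Endpoint names must come from [admet_endpoints()].
#' @return A data frame of class `admet_profiles`: `compound_id` plus one
#'   numeric column per endpoint (`NA` = unavailable).
#' @export
load_admet_table <- function(path, column_map = NULL) {
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  tab <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(tab) == 0L) stop("empty ADMET table: ", path, call. = FALSE)

  cmap <- as.list(column_map)
  unknown <- setdiff(names(cmap), c(admet_endpoints(), "compound_id"))
  if (length(unknown)) {
    stop("unknown endpoint name(s) in column_map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  id_col <- if (!is.null(cmap$compound_id)) cmap$compound_id else "compound_id"
  if (!id_col %in% names(tab)) {
    stop("compound id column '", id_col, "' missing from ", path,
         call. = FALSE)
  }
  ids <- as.character(tab[[id_col]])
  if (anyDuplicated(ids)) {
    stop("duplicate compound_id in ADMET table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  out <- data.frame(compound_id = ids, stringsAsFactors = FALSE)
  for (ep in admet_endpoints()) {
    col <- if (!is.null(cmap[[ep]])) cmap[[ep]] else ep
    if (col %in% names(tab)) {
      v <- suppressWarnings(as.numeric(tab[[col]]))
      bad <- which(!is.na(v) & (v < 0 | v > 1))
      if (length(bad)) {
        stop("probability outside [0,1] for endpoint '", ep, "' at row(s) ",
             paste(bad, collapse = ", "), " of ", path, call. = FALSE)
      }
      out[[ep]] <- v
    } else {
      out[[ep]] <- NA_real_
    }
  }
  class(out) <- c("admet_profiles", "data.frame")
  out
}

#' Default drug-likeness and toxicity ruleset
#'
#' A reconstructed cumulative-score ruleset covering the seven
#' physicochemical descriptors and the eight toxicity endpoints, all with
#' unit weights: molecular size restricted to 100-600 Da, hydrogen-bond
#' acceptors at most 12, donors at most 7, rotatable bonds at most 11, at
#' least one ring, net formal charge within one elementary charge, logP
#' between 0 and 5, and every toxicity endpoint predicted negative
#' (probability below 0.5). Every threshold is overridable via a ruleset
#' file; [run_screening()] echoes the active ruleset in its report.
#'
#' @return A `data.frame` of class `ruleset` with columns `rule_id`,
#'   `property`, `comparator`, `threshold`, `threshold_high`, `weight`.
#' @seealso [read_ruleset()], [evaluate_rules()]
#' @export
default_ruleset <- function() {
  desc <- data.frame(
    rule_id = c("mw_range", "nha_max", "nhd_max", "nrot_max", "nring_min",
                "fchar_range", "logp_range"),
    property = c("mw", "n_ha", "n_hd", "n_rot", "n_ring", "f_char", "logp"),
    comparator = c("between", "le", "le", "le", "ge", "between", "between"),
    threshold = c(100, 12, 7, 11, 1, -1, 0),
    threshold_high = c(600, NA, NA, NA, NA, 1, 5),
    stringsAsFactors = FALSE
  )
  tox <- data.frame(
    rule_id = paste0("tox_", gsub("[^A-Za-z]+", "_", admet_endpoints())),
    property = admet_endpoints(),
    comparator = "lt",
    threshold = 0.5,
    threshold_high = NA_real_,
    stringsAsFactors = FALSE
  )
  rs <- rbind(desc, tox)
  rs$weight <- 1
  validate_ruleset(rs)
}

validate_ruleset <- function(rs) {
  needed <- c("rule_id", "property", "comparator", "threshold")
  for (col in setdiff(needed, names(rs))) {
    stop("ruleset lacks column '", col, "'", call. = FALSE)
  }
  if (!"threshold_high" %in% names(rs)) rs$threshold_high <- NA_real_
  if (!"weight" %in% names(rs)) rs$weight <- 1
  rs$weight[is.na(rs$weight)] <- 1
  ok_cmp <- c("lt", "le", "gt", "ge", "between", "category_equals")
  bad <- setdiff(rs$comparator, ok_cmp)
  if (length(bad)) {
    stop("unknown comparator(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  btw <- rs$comparator == "between"
  if (any(btw & (is.na(rs$threshold_high) |
                 rs$threshold > rs$threshold_high))) {
    stop("'between' rules require threshold <= threshold_high",
         call. = FALSE)
  }
  if (any(rs$weight < 0)) stop("rule weights must be non-negative",
                               call. = FALSE)
  if (anyDuplicated(rs$rule_id)) stop("duplicate rule_id", call. = FALSE)
  rownames(rs) <- NULL
  class(rs) <- c("ruleset", "data.frame")
  rs
}

#' Read / write a ruleset file
#'
#' Rulesets are stored as YAML: a list of blocks with fields `rule_id`,
#' `property`, `comparator` (`lt`, `le`, `gt`, `ge`, `between`,
#' `category_equals`), `threshold`, optional `threshold_high` and `weight`
#' (default 1).
#'
#' @param path Path to a YAML ruleset file.
#' @return `read_ruleset()`: a validated `ruleset` data frame.
#' @export
read_ruleset <- function(path) {
  raw <- yaml::read_yaml(path)
  rows <- lapply(raw, function(r) {
    data.frame(
      rule_id = r$rule_id, property = r$property, comparator = r$comparator,
      threshold = if (is.null(r$threshold)) NA_real_ else
        suppressWarnings(as.numeric(r$threshold)),
      threshold_high = if (is.null(r$threshold_high)) NA_real_ else
        as.numeric(r$threshold_high),
      weight = if (is.null(r$weight)) 1 else as.numeric(r$weight),
      category = if (is.null(r$category)) NA_character_ else
        as.character(r$category),
      stringsAsFactors = FALSE
    )
  })
  validate_ruleset(do.call(rbind, rows))
}

#' @param ruleset A `ruleset` data frame.
#' @rdname read_ruleset
#' @export
write_ruleset <- function(ruleset, path) {
  blocks <- lapply(seq_len(nrow(ruleset)), function(i) {
    r <- as.list(ruleset[i, ])
    r <- r[!vapply(r, function(x) is.na(x) || is.null(x), logical(1))]
    r
  })
  yaml::write_yaml(blocks, path)
  invisible(path)
}

eval_one_rule <- function(value, comparator, lo, hi, category = NA) {
  if (is.null(value) || (length(value) == 1L && is.na(value))) {
    return("not_evaluable")
  }
  pass <- switch(comparator,
                 lt = value < lo,
                 le = value <= lo,
                 gt = value > lo,
                 ge = value >= lo,
                 between = value >= lo & value <= hi,
                 category_equals = as.character(value) == as.character(category))
  if (isTRUE(pass)) "pass" else "fail"
}

#' Evaluate a scoring ruleset for one compound
#'
#' Each rule is evaluated against the compound's descriptors or ADMET
#' endpoint profile. Rules whose property is unavailable (e.g. a missing
#' endpoint column) score `not_evaluable` and are removed from the
#' attainable maximum, so the normalized score stays comparable across
#' coverage gaps. The cumulative (raw) score is the weight sum over passed
#' rules.
#'
#' @param descriptors One-row data frame (or named list) of descriptor
#'   values for the compound; may be `NULL`.
#' @param profile One-row slice of an `admet_profiles` table for the
#'   compound; may be `NULL` (all endpoints unavailable).
#' @param ruleset A `ruleset` data frame; see [default_ruleset()].
#' @return A list of class `scorecard`: `outcomes` (named character
#'   vector per rule), `raw_score`, `max_possible`, `normalized_score`.
#' @export
evaluate_rules <- function(descriptors, profile, ruleset) {
  ruleset <- validate_ruleset(as.data.frame(ruleset))
  if (nrow(ruleset) == 0L) stop("empty ruleset", call. = FALSE)
  known <- c(descriptor_names(), admet_endpoints())
  bad <- setdiff(ruleset$property, known)
  if (length(bad)) {
    stop("rule(s) reference unknown property: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  get_value <- function(prop) {
    src <- if (prop %in% descriptor_names()) descriptors else profile
    if (is.null(src) || !prop %in% names(src)) return(NA)
    src[[prop]][1L]
  }
  outcomes <- vapply(seq_len(nrow(ruleset)), function(i) {
    eval_one_rule(get_value(ruleset$property[i]), ruleset$comparator[i],
                  ruleset$threshold[i], ruleset$threshold_high[i],
                  if ("category" %in% names(ruleset))
                    ruleset$category[i] else NA)
  }, character(1))
  names(outcomes) <- ruleset$rule_id
  evaluable <- outcomes != "not_evaluable"
  raw <- sum(ruleset$weight[outcomes == "pass"])
  maxp <- sum(ruleset$weight[evaluable])
  structure(list(outcomes = outcomes,
                 raw_score = raw,
                 max_possible = maxp,
                 normalized_score = if (maxp > 0) raw / maxp else 0),
            class = "scorecard")
}

#' Score every compound in a library
#'
#' Vectorised wrapper around [evaluate_rules()]: joins descriptor and
#' ADMET tables by `compound_id` and returns one scorecard row per
#' compound, with one outcome column per rule.
#'
#' @param descriptors Data frame from [compute_descriptor_table()] (or the
#'   synthetic generator).
#' @param profiles An `admet_profiles` data frame, or `NULL`.
#' @param ruleset A `ruleset` data frame.
#' @param compound_ids Compounds to score; defaults to the ids present in
#'   `descriptors`.
#' @return A `data.frame` with `compound_id`, `outcome_<rule_id>` columns,
#'   `raw_score`, `max_possible`, `normalized_score`.
#' @export
evaluate_scorecards <- function(descriptors, profiles, ruleset,
                                compound_ids = NULL) {
  if (is.null(compound_ids)) compound_ids <- descriptors$compound_id
  rows <- lapply(compound_ids, function(cid) {
    d <- descriptors[descriptors$compound_id == cid, , drop = FALSE]
    p <- if (!is.null(profiles))
      profiles[profiles$compound_id == cid, , drop = FALSE] else NULL
    if (!is.null(p) && nrow(p) == 0L) p <- NULL
    sc <- evaluate_rules(if (nrow(d)) d else NULL, p, ruleset)
    out <- data.frame(compound_id = cid, stringsAsFactors = FALSE)
    for (rid in names(sc$outcomes)) {
      out[[paste0("outcome_", rid)]] <- sc$outcomes[[rid]]
    }
    out$raw_score <- sc$raw_score
    out$max_possible <- sc$max_possible
    out$normalized_score <- sc$normalized_score
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Rank scorecards and select the top k ingredients
#'
#' Sorts by raw cumulative score (descending), then normalized score
#' (descending), then `compound_id` (ascending) for a deterministic,
#' bit-reproducible ordering, and returns the first `k` rows with a
#' 1-based `rank` column. A tie across the selection boundary is reported
#' via `message()`.
#'
#' @param scorecards Data frame from [evaluate_scorecards()].
#' @param k Number of compounds to select (default 10).
#' @return The top `min(k, n)` rows, ranked.
#' @export
rank_and_select <- function(scorecards, k = 10) {
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop("k must be a positive count", call. = FALSE)
  }
  if (nrow(scorecards) == 0L) stop("no scorecards to rank", call. = FALSE)
  ord <- order(-scorecards$raw_score, -scorecards$normalized_score,
               scorecards$compound_id)
  ranked <- scorecards[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  k <- min(k, nrow(ranked))
  if (k < nrow(ranked) &&
      ranked$raw_score[k] == ranked$raw_score[k + 1L] &&
      ranked$normalized_score[k] == ranked$normalized_score[k + 1L]) {
    message("tie at the selection boundary (rank ", k, "): broken by ",
            "compound_id order")
  }
  out <- ranked[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write scorecards to CSV
#'
#' @param scorecards Data frame from [evaluate_scorecards()] or
#'   [rank_and_select()].
#' @param path Output CSV path.
#' @export
write_scorecards <- function(scorecards, path) {
  utils::write.csv(scorecards, path, row.names = FALSE)
  invisible(path)
}
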