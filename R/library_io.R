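#' Chemical-class vocabulary for library curation
#'
#' Controlled vocabulary of class tags used by the curation filters. The
#' lipid classes (triacylglycerol, diacylglycerol,
#' phosphatidylethanolamine, glycerolipid, fatty_acid) are the typical
#' first-stage exclusions for a food-constituent export; `inorganic`
#' marks entries removed by [filter_inorganic()] regardless of structure.
#'
#' @return Character vector of known class tags.
#' @export
compound_classes <- function() {
  c("triacylglycerol", "diacylglycerol", "phosphatidylethanolamine",
    "glycerolipid", "fatty_acid", "inorganic", "flavonoid", "anthocyanin",
    "phenolic", "small_molecule", "other")
}

new_compound_library <- function(df) {
  needed <- c("compound_id", "name", "smiles", "compound_class", "source",
              "parse_ok")
  for (col in setdiff(needed, names(df))) {
    df[[col]] <- if (col == "parse_ok") NA else NA_character_
  }
  df <- df[, needed]
  df$compound_id <- as.character(df$compound_id)
  if (anyDuplicated(df$compound_id)) {
    dup <- unique(df$compound_id[duplicated(df$compound_id)])
    stop("duplicate compound_id: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("compound_library", "data.frame")
  df
}

#' Read a compound library table
#'
#' Ingests a compound library from CSV (columns `compound_id`, `name`,
#' `smiles`, optional `compound_class` and `source`), an SDF file, or a
#' plain SMILES file (one structure per line, optional tab-separated
#' identifier). Every row/molecule block becomes a record; structures that
#' fail to parse are kept with `parse_ok = FALSE` rather than dropped, so
#' curation counts remain auditable. Input order is preserved.
#'
#' @param path Path to the input file.
#' @param format One of `"auto"` (by file extension), `"csv"`, `"sdf"`,
#'   `"smiles"`.
#' @return A `compound_library` data frame with columns `compound_id`,
#'   `name`, `smiles`, `compound_class`, `source`, `parse_ok`.
#' @export
read_compound_table <- function(path,
                                format = c("auto", "csv", "sdf", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
                     csv = "csv",
                     sdf = "sdf",
                     smi = "smiles", smiles = "smiles", txt = "smiles",
                     stop("cannot infer format from extension '", ext,
                          "'; pass format explicitly", call. = FALSE))
  }
  switch(format,
         csv = read_compound_csv(path),
         sdf = read_compound_sdf(path),
         smiles = read_compound_smiles(path))
}

read_compound_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(tab) == 0L) stop("empty compound table: ", path, call. = FALSE)
  for (col in c("compound_id", "name", "smiles")) {
    if (!col %in% names(tab)) {
      stop("required column '", col, "' missing from ", path, call. = FALSE)
    }
  }
  tab$parse_ok <- is_valid_smiles(tab$smiles)
  new_compound_library(tab)
}

read_compound_sdf <- function(path) {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  if (length(sdfset) == 0L) stop("empty SDF file: ", path, call. = FALSE)
  valid <- suppressWarnings(ChemmineR::validSDF(sdfset))
  id_tags <- c("compound_id", "COMPOUND_ID", "ID", "id", "DATABASE_ID")
  rows <- lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    db <- ChemmineR::datablock(sdf)
    pick <- function(tags, default) {
      hit <- tags[tags %in% names(db)]
      if (length(hit)) db[[hit[1L]]] else default
    }
    cid <- pick(id_tags, sprintf("CMPD_%04d", i))
    nm <- pick(c("name", "NAME"), ChemmineR::sdfid(sdf))
    smi <- if (valid[i]) {
      out <- tryCatch(
        as.character(suppressWarnings(ChemmineR::sdf2smiles(sdfset[i]))),
        error = function(e) NA_character_)
      if (length(out) == 0L || !nzchar(out)) NA_character_ else out
    } else NA_character_
    data.frame(compound_id = cid, name = nm, smiles = smi,
               compound_class = pick(c("compound_class", "CLASS"),
                                     NA_character_),
               source = pick(c("source", "SOURCE"), NA_character_),
               parse_ok = valid[i] && !is.na(smi),
               stringsAsFactors = FALSE)
  })
  new_compound_library(do.call(rbind, rows))
}

read_compound_smiles <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty SMILES file: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  smi <- vapply(parts, `[[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2L) parts[[i]][[2L]] else
      sprintf("CMPD_%04d", i)
  }, character(1))
  new_compound_library(data.frame(
    compound_id = ids, name = ids, smiles = smi,
    parse_ok = is_valid_smiles(smi), stringsAsFactors = FALSE))
}

#' Write a compound library to CSV
#'
#' Round-trip companion to [read_compound_table()]: the written file reads
#' back to identical records.
#'
#' @param records A `compound_library` data frame.
#' @param path Output CSV path.
#' @export
write_compound_table <- function(records, path) {
  out <- records[, c("compound_id", "name", "smiles", "compound_class",
                     "source")]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Per-stage curation report
#'
#' Records how many compounds entered and left a filter stage and which
#' identifiers were removed. Stage reports chain: the `n_out` of one stage
#' is the `n_in` of the next.
#'
#' @param stage_name Label of the filter stage.
#' @param n_in,n_out Input/output record counts.
#' @param removed_ids Identifiers removed at this stage.
#' @return An object of class `filter_stage_report`.
#' @export
filter_stage_report <- function(stage_name, n_in, n_out, removed_ids) {
  stopifnot(n_out == n_in - length(removed_ids))
  structure(list(stage_name = stage_name, n_in = as.integer(n_in),
                 n_out = as.integer(n_out),
                 removed_ids = as.character(removed_ids)),
            class = "filter_stage_report")
}

#' @export
print.filter_stage_report <- function(x, ...) {
  cat(sprintf("<filter stage '%s'> %d -> %d (removed %d)\n",
              x$stage_name, x$n_in, x$n_out, length(x$removed_ids)))
  invisible(x)
}

#' @export
format.filter_stage_report <- function(x, ...) {
  sprintf("%s: %d -> %d", x$stage_name, x$n_in, x$n_out)
}

#' Remove compounds by chemical class
#'
#' First curation stage: drops records whose `compound_class` tag is in
#' `excluded_tags` (typically the glycerolipid classes of a food export).
#' Tags not in the controlled vocabulary are ignored with a warning.
#'
#' @param records A `compound_library` data frame.
#' @param excluded_tags Character vector of class tags to remove.
#' @param vocabulary Known tags; defaults to [compound_classes()].
#' @return A list with elements `records` (kept rows) and `report`
#'   (a [filter_stage_report()]).
#' @export
filter_by_class <- function(records, excluded_tags,
                            vocabulary = compound_classes()) {
  unknown <- setdiff(excluded_tags, vocabulary)
  if (length(unknown)) {
    warning("ignoring unknown class tag(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
    excluded_tags <- setdiff(excluded_tags, unknown)
  }
  drop <- !is.na(records$compound_class) &
    records$compound_class %in% excluded_tags
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept,
       report = filter_stage_report("class", nrow(records), nrow(kept),
                                    records$compound_id[drop]))
}

#' Remove water and inorganic entries
#'
#' Second curation stage: drops records tagged `inorganic` as well as
#' parsed structures containing no carbon atom (water, simple salts,
#' mineral entries). Records whose structure failed to parse pass through
#' untouched; they stay flagged via `parse_ok`.
#'
#' @param records A `compound_library` data frame.
#' @return A list with elements `records` and `report`.
#' @export
filter_inorganic <- function(records) {
  drop <- vapply(seq_len(nrow(records)), function(i) {
    if (!is.na(records$compound_class[i]) &&
        records$compound_class[i] == "inorganic") return(TRUE)
    if (!isTRUE(records$parse_ok[i])) return(FALSE)
    p <- ob_props(records$smiles[i])
    if (is.null(p)) return(FALSE)
    !contains_carbon(p$formula)
  }, logical(1))
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept,
       report = filter_stage_report("inorganic", nrow(records), nrow(kept),
                                    records$compound_id[drop]))
}

#' Remove very small molecules by molecular weight
#'
#' Third curation stage: compounds with very small molecular weights tend
#' to bind without specificity, so records with `mw < min_mw` are removed
#' (a compound at exactly the cut-off is retained). Unparsed records are
#' carried through unchanged; every parsed record must have a descriptor
#' entry.
#'
#' @param records A `compound_library` data frame.
#' @param descriptors A data frame with `compound_id` and `mw` columns
#'   (e.g. from [compute_descriptor_table()]).
#' @param min_mw Molecular-weight cut-off in Da (default 100).
#' @return A list with elements `records` and `report`.
#' @export
filter_by_molecular_weight <- function(records, descriptors, min_mw = 100) {
  mw <- descriptors$mw[match(records$compound_id, descriptors$compound_id)]
  needs_mw <- vapply(records$parse_ok, isTRUE, logical(1))
  missing <- needs_mw & is.na(mw)
  if (any(missing)) {
    stop("no molecular weight available for compound(s): ",
         paste(records$compound_id[missing], collapse = ", "),
         call. = FALSE)
  }
  drop <- needs_mw & !is.na(mw) & mw < min_mw
  kept <- records[!drop, , drop = FALSE]
  rownames(kept) <- NULL
  list(records = kept,
       report = filter_stage_report("molecular_weight", nrow(records),
                                    nrow(kept), records$compound_id[drop]))
}
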