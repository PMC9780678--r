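#' Physicochemical descriptors for drug-likeness filtering
#'
#' The screening cascade filters compounds on seven physicochemical
#' properties: average molecular weight (`mw`, Da), number of hydrogen-bond
#' acceptors (`n_ha`), number of hydrogen-bond donors (`n_hd`), number of
#' rotatable bonds (`n_rot`), number of rings (`n_ring`, smallest set of
#' smallest rings), net formal charge (`f_char`, elementary charges) and an
#' estimated octanol-water partition coefficient (`logp`, Wildman-Crippen
#' atom-contribution scheme).
#'
#' Conventions:
#' * acceptors: count of nitrogen plus oxygen atoms (Lipinski-style);
#' * donors: count of nitrogen/oxygen atoms bearing at least one hydrogen;
#' * rotatable bond: non-ring single bond between two non-terminal heavy
#'   atoms, amide C-N bonds excluded;
#' * ring count: cyclomatic number of the molecular graph (equals the size
#'   of the smallest set of smallest rings);
#' * molecular weight uses average (not monoisotopic) atomic masses.
#'
#' An alternative surface-chemistry hydrogen-bond convention (the Open Babel
#' SMARTS definitions, which e.g. do not count a charged pyrylium oxygen as
#' an acceptor) is available with `hbond_convention = "openbabel"`.
#'
#' @param smiles A single SMILES string. Must be single-fragment; strip
#'   counter-ions first with [strip_counterions()].
#' @param hbond_convention Either `"lipinski"` (default, atom counts as
#'   above) or `"openbabel"` (SMARTS-based donor/acceptor definitions).
#' @return A one-row `data.frame` with columns `mw`, `n_ha`, `n_hd`,
#'   `n_rot`, `n_ring`, `f_char`, `logp`.
#' @examples
#' compute_descriptors("CCO")          # ethanol
#' compute_descriptors("c1ccccc1")     # benzene
#' @seealso [compute_descriptor_table()] for batch computation,
#'   [strip_counterions()] for salt handling.
#' @export
compute_descriptors <- function(smiles,
                                hbond_convention = c("lipinski", "openbabel")) {
  hbond_convention <- match.arg(hbond_convention)
  stopifnot(is.character(smiles), length(smiles) == 1L)
  p <- ob_props(smiles)
  if (is.null(p)) {
    stop("cannot parse structure: '", smiles, "'", call. = FALSE)
  }
  ec <- elem_counts(p$formula)

  molfile <- explicit_h_molfile(smiles)
  parsed <- parse_explicit_h_molfile(molfile)

  if (hbond_convention == "lipinski") {
    n_ha <- sum(ec[intersect(c("N", "O"), names(ec))])
    n_hd <- parsed$n_donor_atoms
  } else {
    n_ha <- as.integer(p$HBA2)
    n_hd <- as.integer(p$HBD)
  }

  data.frame(
    mw = p$MW,
    n_ha = as.integer(n_ha),
    n_hd = as.integer(n_hd),
    n_rot = count_rotatable_bonds(smiles),
    n_ring = parsed$n_ring,
    f_char = molfile_formal_charge(molfile),
    logp = p$logP
  )
}

# SMARTS main pattern: non-ring single bond between two non-terminal atoms;
# amide C-N bonds subtracted.
ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]"
AMIDE_SMARTS <- "[CX3](=[OX1])-!@[NX3&!D1]"

count_rotatable_bonds <- function(smiles) {
  smarts_count(smiles, ROTATABLE_SMARTS) - smarts_count(smiles, AMIDE_SMARTS)
}

# Ring count, donor-atom count and atom/bond totals from an explicit-H
# molfile. Works down to single-atom species (bare monoatomic ions), where
# the bond block is empty.
parse_explicit_h_molfile <- function(molfile_text) {
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf), add = TRUE)
  writeLines(molfile_text, tf)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tf))
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  els <- gsub("_.*$", "", rownames(ab))
  n_atoms <- nrow(ab)
  n_bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) 0L else nrow(bb)

  donors <- integer(0)
  if (n_bonds > 0L) {
    for (i in seq_len(n_bonds)) {
      a <- bb[i, 1L]
      b <- bb[i, 2L]
      if (els[a] %in% c("N", "O") && els[b] == "H") donors <- union(donors, a)
      if (els[b] %in% c("N", "O") && els[a] == "H") donors <- union(donors, b)
    }
  }
  list(
    n_ring = max(0L, n_bonds - n_atoms + 1L),
    n_donor_atoms = length(donors)
  )
}

#' Strip counter-ions from a multi-fragment structure
#'
#' Keeps the fragment with the most heavy atoms; ties are broken by larger
#' molecular weight, then by lexicographically smaller canonical SMILES.
#' Single-fragment inputs are returned unchanged. Anthocyanin chloride
#' salts, for example, reduce to the flavylium cation.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of single-fragment SMILES (input spelling of
#'   the kept fragment, not canonicalised).
#' @examples
#' strip_counterions("[Cl-].CCO")
#' @export
strip_counterions <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) stop("cannot parse structure: NA", call. = FALSE)
    frags <- strsplit(s, ".", fixed = TRUE)[[1L]]
    if (length(frags) == 1L) {
      if (is.null(ob_props(s))) {
        stop("cannot parse structure: '", s, "'", call. = FALSE)
      }
      return(s)
    }
    info <- lapply(frags, ob_props)
    if (any(vapply(info, is.null, logical(1)))) {
      stop("cannot parse structure: '", s, "'", call. = FALSE)
    }
    heavy <- vapply(info, function(p) heavy_atom_count(p$formula), numeric(1))
    mw <- vapply(info, function(p) p$MW, numeric(1))
    can <- vapply(info, function(p) p$cansmi, character(1))
    frags[order(-heavy, -mw, can)[1L]]
  }, character(1), USE.NAMES = FALSE)
}

#' Compute descriptors for a set of compounds
#'
#' Batch wrapper around [compute_descriptors()]. Counter-ions are stripped
#' first (largest-fragment rule), so salts are profiled on their parent
#' ingredient. Records that fail to parse yield a row of `NA` descriptors
#' rather than an error, so curation reports stay complete.
#'
#' @param smiles Character vector of SMILES strings.
#' @param compound_id Identifiers for the result rows; defaults to names of
#'   `smiles` or a generated sequence.
#' @param strip Strip counter-ions before computing (default `TRUE`).
#' @param hbond_convention Passed to [compute_descriptors()].
#' @return A `data.frame` with `compound_id` plus the seven descriptor
#'   columns, one row per input in input order.
#' @export
compute_descriptor_table <- function(smiles, compound_id = NULL,
                                     strip = TRUE,
                                     hbond_convention = "lipinski") {
  if (is.null(compound_id)) {
    compound_id <- if (!is.null(names(smiles))) names(smiles) else
      sprintf("CMPD_%04d", seq_along(smiles))
  }
  stopifnot(length(compound_id) == length(smiles))
  na_row <- data.frame(mw = NA_real_, n_ha = NA_integer_, n_hd = NA_integer_,
                       n_rot = NA_integer_, n_ring = NA_integer_,
                       f_char = NA_integer_, logp = NA_real_)
  rows <- lapply(seq_along(smiles), function(i) {
    s <- smiles[[i]]
    if (is.na(s) || !nzchar(s)) return(na_row)
    tryCatch({
      if (strip) s <- strip_counterions(s)
      compute_descriptors(s, hbond_convention = hbond_convention)
    }, error = function(e) na_row)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(compound_id = as.character(compound_id),
                          stringsAsFactors = FALSE), out)
  rownames(out) <- NULL
  out
}

#' Append descriptor columns to a compound CSV
#'
#' Batch-mode convenience: reads a compound table CSV (see
#' [read_compound_table()]), computes the seven descriptors for each parsed
#' structure and writes the input columns plus the descriptor columns.
#'
#' @param path_in Input CSV with at least `compound_id` and `smiles`.
#' @param path_out Output CSV path.
#' @param ... Passed to [compute_descriptor_table()].
#' @return Invisibly, the written `data.frame`.
#' @export
append_descriptors_csv <- function(path_in, path_out, ...) {
  tab <- utils::read.csv(path_in, stringsAsFactors = FALSE)
  if (!all(c("compound_id", "smiles") %in% names(tab))) {
    stop("input CSV must contain 'compound_id' and 'smiles' columns",
         call. = FALSE)
  }
  desc <- compute_descriptor_table(tab$smiles, tab$compound_id, ...)
  out <- cbind(tab, desc[, setdiff(names(desc), "compound_id")])
  utils::write.csv(out, path_out, row.names = FALSE)
  invisible(out)
}

descriptor_names <- function() {
  c("mw", "n_ha", "n_hd", "n_rot", "n_ring", "f_char", "logp")
}
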