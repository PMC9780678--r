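# Internal helpers wrapping the Open Babel toolkit (via ChemmineOB).
# All structure parsing, canonicalisation, property calculation and SMARTS
# matching in the package funnels through these functions.

#' @importFrom ChemmineOB forEachMol prop_OB smartsSearch_OB convertFormat
NULL

# Open Babel property block for a single SMILES, or NULL when unparsable.
ob_props <- function(smiles) {
  res <- tryCatch(
    ChemmineOB::forEachMol("SMILES", smiles, function(m) ChemmineOB::prop_OB(m)),
    error = function(e) NULL
  )
  if (is.null(res) || length(res) == 0L) return(NULL)
  p <- res[[1L]]
  if (is.null(p) || !nzchar(p$formula)) return(NULL)
  p
}

# Canonical SMILES, or NA_character_ when the input does not parse.
ob_canonical <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMILES", "CAN", smiles),
    error = function(e) ""
  )
  out <- sub("\\s+$", "", out)
  if (!nzchar(out)) NA_character_ else out
}

is_valid_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    !is.na(ob_canonical(s))
  }, logical(1), USE.NAMES = FALSE)
}

# Element counts from a Hill-order molecular formula such as "C6H12O6" or
# "C5H5O+". The trailing charge token is ignored.
elem_counts <- function(formula) {
  f <- sub("[+-][0-9]*$", "", formula)
  toks <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1L]]
  out <- integer(0)
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    n <- suppressWarnings(as.integer(gsub("[^0-9]", "", t)))
    if (is.na(n)) n <- 1L
    out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + n
  }
  out
}

heavy_atom_count <- function(formula) {
  ec <- elem_counts(formula)
  sum(ec[setdiff(names(ec), "H")])
}

contains_carbon <- function(formula) {
  "C" %in% names(elem_counts(formula))
}

# Molfile (V2000) text with explicit hydrogens for a single SMILES.
explicit_h_molfile <- function(smiles) {
  ChemmineOB::convertFormat("SMILES", "SDF", paste0(smiles, "\tmol"),
                            options = data.frame(names = "h", args = ""))
}

# Net formal charge summed over "M  CHG" property lines of a molfile.
molfile_formal_charge <- function(sdf_text) {
  lines <- strsplit(sdf_text, "\n", fixed = TRUE)[[1L]]
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  total <- 0L
  for (l in chg_lines) {
    v <- suppressWarnings(
      as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", l)), " +")[[1L]])
    )
    v <- v[!is.na(v)]
    if (length(v) >= 2L) total <- total + sum(v[seq(2L, length(v), by = 2L)])
  }
  total
}

# Number of unique SMARTS matches in a single molecule.
smarts_count <- function(smiles, pattern) {
  res <- ChemmineOB::forEachMol("SMILES", smiles, function(m) {
    ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE)
  })
  as.integer(res[[1L]])
}
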