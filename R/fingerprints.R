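#' Hashed circular fingerprints for a set of structures
#'
#' Computes hashed circular (extended-connectivity, radius 2 by default)
#' fingerprints and folds them to a fixed bit length. The fingerprint type
#' is any supported by the Open Babel backend (`"ECFP4"` is the standard
#' radius-2 choice; `"ECFP2"`, `"ECFP6"`, `"FP2"` etc. are also accepted).
#'
#' @param smiles Character vector of SMILES strings (all must parse).
#' @param fp_type Fingerprint name (default `"ECFP4"`).
#' @param fp_bits Folded fingerprint length in bits (default 2048).
#' @return A 0/1 integer matrix, one row per structure.
#' @export
smiles_fingerprints <- function(smiles, fp_type = "ECFP4", fp_bits = 2048) {
  bad <- !is_valid_smiles(smiles)
  if (any(bad)) {
    stop("cannot parse structure(s): ",
         paste(smiles[bad], collapse = ", "), call. = FALSE)
  }
  names(smiles) <- sprintf("m%04d", seq_along(smiles))
  sdfset <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  fp <- ChemmineR::fingerprintOB(sdfset, fp_type)
  m <- fp@fpma
  storage.mode(m) <- "integer"
  fold_fingerprints(m, fp_bits)
}

# OR-fold fingerprint columns down to `bits` columns.
fold_fingerprints <- function(m, bits) {
  if (ncol(m) <= bits) return(m)
  if (ncol(m) %% bits != 0) {
    stop("fp_bits must divide the native fingerprint length (",
         ncol(m), ")", call. = FALSE)
  }
  out <- matrix(0L, nrow = nrow(m), ncol = bits)
  for (block in seq_len(ncol(m) / bits)) {
    cols <- seq.int((block - 1L) * bits + 1L, block * bits)
    out <- pmax(out, m[, cols, drop = FALSE])
  }
  rownames(out) <- rownames(m)
  out
}

#' Tanimoto similarity between two bit fingerprints
#'
#' `|A & B| / |A | B|` over the set bits. Two all-zero fingerprints have
#' similarity 0 by convention.
#'
#' @param a,b 0/1 integer vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  stopifnot(length(a) == length(b))
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Ligand-based target prediction by fingerprint similarity
#'
#' A self-contained similarity ("target fishing") predictor: each
#' reference target is represented by its known ligands, the query is
#' compared to every ligand by Tanimoto similarity of hashed circular
#' fingerprints, and each target is scored by its best-matching ligand.
#' Targets are ranked by similarity (descending), ties broken by
#' `target_id`, and the top `k` are returned as prediction records under
#' tool id `"builtin_sim"`.
#'
#' @param query_smiles A single SMILES string.
#' @param reference Data frame with columns `smiles` and `target_id`.
#' @param fp_type,fp_bits Fingerprint parameters; see
#'   [smiles_fingerprints()].
#' @param k Number of targets to return (default: all).
#' @return Prediction records as in [load_predictions()], with `score` =
#'   best Tanimoto similarity.
#' @export
similarity_target_predictor <- function(query_smiles, reference,
                                        fp_type = "ECFP4", fp_bits = 2048,
                                        k = NULL) {
  if (is.null(reference) || nrow(reference) == 0L) {
    stop("empty reference ligand set", call. = FALSE)
  }
  if (!all(c("smiles", "target_id") %in% names(reference))) {
    stop("reference needs 'smiles' and 'target_id' columns", call. = FALSE)
  }
  if (!is_valid_smiles(query_smiles)) {
    stop("cannot parse query structure: '", query_smiles, "'",
         call. = FALSE)
  }
  fps <- smiles_fingerprints(c(query_smiles, reference$smiles),
                             fp_type = fp_type, fp_bits = fp_bits)
  qfp <- fps[1L, ]
  sims <- vapply(seq_len(nrow(reference)), function(i) {
    tanimoto(qfp, fps[i + 1L, ])
  }, numeric(1))
  per_target <- stats::aggregate(sims,
                                 by = list(target_id = reference$target_id),
                                 FUN = max)
  names(per_target)[2L] <- "score"
  per_target <- per_target[order(-per_target$score, per_target$target_id), ,
                           drop = FALSE]
  if (is.null(k)) k <- nrow(per_target)
  k <- min(k, nrow(per_target))
  out <- data.frame(
    tool_id = "builtin_sim",
    compound_id = "query",
    target_id = per_target$target_id[seq_len(k)],
    rank = seq_len(k),
    score = per_target$score[seq_len(k)],
    in_topk = NA,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
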