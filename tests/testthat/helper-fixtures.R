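# Shared fixtures built in code.

# Reference descriptor panel: values computed once with an independent
# cheminformatics toolkit (RDKit 2024.09) under the same conventions
# (average-mass MW; acceptors = N + O atoms; donors = N/O atoms bearing
# at least one hydrogen; rotatable = non-ring single bonds between
# non-terminal heavy atoms minus amide C-N; rings = SSSR; Wildman-Crippen
# logP). Salts reduced to their largest fragment before calculation.
oracle_panel <- function() {
  tab <- c(
    "water             O                                  18.0150  1 1 0 0 0  -0.8247",
    "benzene           c1ccccc1                           78.1140  0 0 0 1 0   1.6866",
    "ethanol           CCO                                46.0690  1 1 0 0 0  -0.0014",
    "glucose           OCC1OC(O)C(O)C(O)C1O              180.1560  6 5 1 1 0  -3.2214",
    "quercetin         O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12 302.2380 7 5 1 3 0 1.9880",
    "malvidin          COc1cc(-c2[o+]c3cc(O)cc(O)c3cc2O)cc(OC)c1O 331.3000 7 4 3 3 1 3.2205",
    "malvidin_3_gal    COc1cc(-c2[o+]c3cc(O)cc(O)c3cc2OC2OC(CO)C(O)C(O)C2O)cc(OC)c1O 493.4410 12 7 6 4 1 0.6936",
    "cyanidin          Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1 287.2470 6 5 1 3 1 2.9089",
    "catechin          Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2 290.2710 6 5 1 3 0 1.5461",
    "gallic_acid       O=C(O)c1cc(O)c(O)c(O)c1           170.1200  5 4 1 1 0   0.5016",
    "caffeine          Cn1c(=O)c2c(ncn2C)n(C)c1=O        194.1940  6 0 0 2 0  -1.0293",
    "aspirin           CC(=O)Oc1ccccc1C(=O)O             180.1590  4 1 3 1 0   1.3101",
    "phenol            Oc1ccccc1                          94.1130  1 1 0 1 0   1.3922",
    "glycine           NCC(=O)O                           75.0670  3 2 1 0 0  -0.9703",
    "pyridine          c1ccncc1                           79.1020  1 0 0 1 0   1.0816",
    "acetamide         CC(N)=O                            59.0680  2 1 0 0 0  -0.5084",
    "naphthalene       c1ccc2ccccc2c1                    128.1740  0 0 0 2 0   2.8398",
    "resveratrol       Oc1ccc(/C=C/c2cc(O)cc(O)c2)cc1    228.2470  3 3 2 2 0   2.9738",
    "ethanolamine      NCCO                               61.0840  2 2 1 0 0  -1.0626",
    "ethanol_hcl_salt  [Cl-].CCO                          46.0690  1 1 0 0 0  -0.0014")
  parts <- strsplit(trimws(tab), "[[:space:]]+")
  df <- data.frame(
    name = vapply(parts, `[[`, "", 1L),
    smiles = vapply(parts, `[[`, "", 2L),
    mw = as.numeric(vapply(parts, `[[`, "", 3L)),
    n_ha = as.integer(vapply(parts, `[[`, "", 4L)),
    n_hd = as.integer(vapply(parts, `[[`, "", 5L)),
    n_rot = as.integer(vapply(parts, `[[`, "", 6L)),
    n_ring = as.integer(vapply(parts, `[[`, "", 7L)),
    f_char = as.integer(vapply(parts, `[[`, "", 8L)),
    logp = as.numeric(vapply(parts, `[[`, "", 9L)),
    stringsAsFactors = FALSE)
  # molecules whose N-H/O-H hydrogen typing differs between the two
  # Wildman-Crippen implementations; logP is not compared for these
  df$logp_comparable <- !df$name %in%
    c("water", "glycine", "acetamide", "ethanolamine")
  df
}

write_temp_csv <- function(df, ext = ".csv") {
  path <- tempfile(fileext = ext)
  utils::write.csv(df, path, row.names = FALSE)
  path
}

basic_library_df <- function() {
  data.frame(
    compound_id = sprintf("C%02d", 1:6),
    name = c("ethanol", "phenol", "water", "salt", "quercetin", "tg_entry"),
    smiles = c("CCO", "Oc1ccccc1", "O", "[Na+].[Cl-]",
               "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12",
               "CCCCCCCC(=O)OCC(COC(=O)CCCCCCC)OC(=O)CCCCCCC"),
    compound_class = c("small_molecule", "phenolic", "inorganic",
                       "inorganic", "flavonoid", "triacylglycerol"),
    stringsAsFactors = FALSE)
}

# 20 reference ligands over 5 synthetic target accessions for the
# similarity-predictor tests.
ref_ligand_panel <- function() {
  data.frame(
    smiles = c("CCO", "CCCO", "CCCCO", "CC(C)O",
               "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "c1ccc2ccccc2c1",
               "O=C(O)c1ccccc1", "O=C(O)c1ccc(O)cc1", "CC(=O)Oc1ccccc1C(=O)O",
               "O=C(O)CC(O)C(=O)O",
               "OCC1OC(O)C(O)C(O)C1O", "OC1OC(CO)C(O)C1O",
               "Oc1ccc(O)cc1", "Oc1ccccc1O",
               "c1ccncc1", "Cc1ccncc1", "c1ccnc(N)c1", "Nc1ccccc1"),
    target_id = rep(c("P10001", "P10002", "P10003", "P10004", "P10005"),
                    each = 4),
    stringsAsFactors = FALSE)
}

# Independent rule evaluation used as the scoring oracle: a plain loop
# with literal comparator logic, sharing no code with evaluate_rules().
brute_force_score <- function(desc_row, admet_row, ruleset) {
  outcomes <- character(nrow(ruleset))
  for (i in seq_len(nrow(ruleset))) {
    prop <- ruleset$property[i]
    val <- NULL
    if (prop %in% names(desc_row)) val <- desc_row[[prop]]
    if (is.null(val) && !is.null(admet_row) && prop %in% names(admet_row)) {
      val <- admet_row[[prop]]
    }
    if (is.null(val) || is.na(val)) {
      outcomes[i] <- "not_evaluable"
      next
    }
    lo <- ruleset$threshold[i]
    hi <- ruleset$threshold_high[i]
    ok <- switch(ruleset$comparator[i],
                 lt = val < lo, le = val <= lo,
                 gt = val > lo, ge = val >= lo,
                 between = (val >= lo) && (val <= hi))
    outcomes[i] <- if (ok) "pass" else "fail"
  }
  raw <- sum(ruleset$weight[outcomes == "pass"])
  maxp <- sum(ruleset$weight[outcomes != "not_evaluable"])
  list(outcomes = stats::setNames(outcomes, ruleset$rule_id),
       raw = raw, maxp = maxp,
       norm = if (maxp > 0) raw / maxp else 0)
}
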