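# Synthetic-data generators: libraries with planted rule-passing actives,
# multi-tool target predictions with controllable operating
# characteristics, and assay readouts with known generating parameters.
# One master seed; each generator draws from a substream keyed by
# (seed, generator name) so adding a generator never perturbs the others.

substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Configuration for a synthetic compound library
#'
#' The defaults emulate a curated food-constituent export at test scale: a
#' class mix dominated by small organic molecules and polyphenols with a
#' substantial glycerolipid fraction and a few inorganic entries, and ten
#' planted rule-passing actives among 200 compounds.
#'
#' @param n_compounds Library size (default 200).
#' @param class_mix Named proportions over class tags (must sum to 1).
#' @param n_planted Number of planted actives that satisfy every scoring
#'   rule (default 10).
#' @param descriptor_ranges Optional overrides for the per-property
#'   sampling ranges of the planted actives.
#' @param seed Master seed (default 1).
#' @return A list of class `library_config`.
#' @export
library_config <- function(n_compounds = 200,
                           class_mix = c(small_molecule = 0.30,
                                         flavonoid = 0.15,
                                         anthocyanin = 0.10,
                                         phenolic = 0.05,
                                         triacylglycerol = 0.15,
                                         diacylglycerol = 0.10,
                                         phosphatidylethanolamine = 0.10,
                                         inorganic = 0.05),
                           n_planted = 10,
                           descriptor_ranges = NULL,
                           seed = 1) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-8, n_planted <= n_compounds)
  unknown <- setdiff(names(class_mix), compound_classes())
  if (length(unknown)) {
    stop("class_mix uses unknown tag(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_compounds = n_compounds, class_mix = class_mix,
                 n_planted = n_planted,
                 descriptor_ranges = descriptor_ranges, seed = seed),
            class = "library_config")
}

# Sampling windows for planted actives: inside every default rule with a
# margin, so actives can never sit on a rule boundary.
active_ranges <- function(overrides = NULL) {
  rng <- list(mw = c(120, 580), n_ha = c(0L, 11L), n_hd = c(0L, 6L),
              n_rot = c(0L, 10L), n_ring = c(1L, 5L), f_char = c(-1L, 1L),
              logp = c(0.2, 4.8))
  if (!is.null(overrides)) rng[names(overrides)] <- overrides
  rng
}

# Pools of small valid structures used to give every synthetic record a
# parseable SMILES of the right kind (organic vs carbon-free). The
# tabulated descriptors, not these token structures, drive the descriptor
# stages, mirroring a workflow where properties arrive as a precomputed
# table.
ORGANIC_SMILES_POOL <- c(
  "CCO", "CC(C)O", "c1ccccc1O", "Oc1ccc(O)cc1", "OCC1OC(O)C(O)C(O)C1O",
  "O=C(O)c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "c1ccc2ccccc2c1",
  "Oc1cc(O)c2cc(O)c(-c3ccc(O)c(O)c3)[o+]c2c1",
  "O=c1c(O)c(-c2ccc(O)c(O)c2)oc2cc(O)cc(O)c12")
INORGANIC_SMILES_POOL <- c("O", "[Na+].[Cl-]", "[K+].[Cl-]", "N",
                           "O=S(=O)([O-])[O-]")

#' Generate a synthetic compound library with planted actives
#'
#' Produces a compound table, a descriptor table, ADMET endpoint profiles
#' and a ground-truth table. Exactly `n_planted` compounds are actives:
#' their descriptors and endpoints satisfy every rule of `ruleset` with a
#' margin. Every other compound (decoy) violates at least one recorded
#' rule by a margin. Class tags are assigned by `class_mix`; inorganic
#' entries receive carbon-free structures, and the ground truth records
#' the curation stage at which each compound should fall out of the
#' cascade (`class`, `inorganic`, `molecular_weight`, or `NA` for
#' survivors).
#'
#' @param config A [library_config()].
#' @param ruleset Ruleset the actives are planted against (default
#'   [default_ruleset()]).
#' @param excluded_classes Class tags the curation cascade will remove;
#'   used for the ground-truth stage labels and to keep actives out of
#'   those classes.
#' @return A list of class `synthetic_library`: `compounds`,
#'   `descriptors`, `admet`, `truth`, `config`.
#' @export
generate_library <- function(config = library_config(),
                             ruleset = default_ruleset(),
                             excluded_classes = c("triacylglycerol",
                                                  "diacylglycerol",
                                                  "phosphatidylethanolamine")) {
  n <- config$n_compounds
  set.seed(substream_seed(config$seed, "library"))
  rng <- active_ranges(config$descriptor_ranges)

  ids <- sprintf("C_%03d", seq_len(n))
  classes <- sample(rep(names(config$class_mix),
                        times = round_proportions(config$class_mix, n)))

  safe_classes <- setdiff(names(config$class_mix),
                          c(excluded_classes, "inorganic"))
  if (length(safe_classes) == 0L && config$n_planted > 0L) {
    stop("class_mix leaves no class for planted actives", call. = FALSE)
  }
  candidate <- which(classes %in% safe_classes)
  if (length(candidate) < config$n_planted) {
    stop("class mix leaves too few non-excluded compounds to plant ",
         config$n_planted, " actives", call. = FALSE)
  }
  active_idx <- sort(sample(candidate, config$n_planted))
  is_active <- seq_len(n) %in% active_idx

  desc <- sample_descriptors(n, rng)
  admet <- as.data.frame(
    matrix(stats::runif(n * length(admet_endpoints()), 0.01, 0.45),
           nrow = n, dimnames = list(NULL, admet_endpoints())),
    check.names = FALSE)

  # Decoys: pick one violated rule each and push that property out of its
  # window by a margin. Scoring-stage rules only; curation-stage removal is
  # handled by class tags and the MW low side below.
  rule_pool <- c(descriptor_names(), admet_endpoints())
  violated <- rep(NA_character_, n)
  for (i in which(!is_active)) {
    v <- sample(rule_pool, 1L)
    violated[i] <- v
    if (v %in% admet_endpoints()) {
      admet[i, v] <- stats::runif(1, 0.55, 0.99)
    } else {
      desc[i, v] <- violate_descriptor(v)
    }
  }

  smiles <- ifelse(classes == "inorganic",
                   sample(INORGANIC_SMILES_POOL, n, replace = TRUE),
                   sample(ORGANIC_SMILES_POOL, n, replace = TRUE))

  compounds <- new_compound_library(data.frame(
    compound_id = ids,
    name = paste0("synthetic_", ids),
    smiles = smiles,
    compound_class = classes,
    source = "synthetic",
    parse_ok = TRUE,
    stringsAsFactors = FALSE))

  desc <- cbind(data.frame(compound_id = ids, stringsAsFactors = FALSE),
                desc)
  admet <- cbind(data.frame(compound_id = ids, stringsAsFactors = FALSE),
                 admet)
  class(admet) <- c("admet_profiles", "data.frame")

  removed_stage <- rep(NA_character_, n)
  removed_stage[classes %in% excluded_classes] <- "class"
  inorg <- is.na(removed_stage) & classes == "inorganic"
  removed_stage[inorg] <- "inorganic"
  low_mw <- is.na(removed_stage) & desc$mw < 100
  removed_stage[low_mw] <- "molecular_weight"

  truth <- data.frame(compound_id = ids, is_active = is_active,
                      violated_rule = violated,
                      removed_stage = removed_stage,
                      stringsAsFactors = FALSE)

  structure(list(compounds = compounds, descriptors = desc, admet = admet,
                 truth = truth, config = config),
            class = "synthetic_library")
}

round_proportions <- function(p, n) {
  counts <- floor(p * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- p * n - counts
    bump <- order(-frac)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  as.integer(counts)
}

sample_descriptors <- function(n, rng) {
  data.frame(
    mw = stats::runif(n, rng$mw[1], rng$mw[2]),
    n_ha = sample(rng$n_ha[1]:rng$n_ha[2], n, replace = TRUE),
    n_hd = sample(rng$n_hd[1]:rng$n_hd[2], n, replace = TRUE),
    n_rot = sample(rng$n_rot[1]:rng$n_rot[2], n, replace = TRUE),
    n_ring = sample(rng$n_ring[1]:rng$n_ring[2], n, replace = TRUE),
    f_char = sample(rng$f_char[1]:rng$f_char[2], n, replace = TRUE),
    logp = stats::runif(n, rng$logp[1], rng$logp[2])
  )
}

# Out-of-window value for a violated descriptor rule, away from the
# boundary so the planted set stays identifiable.
violate_descriptor <- function(property) {
  switch(property,
         mw = if (stats::runif(1) < 0.5) stats::runif(1, 40, 90) else
           stats::runif(1, 620, 900),
         n_ha = sample(13:20, 1L),
         n_hd = sample(8:14, 1L),
         n_rot = sample(12:20, 1L),
         n_ring = 0L,
         f_char = sample(c(-3L, -2L, 2L, 3L), 1L),
         logp = if (stats::runif(1) < 0.5) stats::runif(1, -3, -0.5) else
           stats::runif(1, 5.5, 8))
}

#' Configuration for the multi-tool prediction simulator
#'
#' Emulates a panel of independent target-prediction services queried with
#' the same compounds: each tool covers a target with probability
#' `coverage`, places a covered true pair in its retained hit list with
#' probability `sensitivity`, places a covered decoy pair there with
#' probability `false_hit_rate`, and may additionally return pairs beyond
#' the retention window with probability `beyond_rate` (exercising the
#' hit-beyond-window vote state).
#'
#' @param n_tools Number of simulated tools (default 6).
#' @param sensitivity P(true pair appears within top-k) (default 0.8).
#' @param false_hit_rate P(decoy pair appears within top-k) (default 0.1).
#' @param coverage P(a tool covers a given target) (default 1.0).
#' @param topk Retention window size (default 20).
#' @param beyond_rate P(an otherwise absent pair is returned beyond the
#'   window) (default 0.1).
#' @param seed Master seed (default 1).
#' @return A list of class `predictor_sim_config`.
#' @export
predictor_sim_config <- function(n_tools = 6, sensitivity = 0.8,
                                 false_hit_rate = 0.1, coverage = 1.0,
                                 topk = 20, beyond_rate = 0.1, seed = 1) {
  probs <- c(sensitivity, false_hit_rate, coverage, beyond_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("sensitivity, false_hit_rate, coverage and beyond_rate must be ",
         "probabilities in [0, 1]", call. = FALSE)
  }
  structure(list(n_tools = n_tools, sensitivity = sensitivity,
                 false_hit_rate = false_hit_rate, coverage = coverage,
                 topk = topk, beyond_rate = beyond_rate, seed = seed),
            class = "predictor_sim_config")
}

#' Simulate per-tool target-prediction hit lists
#'
#' @param config A [predictor_sim_config()].
#' @param true_pairs Data frame with columns `compound_id`, `target_id`:
#'   the planted compound-target interactions.
#' @param decoy_targets Character vector of additional target accessions a
#'   tool may (falsely) return for any compound.
#' @return A list of class `prediction_sim`: `predictions` (records for
#'   all tools, ranked within tool and compound), `manifests` (list of
#'   [tool_manifest()]), `config`.
#' @export
generate_predictions <- function(config, true_pairs, decoy_targets) {
  if ((is.null(true_pairs) || nrow(true_pairs) == 0L) &&
      length(decoy_targets) == 0L) {
    stop("need at least one true pair or decoy target", call. = FALSE)
  }
  set.seed(substream_seed(config$seed, "predictions"))
  tools <- sprintf("sim_tool_%d", seq_len(config$n_tools))
  targets <- unique(c(if (!is.null(true_pairs)) true_pairs$target_id,
                      decoy_targets))
  compounds <- unique(if (!is.null(true_pairs)) true_pairs$compound_id else
    character(0))
  true_key <- if (!is.null(true_pairs))
    paste(true_pairs$compound_id, true_pairs$target_id) else character(0)

  manifests <- list()
  all_rec <- list()
  for (tool in tools) {
    covered <- targets[stats::runif(length(targets)) < config$coverage]
    manifests[[tool]] <- tool_manifest(tool, covered)
    for (cmp in compounds) {
      cand <- covered
      if (length(cand) == 0L) next
      is_true <- paste(cmp, cand) %in% true_key
      p_top <- ifelse(is_true, config$sensitivity, config$false_hit_rate)
      u <- stats::runif(length(cand))
      in_top <- u < p_top
      beyond <- !in_top & (stats::runif(length(cand)) < config$beyond_rate)
      n_top <- sum(in_top)
      if (n_top > config$topk) {
        warning("more hits than the retention window for ", cmp, " in ",
                tool, call. = FALSE)
      }
      recs <- list()
      if (n_top > 0L) {
        recs[[length(recs) + 1L]] <- data.frame(
          tool_id = tool, compound_id = cmp,
          target_id = cand[in_top],
          rank = sample(seq_len(n_top)),
          score = NA_real_, stringsAsFactors = FALSE)
      }
      n_beyond <- sum(beyond)
      if (n_beyond > 0L) {
        recs[[length(recs) + 1L]] <- data.frame(
          tool_id = tool, compound_id = cmp,
          target_id = cand[beyond],
          rank = max(config$topk, n_top) + sample(seq_len(n_beyond)),
          score = NA_real_, stringsAsFactors = FALSE)
      }
      if (length(recs)) all_rec[[length(all_rec) + 1L]] <-
          do.call(rbind, recs)
    }
  }
  predictions <- if (length(all_rec)) do.call(rbind, all_rec) else
    data.frame(tool_id = character(0), compound_id = character(0),
               target_id = character(0), rank = integer(0),
               score = numeric(0), stringsAsFactors = FALSE)
  predictions$in_topk <- rep(NA, nrow(predictions))
  rownames(predictions) <- NULL
  structure(list(predictions = predictions, manifests = unname(manifests),
                 config = config),
            class = "prediction_sim")
}

#' Configuration for synthetic assay data
#'
#' Replicate groups are true means plus Gaussian noise with `n` replicates
#' per group (three, matching the usual assay design); the aggregation
#' time course is a logistic curve sampled at the assay's measurement
#' times (0-96 h).
#'
#' @param group_means Named vector of true group means.
#' @param noise_sd Gaussian noise SD added to every replicate (default 5).
#' @param n_replicates Replicates per group (default 3).
#' @param tht_times Sampling times in hours.
#' @param tht_baseline,tht_plateau,tht_midpoint,tht_rate Logistic
#'   parameters of the aggregation curve (intensity units, hours, 1/h).
#' @param tht_noise_sd Noise SD for the time course (default 0).
#' @param seed Master seed.
#' @return A list of class `assay_sim_config`.
#' @export
assay_sim_config <- function(group_means = c(control = 100,
                                             stressed = 55,
                                             treated_low = 70,
                                             treated_high = 90),
                             noise_sd = 5, n_replicates = 3,
                             tht_times = c(0, 2, 4, 6, 12, 24, 48, 72, 96),
                             tht_baseline = 100, tht_plateau = 1000,
                             tht_midpoint = 24, tht_rate = 0.12,
                             tht_noise_sd = 0, seed = 1) {
  if (noise_sd < 0 || tht_noise_sd < 0) {
    stop("noise SD must be non-negative", call. = FALSE)
  }
  structure(list(group_means = group_means, noise_sd = noise_sd,
                 n_replicates = n_replicates, tht_times = tht_times,
                 tht_baseline = tht_baseline, tht_plateau = tht_plateau,
                 tht_midpoint = tht_midpoint, tht_rate = tht_rate,
                 tht_noise_sd = tht_noise_sd, seed = seed),
            class = "assay_sim_config")
}

#' Generate synthetic assay data with known ground truth
#'
#' @param config An [assay_sim_config()].
#' @return A list of class `assay_sim`: `replicates` (long data frame
#'   `group`, `replicate`, `value`), `tht` (data frame `time`,
#'   `intensity`), and `params` echoing the generating values, including
#'   the analytic threshold-crossing time of the noise-free logistic at
#'   fraction 0.1 (`tht_lag_analytic`).
#' @export
generate_assay_data <- function(config = assay_sim_config()) {
  set.seed(substream_seed(config$seed, "assay"))
  groups <- names(config$group_means)
  replicates <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g, replicate = seq_len(config$n_replicates),
               value = config$group_means[[g]] +
                 stats::rnorm(config$n_replicates, 0, config$noise_sd),
               stringsAsFactors = FALSE)
  }))
  logistic <- function(t) {
    config$tht_baseline + (config$tht_plateau - config$tht_baseline) /
      (1 + exp(-config$tht_rate * (t - config$tht_midpoint)))
  }
  tht <- data.frame(time = config$tht_times,
                    intensity = logistic(config$tht_times) +
                      stats::rnorm(length(config$tht_times), 0,
                                   config$tht_noise_sd))
  # analytic crossing time matching the lag-phase definition: baseline is
  # the curve value at the first sampling time, plateau at the last, and
  # the lag ends where the curve reaches baseline + f * (plateau - baseline)
  f <- 0.1
  b0 <- logistic(min(config$tht_times))
  p0 <- logistic(max(config$tht_times))
  v <- b0 + f * (p0 - b0)
  lag <- config$tht_midpoint -
    log((config$tht_plateau - config$tht_baseline) /
          (v - config$tht_baseline) - 1) / config$tht_rate
  structure(list(replicates = replicates, tht = tht,
                 params = c(config, list(tht_lag_analytic = lag))),
            class = "assay_sim")
}

#' Write a synthetic library as pipeline input files
#'
#' Emits the exact CSV/TSV dialects consumed by [read_compound_table()],
#' [load_admet_table()] and [load_predictions()]: `compounds.csv`,
#' `descriptors.csv`, `admet.csv`, `truth.csv` and, when a prediction
#' simulation is supplied, one `predictions_<tool>.tsv` per tool plus
#' `manifests.yaml`.
#'
#' @param lib A `synthetic_library` from [generate_library()].
#' @param dir Output directory (created if needed).
#' @param prediction_sim Optional `prediction_sim` from
#'   [generate_predictions()].
#' @return Invisibly, the directory path.
#' @export
write_library_fixture <- function(lib, dir, prediction_sim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_compound_table(lib$compounds, file.path(dir, "compounds.csv"))
  utils::write.csv(lib$descriptors, file.path(dir, "descriptors.csv"),
                   row.names = FALSE)
  utils::write.csv(lib$admet, file.path(dir, "admet.csv"),
                   row.names = FALSE)
  utils::write.csv(lib$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  if (!is.null(prediction_sim)) {
    preds <- prediction_sim$predictions
    for (tool in unique(preds$tool_id)) {
      sub <- preds[preds$tool_id == tool,
                   c("compound_id", "target_id", "rank")]
      utils::write.table(sub, file.path(dir,
                                        paste0("predictions_", tool, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    man <- lapply(prediction_sim$manifests, function(m) {
      list(tool_id = m$tool_id, covered_targets = as.list(m$covered_targets))
    })
    yaml::write_yaml(man, file.path(dir, "manifests.yaml"))
  }
  invisible(dir)
}
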