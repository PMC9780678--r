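write_pred_file <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

test_that("prediction tables load with explicit or derived ranks", {
  df <- data.frame(compound_id = "C1",
                   target_id = sprintf("P%05d", 1:30),
                   rank = 1:30)
  rec <- load_predictions(write_pred_file(df), "toolA")
  expect_equal(nrow(rec), 30L)
  expect_equal(rec$rank, 1:30)

  # score-only table: ranks by descending score, ties by target accession
  df2 <- data.frame(compound_id = "C1",
                    target_id = c("P00003", "P00001", "P00002"),
                    score = c(0.5, 0.9, 0.5))
  rec2 <- load_predictions(write_pred_file(df2), "toolB")
  expect_equal(rec2$target_id[rec2$rank], c("P00001", "P00002", "P00003"))

  df3 <- rbind(df2, df2[1, ])
  expect_error(load_predictions(write_pred_file(df3), "toolB"), "duplicate")

  df4 <- data.frame(compound_id = "C1", target_id = "P1")
  expect_error(load_predictions(write_pred_file(df4), "toolC"),
               "rank.*score|score.*rank")
})

test_that("the retention window flags but never drops records", {
  df <- data.frame(compound_id = "C1", target_id = sprintf("T%02d", 1:30),
                   rank = 1:30)
  rec <- load_predictions(write_pred_file(df), "t")
  r20 <- apply_topk(rec, 20)
  expect_equal(sum(r20$in_topk), 20L)
  expect_equal(nrow(r20), 30L)

  r_all <- apply_topk(rec[rec$rank <= 15, ], 20)
  expect_true(all(r_all$in_topk))

  r1 <- apply_topk(rec, 1)
  expect_equal(rec$target_id[which(r1$in_topk)], rec$target_id[rec$rank == 1])
  expect_error(apply_topk(rec, 0), "positive")
})

# Six tools as in the worked vote example: 2 in-window hits, 1 beyond,
# 2 covered misses, 1 tool that does not cover the target.
six_tool_records <- function() {
  recs <- rbind(
    data.frame(tool_id = "t1", compound_id = "C_26", target_id = "P05067",
               rank = 3),
    data.frame(tool_id = "t2", compound_id = "C_26", target_id = "P05067",
               rank = 11),
    data.frame(tool_id = "t3", compound_id = "C_26", target_id = "P05067",
               rank = 25))
  recs$score <- NA_real_
  recs$in_topk <- NA
  recs
}

test_that("vote states follow the four-way definition and conserve counts", {
  recs <- apply_topk(six_tool_records(), 20)
  manifests <- c(lapply(paste0("t", 1:5),
                        function(t) tool_manifest(t, "P05067")),
                 list(tool_manifest("t6", character(0))))
  vm <- assign_vote_states(recs, manifests, targets_of_interest = "P05067")
  tally <- table(vm$states$state)
  expect_equal(as.integer(tally[c("hit", "hit_beyond_topk", "no_hit",
                                  "not_covered")]),
               c(2L, 1L, 2L, 1L))
  expect_equal(consensus_votes(vm)$votes, 2L)
  # conservation: states sum to the number of tools
  expect_equal(sum(tally), 6L)
})

test_that("consensus votes reproduce the worked two- and three-tool cases", {
  # amyloid-beta precursor: exactly two tools with in-window hits
  recs <- data.frame(
    tool_id = c("TargetNet", "SwissTargetPrediction"),
    compound_id = "Ma-3-gal-Cl", target_id = "P05067", rank = c(1, 5),
    score = NA_real_, in_topk = NA)
  manifests <- lapply(c("TargetNet", "SwissTargetPrediction", "SEA",
                        "PPB2", "PharmMapper", "SuperPred"),
                      function(t) tool_manifest(t, default_targets()))
  vm <- assign_vote_states(apply_topk(recs, 20), manifests,
                           targets_of_interest = "P05067")
  expect_equal(consensus_votes(vm)$votes, 2L)

  # acetylcholinesterase: three voting tools
  recs2 <- data.frame(
    tool_id = c("TargetNet", "SwissTargetPrediction", "PPB2"),
    compound_id = "Ma-3-gal-Cl", target_id = "P22303", rank = c(2, 4, 9),
    score = NA_real_, in_topk = NA)
  vm2 <- assign_vote_states(apply_topk(recs2, 20), manifests,
                            targets_of_interest = "P22303")
  expect_equal(consensus_votes(vm2)$votes, 3L)
})

test_that("per-pair vote states always sum to the number of tools", {
  for (seed in 1:25) {
    cfg <- predictor_sim_config(
      n_tools = sample(2:7, 1), sensitivity = stats::runif(1),
      false_hit_rate = stats::runif(1, 0, 0.5),
      coverage = stats::runif(1, 0.3, 1), seed = seed)
    tp <- expand.grid(compound_id = paste0("C", 1:3),
                      target_id = paste0("P0000", 1:3),
                      stringsAsFactors = FALSE)
    sim <- generate_predictions(cfg, tp, decoy_targets = character(0))
    vm <- assign_vote_states(apply_topk(sim$predictions, cfg$topk),
                             sim$manifests,
                             targets_of_interest = unique(tp$target_id),
                             compounds = unique(tp$compound_id))
    per_pair <- table(paste(vm$states$compound_id, vm$states$target_id))
    expect_true(all(per_pair == cfg$n_tools))
  }
})

test_that("widening the retention window never demotes a hit", {
  df <- data.frame(compound_id = "C1", target_id = sprintf("T%02d", 1:30),
                   rank = 1:30, score = NA_real_, in_topk = NA,
                   tool_id = "t1")
  man <- list(tool_manifest("t1", df$target_id))
  votes_at <- function(k) {
    vm <- assign_vote_states(apply_topk(df, k), man,
                             targets_of_interest = df$target_id)
    v <- consensus_votes(vm)
    stats::setNames(v$votes, v$target_id)
  }
  v10 <- votes_at(10); v20 <- votes_at(20); v30 <- votes_at(30)
  expect_true(all(v20 >= v10))
  expect_true(all(v30 >= v20))
})

test_that("tools with unknown target universes need an explicit override", {
  recs <- apply_topk(six_tool_records()[1, ], 20)
  man_unknown <- list(tool_manifest("t1", NULL),
                      tool_manifest("t2", NULL))
  recs2 <- recs
  recs2$tool_id <- "t1"
  expect_error(
    assign_vote_states(apply_topk(six_tool_records()[1:2, ], 20),
                       man_unknown, targets_of_interest = c("P05067",
                                                            "P99999")),
    "unknown target universe")
  vm <- assign_vote_states(apply_topk(six_tool_records()[1:2, ], 20),
                           man_unknown,
                           targets_of_interest = c("P05067", "P99999"),
                           unknown_universe = "not_covered")
  st <- vm$states
  expect_true(all(st$state[st$target_id == "P99999"] == "not_covered"))
})

test_that("the network has the nodes and edges forced by the vote matrix", {
  compounds <- sprintf("C%02d", 1:10)
  targets <- default_targets()
  recs <- expand.grid(compound_id = compounds, target_id = targets,
                      stringsAsFactors = FALSE)
  recs$tool_id <- "t1"
  recs$rank <- 1
  recs$score <- NA_real_
  recs$in_topk <- NA
  man <- list(tool_manifest("t1", targets))
  vm <- assign_vote_states(apply_topk(recs, 20), man,
                           targets_of_interest = targets,
                           compounds = compounds)
  g <- build_network(vm)
  expect_equal(igraph::vcount(g), 13L)
  expect_equal(igraph::ecount(g), 30L)
  expect_true(igraph::bipartite_mapping(g)$res)

  g0 <- build_network(vm, min_votes = 4)   # max possible is 1 here
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("a two-vote pair yields a single edge of weight two", {
  recs <- data.frame(tool_id = c("t1", "t2"), compound_id = "C1",
                     target_id = "P05067", rank = 1, score = NA_real_,
                     in_topk = NA)
  man <- list(tool_manifest("t1", "P05067"), tool_manifest("t2", "P05067"))
  vm <- assign_vote_states(apply_topk(recs, 20), man,
                           targets_of_interest = "P05067")
  g <- build_network(vm, min_votes = 2)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(igraph::E(g)$votes, 2L)
})

test_that("identical vote matrices export byte-identical edge lists", {
  lib_cfg <- list(seed = 5, simulate = list(n_compounds = 30, n_planted = 5))
  f1 <- tempfile(); f2 <- tempfile()
  r1 <- run_screening(lib_cfg)
  r2 <- run_screening(lib_cfg)
  export_network(r1$network, f1)
  export_network(r2$network, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("tanimoto similarity is a bounded symmetric identity-1 measure", {
  set.seed(7)
  for (i in 1:20) {
    a <- as.integer(stats::runif(256) < 0.3)
    b <- as.integer(stats::runif(256) < 0.3)
    s <- tanimoto(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, tanimoto(b, a))
    expect_equal(tanimoto(a, a), if (sum(a) > 0) 1 else 0)
  }
})

test_that("similarity target fishing matches the exhaustive pairwise loop", {
  ref <- ref_ligand_panel()
  query <- "CCCCCO"
  pred <- similarity_target_predictor(query, ref)

  # independent oracle: exhaustive pairwise Tanimoto over the same
  # fingerprints, max-pooled per target
  fps <- smiles_fingerprints(c(query, ref$smiles))
  best <- rep(0, 5)
  names(best) <- sort(unique(ref$target_id))
  for (i in seq_len(nrow(ref))) {
    inter <- sum(fps[1, ] & fps[i + 1, ])
    uni <- sum(fps[1, ] | fps[i + 1, ])
    s <- if (uni == 0) 0 else inter / uni
    tid <- ref$target_id[i]
    if (s > best[tid]) best[tid] <- s
  }
  expected_order <- names(sort(-best))
  expect_equal(pred$target_id, expected_order)
  expect_equal(unname(pred$score), unname(best[pred$target_id]))
})

test_that("a self-query retrieves its own target at rank 1, similarity 1", {
  ref <- ref_ligand_panel()
  pred <- similarity_target_predictor(ref$smiles[5], ref)
  expect_equal(pred$target_id[1], ref$target_id[5])
  expect_equal(pred$score[1], 1.0)

  single <- ref[1:2, ]
  single$target_id <- "P10001"
  out <- similarity_target_predictor("CCO", single, k = 10)
  expect_equal(nrow(out), 1L)

  expect_error(similarity_target_predictor("CCO", ref[0, ]), "empty")
  expect_error(similarity_target_predictor("bad_smiles", ref), "parse")
})
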