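test_that("CSV ingestion keeps every row and flags unparsable structures", {
  df <- basic_library_df()
  recs <- read_compound_table(write_temp_csv(df), format = "csv")
  expect_s3_class(recs, "compound_library")
  expect_equal(nrow(recs), 6L)
  expect_equal(recs$compound_id, df$compound_id)  # order preserved
  expect_true(all(recs$parse_ok))

  df$smiles[2] <- "not_a_molecule"
  recs2 <- read_compound_table(write_temp_csv(df), format = "csv")
  expect_equal(nrow(recs2), 6L)
  expect_false(recs2$parse_ok[2])
  expect_true(all(recs2$parse_ok[-2]))
})

test_that("CSV ingestion rejects malformed tables with a named error", {
  df <- basic_library_df()
  df$smiles <- NULL
  expect_error(read_compound_table(write_temp_csv(df), format = "csv"),
               "smiles")
  empty <- tempfile(fileext = ".csv")
  writeLines("compound_id,name,smiles", empty)
  expect_error(read_compound_table(empty, format = "csv"), "empty")
  dup <- basic_library_df()
  dup$compound_id[2] <- dup$compound_id[1]
  expect_error(read_compound_table(write_temp_csv(dup), format = "csv"),
               "duplicate")
})

test_that("SDF and SMILES inputs yield one record per molecule", {
  smis <- c(a = "CCO", b = "c1ccccc1", c = "CC(=O)O")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smis))
  path <- tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, path)
  recs <- read_compound_table(path, format = "sdf")
  expect_equal(nrow(recs), 3L)
  expect_true(all(recs$parse_ok))
  expect_equal(anyDuplicated(recs$compound_id), 0L)

  smi_path <- tempfile(fileext = ".smi")
  writeLines(c("CCO\tet", "c1ccccc1\tbz", "O"), smi_path)
  recs2 <- read_compound_table(smi_path, format = "smiles")
  expect_equal(recs2$compound_id[1:2], c("et", "bz"))
  expect_equal(nrow(recs2), 3L)
})

test_that("class filtering is tag-driven and reports what it removed", {
  df <- data.frame(
    compound_id = sprintf("C%02d", 1:10),
    name = "x", smiles = "CCO",
    compound_class = c(rep("triacylglycerol", 3), rep("flavonoid", 7)),
    stringsAsFactors = FALSE)
  recs <- read_compound_table(write_temp_csv(df), format = "csv")

  res <- filter_by_class(recs, "triacylglycerol")
  expect_equal(nrow(res$records), 7L)
  expect_equal(res$report$n_in, 10L)
  expect_equal(res$report$n_out, 7L)
  expect_equal(sort(res$report$removed_ids), c("C01", "C02", "C03"))

  ident <- filter_by_class(recs, character(0))
  expect_equal(nrow(ident$records), 10L)
  expect_length(ident$report$removed_ids, 0L)

  expect_warning(out <- filter_by_class(recs, c("flavonoid", "not_a_tag")),
                 "unknown class tag")
  expect_equal(nrow(out$records), 3L)
})

test_that("lipid-class exclusion removes exactly the tagged records", {
  df <- data.frame(
    compound_id = paste0("K", 1:5), name = "x", smiles = "CCO",
    compound_class = c("triacylglycerol", "diacylglycerol",
                       "phosphatidylethanolamine", "flavonoid",
                       "anthocyanin"),
    stringsAsFactors = FALSE)
  recs <- read_compound_table(write_temp_csv(df), format = "csv")
  res <- filter_by_class(recs, c("triacylglycerol", "diacylglycerol",
                                 "phosphatidylethanolamine"))
  expect_equal(res$records$compound_id, c("K4", "K5"))
})

test_that("inorganic filter removes carbon-free structures and tagged rows", {
  df <- data.frame(
    compound_id = c("W", "E", "S", "B"),
    name = c("water", "ethanol", "salt", "bad"),
    smiles = c("O", "CCO", "[Na+].[Cl-]", "xx_not_parseable"),
    compound_class = NA_character_,
    stringsAsFactors = FALSE)
  recs <- read_compound_table(write_temp_csv(df), format = "csv")
  res <- filter_inorganic(recs)
  expect_equal(sort(res$report$removed_ids), c("S", "W"))
  # parse failures pass through untouched, still flagged
  expect_true("B" %in% res$records$compound_id)
  expect_false(res$records$parse_ok[res$records$compound_id == "B"])
})

test_that("molecular-weight cut removes strictly-below compounds only", {
  df <- data.frame(
    compound_id = c("A", "B", "C"), name = "x",
    smiles = c("CCO", "CCO", "CCO"),
    stringsAsFactors = FALSE)
  recs <- read_compound_table(write_temp_csv(df), format = "csv")
  desc <- data.frame(compound_id = c("A", "B", "C"),
                     mw = c(46.07, 100.0, 250))

  res <- filter_by_molecular_weight(recs, desc, min_mw = 100)
  expect_equal(res$report$removed_ids, "A")       # ethanol removed
  expect_true("B" %in% res$records$compound_id)   # boundary retained

  ident <- filter_by_molecular_weight(recs, desc, min_mw = 0)
  expect_equal(nrow(ident$records), 3L)

  expect_error(
    filter_by_molecular_weight(recs, desc[-2, ], min_mw = 100), "B")
})

test_that("filters are subset operations whose reports compose", {
  lib <- generate_library(library_config(n_compounds = 60, n_planted = 5,
                                         seed = 11))
  s1 <- filter_by_class(lib$compounds, c("triacylglycerol", "diacylglycerol",
                                         "phosphatidylethanolamine"))
  s2 <- filter_inorganic(s1$records)
  s3 <- filter_by_molecular_weight(s2$records, lib$descriptors)
  reports <- list(s1$report, s2$report, s3$report)

  for (r in reports) {
    expect_equal(r$n_out, r$n_in - length(r$removed_ids))
  }
  # stages chain
  expect_equal(s1$report$n_out, s2$report$n_in)
  expect_equal(s2$report$n_out, s3$report$n_in)
  total_removed <- sum(vapply(reports, function(r) length(r$removed_ids), 0L))
  expect_equal(total_removed, nrow(lib$compounds) - nrow(s3$records))
  # subset property
  expect_true(all(s3$records$compound_id %in% lib$compounds$compound_id))
})

test_that("filtering commutes with row permutation", {
  lib <- generate_library(library_config(n_compounds = 40, n_planted = 4,
                                         seed = 5))
  perm <- sample(nrow(lib$compounds))
  shuffled <- lib$compounds[perm, ]
  class(shuffled) <- class(lib$compounds)
  a <- filter_by_class(lib$compounds, "triacylglycerol")
  b <- filter_by_class(shuffled, "triacylglycerol")
  expect_setequal(a$records$compound_id, b$records$compound_id)
  expect_setequal(a$report$removed_ids, b$report$removed_ids)
})

test_that("writing and re-reading a library reproduces identical records", {
  df <- basic_library_df()
  recs <- read_compound_table(write_temp_csv(df), format = "csv")
  out <- tempfile(fileext = ".csv")
  write_compound_table(recs, out)
  back <- read_compound_table(out, format = "csv")
  expect_equal(back$compound_id, recs$compound_id)
  expect_equal(back$smiles, recs$smiles)
  expect_equal(back$compound_class, recs$compound_class)
  expect_equal(back$parse_ok, recs$parse_ok)
})
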