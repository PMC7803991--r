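test_that("p-activity transform follows the molar convention", {
  expect_equal(to_p_activity(1), 9)
  expect_equal(to_p_activity(100000), 4)
  expect_equal(to_p_activity(10), 8)
  expect_error(to_p_activity(0), "positive")
  expect_error(to_p_activity(-5), "positive")
})

test_that("p-activity transform is strictly decreasing and invertible", {
  v <- sort(10^stats::runif(50, -2, 6))
  p <- to_p_activity(v)
  expect_true(all(diff(p) < 0))
  for (pp in seq(0, 12, by = 0.5)) {
    expect_equal(to_p_activity(10^(9 - pp)), pp, tolerance = 1e-9)
  }
})

test_that("record filtering applies every rule and itemizes drops", {
  tab <- hand_activity_fixture()
  res <- filter_records(tab)
  expect_equal(nrow(res$records), 7)
  expect_equal(unname(res$report[["low_confidence"]]), 2)
  expect_equal(unname(res$report[["units"]]), 1)
  expect_equal(unname(res$report[["activity_comment"]]), 1)
  expect_equal(unname(res$report[["potential_duplicate"]]), 1)
  # drops + survivors account for every input row
  expect_equal(sum(res$report), nrow(tab))
  # order preserved
  expect_equal(res$records$compound_id,
               c("c01", "c07", "c08", "c09", "c10", "c11", "c12"))
})

test_that("single-rule drops behave as specified", {
  tab <- hand_activity_fixture()[1, , drop = FALSE]
  low <- tab; low$confidence_score <- 5
  expect_equal(nrow(filter_records(low)$records), 0)
  fun <- tab; fun$assay_type <- "F"
  expect_equal(nrow(filter_records(fun)$records), 0)
})

test_that("filtering is idempotent", {
  tab <- hand_activity_fixture()
  once <- filter_records(tab)$records
  twice <- filter_records(once)$records
  expect_identical(once, twice)
})

test_that("filtering demands the full schema", {
  tab <- hand_activity_fixture()
  tab$standard_units <- NULL
  expect_error(filter_records(tab), "standard_units")
})

test_that("structure standardization strips salts and neutralizes", {
  res <- standardize_structure(c("CCO", "CC(=O)[O-].[Na+]", "C1CC"))
  expect_true(res$ok[1])
  expect_true(res$ok[2])
  expect_false(res$ok[3])
  expect_match(res$reason[3], "unparseable")
  # acetate salt becomes neutral acetic acid, same canonical form as CC(=O)O
  expect_equal(res$canonical_smiles[2],
               standardize_structure("CC(=O)O")$canonical_smiles)
  # ethanol unchanged in semantics
  expect_equal(res$canonical_smiles[1],
               standardize_structure("OCC")$canonical_smiles)
})

test_that("standardization is idempotent on its own outputs", {
  inputs <- c("Cc1ccccc1C(=O)[O-].[Na+]", "CC(C)O", "c1ccncc1.Cl",
              "C[NH3+].[Cl-]")
  first <- standardize_structure(inputs)
  again <- standardize_structure(first$canonical_smiles[first$ok])
  expect_identical(again$canonical_smiles,
                   first$canonical_smiles[first$ok])
})

test_that("over-long canonical SMILES are rejected", {
  long <- paste0("C", strrep("C", 1100))
  res <- standardize_structure(long)
  expect_false(res$ok)
  expect_match(res$reason, "1000")
})

test_that("duplicate aggregation keeps the most active record", {
  recs <- data.frame(
    canonical_smiles = c("S", "S"), p_activity = c(5.2, 6.8),
    relation = c("=", "="), target_id = "T", stringsAsFactors = FALSE)
  out <- aggregate_duplicates(recs)
  expect_equal(nrow(out), 1)
  expect_equal(out$p_activity, 6.8)
  # single record unchanged
  one <- recs[1, , drop = FALSE]
  expect_equal(aggregate_duplicates(one)$p_activity, 5.2)
  # tie broken by first occurrence
  tie <- data.frame(
    canonical_smiles = "S", p_activity = 7.0, relation = c("=", ">"),
    target_id = "T", stringsAsFactors = FALSE)
  expect_equal(aggregate_duplicates(tie)$relation, "=")
})

test_that("duplicate aggregation matches a brute-force grouping oracle", {
  withr::with_seed(4, {
    recs <- data.frame(
      canonical_smiles = sample(LETTERS[1:8], 60, replace = TRUE),
      p_activity = round(stats::runif(60, 4, 9), 3),
      relation = sample(c("=", ">", "<"), 60, replace = TRUE),
      target_id = sample(c("T1", "T2"), 60, replace = TRUE),
      stringsAsFactors = FALSE)
  })
  out <- aggregate_duplicates(recs)
  key <- paste(recs$canonical_smiles, recs$target_id)
  okey <- paste(out$canonical_smiles, out$target_id)
  expect_setequal(unique(key), okey)
  expect_lte(nrow(out), nrow(recs))
  oracle <- tapply(recs$p_activity, key, max)
  expect_equal(as.numeric(oracle[okey]), out$p_activity)
})

test_that("the full curation pipeline composes filter, standardize, aggregate", {
  res <- build_dataset(hand_activity_fixture())
  # 7 filter survivors minus one collapsed duplicate pair (c11/c12)
  expect_equal(nrow(res$dataset), 6)
  expect_equal(res$report$duplicate_collapsed, 1)
  # the collapsed pair kept the more active measurement (8 nM -> pIC50 ~8.1)
  iso <- standardize_structure("CC(C)O")$canonical_smiles
  expect_equal(res$dataset$p_activity[res$dataset$canonical_smiles == iso],
               to_p_activity(8))
  # censored relation retained as-is
  pyr <- standardize_structure("c1ccncc1")$canonical_smiles
  expect_equal(res$dataset$relation[res$dataset$canonical_smiles == pyr],
               ">")
})

test_that("an all-filtered table yields an empty dataset with a warning", {
  tab <- hand_activity_fixture()
  tab$confidence_score <- 0
  expect_warning(res <- build_dataset(tab), "empty")
  expect_equal(nrow(res$dataset), 0)
  expect_equal(sum(res$report$filter_drops), nrow(tab))
})

test_that("a clean generated table survives curation intact", {
  spec <- tiny_sar(n = 60, seed = 5)
  tab <- generate_activity_table(spec)
  res <- build_dataset(tab)
  expect_equal(nrow(res$dataset), 60)
  expect_equal(res$report$duplicate_collapsed, 0)
})
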