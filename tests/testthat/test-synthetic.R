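test_that("planted activity is additive over fragments and deterministic", {
  spec <- tiny_sar(seed = 1)
  # bare scaffold: baseline only
  bare <- molgcn:::assemble_molecule(spec, 3L, rep(NA_integer_, 3))
  expect_equal(true_activity(bare$smiles, spec), spec$baseline)
  # one fragment: baseline + its weight
  sub_i <- which(spec$substituents$fragment == "Cl")
  one <- molgcn:::assemble_molecule(spec, 3L, c(sub_i, NA, NA))
  expect_equal(true_activity(one$smiles, spec),
               spec$baseline + spec$substituents$w[sub_i])
  # deterministic
  expect_equal(true_activity(one$smiles, spec),
               true_activity(one$smiles, spec))
  # molecules outside the grammar are refused
  expect_error(true_activity("c1ccc(I)cc1CCCCCl", spec), "grammar")
})

test_that("grammar inversion recovers the generating composition exactly", {
  spec <- tiny_sar(n = 150, seed = 23)
  tab <- generate_activity_table(spec)
  truth <- attr(tab, "truth")
  expect_equal(true_activity(truth$smiles, spec), truth$p_true)
})

test_that("every scaffold template yields parseable molecules", {
  spec <- tiny_sar(seed = 1)
  n_sub <- nrow(spec$substituents)
  for (sc in seq_len(nrow(spec$scaffolds))) {
    n_slots <- molgcn:::template_slots(spec$scaffolds$template[sc])
    fills <- list(rep(NA_integer_, n_slots),
                  seq_len(min(n_slots, n_sub)),
                  rep(n_sub, n_slots))
    for (f in fills) {
      fill <- rep(NA_integer_, n_slots)
      fill[seq_along(f)] <- f
      smi <- molgcn:::assemble_molecule(spec, sc, fill)$smiles
      expect_false(is.na(molgcn:::ob_canonical(smi)),
                   label = paste("template", sc, "fill",
                                 paste(f, collapse = ",")))
    }
  }
})

test_that("generated tables are byte-identical under the same spec", {
  spec <- tiny_sar(n = 80, seed = 12, junk = 0.1, dup = 0.05)
  a <- generate_activity_table(spec)
  b <- generate_activity_table(spec)
  attr(a, "sar_spec") <- attr(b, "sar_spec") <- NULL
  attr(a, "truth") <- attr(b, "truth") <- NULL
  expect_identical(a, b)
  c2 <- generate_activity_table(tiny_sar(n = 80, seed = 13, junk = 0.1))
  expect_false(identical(a$smiles, c2$smiles))
})

test_that("junk and duplicate quotas are exact by construction", {
  spec <- sar_spec(n = 80, seed = 3, junk_fraction = 0.25,
                   duplicate_fraction = 0.1, noise_sd = 0.2)
  tab <- generate_activity_table(spec)
  expect_equal(nrow(tab), 80)
  res <- suppressWarnings(build_dataset(tab))
  # 80 - 20 junk - 8 duplicate re-measurements = 52 unique survivors
  expect_equal(nrow(res$dataset), 52)
})

test_that("the noiseless path reproduces true activities through curation", {
  spec <- sar_spec(n = 60, seed = 9, noise_sd = 0, junk_fraction = 0,
                   duplicate_fraction = 0, censor_fraction = 0)
  tab <- generate_activity_table(spec)
  res <- build_dataset(tab)
  truth <- attr(tab, "truth")
  m <- match(res$dataset$canonical_smiles, truth$canonical)
  expect_equal(res$dataset$p_activity, truth$p_true[m], tolerance = 1e-9)
})

test_that("censored rows carry bound relations at the assay limits", {
  spec <- sar_spec(n = 200, seed = 7, censor_fraction = 0.1,
                   junk_fraction = 0, duplicate_fraction = 0)
  tab <- generate_activity_table(spec)
  cens <- tab$standard_relation %in% c("<", ">")
  expect_gte(sum(cens), 20)
  expect_true(all(tab$standard_value[cens] %in% spec$v_limits))
  # ">" rows sit at the high-concentration (low-activity) limit
  expect_true(all(tab$standard_value[tab$standard_relation == ">"] ==
                    spec$v_limits[2]))
})

test_that("the reported activity range is controllable and reported", {
  spec <- tiny_sar(n = 150, seed = 2)
  truth <- attr(generate_activity_table(spec), "truth")
  rng <- range(truth$p_true)
  # the library spans roughly baseline +/- 3 x the largest |w|
  expect_gte(rng[1], spec$baseline - 4.5)
  expect_lte(rng[2], spec$baseline + 4.5)
  expect_gt(diff(rng), 1)  # enough spread to regress on
})

test_that("infeasible fraction combinations are rejected", {
  expect_error(sar_spec(junk_fraction = 0.6, duplicate_fraction = 0.5),
               "fraction")
})

test_that("scaffold-profile datasets realize the requested distribution", {
  ref <- generate_reference_skeletons(150)
  scheme <- build_binning(ref, capacity = 10)
  expect_equal(scheme$n_bins, 15)
  # point mass
  pm <- c(1, rep(0, 14))
  d <- generate_scaffold_profile(pm, scheme, n = 300, seed = 2)
  expect_equal(shannon_H(dataset_histogram(d, scheme)), 0)
  # uniform profile approaches the 15-bin entropy maximum
  du <- generate_scaffold_profile(rep(1 / 15, 15), scheme, n = 1e5, seed = 3)
  expect_lt(abs(shannon_H(dataset_histogram(du, scheme)) - 3.91), 0.05)
  # same profile, different seeds: different membership, similar histogram
  d1 <- generate_scaffold_profile(rep(1 / 15, 15), scheme, n = 2000, seed = 4)
  d2 <- generate_scaffold_profile(rep(1 / 15, 15), scheme, n = 2000, seed = 5)
  expect_false(identical(d1$canonical_smiles, d2$canonical_smiles))
  h1 <- dataset_histogram(d1, scheme); h2 <- dataset_histogram(d2, scheme)
  expect_lt(max(abs(h1$p - h2$p)), 0.05)
  expect_error(generate_scaffold_profile(rep(1 / 14, 14), scheme, 10, 1),
               "bin count")
})

test_that("the reference skeleton inventory is distinct and size-ordered", {
  ref <- generate_reference_skeletons(120)
  expect_equal(anyDuplicated(ref$skeleton_smiles), 0)
  expect_equal(nrow(ref), 120)
  sizes <- carbon_skeleton(ref$skeleton_smiles)$size
  expect_equal(sizes, ref$size)
})
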