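small_packed <- local({
  p <- NULL
  function() {
    if (is.null(p)) {
      d <- shared_curated
      p <<- list(
        tr = molgcn:::as_packed(d$canonical_smiles[1:80]),
        try = d$p_activity[1:80],
        va = molgcn:::as_packed(d$canonical_smiles[81:110]),
        vay = d$p_activity[81:110],
        te = molgcn:::as_packed(d$canonical_smiles[111:140]),
        tey = d$p_activity[111:140]
      )
    }
    p
  }
})

tiny_space <- search_space(conv_size = c(8, 24), dense_size = c(8, 24),
                           epochs = c(4, 8), batch_size = c(16, 32),
                           tiers = "1")

test_that("the search returns one max-2R2_MAE candidate per tier and repeat", {
  d <- small_packed()
  cands <- search_hyperparameters(d$tr, d$try, d$va, d$vay,
                                  space = tiny_space, n_iter = 2,
                                  n_repeats = 2, backend = "random",
                                  seed = 5)
  expect_s3_class(cands, "gcn_candidates")
  expect_equal(nrow(cands), 2)
  expect_equal(cands$tier, c("1", "1"))
  expect_equal(cands$repeat_id, 1:2)
  expect_true(all(is.finite(cands$valid_trmae)))
  # candidate metrics satisfy the 2R2_MAE identity
  expect_equal(cands$valid_trmae,
               compute_2r2_mae(cands$valid_r2, cands$valid_mae),
               tolerance = 1e-6)
})

test_that("the search is deterministic under a fixed master seed", {
  d <- small_packed()
  run <- function() search_hyperparameters(
    d$tr, d$try, d$va, d$vay, space = tiny_space, n_iter = 2, n_repeats = 1,
    backend = "random", seed = 11)
  expect_identical(as.data.frame(run()), as.data.frame(run()))
})

test_that("n_iter = 1 returns the single trial per repeat", {
  d <- small_packed()
  cands <- search_hyperparameters(d$tr, d$try, d$va, d$vay,
                                  space = tiny_space, n_iter = 1,
                                  n_repeats = 1, backend = "random",
                                  seed = 2)
  expect_equal(nrow(cands), 1)
})

test_that("the GP expected-improvement proposal stays in the unit cube", {
  withr::with_seed(3, {
    X <- matrix(stats::runif(30), 5, 6)
    y <- stats::runif(5)
    u <- molgcn:::propose_point(X, y, 6)
    expect_length(u, 6)
    expect_true(all(u >= 0 & u <= 1))
    # with too few observations the proposal is a random draw
    u2 <- molgcn:::propose_point(NULL, numeric(0), 6)
    expect_true(all(u2 >= 0 & u2 <= 1))
  })
})

test_that("gp_ei search runs end to end and improves over its trials", {
  d <- small_packed()
  cands <- search_hyperparameters(d$tr, d$try, d$va, d$vay,
                                  space = tiny_space, n_iter = 5,
                                  n_repeats = 1, backend = "gp_ei",
                                  seed = 7)
  expect_equal(nrow(cands), 1)
  expect_true(is.finite(cands$valid_mae))
})

test_that("tier retention rules reproduce the worked examples", {
  mk <- function(tier, r2) {
    data.frame(tier = tier, repeat_id = 1, n_conv_layers = 1, conv_size = 32,
               dense_size = 32, learning_rate = 1e-3, dropout = 0,
               batch_size = 32, epochs = 50, search_seed = 1,
               valid_mae = 0.5, valid_r2 = r2,
               valid_trmae = compute_2r2_mae(r2, 0.5),
               stringsAsFactors = FALSE)
  }
  # one shallow repeat above 0.45: no re-search
  t1 <- do.call(rbind, lapply(c(0.5, 0.3, 0.2, 0.1), mk, tier = "1"))
  res <- apply_tier_rules(t1)
  expect_false(res$tier1_research)
  expect_equal(nrow(res$retained), 4)
  # all shallow repeats below 0.45: flag re-search
  t1b <- do.call(rbind, lapply(c(0.44, 0.3, 0.2, 0.1), mk, tier = "1"))
  expect_true(apply_tier_rules(t1b)$tier1_research)
  # tier 2 floor at 0.40
  t2 <- rbind(mk("1", 0.5), mk("2", 0.39), mk("2", 0.40))
  r2 <- apply_tier_rules(t2)$retained
  expect_equal(r2$valid_r2[r2$tier == "2"], 0.40)
  # deep tier must beat every retained shallower candidate
  deep <- rbind(mk("1", 0.52), mk("3-4", 0.55))
  expect_true("3-4" %in% apply_tier_rules(deep)$retained$tier)
  deep2 <- rbind(mk("1", 0.56), mk("3-4", 0.55))
  expect_false("3-4" %in% apply_tier_rules(deep2)$retained$tier)
})

test_that("the reproducibility filter separates the quoted failure case", {
  # search R2 0.53 -> retrain 0.16 is dropped; 0.53 -> 0.50 is kept
  expect_equal(filter_reproducible(c(0.53, 0.53), c(0.16, 0.50)),
               c(FALSE, TRUE))
  # a vacuous tolerance keeps everything
  expect_true(all(filter_reproducible(c(0.9, 0.9), c(0.0, 0.2), delta = 1)))
})

test_that("max-2R2_MAE selection matches a brute-force scan", {
  withr::with_seed(29, {
    for (i in 1:20) {
      k <- sample(2:30, 1)
      r2 <- stats::runif(k, -0.5, 1)
      mae <- stats::runif(k, 0, 1.5)
      tr <- compute_2r2_mae(r2, mae)
      pick <- select_final_epoch(data.frame(epoch = seq_len(k), trmae = tr))
      brute <- which(tr == max(tr))[1]
      expect_equal(pick, brute)
    }
  })
})

test_that("ensembling averages members and obeys the MSE identity", {
  d <- small_packed()
  models <- lapply(1:3, function(s) {
    cfg <- gcn_config(conv_size = 12, dense_size = 12, learning_rate = 2e-3,
                      batch_size = 16, seed = s)
    gcn_fit(d$tr, d$try, d$va, d$vay, cfg, epochs = 6)
  })
  ens <- gcn_ensemble(models)
  pm <- ensemble_predict(models, d$te)
  expect_equal(pm[, "ensemble"],
               rowMeans(pm[, 1:3]), tolerance = 1e-12)
  expect_equal(predict(ens, d$te), pm[, "ensemble"])
  # single-member ensemble collapses to that member
  expect_equal(predict(gcn_ensemble(models[1]), d$te),
               predict(models[[1]], d$te))
  # exact property of mean ensembles: MSE <= mean member MSE
  mse <- function(f) mean((f - d$tey)^2)
  expect_lte(mse(pm[, "ensemble"]),
             mean(apply(pm[, 1:3], 2, mse)) + 1e-10)
  expect_error(gcn_ensemble(list()), "at least one")
})

test_that("averaging diverse members does not hurt the expected MAE", {
  d <- small_packed()
  viol <- 0
  for (s in 1:10) {
    models <- lapply(1:5, function(k) {
      cfg <- gcn_config(conv_size = 8 + 4 * k, dense_size = 8 + 2 * k,
                        learning_rate = 2e-3, batch_size = 16,
                        seed = 100 * s + k)
      gcn_fit(d$tr, d$try, d$va, d$vay, cfg, epochs = 12)
    })
    pm <- ensemble_predict(models, d$te)
    mae_e <- compute_mae(d$tey, pm[, "ensemble"])
    mae_m <- mean(apply(pm[, 1:5], 2, function(f) compute_mae(d$tey, f)))
    if (mae_e > mae_m) viol <- viol + 1
  }
  expect_lte(viol, 1)
})
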