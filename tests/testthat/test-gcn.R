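# The network itself is exercised through gcn_fit/predict; the reference
# forward pass in helper-fixtures.R re-implements conv, batch-norm, pooling,
# gathering and the output layer in plain R as an independent oracle.

fit_tiny <- function(smiles, y, vsm, vy, ...) {
  cfg <- gcn_config(conv_size = 16, dense_size = 16, learning_rate = 2e-3,
                    batch_size = 16, seed = 3, ...)
  gcn_fit(smiles, y, vsm, vy, cfg, epochs = 8)
}

tiny_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      d <- shared_curated
      m <<- fit_tiny(d$canonical_smiles[1:60], d$p_activity[1:60],
                     d$canonical_smiles[61:80], d$p_activity[61:80])
    }
    m
  }
})

test_that("the C++ forward pass matches the R reference implementation", {
  m <- tiny_model()
  smiles <- shared_curated$canonical_smiles[81:110]
  fb <- featurize_batch(smiles)
  expect_true(all(fb$ok))
  got <- predict(m, smiles)
  want <- ref_forward(m, fb$graphs)
  expect_equal(got, want, tolerance = 1e-4)
})

test_that("predictions are finite, deterministic and batch-consistent", {
  m <- tiny_model()
  smiles <- shared_curated$canonical_smiles[111:130]
  p1 <- predict(m, smiles)
  p2 <- predict(m, smiles)
  expect_true(all(is.finite(p1)))
  expect_identical(p1, p2)
  # batch prediction equals per-molecule prediction
  singles <- vapply(smiles, function(s) predict(m, s), numeric(1),
                    USE.NAMES = FALSE)
  expect_equal(p1, singles, tolerance = 1e-5)
  # identical molecules in one batch get identical predictions
  pd <- predict(m, c(smiles[1], smiles[1]))
  expect_equal(pd[1], pd[2])
})

test_that("node relabeling does not change the molecule prediction", {
  m <- tiny_model()
  pairs <- list(c("CCOC(=O)C1CCCC1", "C1CCC(C1)C(=O)OCC"),
                c("Cc1ccc(N)cc1", "Nc1ccc(C)cc1"),
                c("OCCN", "NCCO"))
  for (pr in pairs) {
    p <- predict(m, pr)
    expect_equal(p[1], p[2], tolerance = 1e-5)
  }
})

test_that("training is reproducible under a fixed seed", {
  d <- shared_curated
  a <- fit_tiny(d$canonical_smiles[1:50], d$p_activity[1:50],
                d$canonical_smiles[51:70], d$p_activity[51:70])
  b <- fit_tiny(d$canonical_smiles[1:50], d$p_activity[1:50],
                d$canonical_smiles[51:70], d$p_activity[51:70])
  expect_identical(a$trace, b$trace)
  expect_identical(predict(a, d$canonical_smiles[71:80]),
                   predict(b, d$canonical_smiles[71:80]))
})

test_that("final-epoch selection maximizes 2R2_MAE with earliest-tie rule", {
  tr <- data.frame(epoch = 1:3, trmae = c(0.1, 0.7, 0.7))
  expect_equal(select_final_epoch(tr), 2)
  tr2 <- data.frame(epoch = 1:4, trmae = c(0.1, 0.2, 0.3, 0.4))
  expect_equal(select_final_epoch(tr2), 4)
  expect_equal(select_final_epoch(data.frame(epoch = 1, trmae = 0.5)), 1)
})

test_that("the epoch-block stopping rule replays the worked examples", {
  # block minima 0.50, 0.48, 0.49 -> stop after epoch 300
  mae <- c(rep(0.50, 100), rep(0.48, 100), rep(0.49, 100), rep(0.47, 100))
  expect_equal(stopping_epoch(mae, block = 100), 300)
  # block minima 0.50 then 0.50 -> stop after epoch 200
  expect_equal(stopping_epoch(rep(0.5, 400), block = 100), 200)
  # monotone improvement runs to the end of the trace
  expect_equal(stopping_epoch(seq(1, 0.1, length.out = 300), block = 100),
               300)
})

test_that("block-rule training stops where an independent replay says", {
  d <- shared_curated
  cfg <- gcn_config(conv_size = 16, dense_size = 16, learning_rate = 2e-3,
                    batch_size = 16, seed = 9, max_epoch_block = 15)
  fit <- gcn_fit(d$canonical_smiles[1:60], d$p_activity[1:60],
                 d$canonical_smiles[61:80], d$p_activity[61:80], cfg)
  # independent replay of the block rule over the recorded trace
  replay <- function(mae, block) {
    rm <- Inf; ep <- 0
    while (ep < length(mae)) {
      bm <- min(mae[(ep + 1):min(ep + block, length(mae))])
      ep <- min(ep + block, length(mae))
      if (bm >= rm) break
      rm <- min(rm, bm)
    }
    ep
  }
  expect_equal(fit$stopped_epoch, replay(fit$trace$mae, 15))
  expect_equal(fit$stopped_epoch, stopping_epoch(fit$trace$mae, 15))
  # the retained snapshot is the max-2R2_MAE epoch
  expect_equal(fit$selected_epoch, select_final_epoch(fit$trace))
  # and the snapshot reproduces that epoch's validation MAE
  pv <- predict(fit, d$canonical_smiles[61:80])
  expect_equal(compute_mae(d$p_activity[61:80], pv),
               fit$trace$mae[fit$selected_epoch], tolerance = 1e-5)
})

test_that("a noiseless additive SAR is learnable to high fidelity", {
  # with no assay noise the only error source is generalization over the
  # scaffold/substituent grammar; 480 training compounds suffice for
  # validation R2 above 0.9 (at n = 300 the combinatorial diversity of the
  # grammar still leaves a generalization gap of ~0.2)
  spec <- sar_spec(n = 600, seed = 31, noise_sd = 0, junk_fraction = 0,
                   duplicate_fraction = 0, censor_fraction = 0)
  cur <- build_dataset(generate_activity_table(spec))$dataset
  sp <- split_dataset(cur, seed = 1)
  cfg <- gcn_config(conv_size = 128, dense_size = 128,
                    learning_rate = 1.5e-3, batch_size = 32, seed = 2)
  fit <- gcn_fit(sp$train$canonical_smiles, sp$train$p_activity,
                 sp$valid$canonical_smiles, sp$valid$p_activity, cfg)
  expect_gt(fit$valid_r2, 0.9)
})

test_that("test error approaches the noise floor as the sample grows", {
  # with sigma = 0.3 Gaussian noise the MAE of a perfect model is
  # sigma * sqrt(2/pi) ~ 0.239; at n = 1000 the fitted model should come
  # within 50% of that floor, and improve on the n = 100 fit
  floor_mae <- 0.3 * sqrt(2 / pi)
  run <- function(n, seed) {
    spec <- sar_spec(n = n, seed = seed, noise_sd = 0.3, junk_fraction = 0,
                     duplicate_fraction = 0, censor_fraction = 0)
    cur <- build_dataset(generate_activity_table(spec))$dataset
    sp <- split_dataset(cur, seed = 1)
    cfg <- gcn_config(conv_size = 64, dense_size = 64,
                      learning_rate = 1.5e-3, batch_size = 32, seed = 2)
    fit <- gcn_fit(sp$train$canonical_smiles, sp$train$p_activity,
                   sp$valid$canonical_smiles, sp$valid$p_activity, cfg)
    compute_mae(sp$test$p_activity,
                predict(fit, sp$test$canonical_smiles))
  }
  mae_small <- run(100, 51)
  mae_large <- run(1000, 51)
  expect_lt(mae_large, mae_small)
  expect_lt(mae_large, 1.5 * floor_mae)
})

test_that("invalid configurations are rejected", {
  expect_error(gcn_config(n_conv_layers = 5))
  expect_error(gcn_config(dropout = 0.9))
  expect_error(gcn_config(learning_rate = -1))
})

test_that("models round-trip through their portable file format", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".bin")
  write_gcn_model(m, path)
  m2 <- read_gcn_model(path)
  smiles <- shared_curated$canonical_smiles[1:10]
  expect_identical(predict(m, smiles), predict(m2, smiles))
  expect_identical(m2$selected_epoch, m$selected_epoch)
  tracecsv <- withr::local_tempfile(fileext = ".csv")
  write_trace(m, tracecsv)
  expect_equal(nrow(utils::read.csv(tracecsv)), nrow(m$trace))
})
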