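#' Default pipeline configuration
#'
#' Desk-scale defaults for the full modelling pipeline: curation, split,
#' tiered hyperparameter search (Gaussian-process expected improvement),
#' block-rule retraining of retained candidates, reproducibility filtering,
#' unweighted ensembling, and scaffold-diversity diagnostics.
#'
#' @param sar A [sar_spec()] to simulate from, or NULL when `input` is given.
#' @param input Path to a raw activity CSV (alternative to `sar`).
#' @param seed Master seed for split, search and retraining.
#' @param n_iter Search trials per tier and repeat.
#' @param n_repeats Weight-initialization repeats per tier.
#' @param space A [search_space()].
#' @param backend Search backend, `"gp_ei"` or `"random"`.
#' @param research_budget Extra trials when the shallow tier triggers an
#'   extended re-search.
#' @param delta Reproducibility-filter tolerance on validation R-squared.
#' @param bin_capacity Scaffolds per diversity bin.
#' @param reference_size Reference skeleton inventory size for binning.
#' @param out_dir Optional directory for persisted artifacts.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sar = sar_spec(), input = NULL, seed = 1L,
                            n_iter = 10L, n_repeats = 2L,
                            space = search_space(scale = "desk",
                                                 tiers = c("1", "2")),
                            backend = c("gp_ei", "random"),
                            research_budget = 10L, delta = 0.15,
                            bin_capacity = 10L, reference_size = 150L,
                            out_dir = NULL) {
  backend <- match.arg(backend)
  structure(list(sar = sar, input = input, seed = as.integer(seed),
                 n_iter = as.integer(n_iter),
                 n_repeats = as.integer(n_repeats), space = space,
                 backend = backend,
                 research_budget = as.integer(research_budget),
                 delta = delta, bin_capacity = as.integer(bin_capacity),
                 reference_size = as.integer(reference_size),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full modelling pipeline
#'
#' Executes, in order: data acquisition (simulation or CSV), curation,
#' two-stage splitting, featurization, tiered hyperparameter search, tier
#' retention rules (with optional extended re-search of the shallow tier),
#' fixed-seed block-rule retraining, reproducibility filtering, ensembling,
#' metric evaluation on all three subsets, and scaffold-diversity
#' diagnostics. Individual-model metrics are reported as mean +/- sd across
#' ensemble members.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit per-stage progress messages (default TRUE).
#' @return List of class `run_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  # ---- stage: data ----
  raw <- if (!is.null(config$input)) {
    say("[data] reading %s", config$input)
    read_activity_table(config$input)
  } else {
    say("[data] simulating %d rows (seed %d)", config$sar$n, config$sar$seed)
    generate_activity_table(config$sar)
  }

  # ---- stage: curation ----
  cur <- build_dataset(raw)
  say("[curate] %d raw rows -> %d compounds", nrow(raw), nrow(cur$dataset))

  # ---- stage: split ----
  split <- split_dataset(cur$dataset, seed = config$seed)
  say("[split] train %d / valid %d / test %d", nrow(split$train),
      nrow(split$valid), nrow(split$test))

  # ---- stage: featurize ----
  packs <- lapply(split[c("train", "valid", "test")],
                  function(d) as_packed(d$canonical_smiles))
  say("[featurize] %d + %d + %d molecules", packs$train$n_mols,
      packs$valid$n_mols, packs$test$n_mols)

  # ---- stage: search ----
  cands <- search_hyperparameters(
    packs$train, split$train$p_activity, packs$valid, split$valid$p_activity,
    space = config$space, n_iter = config$n_iter,
    n_repeats = config$n_repeats, backend = config$backend,
    seed = config$seed, verbose = verbose
  )
  rules <- apply_tier_rules(cands)
  if (rules$tier1_research && config$research_budget > 0) {
    say("[search] shallow tier below threshold; extended re-search (%d trials)",
        config$research_budget)
    sp1 <- config$space; sp1$tiers <- "1"
    extra <- search_hyperparameters(
      packs$train, split$train$p_activity, packs$valid,
      split$valid$p_activity, space = sp1,
      n_iter = config$research_budget, n_repeats = config$n_repeats,
      backend = config$backend, seed = config$seed + 1L, verbose = verbose
    )
    cands <- rbind(cands, extra)
    rules <- apply_tier_rules(cands)
  }
  retained <- rules$retained
  say("[search] %d candidate(s), %d retained by tier rules", nrow(cands),
      nrow(retained))
  if (nrow(retained) == 0L) {
    stop("no candidate survived the tier retention rules", call. = FALSE)
  }

  # ---- stage: retrain (block rule, fixed seed) ----
  models <- vector("list", nrow(retained))
  retrain_r2 <- numeric(nrow(retained))
  for (i in seq_len(nrow(retained))) {
    cfg <- gcn_config(
      n_conv_layers = retained$n_conv_layers[i],
      conv_size = retained$conv_size[i],
      dense_size = retained$dense_size[i],
      learning_rate = retained$learning_rate[i],
      dropout = retained$dropout[i], batch_size = retained$batch_size[i],
      seed = config$seed + 1000L + i
    )
    models[[i]] <- gcn_fit(packs$train, split$train$p_activity, packs$valid,
                           split$valid$p_activity, cfg)
    retrain_r2[i] <- models[[i]]$valid_r2
    say("[retrain] candidate %d/%d: %d epochs, valid R2 %.3f", i,
        nrow(retained), models[[i]]$stopped_epoch, retrain_r2[i])
  }

  # ---- stage: reproducibility filter ----
  keep <- filter_reproducible(retained$valid_r2, retrain_r2,
                              delta = config$delta)
  say("[ensemble] %d/%d model(s) reproduced the search performance",
      sum(keep), length(keep))
  if (!any(keep)) {
    warning("no retrained model reproduced its search performance; ",
            "keeping the best available model", call. = FALSE)
    keep <- seq_along(models) == which.max(retrain_r2)
  }
  members <- models[keep]
  ens <- gcn_ensemble(members)

  # ---- stage: evaluation ----
  eval_subset <- function(pack, y) {
    pm <- ensemble_predict(members, pack)
    memb <- pm[, seq_along(members), drop = FALSE]
    data.frame(
      mae_ensemble = compute_mae(y, pm[, "ensemble"]),
      rmse_ensemble = compute_rmse(y, pm[, "ensemble"]),
      r2_ensemble = compute_r2(y, pm[, "ensemble"]),
      mae_individual_mean = mean(apply(memb, 2, function(f)
        compute_mae(y, f))),
      mae_individual_sd = stats::sd(apply(memb, 2, function(f)
        compute_mae(y, f))),
      mse_ensemble = mean((pm[, "ensemble"] - y)^2),
      mse_individual_mean = mean(apply(memb, 2, function(f)
        mean((f - y)^2)))
    )
  }
  metrics <- rbind(
    train = eval_subset(packs$train, split$train$p_activity),
    valid = eval_subset(packs$valid, split$valid$p_activity),
    test = eval_subset(packs$test, split$test$p_activity)
  )
  metrics <- cbind(subset = rownames(metrics), metrics)
  rownames(metrics) <- NULL
  say("[evaluate] test: ensemble MAE %.3f, R2 %.3f",
      metrics$mae_ensemble[3], metrics$r2_ensemble[3])

  # ---- stage: diversity ----
  ref <- generate_reference_skeletons(config$reference_size)
  scheme <- build_binning(ref, capacity = config$bin_capacity)
  diversity <- diversity_report(split, scheme)

  report <- structure(list(
    seed = config$seed,
    curation = cur$report,
    split_sizes = c(train = nrow(split$train), valid = nrow(split$valid),
                    test = nrow(split$test)),
    candidates = as.data.frame(cands),
    retained = as.data.frame(retained),
    retrain_r2 = retrain_r2,
    reproducible = keep,
    metrics = metrics,
    diversity = diversity,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    ensemble = ens,
    split = split
  ), class = "run_report")

  if (!is.null(config$out_dir)) persist_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run report (seed", x$seed, ")\n")
  cat(sprintf("  compounds: %d (train %d / valid %d / test %d)\n",
              sum(x$split_sizes), x$split_sizes["train"],
              x$split_sizes["valid"], x$split_sizes["test"]))
  cat(sprintf("  ensemble members: %d of %d candidates\n",
              sum(x$reproducible), nrow(x$candidates)))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf(
      "  %-5s  MAE %.3f  RMSE %.3f  R2 %.3f  (individual MAE %.3f +/- %.3f)\n",
      m$subset[i], m$mae_ensemble[i], m$rmse_ensemble[i], m$r2_ensemble[i],
      m$mae_individual_mean[i], m$mae_individual_sd[i]))
  }
  d <- x$diversity
  cat("  diversity:",
      paste(sprintf("%s H=%.2f KLD=%.3f", d$subset, d$H, d$KLD_vs_full),
            collapse = "; "), "\n")
  cat(sprintf("  runtime: %.1f s\n", x$runtime_s))
  invisible(x)
}

# Persist the machine-readable parts of a run report.
persist_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$candidates, file.path(out_dir, "candidates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$diversity, file.path(out_dir, "diversity.csv"),
                   row.names = FALSE)
  json <- report[c("seed", "curation", "split_sizes", "retrain_r2",
                   "reproducible", "runtime_s")]
  json$metrics <- report$metrics
  json$diversity <- report$diversity
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; keys mirror the arguments of [pipeline_config()],
#'   with `sar` and `space` given as nested maps.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sar)) {
    # YAML 1.1 reads a bare key "n" as boolean FALSE; map it back
    names(y$sar)[names(y$sar) == "FALSE"] <- "n"
  }
  sar <- if (!is.null(y$sar)) do.call(sar_spec, y$sar) else sar_spec()
  space <- if (!is.null(y$space)) do.call(search_space, y$space)
    else search_space(scale = "desk", tiers = c("1", "2"))
  args <- y[setdiff(names(y), c("sar", "space"))]
  do.call(pipeline_config, c(list(sar = sar, space = space), args))
}
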