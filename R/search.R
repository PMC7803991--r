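#' Hyperparameter search space
#'
#' Ranges over which the network hyperparameters are explored. Three presets
#' are provided: `"paper"` (the full benchmark ranges: conv and dense sizes
#' up to 2048), `"small"` (the reduced ranges used for small datasets, sizes
#' up to 512), and `"desk"` (the package default for synthetic desk-scale
#' problems, sizes up to 64 and epochs up to 80 — a planted additive
#' structure-activity relationship needs far less network capacity than the
#' real assay panels the larger ranges address). Sizes and the learning rate
#' are sampled log-uniformly, other parameters uniformly.
#'
#' @param scale One of `"desk"`, `"small"`, `"paper"`.
#' @param conv_size,dense_size,learning_rate,dropout,epochs,batch_size
#'   Optional length-2 numeric ranges overriding the preset.
#' @param tiers Layer-count tiers to search; subset of
#'   `c("1", "2", "3-4")`. The "3-4" tier samples the layer count from {3,4}.
#' @return List of class `search_space`.
#' @export
search_space <- function(scale = c("desk", "small", "paper"),
                         conv_size = NULL, dense_size = NULL,
                         learning_rate = NULL, dropout = NULL, epochs = NULL,
                         batch_size = NULL, tiers = c("1", "2")) {
  scale <- match.arg(scale)
  preset <- switch(scale,
    paper = list(conv_size = c(32, 2048), dense_size = c(16, 2048),
                 epochs = c(20, 200), batch_size = c(10, 100)),
    small = list(conv_size = c(16, 512), dense_size = c(16, 512),
                 epochs = c(20, 200), batch_size = c(10, 100)),
    desk = list(conv_size = c(16, 64), dense_size = c(16, 64),
                epochs = c(20, 80), batch_size = c(32, 100))
  )
  sp <- list(
    conv_size = conv_size %||% preset$conv_size,
    dense_size = dense_size %||% preset$dense_size,
    learning_rate = learning_rate %||% c(1e-4, 2e-3),
    dropout = dropout %||% c(0, 0.5),
    epochs = epochs %||% preset$epochs,
    batch_size = batch_size %||% preset$batch_size,
    tiers = match.arg(tiers, c("1", "2", "3-4"), several.ok = TRUE)
  )
  for (nm in setdiff(names(sp), "tiers")) {
    if (sp[[nm]][1] > sp[[nm]][2]) {
      stop("lower bound exceeds upper bound for ", nm, call. = FALSE)
    }
  }
  structure(sp, class = "search_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Unit-cube encoding of a trial point. Dimensions: conv, dense (log2), lr
# (log), dropout, epochs, batch (linear); tier "3-4" adds a layer dimension.
space_dim <- function(tier) if (tier == "3-4") 7L else 6L

decode_point <- function(u, space, tier) {
  geo <- function(r, t) round(exp(log(r[1]) + t * (log(r[2]) - log(r[1]))))
  lin <- function(r, t) r[1] + t * (r[2] - r[1])
  layers <- switch(tier, "1" = 1L, "2" = 2L, "3-4" = if (u[7] < 0.5) 3L else 4L)
  list(
    n_conv_layers = layers,
    conv_size = as.integer(geo(space$conv_size, u[1])),
    dense_size = as.integer(geo(space$dense_size, u[2])),
    learning_rate = exp(lin(log(space$learning_rate), u[3])),
    dropout = lin(space$dropout, u[4]),
    epochs = as.integer(round(lin(space$epochs, u[5]))),
    batch_size = as.integer(round(lin(space$batch_size, u[6])))
  )
}

# Matern 5/2 covariance on scaled distances.
matern52 <- function(X1, X2, lengthscale) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d <- sqrt(pmax(d2, 0))
  r <- sqrt(5) * d / lengthscale
  (1 + r + r^2 / 3) * exp(-r)
}

# Propose the next trial point by expected improvement under a GP posterior
# fitted to the observed (point, objective) pairs; the objective is
# minimized. Falls back to random draws while fewer than 4 observations
# exist. All randomness comes from the current RNG state.
propose_point <- function(X_obs, y_obs, dim, n_cand = 256L,
                          lengthscale = 0.5) {
  cand <- matrix(stats::runif(n_cand * dim), n_cand, dim)
  if (is.null(X_obs) || nrow(X_obs) < 4L) {
    return(cand[1L, ])
  }
  mu0 <- mean(y_obs); sd0 <- stats::sd(y_obs)
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- 1
  z <- (y_obs - mu0) / sd0
  K <- matern52(X_obs, X_obs, lengthscale)
  diag(K) <- diag(K) + 1e-6
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, z, transpose = TRUE))
  Ks <- matern52(cand, X_obs, lengthscale)
  mu <- as.numeric(Ks %*% alpha)
  v <- backsolve(L, t(Ks), transpose = TRUE)
  s2 <- pmax(1 - colSums(v^2), 1e-12)
  s <- sqrt(s2)
  fbest <- min(z)
  imp <- fbest - mu
  zz <- imp / s
  ei <- imp * stats::pnorm(zz) + s * stats::dnorm(zz)
  cand[which.max(ei), ]
}

#' Hyperparameter search for the GCN regressor
#'
#' For each layer-count tier and each repeat (distinct weight-initialization
#' seed), runs `n_iter` training trials chosen either by Gaussian-process
#' Bayesian optimization (Matern 5/2 kernel, expected-improvement
#' acquisition, minimizing validation MAE) or uniformly at random. Each trial
#' trains for its sampled epoch count. From each repeat's trials, the
#' candidate maximizing the validation 2R2_MAE is returned.
#'
#' @param train_x,train_y,valid_x,valid_y Training and validation molecules
#'   (SMILES, `mol_graph` lists, or packed graphs) and responses.
#' @param space A [search_space()].
#' @param n_iter Trials per tier and repeat.
#' @param n_repeats Weight-initialization repeats per tier.
#' @param backend `"gp_ei"` or `"random"`.
#' @param seed Master seed; all trial sampling and weight seeds derive from
#'   it.
#' @param verbose Emit per-trial progress messages.
#' @return Data frame of class `gcn_candidates`: one row per (tier, repeat)
#'   with the winning configuration and its validation metrics.
#' @export
search_hyperparameters <- function(train_x, train_y, valid_x, valid_y,
                                   space = search_space(), n_iter = 10L,
                                   n_repeats = 2L,
                                   backend = c("gp_ei", "random"),
                                   seed = 1L, verbose = FALSE) {
  backend <- match.arg(backend)
  tr <- as_packed(train_x); va <- as_packed(valid_x)
  out <- list()
  for (tier in space$tiers) {
    for (rep_i in seq_len(n_repeats)) {
      init_seed <- as.integer((seed * 131L + match(tier, c("1", "2", "3-4")) *
                                 17L + rep_i) %% .Machine$integer.max)
      dim <- space_dim(tier)
      X_obs <- NULL; trials <- list()
      for (it in seq_len(n_iter)) {
        u <- withr::with_seed(init_seed + 7919L * it, {
          if (backend == "random") stats::runif(dim)
          else propose_point(X_obs, vapply(trials, `[[`, numeric(1),
                                           "valid_mae"), dim)
        })
        cfg_par <- decode_point(u, space, tier)
        cfg <- gcn_config(
          n_conv_layers = cfg_par$n_conv_layers,
          conv_size = cfg_par$conv_size, dense_size = cfg_par$dense_size,
          learning_rate = cfg_par$learning_rate, dropout = cfg_par$dropout,
          batch_size = cfg_par$batch_size, seed = init_seed
        )
        fit <- tryCatch(
          gcn_fit(tr, train_y, va, valid_y, cfg, epochs = cfg_par$epochs),
          error = function(e) NULL
        )
        if (is.null(fit)) next
        last <- nrow(fit$trace)
        trial <- list(
          config = cfg, epochs = cfg_par$epochs,
          valid_mae = fit$trace$mae[last], valid_r2 = fit$trace$r2[last],
          valid_trmae = fit$trace$trmae[last]
        )
        trials[[length(trials) + 1L]] <- trial
        X_obs <- rbind(X_obs, u)
        if (verbose) {
          message(sprintf(
            "tier %s repeat %d trial %d: conv %d dense %d -> MAE %.3f R2 %.3f",
            tier, rep_i, it, cfg$conv_size, cfg$dense_size, trial$valid_mae,
            trial$valid_r2))
        }
      }
      if (length(trials) == 0L) {
        warning(sprintf("all trials failed for tier %s repeat %d", tier,
                        rep_i), call. = FALSE)
        next
      }
      best <- trials[[which.max(vapply(trials, `[[`, numeric(1),
                                       "valid_trmae"))]]
      out[[length(out) + 1L]] <- data.frame(
        tier = tier, repeat_id = rep_i,
        n_conv_layers = best$config$n_conv_layers,
        conv_size = best$config$conv_size,
        dense_size = best$config$dense_size,
        learning_rate = best$config$learning_rate,
        dropout = best$config$dropout, batch_size = best$config$batch_size,
        epochs = best$epochs, search_seed = best$config$seed,
        valid_mae = best$valid_mae, valid_r2 = best$valid_r2,
        valid_trmae = best$valid_trmae,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    warning("hyperparameter search produced no candidates", call. = FALSE)
    return(structure(data.frame(), class = c("gcn_candidates", "data.frame")))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("gcn_candidates", "data.frame"))
}

#' Tiered candidate retention rules
#'
#' Applies the per-architecture retention rules to the best candidate of each
#' (tier, repeat):
#' * tier "1": candidates are retained; if all repeats' validation R-squared
#'   values fall below `research_threshold` (default 0.45), the tier is
#'   flagged for an extended re-search.
#' * tier "2": a candidate is retained when its R-squared is at least
#'   `retain_threshold` (default 0.40).
#' * tier "3-4": a candidate is retained only when its R-squared exceeds
#'   every retained shallower candidate's R-squared.
#'
#' @param candidates A `gcn_candidates` data frame.
#' @param research_threshold Tier-1 re-search trigger (default 0.45).
#' @param retain_threshold Tier-2 retention floor (default 0.40).
#' @return List with `retained` (candidate rows that survive) and
#'   `tier1_research` (logical: extended re-search recommended).
#' @export
apply_tier_rules <- function(candidates, research_threshold = 0.45,
                             retain_threshold = 0.40) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) {
    return(list(retained = candidates, tier1_research = FALSE))
  }
  keep <- logical(nrow(candidates))
  t1 <- candidates$tier == "1"
  keep[t1] <- TRUE
  tier1_research <- any(t1) && all(candidates$valid_r2[t1] <
                                     research_threshold)
  t2 <- candidates$tier == "2"
  keep[t2] <- candidates$valid_r2[t2] >= retain_threshold
  shallower_max <- suppressWarnings(
    max(candidates$valid_r2[(t1 | t2) & keep], -Inf))
  t34 <- candidates$tier == "3-4"
  keep[t34] <- candidates$valid_r2[t34] > shallower_max
  list(retained = candidates[keep, , drop = FALSE],
       tier1_research = tier1_research)
}

#' Reproducibility filter for retrained candidates
#'
#' A candidate whose fixed-seed retraining fails to reproduce its search-time
#' validation performance within `delta` is excluded from the ensemble: keep
#' when `retrain_r2 >= search_r2 - delta`.
#'
#' @param search_r2 Validation R-squared observed during the search.
#' @param retrain_r2 Validation R-squared after retraining.
#' @param delta Allowed degradation (default 0.15).
#' @return Logical vector: TRUE where the candidate is kept.
#' @export
filter_reproducible <- function(search_r2, retrain_r2, delta = 0.15) {
  stopifnot(length(search_r2) == length(retrain_r2))
  retrain_r2 >= search_r2 - delta
}

#' Unweighted ensemble of GCN models
#'
#' @param models List of fitted `gcn_model` objects.
#' @return Object of class `gcn_ensemble`.
#' @export
gcn_ensemble <- function(models) {
  if (length(models) < 1L) stop("ensemble needs at least one model",
                                call. = FALSE)
  stopifnot(all(vapply(models, inherits, logical(1), "gcn_model")))
  structure(list(models = models), class = "gcn_ensemble")
}

#' Ensemble prediction by unweighted averaging
#'
#' @param object A `gcn_ensemble`.
#' @param newdata Molecules (see [predict.gcn_model()]).
#' @param ... Unused.
#' @return Numeric vector: the arithmetic mean of member predictions.
#' @export
predict.gcn_ensemble <- function(object, newdata, ...) {
  pk <- as_packed(newdata)
  preds <- vapply(object$models, function(m) predict(m, pk),
                  numeric(pk$n_mols))
  if (pk$n_mols == 1L) preds <- matrix(preds, nrow = 1L)
  rowMeans(preds)
}

#' @export
print.gcn_ensemble <- function(x, ...) {
  cat(sprintf("GCN ensemble of %d member model(s)\n", length(x$models)))
  for (m in x$models) {
    cat(sprintf("  - %d conv x %d, dense %d: valid MAE %.3f, R2 %.3f\n",
                m$config$n_conv_layers, m$config$conv_size,
                m$config$dense_size, m$valid_mae, m$valid_r2))
  }
  invisible(x)
}

#' Member-wise and ensemble predictions
#'
#' @param models List of `gcn_model`s or a `gcn_ensemble`.
#' @param newdata Molecules.
#' @return Matrix with one column per member plus attribute-free ensemble
#'   mean in column `"ensemble"`.
#' @export
ensemble_predict <- function(models, newdata) {
  if (inherits(models, "gcn_ensemble")) models <- models$models
  if (length(models) < 1L) stop("no models supplied", call. = FALSE)
  pk <- as_packed(newdata)
  preds <- vapply(models, function(m) predict(m, pk), numeric(pk$n_mols))
  if (pk$n_mols == 1L) preds <- matrix(preds, nrow = 1L)
  colnames(preds) <- paste0("member_", seq_along(models))
  cbind(preds, ensemble = rowMeans(preds))
}
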