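#' @useDynLib molgcn, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Configuration of the graph convolutional regressor
#'
#' @param n_conv_layers Number of graph-convolution blocks (1-4).
#' @param conv_size Width of each convolution layer.
#' @param dense_size Width of the atomwise dense layer feeding the gather.
#' @param learning_rate Adam step size.
#' @param dropout Dropout probability on the dense layer, in [0, 0.5].
#' @param batch_size Molecules per gradient step.
#' @param max_epoch_block Epochs per stopping-rule block (default 100).
#' @param seed Integer seed for weight initialization, shuffling and dropout.
#' @return List of class `gcn_config`.
#' @export
gcn_config <- function(n_conv_layers = 1L, conv_size = 64L, dense_size = 64L,
                       learning_rate = 1e-3, dropout = 0, batch_size = 48L,
                       max_epoch_block = 100L, seed = 1L) {
  stopifnot(n_conv_layers %in% 1:4, conv_size >= 1, dense_size >= 1,
            learning_rate > 0, dropout >= 0, dropout <= 0.5, batch_size >= 1,
            max_epoch_block >= 1)
  structure(list(
    n_conv_layers = as.integer(n_conv_layers),
    conv_size = as.integer(conv_size),
    dense_size = as.integer(dense_size),
    learning_rate = learning_rate,
    dropout = dropout,
    batch_size = as.integer(batch_size),
    max_epoch_block = as.integer(max_epoch_block),
    seed = as.integer(seed)
  ), class = "gcn_config")
}

#' @export
print.gcn_config <- function(x, ...) {
  cat(sprintf(
    "GCN config: %d conv layer(s) x %d, dense %d, lr %.2g, dropout %.2f, batch %d, seed %d\n",
    x$n_conv_layers, x$conv_size, x$dense_size, x$learning_rate, x$dropout,
    x$batch_size, x$seed))
  invisible(x)
}

as_packed <- function(x) {
  if (is.list(x) && !is.null(x$X) && !is.null(x$mol_ptr)) return(x)
  if (is.character(x)) {
    fb <- featurize_batch(x)
    if (any(!fb$ok)) {
      stop("unparseable SMILES at position(s): ",
           paste(utils::head(which(!fb$ok), 5), collapse = ", "),
           call. = FALSE)
    }
    return(pack_graphs(fb$graphs))
  }
  if (is.list(x) && all(vapply(x, inherits, logical(1), "mol_graph"))) {
    return(pack_graphs(x))
  }
  stop("`x` must be SMILES, a list of mol_graph, or a packed graph set",
       call. = FALSE)
}

#' Fit a graph convolutional activity regressor
#'
#' Trains the network with Adam to minimize mean-squared error on the
#' training molecules, evaluating MAE, R-squared and the 2R2_MAE score on the
#' validation set after every epoch (inference mode: running batch-norm
#' statistics, dropout off). Two stopping regimes are available:
#'
#' * `epochs = NULL` (default): the epoch-block rule. Training proceeds in
#'   blocks of `config$max_epoch_block` epochs and stops when the running
#'   minimum validation MAE fails to decrease during a block; there is no
#'   upper limit on the total number of epochs.
#' * `epochs = k`: exactly `k` epochs (used by the hyperparameter search,
#'   where the epoch count is itself a searched value).
#'
#' The returned model carries the weight snapshot of the epoch with the
#' maximum validation 2R2_MAE (earliest epoch on ties), which is the state
#' used by [predict.gcn_model()].
#'
#' @param x Training molecules: SMILES vector, list of `mol_graph`, or a
#'   packed graph set.
#' @param y Observed p-activity values, one per training molecule.
#' @param valid_x,valid_y Validation molecules and observations.
#' @param config A [gcn_config()].
#' @param epochs Fixed epoch count, or NULL for the block stopping rule.
#' @return Object of class `gcn_model`.
#' @export
gcn_fit <- function(x, y, valid_x, valid_y, config = gcn_config(),
                    epochs = NULL) {
  stopifnot(inherits(config, "gcn_config"))
  tr <- as_packed(x)
  va <- as_packed(valid_x)
  y <- as.numeric(y); valid_y <- as.numeric(valid_y)
  if (length(y) != tr$n_mols || length(valid_y) != va$n_mols) {
    stop("response length does not match molecule count", call. = FALSE)
  }

  state <- cpp_gcn_init(75L, config$n_conv_layers, config$conv_size,
                        config$dense_size, config$seed)
  weights <- state$weights; rstats <- state$rstats; opt <- NULL

  trace <- data.frame(epoch = integer(0), mae = numeric(0), r2 = numeric(0),
                      trmae = numeric(0))
  best <- list(trmae = -Inf, epoch = NA_integer_, weights = NULL,
               rstats = NULL)
  block <- config$max_epoch_block
  fixed <- !is.null(epochs)
  total <- 0L
  running_min <- Inf
  repeat {
    n_ep <- if (fixed) min(block, epochs - total) else block
    if (n_ep <= 0L) break
    res <- cpp_gcn_train(
      weights, rstats, opt, config$n_conv_layers,
      tr$X, tr$mol_ptr, tr$edges, y,
      va$X, va$mol_ptr, va$edges, valid_y,
      config$learning_rate, config$dropout, config$batch_size, n_ep,
      config$seed + total
    )
    if (isTRUE(res$diverged)) {
      stop("training diverged to a non-finite loss; reduce the learning rate",
           call. = FALSE)
    }
    weights <- res$weights; rstats <- res$rstats; opt <- res$opt
    trace <- rbind(trace, data.frame(
      epoch = total + seq_len(n_ep), mae = res$val_mae, r2 = res$val_r2,
      trmae = res$val_trmae))
    if (res$best_epoch > 0 && res$best_trmae > best$trmae) {
      best <- list(trmae = res$best_trmae, epoch = total + res$best_epoch,
                   weights = res$best_weights, rstats = res$best_rstats)
    }
    total <- total + n_ep
    if (fixed) {
      if (total >= epochs) break
    } else {
      block_min <- min(trace$mae[trace$epoch > total - block])
      if (block_min >= running_min) break
      running_min <- min(running_min, block_min)
    }
  }

  if (!is.finite(best$trmae)) {
    stop("no epoch produced finite validation metrics ",
         "(is the validation response constant?)", call. = FALSE)
  }
  structure(list(
    call_epochs = epochs,
    weights = best$weights, rstats = best$rstats, config = config,
    trace = trace, selected_epoch = best$epoch, stopped_epoch = total,
    final_weights = weights, final_rstats = rstats,
    n_train = tr$n_mols, n_valid = va$n_mols,
    valid_mae = trace$mae[best$epoch], valid_r2 = trace$r2[best$epoch],
    valid_trmae = trace$trmae[best$epoch]
  ), class = "gcn_model")
}

#' Epoch of maximum validation 2R2_MAE
#'
#' @param trace A training trace data frame (columns `epoch`, `trmae`), or a
#'   `gcn_model`.
#' @return The earliest epoch attaining the maximum 2R2_MAE.
#' @export
select_final_epoch <- function(trace) {
  if (inherits(trace, "gcn_model")) trace <- trace$trace
  stopifnot(nrow(trace) >= 1L)
  trace$epoch[which.max(trace$trmae)]
}

#' Stopping epoch under the epoch-block rule
#'
#' Replays a per-epoch validation MAE sequence through the block stopping
#' rule: training runs in blocks of `block` epochs and stops at the end of
#' the first block whose minimum fails to improve on the running minimum of
#' all previous blocks.
#'
#' @param val_mae Numeric vector of per-epoch validation MAE.
#' @param block Block length in epochs (default 100).
#' @return The stopping epoch (a multiple of `block`, capped at the trace
#'   length).
#' @export
stopping_epoch <- function(val_mae, block = 100L) {
  n <- length(val_mae)
  running_min <- Inf
  ep <- 0L
  while (ep < n) {
    hi <- min(ep + block, n)
    block_min <- min(val_mae[(ep + 1L):hi])
    ep <- hi
    if (block_min >= running_min) return(ep)
    running_min <- min(running_min, block_min)
  }
  ep
}

#' Predict p-activity for new molecules
#'
#' @param object A fitted `gcn_model`.
#' @param newdata SMILES vector, list of `mol_graph`, or packed graph set.
#' @param ... Unused.
#' @return Numeric vector of predicted p-activity values.
#' @export
predict.gcn_model <- function(object, newdata, ...) {
  pk <- as_packed(newdata)
  as.numeric(cpp_gcn_predict(object$weights, object$rstats,
                             object$config$n_conv_layers,
                             pk$X, pk$mol_ptr, pk$edges))
}

#' @export
print.gcn_model <- function(x, ...) {
  cat("Graph convolutional activity regressor\n")
  print(x$config)
  cat(sprintf("  trained %d epochs (stopped by %s); selected epoch %d\n",
              x$stopped_epoch,
              if (is.null(x$call_epochs)) "block rule" else "fixed budget",
              x$selected_epoch))
  cat(sprintf("  validation: MAE %.3f, R2 %.3f, 2R2_MAE %.3f\n",
              x$valid_mae, x$valid_r2, x$valid_trmae))
  invisible(x)
}

#' @export
summary.gcn_model <- function(object, ...) {
  cat("Graph convolutional activity regressor\n\n")
  print(object$config)
  cat(sprintf("Training molecules: %d; validation molecules: %d\n",
              object$n_train, object$n_valid))
  cat(sprintf("Epochs trained: %d; selected epoch (max 2R2_MAE): %d\n",
              object$stopped_epoch, object$selected_epoch))
  cat("\nValidation metrics at the selected epoch:\n")
  print(round(c(MAE = object$valid_mae, R2 = object$valid_r2,
                `2R2_MAE` = object$valid_trmae), 4))
  invisible(object)
}

#' Plot the validation-metric training trace
#'
#' @param x A `gcn_model`.
#' @param ... Passed to [plot()].
#' @export
plot.gcn_model <- function(x, ...) {
  tr <- x$trace
  graphics::plot(tr$epoch, tr$mae, type = "l", xlab = "epoch",
                 ylab = "validation MAE", ...)
  graphics::abline(v = x$selected_epoch, lty = 2, col = "grey40")
  invisible(x)
}

#' Residuals of a fitted GCN model on a labelled set
#'
#' @param object A `gcn_model`.
#' @param newdata Molecules (see [predict.gcn_model()]).
#' @param y Observed values.
#' @param ... Unused.
#' @return `y - prediction`.
#' @export
residuals.gcn_model <- function(object, newdata, y, ...) {
  as.numeric(y) - predict(object, newdata)
}

#' Save a fitted GCN model to a single portable file
#'
#' The file holds a versioned list: format version, configuration, the
#' selected-epoch weight arrays and batch-norm statistics, and the training
#' trace.
#'
#' @param model A `gcn_model`.
#' @param path Output file path.
#' @export
write_gcn_model <- function(model, path) {
  stopifnot(inherits(model, "gcn_model"))
  obj <- list(format = "molgcn-gcn", version = 1L,
              config = unclass(model$config), weights = model$weights,
              rstats = model$rstats, trace = model$trace,
              selected_epoch = model$selected_epoch,
              stopped_epoch = model$stopped_epoch)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a GCN model saved by [write_gcn_model()]
#'
#' @param path File path.
#' @return A `gcn_model` usable with [predict.gcn_model()].
#' @export
read_gcn_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "molgcn-gcn")) {
    stop("not a molgcn model file: ", path, call. = FALSE)
  }
  structure(list(
    weights = obj$weights, rstats = obj$rstats,
    config = structure(obj$config, class = "gcn_config"),
    trace = obj$trace, selected_epoch = obj$selected_epoch,
    stopped_epoch = obj$stopped_epoch,
    n_train = NA_integer_, n_valid = NA_integer_,
    valid_mae = obj$trace$mae[obj$selected_epoch],
    valid_r2 = obj$trace$r2[obj$selected_epoch],
    valid_trmae = obj$trace$trmae[obj$selected_epoch]
  ), class = "gcn_model")
}

#' Write a training trace as CSV
#' @param model A `gcn_model` (or its trace data frame).
#' @param path Output file path.
#' @export
write_trace <- function(model, path) {
  tr <- if (inherits(model, "gcn_model")) model$trace else model
  utils::write.csv(tr, path, row.names = FALSE)
  invisible(path)
}
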