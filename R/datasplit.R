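#' Two-stage random train/validation/test split
#'
#' Splits a curated dataset into a training-validation part (fraction `f1`,
#' default 90%) and a test part, then splits the former into training
#' (fraction `f2`, default 88.8%) and validation parts, giving an
#' approximately 80:10:10 partition. Subset sizes use round-half-away-from-
#' zero on the test count first, then the validation count. Membership is a
#' uniformly random permutation determined entirely by `seed` (applied to the
#' dataset in a key-normalized order, so storage order does not matter).
#'
#' @param dataset Curated data frame with `canonical_smiles` and `target_id`
#'   columns (one row per compound-target pair).
#' @param seed Integer seed controlling the permutation.
#' @param f1 First-stage training-validation fraction (default 0.90).
#' @param f2 Second-stage training fraction (default 0.888).
#' @return List of class `split_result` with data frames `train`, `valid`,
#'   `test`, plus `seed` and `fractions`.
#' @export
split_dataset <- function(dataset, seed, f1 = 0.90, f2 = 0.888) {
  stopifnot(is.data.frame(dataset))
  n <- nrow(dataset)
  if (n < 3L) stop("need at least 3 records to populate three subsets",
                   call. = FALSE)
  if (!(f1 > 0 && f1 < 1 && f2 > 0 && f2 < 1)) {
    stop("split fractions must lie strictly between 0 and 1", call. = FALSE)
  }
  # order-normalize so the split depends only on content and seed
  key <- paste(dataset$canonical_smiles, dataset$target_id, sep = "\r")
  dataset <- dataset[order(key), , drop = FALSE]

  n_test <- round_half_up(n * (1 - f1))
  n_valid <- round_half_up((n - n_test) * (1 - f2))
  n_test <- max(1L, min(n_test, n - 2L))
  n_valid <- max(1L, min(n_valid, n - n_test - 1L))

  perm <- withr::with_seed(as.integer(seed), sample.int(n))
  test_idx <- perm[seq_len(n_test)]
  valid_idx <- perm[n_test + seq_len(n_valid)]
  train_idx <- perm[-seq_len(n_test + n_valid)]

  res <- list(
    train = dataset[sort(train_idx), , drop = FALSE],
    valid = dataset[sort(valid_idx), , drop = FALSE],
    test = dataset[sort(test_idx), , drop = FALSE],
    seed = as.integer(seed),
    fractions = c(f1 = f1, f2 = f2)
  )
  rownames(res$train) <- rownames(res$valid) <- rownames(res$test) <- NULL
  structure(res, class = "split_result")
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' @export
print.split_result <- function(x, ...) {
  n <- nrow(x$train) + nrow(x$valid) + nrow(x$test)
  cat(sprintf(
    "Split (seed %d): train %d / valid %d / test %d  (%.1f%%/%.1f%%/%.1f%%)\n",
    x$seed, nrow(x$train), nrow(x$valid), nrow(x$test),
    100 * nrow(x$train) / n, 100 * nrow(x$valid) / n, 100 * nrow(x$test) / n
  ))
  invisible(x)
}

#' Write split subsets and a manifest
#'
#' @param split A `split_result`.
#' @param prefix Output path prefix; writes `<prefix>train.csv`,
#'   `<prefix>valid.csv`, `<prefix>test.csv` and `<prefix>manifest.json`.
#' @export
write_split <- function(split, prefix) {
  for (part in c("train", "valid", "test")) {
    utils::write.csv(split[[part]], paste0(prefix, part, ".csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    seed = split$seed,
    fractions = as.list(split$fractions),
    members = lapply(split[c("train", "valid", "test")],
                     function(d) paste(d$canonical_smiles, d$target_id,
                                       sep = "|"))
  )
  jsonlite::write_json(manifest, paste0(prefix, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prefix)
}
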