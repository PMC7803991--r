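#' Murcko carbon skeleton of a molecule
#'
#' Reduces a molecule to its ring systems plus the linkers connecting them
#' (side chains removed by iteratively deleting terminal atoms), then
#' replaces every heavy atom with carbon and every bond with a single bond,
#' and canonicalizes the result. Acyclic molecules yield the designated empty
#' skeleton of size 0.
#'
#' @param smiles Character vector of SMILES.
#' @return Data frame with columns `smiles`, `skeleton_smiles` ("" for the
#'   empty skeleton, NA on parse failure) and `size` (skeleton atom count).
#' @examples
#' carbon_skeleton("Cc1ccccc1")  # toluene -> C1CCCCC1, size 6
#' @export
carbon_skeleton <- function(smiles) {
  parsed <- ob_parse(smiles)
  out <- data.frame(smiles = as.character(smiles),
                    skeleton_smiles = NA_character_,
                    size = NA_integer_, stringsAsFactors = FALSE)
  cache <- new.env(parent = emptyenv())
  for (i in seq_along(smiles)) {
    if (!parsed$ok[i]) next
    tab <- sdf_tables(parsed$sdf[[i]])
    n <- tab$n
    adj <- rep(list(integer(0)), n)
    if (nrow(tab$bonds)) {
      for (k in seq_len(nrow(tab$bonds))) {
        a <- tab$bonds[k, 1L]; b <- tab$bonds[k, 2L]
        adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      }
    }
    alive <- rep(TRUE, n)
    deg <- lengths(adj)
    # iteratively prune terminal atoms; what survives is rings + linkers
    repeat {
      leaves <- which(alive & deg <= 1L)
      if (!length(leaves)) break
      alive[leaves] <- FALSE
      for (v in leaves) {
        for (u in adj[[v]]) if (alive[u]) deg[u] <- deg[u] - 1L
      }
      deg[leaves] <- 0L
    }
    if (!any(alive)) {
      out$skeleton_smiles[i] <- ""
      out$size[i] <- 0L
      next
    }
    keep <- which(alive)
    remap <- match(seq_len(n), keep)
    edges <- tab$bonds[alive[tab$bonds[, 1L]] & alive[tab$bonds[, 2L]], ,
                       drop = FALSE]
    e2 <- cbind(remap[edges[, 1L]], remap[edges[, 2L]])
    key <- paste(length(keep), paste(pmin(e2[, 1], e2[, 2]),
                                     pmax(e2[, 1], e2[, 2]),
                                     sep = "-", collapse = ","))
    hit <- get0(key, envir = cache)
    sk <- if (!is.null(hit)) hit else {
      v <- carbon_graph_smiles(length(keep), e2)
      assign(key, v, envir = cache)
      v
    }
    out$skeleton_smiles[i] <- sk
    out$size[i] <- length(keep)
  }
  out
}

#' Size-ordered scaffold binning scheme
#'
#' Sorts a deduplicated reference scaffold list in ascending order of
#' scaffold size (canonical-SMILES tiebreak) and chunks it into consecutive
#' bins of `capacity` scaffolds; the last bin may be smaller. The empty
#' skeleton, if present, sorts first.
#'
#' @param reference Data frame as returned by [carbon_skeleton()] (columns
#'   `skeleton_smiles`, `size`), or a character vector of skeleton SMILES.
#' @param capacity Scaffolds per bin (default 10000).
#' @return List of class `binning_scheme` with the scaffold-to-bin map,
#'   `n_bins`, per-bin size ranges and `capacity`.
#' @export
build_binning <- function(reference, capacity = 10000L) {
  if (is.character(reference)) {
    sizes <- ifelse(nzchar(reference),
                    carbon_skeleton(reference)$size, 0L)
    reference <- data.frame(skeleton_smiles = reference, size = sizes,
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("skeleton_smiles", "size") %in% names(reference)))
  reference <- reference[!is.na(reference$skeleton_smiles), , drop = FALSE]
  reference <- reference[!duplicated(reference$skeleton_smiles), ,
                         drop = FALSE]
  if (nrow(reference) == 0L) stop("empty scaffold reference", call. = FALSE)
  capacity <- as.integer(capacity)
  stopifnot(capacity >= 1L)
  ord <- order(reference$size, reference$skeleton_smiles, method = "radix")
  reference <- reference[ord, , drop = FALSE]
  n <- nrow(reference)
  n_bins <- as.integer(ceiling(n / capacity))
  bin <- as.integer((seq_len(n) - 1L) %/% capacity + 1L)
  size_ranges <- t(vapply(seq_len(n_bins), function(b) {
    s <- reference$size[bin == b]
    c(min = min(s), max = max(s))
  }, numeric(2)))
  map <- bin
  names(map) <- reference$skeleton_smiles
  structure(list(map = map, n_bins = n_bins, capacity = capacity,
                 size_ranges = size_ranges,
                 reference = reference$skeleton_smiles),
            class = "binning_scheme")
}

#' @export
print.binning_scheme <- function(x, ...) {
  cat(sprintf("Scaffold binning: %d scaffolds, capacity %d -> %d bins (last bin %d)\n",
              length(x$map), x$capacity, x$n_bins,
              sum(x$map == x$n_bins)))
  invisible(x)
}

# Bin index for arbitrary skeletons: known ones via the map; unseen ones go
# to the first bin whose size range reaches their size (last bin as overflow).
assign_bins <- function(skeleton_smiles, size, scheme) {
  bin <- unname(scheme$map[skeleton_smiles])
  missing <- which(is.na(bin))
  for (i in missing) {
    b <- which(scheme$size_ranges[, "max"] >= size[i])
    bin[i] <- if (length(b)) b[1] else scheme$n_bins
  }
  bin
}

#' Compound-over-scaffold-bin histogram of a dataset
#'
#' Counts compounds (not scaffolds) whose carbon skeleton falls into each bin
#' of the scheme and normalizes to a probability distribution
#' `p_i = c_i / c`.
#'
#' @param dataset Curated data frame with a `canonical_smiles` column, or a
#'   character vector of SMILES.
#' @param scheme A [build_binning()] scheme.
#' @param skeletons Optional precomputed [carbon_skeleton()] result for the
#'   dataset compounds (computed, with deduplication, when omitted).
#' @return Object of class `scaffold_histogram`: list with `p`, `counts`,
#'   `c` (total compounds) and `n_bins`.
#' @export
dataset_histogram <- function(dataset, scheme, skeletons = NULL) {
  smiles <- if (is.data.frame(dataset)) dataset$canonical_smiles else dataset
  if (length(smiles) == 0L) stop("empty dataset", call. = FALSE)
  if (is.null(skeletons)) {
    uniq <- unique(smiles)
    sk <- carbon_skeleton(uniq)
    skeletons <- sk[match(smiles, uniq), , drop = FALSE]
  }
  ok <- !is.na(skeletons$skeleton_smiles)
  bins <- assign_bins(skeletons$skeleton_smiles[ok], skeletons$size[ok],
                      scheme)
  counts <- tabulate(bins, nbins = scheme$n_bins)
  structure(list(p = counts / sum(counts), counts = counts,
                 c = sum(counts), n_bins = scheme$n_bins),
            class = "scaffold_histogram")
}

as_prob <- function(hist) {
  p <- if (inherits(hist, "scaffold_histogram")) hist$p else as.numeric(hist)
  if (any(p < 0)) stop("negative probability mass", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-9) {
    if (s <= 0) stop("probabilities sum to zero", call. = FALSE)
    p <- p / s
  }
  p
}

#' Shannon scaffold-diversity index (bits)
#'
#' `H = -sum_i p_i log2 p_i` over the compound-per-bin distribution. H is 0
#' for a point mass and log2(n_bins) for the uniform distribution (3.91 bits
#' for 15 bins).
#'
#' @param hist A `scaffold_histogram` or a probability vector.
#' @return Entropy in bits.
#' @examples
#' shannon_H(rep(1 / 15, 15))  # 3.91
#' @export
shannon_H <- function(hist) {
  p <- as_prob(hist)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Kullback-Leibler divergence between scaffold histograms (bits)
#'
#' `KLD(p||q) = sum_i p_i log2(p_i / q_i)`, non-negative and zero iff
#' `p = q`. Because random splits of small datasets routinely leave bins of
#' `q` empty, additive smoothing with `eps = 1/(10 c)` (c = compound count
#' behind `q`) is applied to `q` by default; with smoothing disabled, mass of
#' `p` on an empty bin of `q` yields `Inf`.
#'
#' @param p,q `scaffold_histogram`s over the same binning scheme, or
#'   probability vectors of equal length.
#' @param smooth Apply additive smoothing to `q` (default TRUE).
#' @return Divergence in bits.
#' @export
kld <- function(p, q, smooth = TRUE) {
  cq <- if (inherits(q, "scaffold_histogram")) q$c else NULL
  pv <- as_prob(p); qv <- as_prob(q)
  if (length(pv) != length(qv)) {
    stop("histograms use different binning schemes", call. = FALSE)
  }
  if (smooth) {
    eps <- if (!is.null(cq)) 1 / (10 * cq) else 1e-4
    qv <- qv + eps
    qv <- qv / sum(qv)
  }
  nz <- pv > 0
  if (any(qv[nz] == 0)) return(Inf)
  sum(pv[nz] * log2(pv[nz] / qv[nz]))
}

#' Scaffold-diversity report for a split
#'
#' Computes H for the unsplit dataset and each subset, and the KLD of each
#' subset's scaffold distribution against the unsplit one.
#'
#' @param split A [split_dataset()] result.
#' @param scheme A [build_binning()] scheme.
#' @return Data frame with one row per subset (`full`, `train`, `valid`,
#'   `test`): compound count, H, and KLD vs the unsplit dataset.
#' @export
diversity_report <- function(split, scheme) {
  full <- rbind(split$train, split$valid, split$test)
  sets <- list(full = full, train = split$train, valid = split$valid,
               test = split$test)
  uniq <- unique(full$canonical_smiles)
  sk <- carbon_skeleton(uniq)
  hists <- lapply(sets, function(d) {
    dataset_histogram(d, scheme,
                      skeletons = sk[match(d$canonical_smiles, uniq), ,
                                     drop = FALSE])
  })
  data.frame(
    subset = names(sets),
    n = vapply(sets, nrow, integer(1)),
    H = vapply(hists, shannon_H, numeric(1)),
    KLD_vs_full = vapply(hists, kld, numeric(1), q = hists$full),
    row.names = NULL
  )
}
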