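# Shared fixtures and reference implementations used across the test files.

# A 12-row hand-built activity table: 2 low-confidence rows, 1 wrong-units
# row, 1 "Inconclusive" row, 1 potential-duplicates row, and 7 clean rows,
# two of which (rows 11 and 12) share one compound-target pair.
hand_activity_fixture <- function() {
  row <- function(id, smiles, value, conf = 8, assay = "B", units = "nM",
                  rel = "=", comment = "", dup = 0L, validity = "") {
    data.frame(
      compound_id = id, smiles = smiles, standard_type = "IC50",
      standard_value = value, standard_units = units,
      standard_relation = rel, assay_type = assay, confidence_score = conf,
      activity_comment = comment, potential_duplicates = dup,
      data_validity_comment = validity, target_id = "T1",
      stringsAsFactors = FALSE
    )
  }
  rbind(
    row("c01", "CCO", 10),
    row("c02", "CCN", 100, conf = 5),            # low confidence
    row("c03", "CCC", 1000, conf = 3),           # low confidence
    row("c04", "CCCl", 50, units = "ug.mL-1"),   # wrong units
    row("c05", "CCBr", 20, comment = "Inconclusive"),
    row("c06", "CCF", 5, dup = 1L),              # flagged duplicate
    row("c07", "c1ccccc1", 200),
    row("c08", "c1ccncc1", 400, rel = ">"),
    row("c09", "CCCC", 30),
    row("c10", "CCCCC", 60),
    row("c11", "CC(C)O", 80),
    row("c12", "OC(C)C", 8)                      # same compound as c11
  )
}

# Small, fast SAR spec for unit tests.
tiny_sar <- function(n = 120, seed = 1, noise_sd = 0.1, junk = 0, dup = 0,
                     cens = 0) {
  sar_spec(n = n, seed = seed, noise_sd = noise_sd, junk_fraction = junk,
           duplicate_fraction = dup, censor_fraction = cens)
}

# A pool of curated molecules reused by several tests (generated once).
local({
  spec <- tiny_sar(n = 260, seed = 99)
  tab <- generate_activity_table(spec)
  assign("shared_curated", build_dataset(tab)$dataset,
         envir = topenv())
})

# ---- reference forward pass (independent oracle for the C++ network) ----
# Evaluation-mode forward in plain double-precision R, from the stored
# weight list: per conv layer [Wself, Wnbr, b, gamma, beta] then
# [Wd, bd, wo, bo]; running stats [rmean, rvar] per layer.
ref_forward <- function(model, graphs) {
  w <- model$weights; rs <- model$rstats
  L <- model$config$n_conv_layers
  vapply(graphs, function(g) {
    H <- t(g$atom_features)  # dim x atoms
    for (l in seq_len(L)) {
      Wself <- w[[5 * (l - 1) + 1]]; Wnbr <- w[[5 * (l - 1) + 2]]
      b <- as.numeric(w[[5 * (l - 1) + 3]])
      gamma <- as.numeric(w[[5 * (l - 1) + 4]])
      beta <- as.numeric(w[[5 * (l - 1) + 5]])
      rmean <- as.numeric(rs[[2 * (l - 1) + 1]])
      rvar <- as.numeric(rs[[2 * (l - 1) + 2]])
      AH <- sapply(seq_len(g$n_atoms), function(v) {
        nb <- g$neighbors[[v]]
        if (length(nb) == 0) numeric(nrow(H)) else
          rowSums(H[, nb, drop = FALSE])
      })
      if (is.null(dim(AH))) AH <- matrix(AH, nrow = nrow(H))
      Z <- t(Wself) %*% H + t(Wnbr) %*% AH + b
      Xh <- (Z - rmean) / sqrt(rvar + 1e-5)
      Y <- Xh * gamma + beta
      R <- pmax(Y, 0)
      # closed-neighborhood max pool
      P <- sapply(seq_len(g$n_atoms), function(v) {
        cols <- c(v, g$neighbors[[v]])
        apply(R[, cols, drop = FALSE], 1, max)
      })
      if (is.null(dim(P))) P <- matrix(P, nrow = nrow(R))
      H <- P
    }
    Wd <- w[[5 * L + 1]]; bd <- as.numeric(w[[5 * L + 2]])
    wo <- as.numeric(w[[5 * L + 3]]); bo <- as.numeric(w[[5 * L + 4]])
    D <- pmax(t(Wd) %*% H + bd, 0)
    gvec <- tanh(rowSums(D))
    sum(gvec * wo) + bo
  }, numeric(1))
}
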