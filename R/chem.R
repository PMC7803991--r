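# Low-level chemistry backend: SMILES parsing, canonicalization and SDF
# handling are delegated to OpenBabel through ChemmineR/ChemmineOB. Everything
# here returns plain R structures; parse failures are values, never conditions.

# Batch-canonicalize SMILES with OpenBabel. Returns a character vector aligned
# with the input; NA where the SMILES could not be parsed. OpenBabel silently
# drops unparseable molecules from batch output, so conversion is chunked and
# any chunk with a line-count mismatch is redone molecule-by-molecule.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0L) return(character(0))
  out <- rep(NA_character_, n)
  blank <- is.na(smiles) | !nzchar(trimws(smiles))
  idx <- which(!blank)
  if (length(idx) == 0L) return(out)
  chunk_size <- 500L
  for (start in seq(1L, length(idx), by = chunk_size)) {
    ii <- idx[start:min(start + chunk_size - 1L, length(idx))]
    res <- ob_convert_lines(smiles[ii])
    if (length(res) == length(ii)) {
      out[ii] <- res
    } else {
      for (i in ii) {
        res1 <- ob_convert_lines(smiles[i])
        out[i] <- if (length(res1) == 1L && nzchar(res1)) res1 else NA_character_
      }
    }
  }
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

ob_convert_lines <- function(smiles) {
  txt <- ChemmineOB::convertFormat(
    "SMI", "CAN", paste0(paste(smiles, collapse = "\n"), "\n")
  )
  if (!nzchar(txt)) return(character(0))
  res <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  # openbabel emits "smiles\ttitle"; strip the title field
  sub("\t.*$", "", res)
}

# Parse a vector of SMILES into an SDFset plus a validity mask. Invalid inputs
# are substituted by methane placeholders so the set stays index-aligned.
ob_parse <- function(smiles) {
  can <- ob_canonical(smiles)
  ok <- !is.na(can)
  filled <- ifelse(ok, smiles, "C")
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(filled))
  list(sdf = sdf, ok = ok)
}

# Extract element symbols, MDL charge codes, and an edge table from one SDF.
# Charge codes: 0 none, 1 +3, 2 +2, 3 +1, 4 doublet radical, 5 -1, 6 -2, 7 -3.
# ChemmineR cannot represent bond-less (single heavy atom) molecules in its
# atom block; for those the element and charge are recovered from the SMILES.
sdf_tables <- function(one_sdf, smiles = NULL) {
  ab <- ChemmineR::atomblock(one_sdf)
  bb <- ChemmineR::bondblock(one_sdf)
  n <- nrow(ab)
  if (!any(grepl("_", rownames(ab), fixed = TRUE)) && !is.null(smiles)) {
    return(single_atom_tables(smiles))
  }
  elem <- sub("_.*$", "", rownames(ab))
  code <- if (ncol(ab) >= 5L) as.integer(ab[, 5L]) else integer(n)
  charge <- integer(n)
  charge[code == 1L] <- 3L; charge[code == 2L] <- 2L; charge[code == 3L] <- 1L
  charge[code == 5L] <- -1L; charge[code == 6L] <- -2L; charge[code == 7L] <- -3L
  radical <- as.integer(code == 4L)
  bonds <- matrix(0L, 0L, 3L)
  if (!is.null(bb) && NROW(bb) > 0L && NCOL(bb) >= 3L) {
    bm <- cbind(as.integer(bb[, 1L]), as.integer(bb[, 2L]), as.integer(bb[, 3L]))
    keep <- bm[, 1L] >= 1L & bm[, 2L] >= 1L & bm[, 1L] <= n & bm[, 2L] <= n &
      bm[, 1L] != bm[, 2L]
    bonds <- bm[keep, , drop = FALSE]
  }
  list(n = n, elem = elem, charge = charge, radical = radical, bonds = bonds)
}

# Atom table for a one-atom SMILES like "C", "O" or "[NH4+]".
single_atom_tables <- function(smiles) {
  s <- gsub("^\\[|\\]$", "", trimws(smiles))
  elem <- regmatches(s, regexpr("^[A-Z][a-z]?|^[a-z]", s))
  if (length(elem) == 0L) elem <- "C"
  rest <- sub("^[A-Z][a-z]?|^[a-z]", "", s)
  chg <- 0L
  cm <- regmatches(rest, regexpr("[+-][0-9]*", rest))
  if (length(cm) == 1L && nzchar(cm)) {
    mag <- sub("^[+-]", "", cm)
    chg <- (if (startsWith(cm, "-")) -1L else 1L) *
      (if (nzchar(mag)) as.integer(mag) else 1L)
  }
  list(n = 1L, elem = elem, charge = chg, radical = 0L,
       bonds = matrix(0L, 0L, 3L))
}

# Indices of atoms that belong to at least one aromatic ring. ChemmineR's ring
# perception fails on bond-less molecules, hence the guard.
aromatic_atoms <- function(one_sdf, tab) {
  if (tab$n < 3L || nrow(tab$bonds) < 3L) return(integer(0))
  rng <- tryCatch(ChemmineR::rings(one_sdf, type = "all", arom = TRUE),
                  error = function(e) NULL)
  if (is.null(rng) || is.null(rng$RINGS) || length(rng$RINGS) == 0L) {
    return(integer(0))
  }
  arom <- unlist(rng$RINGS[which(unlist(rng$AROMATIC))], use.names = FALSE)
  if (is.null(arom)) return(integer(0))
  sort(unique(as.integer(sub("^[^_]*_", "", arom))))
}

# Lower bound on the heavy-atom count of a SMILES string by counting atom
# tokens (bracket atoms, two-letter halogens, organic-subset symbols). Used
# only as a size guard, never as a parser.
smiles_atom_count <- function(smiles) {
  pat <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]"
  vapply(gregexpr(pat, smiles), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1))
}

# Heavy-atom count per SMILES fragment, via the V2000 counts line.
ob_heavy_atoms <- function(fragments) {
  vapply(fragments, function(f) {
    sdftxt <- tryCatch(
      ChemmineOB::convertFormat("SMI", "SDF", paste0(f, "\n")),
      error = function(e) ""
    )
    if (!nzchar(sdftxt)) return(NA_integer_)
    lines <- strsplit(sdftxt, "\n", fixed = TRUE)[[1]]
    if (length(lines) < 4L) return(NA_integer_)
    as.integer(substr(lines[4L], 1L, 3L))
  }, integer(1), USE.NAMES = FALSE)
}

# Canonical SMILES of a plain carbon graph (all single bonds), given its edge
# list, by way of a minimal V2000 block. Used for scaffold skeletons.
carbon_graph_smiles <- function(n_atoms, edges) {
  atom_line <- "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0"
  al <- paste(rep(atom_line, n_atoms), collapse = "\n")
  bl <- if (nrow(edges) > 0L) {
    paste(sprintf("%3d%3d  1  0  0  0  0", edges[, 1L], edges[, 2L]),
          collapse = "\n")
  } else ""
  txt <- paste0(
    "\n molgcn2D\n\n",
    sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000\n", n_atoms, nrow(edges)),
    al, "\n", if (nzchar(bl)) paste0(bl, "\n"), "M  END\n$$$$\n"
  )
  out <- ChemmineOB::convertFormat("SDF", "CAN", txt)
  sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
}
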