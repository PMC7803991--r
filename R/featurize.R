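# Per-atom 75-bit feature layout. Blocks, in order:
#   element one-hot over 44 symbols (43 named + "other")
#   heavy-atom degree one-hot 0..10          (11)
#   implicit valence (implicit H) one-hot 0..6 (7)
#   formal-charge presence bit                (1)
#   radical-electron presence bit             (1)
#   hybridization one-hot SP/SP2/SP3/SP3D/SP3D2 (5)
#   aromaticity flag                          (1)
#   total attached hydrogens one-hot 0..4     (5)
FEATURE_ELEMENTS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb"
)

#' Dimension and block layout of the atom feature vector
#'
#' @return Named integer vector of block widths; the widths sum to 75.
#' @export
atom_feature_blocks <- function() {
  c(element = length(FEATURE_ELEMENTS) + 1L, degree = 11L,
    implicit_valence = 7L, formal_charge = 1L, radical = 1L,
    hybridization = 5L, aromatic = 1L, total_h = 5L)
}

default_valence <- function(elem) {
  v <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1, I = 1,
         B = 3, Si = 4)
  out <- unname(v[elem])
  out[is.na(out)] <- 0
  out
}

one_hot <- function(value, n_slots, clip = TRUE) {
  v <- numeric(n_slots)
  idx <- value + 1L
  if (clip) idx <- min(max(idx, 1L), n_slots)
  v[idx] <- 1
  v
}

# Build the 75-vector for one atom from its descriptor list.
# Descriptor fields: elem, degree, implicit_h, charge, radical, aromatic,
# n_double, n_triple.
atom_feature_vector <- function(a) {
  elem_slot <- match(a$elem, FEATURE_ELEMENTS)
  elem <- numeric(length(FEATURE_ELEMENTS) + 1L)
  elem[if (is.na(elem_slot)) length(elem) else elem_slot] <- 1

  hyb <- if (a$n_triple > 0L || a$n_double >= 2L) 1L
    else if (a$aromatic || a$n_double == 1L) 2L
    else if (a$degree >= 6L) 5L
    else if (a$degree == 5L) 4L
    else 3L

  c(elem,
    one_hot(a$degree, 11L),
    one_hot(a$implicit_h, 7L),
    as.numeric(a$charge != 0L),
    as.numeric(a$radical != 0L),
    one_hot(hyb - 1L, 5L),
    as.numeric(a$aromatic),
    one_hot(a$implicit_h + a$explicit_h, 5L))
}

# Atom descriptors for every atom of a parsed molecule (sdf_tables output
# plus aromatic atom indices).
atom_descriptors <- function(tab, arom_idx) {
  n <- tab$n
  deg <- integer(n); n_double <- integer(n); n_triple <- integer(n)
  expl_h <- integer(n)
  bsum <- integer(n)
  if (nrow(tab$bonds) > 0L) {
    for (k in seq_len(nrow(tab$bonds))) {
      i <- tab$bonds[k, 1L]; j <- tab$bonds[k, 2L]; o <- tab$bonds[k, 3L]
      deg[i] <- deg[i] + 1L; deg[j] <- deg[j] + 1L
      bsum[i] <- bsum[i] + o; bsum[j] <- bsum[j] + o
      if (o == 2L) { n_double[i] <- n_double[i] + 1L
                     n_double[j] <- n_double[j] + 1L }
      if (o == 3L) { n_triple[i] <- n_triple[i] + 1L
                     n_triple[j] <- n_triple[j] + 1L }
    }
  }
  lapply(seq_len(n), function(i) {
    elem <- tab$elem[i]
    base <- default_valence(elem)
    # hypervalent S/P step up to the next standard valence state
    if (elem == "S" && bsum[i] > 2) base <- if (bsum[i] > 4) 6 else 4
    if (elem == "P" && bsum[i] > 3) base <- 5
    allowed <- base + if (elem %in% c("N", "O", "S", "C", "P")) tab$charge[i] else 0
    imp_h <- max(0L, as.integer(allowed) - bsum[i])
    list(elem = elem, degree = deg[i], implicit_h = imp_h,
         charge = tab$charge[i], radical = tab$radical[i],
         aromatic = i %in% arom_idx,
         n_double = n_double[i], n_triple = n_triple[i],
         explicit_h = 0L)
  })
}

#' Per-atom feature vectors of a molecule
#'
#' Computes the 75-component binary feature vector for every atom of a
#' molecule: element, heavy-atom degree, implicit valence, formal charge and
#' radical presence, hybridization, aromaticity, and attached-hydrogen count,
#' in fixed one-hot blocks (see [atom_feature_blocks()]).
#'
#' @param smiles A single SMILES string.
#' @return Numeric matrix with one 75-column row per heavy atom.
#' @export
atom_features <- function(smiles) {
  featurize_molecule(smiles)$atom_features
}

#' Convert a SMILES into a molecular graph
#'
#' One node per heavy atom (hydrogens are implicit), undirected edges from
#' covalent bonds, and a 75-bit feature vector per atom.
#'
#' @param smiles A single SMILES string.
#' @return List of class `mol_graph` with `n_atoms`, `atom_features`
#'   (n x 75 binary matrix) and `neighbors` (list of 1-based index vectors).
#' @export
featurize_molecule <- function(smiles) {
  res <- featurize_batch(smiles)
  if (!res$ok[1]) {
    stop("cannot parse SMILES: ", smiles, call. = FALSE)
  }
  res$graphs[[1]]
}

#' Featurize a batch of SMILES
#'
#' @param smiles Character vector of SMILES.
#' @return List with `graphs` (list of `mol_graph`, NULL where parsing
#'   failed) and `ok` (logical vector).
#' @export
featurize_batch <- function(smiles) {
  parsed <- ob_parse(smiles)
  graphs <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    if (!parsed$ok[i]) next
    one <- parsed$sdf[[i]]
    tab <- sdf_tables(one, smiles = smiles[i])
    arom <- aromatic_atoms(one, tab)
    desc <- atom_descriptors(tab, arom)
    feats <- t(vapply(desc, atom_feature_vector, numeric(75L)))
    nbrs <- rep(list(integer(0)), tab$n)
    if (nrow(tab$bonds) > 0L) {
      for (k in seq_len(nrow(tab$bonds))) {
        a <- tab$bonds[k, 1L]; b <- tab$bonds[k, 2L]
        nbrs[[a]] <- c(nbrs[[a]], b)
        nbrs[[b]] <- c(nbrs[[b]], a)
      }
      nbrs <- lapply(nbrs, function(v) sort(unique(v)))
    }
    graphs[[i]] <- structure(
      list(n_atoms = tab$n, atom_features = feats, neighbors = nbrs,
           smiles = smiles[i]),
      class = "mol_graph")
  }
  list(graphs = graphs, ok = parsed$ok)
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("Molecular graph: %d atoms, %d bonds (%s)\n", x$n_atoms,
              sum(lengths(x$neighbors)) / 2, x$smiles))
  invisible(x)
}

# Pack a list of mol_graph objects into the flat arrays the C++ core
# consumes: stacked feature matrix, 0-based molecule offsets, and a 0-based
# directed edge list (both directions present).
pack_graphs <- function(graphs) {
  if (any(vapply(graphs, is.null, logical(1)))) {
    stop("cannot pack unparsed molecules", call. = FALSE)
  }
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  offsets <- c(0L, cumsum(n_atoms))
  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  edges <- vector("list", length(graphs))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (sum(lengths(g$neighbors)) == 0L) {
      edges[[i]] <- matrix(0L, 0L, 2L)
      next
    }
    src <- rep(seq_len(g$n_atoms), lengths(g$neighbors))
    dst <- unlist(g$neighbors, use.names = FALSE)
    edges[[i]] <- cbind(src, dst) + offsets[i] - 1L
  }
  e <- do.call(rbind, edges)
  list(X = X, mol_ptr = offsets, edges = e, n_mols = length(graphs))
}

#' Read a SMILES file
#'
#' One molecule per line, optionally followed by whitespace and an
#' identifier.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `id`.
#' @export
read_smiles_file <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(
    smiles = vapply(parts, `[[`, character(1), 1),
    id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("mol%05d", i)
    }, character(1)),
    stringsAsFactors = FALSE
  )
}

#' Dump a molecular graph as JSON (debugging aid)
#'
#' @param graph A `mol_graph`.
#' @param path Output file path.
#' @export
write_graph_json <- function(graph, path) {
  stopifnot(inherits(graph, "mol_graph"))
  jsonlite::write_json(
    list(smiles = graph$smiles, n_atoms = graph$n_atoms,
         atom_features = graph$atom_features, neighbors = graph$neighbors),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
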