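# Scaffold/substituent grammar with a planted additive SAR. Scaffold
# templates carry parenthesized attachment slots "(%1)".."(%3)" on ring
# atoms; a generated molecule is a template with each slot either removed or
# filled by a substituent fragment. Activity is
#   baseline + sum_f w_f * count(f)  (pIC50 units)
# which makes fragment membership decidable by inverting the grammar.

default_scaffold_library <- function() {
  data.frame(
    template = c(
      "C1C(%1)C(%2)C(%3)C1",                 # cyclopentane
      "C1C(%1)C(%2)C(%3)CC1",                # cyclohexane
      "c1c(%1)c(%2)cc(%3)c1",                # benzene
      "c1c(%1)c(%2)cc(%3)n1",                # pyridine
      "C1C(%1)CC2CC(%2)CC(%3)C12",           # fused bicyclononane
      "c1c(%1)cc2cc(%2)c(%3)cc2c1",          # naphthalene
      "C1CC(%1)CCC1c1cc(%2)c(%3)cc1",        # phenylcyclohexane
      "c1c(%1)ccc(c1)Cc1cc(%2)cc(%3)c1",     # diphenylmethane
      "c1c(%1)ccc(c1)CCc1cc(%2)c(%3)cc1",    # bibenzyl
      "C1CC(%1)N(CC1)c1cc(%2)c(%3)cc1",      # N-phenylpiperidine
      "c1c(%1)cc2c(c1)CC(%2)C(%3)C2",        # indane
      "c1c(%1)ccc(c1)CCCc1cc(%2)c(%3)cc1"    # 1,3-diphenylpropane
    ),
    weight = c(1.5, 1.5, 2, 1.5, 1, 1, 1, 0.8, 0.8, 1, 1, 0.6),
    stringsAsFactors = FALSE
  )
}

default_substituent_library <- function() {
  data.frame(
    fragment = c("C", "CC", "C(C)C", "F", "Cl", "Br", "I", "O", "OC", "OCC",
                 "N", "NC", "N(C)C", "C#N", "C(=O)O", "C(=O)OC", "C(=O)N",
                 "C(F)(F)F", "S", "c8ccccc8"),
    w = c(0.20, 0.35, 0.45, 0.60, 0.90, 1.10, 0.75, -0.40, 0.55, 0.30,
          -0.60, -0.25, 0.80, -0.90, -1.20, -0.50, -1.00, 1.30, 0.15, 1.45),
    stringsAsFactors = FALSE
  )
}

#' Specification of a synthetic structure-activity dataset
#'
#' Defines the generative model behind [generate_activity_table()]: a
#' scaffold library with attachment slots, substituent fragments with
#' additive activity contributions, Gaussian assay noise, censoring limits,
#' and the fractions of duplicated and curation-violating ("junk") rows.
#'
#' @param n Total rows of the raw activity table.
#' @param seed Integer seed; the emitted table is a pure function of this
#'   object.
#' @param baseline Activity (pIC50) of a bare scaffold.
#' @param noise_sd Gaussian noise s.d. on the pIC50 scale.
#' @param censor_fraction Fraction of rows reported as censored bounds.
#' @param duplicate_fraction Fraction of rows that re-measure an already
#'   emitted compound (independent noise draw).
#' @param junk_fraction Fraction of rows carrying a curation violation.
#' @param v_limits Assay reporting limits in nM (values are clipped here and
#'   flagged with ">"/"<").
#' @param scaffolds,substituents Optional library overrides (data frames
#'   with columns `template`/`weight` and `fragment`/`w`).
#' @param target_id Target identifier stamped on every row.
#' @return List of class `sar_spec`.
#' @export
sar_spec <- function(n = 1000L, seed = 1L, baseline = 6.0, noise_sd = 0.3,
                     censor_fraction = 0.03, duplicate_fraction = 0.05,
                     junk_fraction = 0.10, v_limits = c(0.1, 1e5),
                     scaffolds = NULL, substituents = NULL,
                     target_id = "SYN-T1") {
  stopifnot(n >= 1, noise_sd >= 0, censor_fraction >= 0,
            duplicate_fraction >= 0, junk_fraction >= 0,
            v_limits[1] > 0, v_limits[1] < v_limits[2])
  if (duplicate_fraction + junk_fraction >= 1) {
    stop("duplicate and junk fractions leave no unique compounds",
         call. = FALSE)
  }
  scaffolds <- scaffolds %||% default_scaffold_library()
  substituents <- substituents %||% default_substituent_library()
  stopifnot(nrow(scaffolds) > 0, nrow(substituents) > 0,
            all(scaffolds$weight >= 0), any(scaffolds$weight > 0))
  structure(list(
    n = as.integer(n), seed = as.integer(seed), baseline = baseline,
    noise_sd = noise_sd, censor_fraction = censor_fraction,
    duplicate_fraction = duplicate_fraction, junk_fraction = junk_fraction,
    v_limits = v_limits, scaffolds = scaffolds, substituents = substituents,
    target_id = target_id
  ), class = "sar_spec")
}

template_slots <- function(template) {
  m <- gregexpr("%[0-9]", template)[[1]]
  if (m[1] == -1) 0L else length(m)
}

regex_escape <- function(s) gsub("([][{}()+*^$|\\\\?.#=])", "\\\\\\1", s)

# Turn a slotted template into a perl regex whose k-th capture group holds
# the fragment filling the k-th slot ("" / absent when the slot is empty).
# Assembled by string splitting, never by sub() replacement, so escaped
# fragments pass through untouched. Slots must not sit at the template end.
template_regex <- function(template, fragments) {
  alt <- paste(regex_escape(fragments), collapse = "|")
  optional <- paste0("(?:\\((", alt, ")\\))?")
  esc <- regex_escape(template)
  for (k in 1:9) {
    token <- regex_escape(paste0("(%", k, ")"))
    pieces <- strsplit(esc, token, fixed = TRUE)[[1]]
    if (length(pieces) > 1L) esc <- paste(pieces, collapse = optional)
  }
  paste0("^", esc, "$")
}

# Assemble one molecule; returns the SMILES and its fragment count vector.
assemble_molecule <- function(spec, scaffold_idx, slot_fill) {
  template <- spec$scaffolds$template[scaffold_idx]
  n_slots <- template_slots(template)
  subs <- character(n_slots)
  subs[seq_along(slot_fill)] <- ifelse(is.na(slot_fill), "",
                                       spec$substituents$fragment[slot_fill])
  smiles <- template
  for (k in seq_len(n_slots)) {
    smiles <- if (nzchar(subs[k])) {
      sub(paste0("%", k), subs[k], smiles, fixed = TRUE)
    } else {
      sub(paste0("(%", k, ")"), "", smiles, fixed = TRUE)
    }
  }
  counts <- tabulate(slot_fill[!is.na(slot_fill)],
                     nbins = nrow(spec$substituents))
  list(smiles = smiles, counts = counts)
}

#' Noiseless planted activity of a generated molecule
#'
#' Recovers the scaffold/substituent decomposition of a molecule assembled by
#' this generator (by inverting the template grammar) and returns
#' `baseline + sum_f w_f * count(f)`. Deterministic; errors on molecules the
#' grammar cannot produce.
#'
#' @param smiles SMILES string(s) as emitted by [generate_activity_table()].
#' @param spec The [sar_spec()] that generated them.
#' @return Numeric vector of noiseless pIC50 values.
#' @export
true_activity <- function(smiles, spec) {
  stopifnot(inherits(spec, "sar_spec"))
  frags <- spec$substituents$fragment
  regs <- vapply(spec$scaffolds$template, template_regex, character(1),
                 fragments = frags)
  vapply(smiles, function(s) {
    for (rg in regs) {
      m <- regexpr(rg, s, perl = TRUE)
      if (m[1] == -1) next
      st <- attr(m, "capture.start"); len <- attr(m, "capture.length")
      caught <- substring(s, st, st + len - 1)[st > 0]
      caught <- caught[nzchar(caught)]
      return(spec$baseline +
               sum(spec$substituents$w[match(caught, frags)]))
    }
    stop("molecule was not produced by this generator grammar: ", s,
         call. = FALSE)
  }, numeric(1), USE.NAMES = FALSE)
}

# Draw unique compounds (distinct canonical SMILES) from the grammar.
sample_unique_compounds <- function(spec, n_unique) {
  got <- data.frame(smiles = character(0), canonical = character(0),
                    p_true = numeric(0), stringsAsFactors = FALSE)
  guard <- 0L
  while (nrow(got) < n_unique) {
    guard <- guard + 1L
    if (guard > 50L) {
      stop("grammar cannot produce enough distinct compounds", call. = FALSE)
    }
    need <- n_unique - nrow(got)
    m <- max(need * 2L, 16L)
    sc <- sample.int(nrow(spec$scaffolds), m, replace = TRUE,
                     prob = spec$scaffolds$weight)
    k <- sample(0:3, m, replace = TRUE)
    batch <- vector("list", m)
    for (i in seq_len(m)) {
      n_slots <- template_slots(spec$scaffolds$template[sc[i]])
      ki <- min(k[i], n_slots)
      fill <- rep(NA_integer_, n_slots)
      if (ki > 0) {
        pos <- sample.int(n_slots, ki)
        fill[pos] <- sample.int(nrow(spec$substituents), ki, replace = TRUE)
      }
      batch[[i]] <- assemble_molecule(spec, sc[i], fill)
    }
    smi <- vapply(batch, `[[`, character(1), "smiles")
    can <- ob_canonical(smi)
    ok <- !is.na(can) & !duplicated(can) & !(can %in% got$canonical)
    p_true <- spec$baseline + vapply(batch, function(b)
      sum(b$counts * spec$substituents$w), numeric(1))
    got <- rbind(got, data.frame(
      smiles = smi[ok], canonical = can[ok], p_true = p_true[ok],
      stringsAsFactors = FALSE)[seq_len(min(need, sum(ok))), , drop = FALSE])
  }
  got
}

junk_violation <- function(row, kind) {
  switch(kind,
    low_confidence = { row$confidence_score <- sample(0:5, 1); row },
    wrong_units = { row$standard_units <- "ug.mL-1"; row },
    wrong_assay = { row$assay_type <- "F"; row },
    banned_comment = {
      row$activity_comment <- sample(c("Inconclusive", "Not determined"), 1)
      row
    },
    duplicate_flag = { row$potential_duplicates <- 1L; row },
    validity_comment = {
      row$data_validity_comment <- "Potential author error"; row
    },
    corrupt_smiles = { row$smiles <- paste0(row$smiles, "(%"); row }
  )
}

#' Generate a ChEMBL-shaped raw activity table
#'
#' Emits `n` activity rows from the planted additive SAR: unique compounds
#' with noisy measurements, an exact quota of duplicated compound re-
#' measurements, an exact quota of censored bounds (values at the assay
#' limits with ">"/"<" relations), and an exact quota of rows violating one
#' curation rule each (including corrupted SMILES). Byte-identical output for
#' identical specs.
#'
#' @param spec A [sar_spec()].
#' @return Data frame with the columns of [required_activity_columns()],
#'   carrying the generating truth in `attr(, "truth")` (a data frame with
#'   canonical SMILES and noiseless activity per unique compound).
#' @export
generate_activity_table <- function(spec) {
  stopifnot(inherits(spec, "sar_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n
    n_junk <- round_half_up(spec$junk_fraction * n)
    n_dup <- round_half_up(spec$duplicate_fraction * n)
    n_cens <- round_half_up(spec$censor_fraction * n)
    n_unique <- n - n_junk - n_dup
    if (n_unique < 1L) stop("no unique compounds left", call. = FALSE)

    uniq <- sample_unique_compounds(spec, n_unique)
    comp_idx <- c(seq_len(n_unique),
                  if (n_dup > 0) sample.int(n_unique, n_dup, replace = TRUE))
    p_noisy <- uniq$p_true[comp_idx] +
      stats::rnorm(length(comp_idx), 0, spec$noise_sd)
    v <- 10^(9 - p_noisy)
    relation <- rep("=", length(v))

    # censoring: natural clipping first, then forced rows to meet the quota
    lo <- v < spec$v_limits[1]; hi <- v > spec$v_limits[2]
    v[lo] <- spec$v_limits[1]; relation[lo] <- "<"
    v[hi] <- spec$v_limits[2]; relation[hi] <- ">"
    n_nat <- sum(lo | hi)
    if (n_nat < n_cens) {
      pool <- which(relation == "=")
      force_idx <- pool[sample.int(length(pool),
                                   min(n_cens - n_nat, length(pool)))]
      weak <- p_noisy[force_idx] < stats::median(p_noisy)
      v[force_idx] <- ifelse(weak, spec$v_limits[2], spec$v_limits[1])
      relation[force_idx] <- ifelse(weak, ">", "<")
    }

    clean <- data.frame(
      compound_id = sprintf("SYN-C%05d", comp_idx),
      smiles = uniq$smiles[comp_idx],
      standard_type = "IC50",
      standard_value = v,
      standard_units = "nM",
      standard_relation = relation,
      assay_type = "B",
      confidence_score = sample(6:9, length(v), replace = TRUE),
      activity_comment = "",
      potential_duplicates = 0L,
      data_validity_comment = "",
      target_id = spec$target_id,
      stringsAsFactors = FALSE
    )

    if (n_junk > 0) {
      kinds <- sample(c("low_confidence", "wrong_units", "wrong_assay",
                        "banned_comment", "duplicate_flag",
                        "validity_comment", "corrupt_smiles"),
                      n_junk, replace = TRUE)
      base_idx <- sample.int(n_unique, n_junk, replace = TRUE)
      junk <- do.call(rbind, lapply(seq_len(n_junk), function(i) {
        row <- clean[1, , drop = FALSE]
        row$compound_id <- sprintf("SYN-J%05d", i)
        row$smiles <- uniq$smiles[base_idx[i]]
        row$standard_value <- 10^(9 - (uniq$p_true[base_idx[i]] +
                                         stats::rnorm(1, 0, spec$noise_sd)))
        row$standard_relation <- "="
        junk_violation(row, kinds[i])
      }))
      tab <- rbind(clean, junk)
    } else {
      tab <- clean
    }

    tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
    rownames(tab) <- NULL
    attr(tab, "truth") <- uniq
    attr(tab, "sar_spec") <- spec
    tab
  })
}

#' Build a synthetic reference skeleton library
#'
#' Enumerates distinct all-carbon ring skeletons (single rings, and ring
#' pairs joined by short linkers) in ascending size order, canonicalized and
#' deduplicated. A synthetic stand-in for a database-wide scaffold inventory,
#' used to anchor binning schemes in tests and examples.
#'
#' @param n Number of skeletons required.
#' @return Data frame with columns `skeleton_smiles` and `size`.
#' @export
generate_reference_skeletons <- function(n) {
  ring <- function(k) paste0("C1", strrep("C", k - 2L), "C1")
  combos <- expand.grid(r1 = 3:12, link = 0:5, r2 = c(0L, 3:12))
  combos <- combos[combos$r2 == 0L | combos$r1 <= combos$r2, , drop = FALSE]
  combos$size <- combos$r1 + ifelse(combos$r2 > 0, combos$link + combos$r2, 0)
  combos <- combos[combos$r2 > 0 | combos$link == 0, , drop = FALSE]
  combos <- combos[order(combos$size, combos$r1, combos$link), , drop = FALSE]
  smi <- character(0); size <- integer(0)
  for (i in seq_len(nrow(combos))) {
    if (length(smi) >= n) break
    s <- if (combos$r2[i] == 0L) ring(combos$r1[i]) else {
      paste0(ring(combos$r1[i]), strrep("C", combos$link[i]),
             gsub("1", "2", ring(combos$r2[i]), fixed = TRUE))
    }
    smi <- c(smi, s); size <- c(size, combos$size[i])
  }
  can <- ob_canonical(smi)
  keep <- !is.na(can) & !duplicated(can)
  res <- data.frame(skeleton_smiles = can[keep], size = size[keep],
                    stringsAsFactors = FALSE)
  if (nrow(res) < n) {
    stop("cannot enumerate ", n, " distinct skeletons", call. = FALSE)
  }
  res[seq_len(n), , drop = FALSE]
}

#' Synthesize a dataset with a prescribed scaffold-bin profile
#'
#' Draws `n` compounds whose carbon skeletons fall into the bins of `scheme`
#' according to a multinomial draw from `bin_probabilities`. Compounds are
#' the skeleton structures themselves, so the profile is exact by
#' construction up to the multinomial draw.
#'
#' @param bin_probabilities Probability vector over the scheme's bins.
#' @param scheme A [build_binning()] scheme.
#' @param n Number of compounds.
#' @param seed Integer seed.
#' @return Curated-style data frame (`canonical_smiles`, `p_activity`,
#'   `relation`, `target_id`).
#' @export
generate_scaffold_profile <- function(bin_probabilities, scheme, n, seed) {
  p <- as.numeric(bin_probabilities)
  if (length(p) != scheme$n_bins) {
    stop("profile length does not match the scheme's bin count",
         call. = FALSE)
  }
  if (abs(sum(p) - 1) > 1e-6 || any(p < 0)) {
    stop("bin probabilities must be a distribution", call. = FALSE)
  }
  bins_of <- unname(scheme$map)
  withr::with_seed(as.integer(seed), {
    counts <- as.integer(stats::rmultinom(1, n, p))
    smiles <- unlist(lapply(seq_along(counts), function(b) {
      if (counts[b] == 0L) return(character(0))
      members <- scheme$reference[bins_of == b]
      if (!length(members)) {
        stop("probability mass on an empty bin (", b, ")", call. = FALSE)
      }
      sample(members, counts[b], replace = TRUE)
    }))
    smiles <- sample(smiles)
    data.frame(canonical_smiles = smiles, p_activity = 6.0, relation = "=",
               target_id = "SYN-T1", stringsAsFactors = FALSE)
  })
}
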