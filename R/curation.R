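#' Convert an activity value in nM to the p-activity (pIC50) scale
#'
#' Activities measured as IC50/EC50/Ki/Kd/Km in nanomolar units are expressed
#' as the negative base-10 logarithm of the molar value, `9 - log10(v_nM)`.
#' A 1 nM compound therefore has a pIC50 of 9, and 100 uM corresponds to 4.
#'
#' @param value Positive numeric vector of activity values in nM.
#' @return Numeric vector of p-activity values.
#' @examples
#' to_p_activity(c(1, 10, 100000))
#' @export
to_p_activity <- function(value) {
  if (!is.numeric(value)) stop("`value` must be numeric", call. = FALSE)
  if (any(!is.finite(value) | value <= 0)) {
    stop("activity values must be positive and finite (nM)", call. = FALSE)
  }
  9 - log10(value)
}

#' Filter settings for activity-table curation
#'
#' Encodes the record-level selection rules used when extracting binding data
#' from a ChEMBL-style activity table: minimum target-assignment confidence,
#' allowed assay types, units, relations, and banned comment strings.
#'
#' @param min_confidence Minimum confidence score retained (default 6).
#' @param assay_types Allowed assay type letters (default "B", binding).
#' @param units Allowed standard units (default "nM").
#' @param relations Allowed standard relations.
#' @param banned_comments Activity comments that disqualify a record.
#' @param banned_validity Data-validity comments that disqualify a record.
#' @return A list of class `curation_filters`.
#' @export
curation_filters <- function(min_confidence = 6L,
                             assay_types = "B",
                             units = "nM",
                             relations = c(">", ">=", "≥", "=",
                                           "<=", "≤", "<"),
                             banned_comments = c("Inconclusive",
                                                 "Not determined"),
                             banned_validity = "Potential author error") {
  structure(list(
    min_confidence = as.integer(min_confidence),
    assay_types = assay_types,
    units = units,
    relations = relations,
    banned_comments = banned_comments,
    banned_validity = banned_validity
  ), class = "curation_filters")
}

required_activity_columns <- function() {
  c("compound_id", "smiles", "standard_type", "standard_value",
    "standard_units", "standard_relation", "assay_type", "confidence_score",
    "activity_comment", "potential_duplicates", "data_validity_comment",
    "target_id")
}

check_activity_schema <- function(records) {
  missing <- setdiff(required_activity_columns(), names(records))
  if (length(missing)) {
    stop("activity table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(records)
}

#' Filter raw activity records
#'
#' Applies the record-level selection rules to a raw activity table: keeps
#' measurements with confidence score at or above the minimum, an allowed
#' assay type, allowed units and relation, a positive numeric value, no
#' banned activity/validity comment, and no potential-duplicate flag. Row
#' order is preserved. Each dropped row is attributed to the first rule it
#' fails, in a fixed rule order, so the per-rule drop counts plus the
#' survivors always sum to the input row count.
#'
#' @param records Data frame with the columns named by
#'   [required_activity_columns()].
#' @param filters A [curation_filters()] object.
#' @return List with `records` (the surviving rows) and `report` (named
#'   integer vector of drops per rule plus `survivors`).
#' @export
filter_records <- function(records, filters = curation_filters()) {
  check_activity_schema(records)
  n <- nrow(records)
  val <- suppressWarnings(as.numeric(records$standard_value))
  conf <- suppressWarnings(as.integer(records$confidence_score))
  fails <- list(
    low_confidence  = is.na(conf) | conf < filters$min_confidence,
    assay_type      = !(records$assay_type %in% filters$assay_types),
    units           = !(records$standard_units %in% filters$units),
    relation        = !(records$standard_relation %in% filters$relations),
    nonpositive_value = is.na(val) | val <= 0,
    activity_comment = records$activity_comment %in% filters$banned_comments,
    validity_comment = records$data_validity_comment %in% filters$banned_validity,
    potential_duplicate = !is.na(records$potential_duplicates) &
      records$potential_duplicates != 0
  )
  dropped_by <- rep(NA_character_, n)
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(dropped_by)
    dropped_by[hit] <- rule
  }
  keep <- is.na(dropped_by)
  drops <- vapply(names(fails), function(r) sum(dropped_by == r, na.rm = TRUE),
                  integer(1))
  list(
    records = records[keep, , drop = FALSE],
    report = c(drops, survivors = sum(keep))
  )
}

# SMILES-level protonation-state neutralization of simple acids and bases.
# Only applied when every charged atom in the fragment carries the same sign,
# which leaves nitro groups, azides and zwitterions untouched.
neutralize_smiles <- function(smiles) {
  neg <- grepl("-\\]", smiles)
  pos <- grepl("\\+\\]", smiles)
  if (neg && pos) return(smiles)
  s <- smiles
  if (neg) {
    s <- gsub("[O-]", "O", s, fixed = TRUE)
    s <- gsub("[S-]", "S", s, fixed = TRUE)
    s <- gsub("[NH-]", "N", s, fixed = TRUE)
    s <- gsub("[N-]", "N", s, fixed = TRUE)
  }
  if (pos) {
    s <- gsub("[NH4+]", "N", s, fixed = TRUE)
    s <- gsub("[NH3+]", "N", s, fixed = TRUE)
    s <- gsub("[NH2+]", "N", s, fixed = TRUE)
    s <- gsub("[NH+]", "N", s, fixed = TRUE)
    s <- gsub("[nH+]", "[nH]", s, fixed = TRUE)
    s <- gsub("[OH2+]", "O", s, fixed = TRUE)
    s <- gsub("[OH+]", "O", s, fixed = TRUE)
    s <- gsub("[SH+]", "S", s, fixed = TRUE)
  }
  s
}

#' Standardize a compound structure
#'
#' Retains the largest fragment by heavy-atom count (stripping salts and
#' solvents), neutralizes simple protonation states, and converts the result
#' to canonical SMILES. Outputs longer than 1000 characters are rejected.
#' Failures are returned as values, never raised, so a batch is never aborted
#' by one bad structure.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Data frame with columns `input`, `canonical_smiles` (NA on
#'   failure), `ok`, and `reason`.
#' @examples
#' standardize_structure("CC(=O)[O-].[Na+]")  # -> acetic acid
#' @export
standardize_structure <- function(smiles) {
  n <- length(smiles)
  out <- data.frame(
    input = as.character(smiles),
    canonical_smiles = rep(NA_character_, n),
    ok = rep(FALSE, n),
    reason = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(out)
  empty <- is.na(smiles) | !nzchar(trimws(smiles))
  out$reason[empty] <- "empty SMILES"
  work <- ifelse(empty, NA_character_, as.character(smiles))

  # salt/solvent stripping: keep the fragment with the most heavy atoms
  multi <- !is.na(work) & grepl(".", work, fixed = TRUE)
  for (i in which(multi)) {
    frags <- strsplit(work[i], ".", fixed = TRUE)[[1]]
    frags <- frags[nzchar(frags)]
    counts <- ob_heavy_atoms(frags)
    if (all(is.na(counts))) {
      work[i] <- NA_character_
      out$reason[i] <- "unparseable SMILES"
    } else {
      work[i] <- frags[which.max(counts)]
    }
  }

  todo <- which(!is.na(work))
  work[todo] <- vapply(work[todo], neutralize_smiles, character(1),
                       USE.NAMES = FALSE)
  # a molecule of > 1000 heavy atoms cannot canonicalize within the length
  # limit; reject before the (expensive) perception step
  huge <- !is.na(work) & nchar(work) > 1000L & smiles_atom_count(work) > 1000L
  out$reason[huge] <- "canonical SMILES longer than 1000 characters"
  work[huge] <- NA_character_
  can <- rep(NA_character_, n)
  can[todo] <- ob_canonical(work[todo])
  parse_fail <- !is.na(work) & is.na(can)
  out$reason[parse_fail] <- "unparseable SMILES"
  too_long <- !is.na(can) & nchar(can) > 1000L
  out$reason[too_long] <- "canonical SMILES longer than 1000 characters"
  can[too_long] <- NA_character_
  out$canonical_smiles <- can
  out$ok <- !is.na(can)
  out
}

#' Collapse duplicate compound-target measurements
#'
#' When a (canonical SMILES, target) pair carries several p-activity values,
#' the maximum (most active) value is kept, together with that record's
#' relation. Ties keep the first record in input order.
#'
#' @param records Data frame with columns `canonical_smiles`, `p_activity`,
#'   `relation`, `target_id`.
#' @return Data frame with one row per (canonical_smiles, target_id).
#' @export
aggregate_duplicates <- function(records) {
  stopifnot(all(c("canonical_smiles", "p_activity", "relation", "target_id")
                %in% names(records)))
  if (nrow(records) == 0L) return(records)
  key <- paste(records$canonical_smiles, records$target_id, sep = "\r")
  ord <- order(factor(key, levels = unique(key)), -records$p_activity,
               seq_len(nrow(records)))
  sorted <- records[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  res <- sorted[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a curated regression dataset from a raw activity table
#'
#' Runs the full curation protocol in order: record filtering, structure
#' standardization, p-activity transformation, and duplicate aggregation.
#' Censored measurements (relation ">" or "<") are retained as-is, with the
#' relation stored for provenance. An all-filtered input yields an empty
#' dataset with a warning, not an error.
#'
#' @param raw_table Raw activity data frame (see
#'   [required_activity_columns()]).
#' @param filters A [curation_filters()] object.
#' @return List of class `curation_result` with `dataset` (columns
#'   `canonical_smiles`, `p_activity`, `relation`, `target_id`) and `report`.
#' @export
build_dataset <- function(raw_table, filters = curation_filters()) {
  flt <- filter_records(raw_table, filters)
  surv <- flt$records
  std <- standardize_structure(surv$smiles)
  n_std_fail <- sum(!std$ok)
  okr <- surv[std$ok, , drop = FALSE]
  curated <- data.frame(
    canonical_smiles = std$canonical_smiles[std$ok],
    p_activity = to_p_activity(as.numeric(okr$standard_value)),
    relation = as.character(okr$standard_relation),
    target_id = as.character(okr$target_id),
    stringsAsFactors = FALSE
  )
  dataset <- aggregate_duplicates(curated)
  report <- list(
    input_rows = nrow(raw_table),
    filter_drops = flt$report[names(flt$report) != "survivors"],
    standardization_failures = n_std_fail,
    duplicate_collapsed = nrow(curated) - nrow(dataset),
    survivors = nrow(dataset)
  )
  if (nrow(dataset) == 0L) {
    warning("curation produced an empty dataset", call. = FALSE)
  }
  structure(list(dataset = dataset, report = report),
            class = "curation_result")
}

#' @export
print.curation_result <- function(x, ...) {
  cat("Curated activity dataset:", nrow(x$dataset), "compounds\n")
  cat("  input rows:              ", x$report$input_rows, "\n")
  drops <- x$report$filter_drops
  for (r in names(drops)) {
    if (drops[[r]] > 0) cat(sprintf("  dropped (%s): %d\n", r, drops[[r]]))
  }
  cat("  standardization failures:", x$report$standardization_failures, "\n")
  cat("  duplicates collapsed:    ", x$report$duplicate_collapsed, "\n")
  invisible(x)
}

#' Read a raw activity table from CSV/TSV
#'
#' @param path File path; tab- or comma-separated, with a header.
#' @param col_map Optional named character vector mapping the required column
#'   names to the names used in the file, e.g.
#'   `c(smiles = "canonical_smiles")`.
#' @return Data frame with the standard column names.
#' @export
read_activity_table <- function(path, col_map = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(tab)) {
        names(tab)[names(tab) == col_map[[std]]] <- std
      }
    }
  }
  check_activity_schema(tab)
  tab
}

#' Write a curated dataset to CSV
#' @param dataset Curated data frame.
#' @param path Output file path.
#' @export
write_curated <- function(dataset, path) {
  utils::write.csv(dataset, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a curation report to JSON
#' @param result A `curation_result` (or its `report` element).
#' @param path Output file path.
#' @export
write_curation_report <- function(result, path) {
  rep <- if (inherits(result, "curation_result")) result$report else result
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
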