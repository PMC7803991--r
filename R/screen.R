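#' Crippen-type octanol/water logP estimate
#'
#' Atomic-contribution lipophilicity (Wildman-Crippen parameterization, as
#' implemented in OpenBabel).
#'
#' @param smiles Character vector of SMILES.
#' @return Numeric vector of logP values (NA where parsing fails).
#' @export
compute_logp <- function(smiles) {
  out <- rep(NA_real_, length(smiles))
  can <- ob_canonical(smiles)
  ok <- which(!is.na(can))
  if (!length(ok)) return(out)
  mols <- ChemmineOB::forEachMol(
    "SMILES", paste0(paste(smiles[ok], collapse = "\n"), "\n"), identity)
  props <- ChemmineOB::prop_OB(mols)
  if (nrow(props) == length(ok)) out[ok] <- props$logP
  out
}

#' Screening criteria
#'
#' Threshold set for the virtual screen: minimum lipophilicity, minimum
#' predicted activity at the target, maximum predicted activity at the
#' anti-target, and a set of compounds excluded for having prior assay
#' reports.
#'
#' @param logp_min Minimum logP (default 2.0).
#' @param target_pic50_min Minimum predicted target pIC50 (default 7.5).
#' @param antitarget_pic50_max Maximum predicted anti-target pIC50
#'   (default 6.0).
#' @param excluded_compounds Character vector of compound ids to exclude.
#' @return List of class `screen_criteria`.
#' @export
screen_criteria <- function(logp_min = 2.0, target_pic50_min = 7.5,
                            antitarget_pic50_max = 6.0,
                            excluded_compounds = character(0)) {
  if (is.finite(target_pic50_min) && is.finite(antitarget_pic50_max) &&
      !(target_pic50_min > antitarget_pic50_max)) {
    stop("target threshold must exceed the anti-target threshold",
         call. = FALSE)
  }
  structure(list(logp_min = logp_min, target_pic50_min = target_pic50_min,
                 antitarget_pic50_max = antitarget_pic50_max,
                 excluded_compounds = excluded_compounds),
            class = "screen_criteria")
}

#' Virtual screen of a candidate library
#'
#' Keeps candidates satisfying all four predicates — lipophilic enough,
#' predicted active at the target, predicted inactive at the anti-target, and
#' not previously assayed — and ranks hits by descending target prediction
#' (stable on ties). Candidates lacking a prediction are skipped with a
#' warning. Every returned row carries its per-criterion values for audit.
#'
#' @param candidates Data frame with columns `id` and `smiles`.
#' @param target_preds,antitarget_preds Numeric vectors aligned with
#'   `candidates` (predicted pIC50 at target and anti-target).
#' @param criteria A [screen_criteria()].
#' @param logp Optional precomputed logP vector (computed when omitted).
#' @return Data frame of hits: id, smiles, logp, target_pred,
#'   antitarget_pred, and the four pass flags, ranked by target prediction.
#' @export
screen <- function(candidates, target_preds, antitarget_preds,
                   criteria = screen_criteria(), logp = NULL) {
  stopifnot(is.data.frame(candidates),
            all(c("id", "smiles") %in% names(candidates)))
  n <- nrow(candidates)
  stopifnot(length(target_preds) == n, length(antitarget_preds) == n)
  missing <- is.na(target_preds) | is.na(antitarget_preds)
  if (any(missing)) {
    warning(sum(missing), " candidate(s) lack predictions and were skipped",
            call. = FALSE)
  }
  if (is.null(logp)) logp <- compute_logp(candidates$smiles)
  audit <- data.frame(
    id = candidates$id, smiles = candidates$smiles, logp = logp,
    target_pred = target_preds, antitarget_pred = antitarget_preds,
    pass_logp = !is.na(logp) & logp > criteria$logp_min,
    pass_target = !missing & target_preds >= criteria$target_pic50_min,
    pass_antitarget = !missing &
      antitarget_preds <= criteria$antitarget_pic50_max,
    pass_not_excluded = !(candidates$id %in% criteria$excluded_compounds),
    stringsAsFactors = FALSE
  )
  hit <- !missing & audit$pass_logp & audit$pass_target &
    audit$pass_antitarget & audit$pass_not_excluded
  hits <- audit[hit, , drop = FALSE]
  hits <- hits[order(-hits$target_pred), , drop = FALSE]  # stable on ties
  rownames(hits) <- NULL
  hits
}
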