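#' Prediction set
#'
#' Pairs observed and predicted p-activity values for metric computation.
#'
#' @param y Observed values.
#' @param f Predicted values.
#' @return List of class `prediction_set` with elements `y`, `f`, `n`.
#' @export
prediction_set <- function(y, f) {
  y <- as.numeric(y); f <- as.numeric(f)
  if (length(y) != length(f)) {
    stop("observed and predicted vectors differ in length", call. = FALSE)
  }
  if (length(y) < 1L) stop("prediction set must be non-empty", call. = FALSE)
  structure(list(y = y, f = f, n = length(y)), class = "prediction_set")
}

as_pred_pair <- function(p, f) {
  if (inherits(p, "prediction_set")) return(p)
  prediction_set(p, f)
}

#' Mean absolute error
#' @param p A [prediction_set()], or the observed values.
#' @param f Predicted values (when `p` is a plain vector).
#' @return `mean(|f - y|)`.
#' @export
compute_mae <- function(p, f = NULL) {
  p <- as_pred_pair(p, f)
  mean(abs(p$f - p$y))
}

#' Root-mean-square error
#'
#' Satisfies `MAE <= RMSE <= sqrt(n) * MAE` for any prediction set.
#' @inheritParams compute_mae
#' @export
compute_rmse <- function(p, f = NULL) {
  p <- as_pred_pair(p, f)
  sqrt(mean((p$f - p$y)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - RSS/TSS` with `RSS = sum((y - f)^2)` and
#' `TSS = sum((y - mean(y))^2)`. Undefined (error) when the observed values
#' are constant.
#' @inheritParams compute_mae
#' @export
compute_r2 <- function(p, f = NULL) {
  p <- as_pred_pair(p, f)
  tss <- sum((p$y - mean(p$y))^2)
  if (p$n < 2L || tss <= 0) {
    stop("R^2 is undefined for constant observed values", call. = FALSE)
  }
  1 - sum((p$y - p$f)^2) / tss
}

#' The 2R2_MAE model-selection score
#'
#' `(R^2 - MAE) + R^2`: among settings of equal MAE the higher R^2 wins, and
#' among settings of equal `R^2 - MAE` the higher R^2 wins. Higher is better;
#' a perfect prediction scores 2.
#'
#' @param r2 Coefficient of determination.
#' @param mae Mean absolute error.
#' @return Numeric score.
#' @examples
#' compute_2r2_mae(r2 = 0.67, mae = 0.86)  # 0.48
#' @export
compute_2r2_mae <- function(r2, mae) {
  (r2 - mae) + r2
}

# All three validation metrics at once; used by the trainer and the search.
validation_metrics <- function(y, f) {
  mae <- mean(abs(f - y))
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum((y - f)^2) / tss else NA_real_
  c(mae = mae, r2 = r2, trmae = (r2 - mae) + r2)
}
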