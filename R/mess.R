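## Multivariate environmental similarity surfaces (MESS) and non-analog
## masking of model predictions.

#' MESS similarity score for one variable
#'
#' With `f` the percentage of reference points strictly below the candidate
#' value `v`, and `min`/`max` the reference extremes:
#' `f = 0   -> S = 100 * (v - min) / (max - min)` (negative: below range),
#' `0 < f <= 50 -> S = 2 f`,
#' `50 < f < 100 -> S = 2 (100 - f)`,
#' `f = 100 -> S = 100 * (max - v) / (max - min)` (negative: above range).
#' S is piecewise linear and continuous in `v`; negative values flag
#' environments outside the reference range.
#'
#' A degenerate reference (min = max) scores 0 when `v` equals the constant
#' and `-100 * |v - min| / scale_guard` otherwise (the extrapolation
#' branches with a unit denominator guard), so constant predictors still
#' flag any departure as non-analog.
#'
#' @param reference numeric vector of training values for the variable.
#' @param v candidate value(s).
#' @param ties_half count ties as half below (some reference implementations
#'   do); default FALSE (strictly below).
#' @return numeric vector of similarity scores.
#' @export
#' @examples
#' mess_score(0:9, 2)                 # f = 20 -> 40
#' mess_score(0:10, 5)                # median -> 100
#' mess_score(0:9, -1) < 0            # extrapolation
mess_score <- function(reference, v, ties_half = FALSE) {
  reference <- reference[is.finite(reference)]
  if (!length(reference)) stop("empty reference")
  rmin <- min(reference); rmax <- max(reference)
  n <- length(reference)
  vapply(v, function(vi) {
    below <- sum(reference < vi)
    if (ties_half) below <- below + 0.5 * sum(reference == vi)
    f <- 100 * below / n
    if (rmax == rmin) {
      if (vi == rmin) 0 else -100 * abs(vi - rmin)
    } else if (f == 0) {
      100 * (vi - rmin) / (rmax - rmin)
    } else if (f <= 50) {
      2 * f
    } else if (f < 100) {
      2 * (100 - f)
    } else {
      100 * (rmax - vi) / (rmax - rmin)
    }
  }, numeric(1))
}

#' Multivariate environmental similarity surface over a prediction table
#'
#' Per prediction location, computes the per-variable similarity scores
#' against the training data and takes the minimum; locations with
#' `mess < 0` are non-analog.
#'
#' @param training data.frame of training-cell predictor values.
#' @param candidates data.frame of prediction-cell predictor values (same
#'   columns).
#' @param ties_half passed to [mess_score()].
#' @return data.frame: one `S_<var>` column per variable, `mess` (row
#'   minimum) and logical `mask` (`mess < 0`).
#' @export
mess_surface <- function(training, candidates, ties_half = FALSE) {
  vars <- names(training)
  if (!setequal(vars, names(candidates)))
    stop("training and candidate predictor sets differ")
  S <- sapply(vars, function(vn) mess_score(training[[vn]], candidates[[vn]],
                                            ties_half = ties_half))
  S <- matrix(S, nrow = nrow(candidates),
              dimnames = list(NULL, paste0("S_", vars)))
  mess <- apply(S, 1, min)
  out <- as.data.frame(S)
  out$mess <- mess
  out$mask <- mess < 0
  out
}

#' Mask predictions in non-analog environments
#'
#' Computes the MESS surface of the prediction cells against the training
#' environment over the model's predictors and sets predictions with
#' `mess < 0` to `NA` in the masked columns; the unmasked values and the
#' mask flag are retained so tables stay complete.
#'
#' @param predictions data.frame with a `cell` column and prediction columns
#'   (e.g. `median`, `lower`, `upper`).
#' @param training_env training-cell predictor table (predictors only).
#' @param prediction_env predictor table aligned row-wise with `predictions`.
#' @param value_cols prediction columns to mask (default all numeric except
#'   `cell`).
#' @return `predictions` with added `mess`, `mask` and `<col>_masked`
#'   columns.
#' @export
mask_predictions <- function(predictions, training_env, prediction_env,
                             value_cols = NULL) {
  if (nrow(prediction_env) != nrow(predictions))
    stop("prediction_env and predictions must align row-wise")
  ms <- mess_surface(training_env, prediction_env)
  if (is.null(value_cols))
    value_cols <- setdiff(names(predictions)[vapply(predictions, is.numeric, TRUE)],
                          c("row", "col", "x", "y", "lat", "lon"))
  out <- predictions
  out$mess <- ms$mess
  out$mask <- ms$mask
  for (vc in value_cols) {
    masked <- out[[vc]]
    masked[out$mask] <- NA_real_
    out[[paste0(vc, "_masked")]] <- masked
  }
  out
}
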