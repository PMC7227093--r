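#' False discovery rate of a signature
#'
#' Fraction of selected genes that are truly non-informative, i.e. have index
#' greater than `n_inf` (informative genes are by convention the first
#' `n_inf`).  The FDR of an empty signature is 1: all existing signal was
#' missed, the worst possible selection outcome.
#'
#' @param selected integer vector of selected gene indices (possibly empty).
#' @param n_inf number of informative genes.
#' @return A proportion in `[0, 1]`.
#' @export
false_discovery_rate <- function(selected, n_inf) {
  if (length(selected) == 0) return(1)
  mean(selected > n_inf)
}

#' Mean squared prediction error
#'
#' `mean((y_hat - y_val)^2)`.  In the study pipeline the predictions feeding
#' this score are computed on normalized but *uncorrected* validation
#' expression, mimicking prediction for single future samples for which batch
#' correction is impossible.
#'
#' @param y_hat predicted outcomes.
#' @param y_val observed validation outcomes, same length.
#' @return Non-negative scalar.
#' @export
mean_square_prediction_error <- function(y_hat, y_val) {
  if (length(y_hat) != length(y_val))
    stop_invalid("'y_hat' and 'y_val' must have the same length")
  mean((y_hat - y_val)^2)
}

#' Successful validation indicator
#'
#' 1 if a one-sided Pearson correlation test (alternative: correlation > 0)
#' between predictions and observed validation outcomes has p < `alpha`, else
#' 0.  Constant predictions -- in particular those of an empty signature --
#' cannot validate and score 0.
#'
#' @param y_hat predicted outcomes.
#' @param y_val observed validation outcomes.
#' @param alpha significance level (default 0.05).
#' @return 0 or 1.
#' @export
successful_validation <- function(y_hat, y_val, alpha = 0.05) {
  if (length(y_hat) != length(y_val))
    stop_invalid("'y_hat' and 'y_val' must have the same length")
  n <- length(y_hat)
  if (n < 3) stop_invalid("need >= 3 observations for the correlation test")
  if (sd(y_hat) == 0 || sd(y_val) == 0) return(0L)
  r <- cor(y_hat, y_val)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- pt(tstat, df = n - 2, lower.tail = FALSE)
  as.integer(p < alpha)
}

#' Calibration slope
#'
#' Slope of the simple linear regression of the observed validation outcome
#' on the predicted outcome; 1 is ideal.  Constants are uncorrelated with
#' anything, so constant predictions (empty signatures included) score 0.
#'
#' @param y_hat predicted outcomes.
#' @param y_val observed validation outcomes.
#' @return OLS slope (scalar).
#' @export
calibration_slope <- function(y_hat, y_val) {
  if (length(y_hat) != length(y_val))
    stop_invalid("'y_hat' and 'y_val' must have the same length")
  if (length(y_hat) < 2) stop_invalid("need >= 2 observations")
  v <- var(y_hat)
  if (v == 0) return(0)
  cov(y_hat, y_val) / v
}

#' @importFrom stats cov
NULL

#' Score one discovery x validation combination
#'
#' Applies a fitted signature to a processed validation cohort and returns
#' all per-iteration quantities: FDR of the selected set, MSPE computed from
#' predictions on the normalized *uncorrected* validation expression, SV and
#' CS computed from predictions on the batch-corrected expression, plus the
#' signature length and a non-emptiness flag.
#'
#' @param signature a `signature_fit` fitted on discovery data.
#' @param validation a `processed_dataset` (the validation cohort).
#' @param n_inf number of informative genes in the generating model.
#' @return One-row `data.frame` with columns `fdr`, `mspe`, `sv`, `cs`,
#'   `sig_length`, `nonempty`.
#' @export
score_combination <- function(signature, validation, n_inf) {
  stopifnot(inherits(validation, "processed_dataset"))
  y_val <- validation$y
  y_hat_raw <- predict_outcome(signature, validation$X_norm)
  y_hat_cor <- predict_outcome(signature, validation$X_corrected)
  k <- length(signature$selected)
  data.frame(
    fdr = false_discovery_rate(signature$selected, n_inf),
    mspe = mean_square_prediction_error(y_hat_raw, y_val),
    sv = successful_validation(y_hat_cor, y_val),
    cs = calibration_slope(y_hat_cor, y_val),
    sig_length = k,
    nonempty = as.integer(k > 0)
  )
}
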