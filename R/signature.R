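#' Fit a lasso signature with the one-standard-error rule
#'
#' Fits the linear model `y = b0 + X b + e` by lasso regression over a
#' descending penalty path (glmnet, internal predictor standardization,
#' unpenalized intercept) and selects the penalty by K-fold cross-validation
#' with the one-standard-error rule: the largest (most strongly penalizing)
#' lambda whose CV mean squared error is within one standard error of the
#' minimum.  Genes with non-zero coefficient at that penalty form the
#' signature; an empty signature (intercept only) is a legitimate outcome and
#' is retained.
#'
#' Fold assignment is drawn from the current RNG stream (or supplied via
#' `foldid`), so fits are bitwise reproducible under a fixed seed.
#'
#' @param X numeric matrix of predictors (samples x genes).
#' @param y numeric outcome vector.
#' @param n_folds number of CV folds (default 10).
#' @param foldid optional integer vector of fold assignments in
#'   `1:n_folds`, one per sample; overrides `n_folds`-based random folds.
#' @return An object of class `signature_fit`: `intercept`, `coefficients`
#'   (length `ncol(X)`, on the input scale), `selected` (indices of non-zero
#'   coefficients), `lambda_1se`, `lambda_min`, `lambda_path`, `cvm`, `cvsd`,
#'   `n_folds`.
#' @export
fit_signature <- function(X, y, n_folds = 10, foldid = NULL) {
  X <- as.matrix(X)
  if (anyNA(X) || any(!is.finite(X)) || anyNA(y) || any(!is.finite(y)))
    stop_invalid("'X' and 'y' must be finite")
  if (nrow(X) != length(y))
    stop_invalid("nrow(X) must equal length(y)")
  if (var(y) == 0)
    stop_invalid("constant outcome: lasso fit is degenerate",
                 "centersim_fit_degenerate")
  if (is.null(foldid)) {
    if (n_folds < 3 || n_folds > nrow(X))
      stop_invalid("need 3 <= n_folds <= number of samples")
    foldid <- sample(rep_len(seq_len(n_folds), nrow(X)))
  }
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                          standardize = TRUE)
  cf <- coef(cv, s = "lambda.1se")
  coefficients <- as.numeric(cf)[-1]
  structure(list(
    intercept = as.numeric(cf)[1],
    coefficients = coefficients,
    selected = which(coefficients != 0),
    lambda_1se = cv$lambda.1se,
    lambda_min = cv$lambda.min,
    lambda_path = cv$lambda,
    cvm = cv$cvm,
    cvsd = cv$cvsd,
    nzero = as.integer(cv$nzero),
    n_folds = max(foldid)
  ), class = "signature_fit")
}

#' @exportS3Method base::print
print.signature_fit <- function(x, ...) {
  cat(sprintf("Lasso signature: %d gene(s), lambda.1se = %.4g\n",
              length(x$selected), x$lambda_1se))
  invisible(x)
}

#' Predict outcomes from a fitted signature
#'
#' Affine prediction `b0 + X b`.  An empty signature predicts the constant
#' intercept for every sample.
#'
#' @param signature a `signature_fit` from [fit_signature()].
#' @param X expression matrix with one column per coefficient.
#' @return Numeric vector of predicted outcomes, one per row of `X`.
#' @export
predict_outcome <- function(signature, X) {
  stopifnot(inherits(signature, "signature_fit"))
  X <- as.matrix(X)
  if (ncol(X) != length(signature$coefficients))
    stop_invalid("ncol(X) must match the signature's coefficient length")
  sel <- signature$selected
  if (length(sel) == 0)
    return(rep(signature$intercept, nrow(X)))
  drop(signature$intercept +
         X[, sel, drop = FALSE] %*% signature$coefficients[sel])
}

#' Write / read a signature as plain text
#'
#' Serializes the non-zero coefficients as CSV (`gene_index, coefficient`)
#' beneath a small comment header carrying the intercept and chosen penalty.
#'
#' @param signature a `signature_fit`.
#' @param path output file.
#' @param n_genes total gene count (needed to reconstruct the coefficient
#'   vector when reading).
#' @return `write_signature` returns `path` invisibly; `read_signature`
#'   returns a `signature_fit` (path/CV diagnostics are not round-tripped).
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "signature_fit"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# intercept=%.17g lambda_1se=%.17g n_genes=%d",
                     signature$intercept, signature$lambda_1se,
                     length(signature$coefficients)), con)
  writeLines("gene_index,coefficient", con)
  if (length(signature$selected))
    writeLines(sprintf("%d,%.17g", signature$selected,
                       signature$coefficients[signature$selected]), con)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  header <- readLines(path, n = 1L)
  kv <- strsplit(strsplit(sub("^#\\s*", "", header), "\\s+")[[1]], "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  intercept <- as.numeric(vals[["intercept"]])
  lambda <- as.numeric(vals[["lambda_1se"]])
  n_genes <- as.integer(vals[["n_genes"]])
  tab <- read.csv(path, skip = 1L)
  coefficients <- numeric(n_genes)
  coefficients[tab$gene_index] <- tab$coefficient
  structure(list(intercept = intercept, coefficients = coefficients,
                 selected = which(coefficients != 0), lambda_1se = lambda,
                 lambda_min = NA_real_, lambda_path = NULL, cvm = NULL,
                 cvsd = NULL, nzero = NULL, n_folds = NA_integer_),
            class = "signature_fit")
}
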