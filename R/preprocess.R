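#' Per-sample standardization
#'
#' Centers and scales every sample (row) of an expression matrix to mean 0 and
#' unit standard deviation.  The sample-SD convention (divisor `N_g - 1`, as
#' in `scale()`) is used.  Genes are left untouched otherwise; the operation
#' is idempotent.
#'
#' @param X numeric matrix, samples x genes, at least 2 genes per sample.
#' @return Matrix of the same shape with every row at mean 0, SD 1.
#' @examples
#' normalize_samples(rbind(c(1, 2, 3)))   # -1 0 1
#' @export
normalize_samples <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2)
    stop_invalid("need >= 2 genes per sample to standardize")
  if (anyNA(X) || any(!is.finite(X)))
    stop_invalid("'X' must be finite")
  mu <- rowMeans(X)
  Xc <- X - mu
  s <- sqrt(rowSums(Xc^2) / (ncol(X) - 1))
  if (any(s == 0))
    stop_invalid("constant sample(s): cannot standardize a zero-variance row",
                 "centersim_degenerate_sample")
  Xc / s
}

#' Parametric empirical-Bayes batch correction (ComBat)
#'
#' Location/scale batch adjustment with parametric empirical-Bayes shrinkage
#' (Johnson, Li & Rabinovic 2007), the default mode of the standard ComBat
#' tool, with no biological covariates and no reference batch:
#' (1) gene-wise standardization using the batch-size-weighted grand mean and
#' the pooled variance of residuals from a batch-means fit; (2) per-batch
#' gene-wise location (`gamma_hat`, batch means) and scale (`delta_hat`,
#' batch variances) estimates; (3) shrinkage of `gamma_hat` toward a normal
#' prior and `delta_hat` toward an inverse-gamma prior, hyperparameters by
#' method of moments, solved by the standard fixed-point iteration; (4) data
#' adjusted and back-transformed to the original location/scale.
#'
#' @param X numeric matrix, samples x genes.
#' @param centers batch labels, one per sample; at least 2 distinct batches
#'   with at least 2 samples each.
#' @param conv convergence tolerance of the fixed-point iteration for the
#'   empirical-Bayes batch parameters.
#' @return Matrix of the same shape as `X`, batch-adjusted.
#' @references Johnson WE, Li C, Rabinovic A (2007). Adjusting batch effects
#'   in microarray expression data using empirical Bayes methods.
#'   Biostatistics 8(1):118-127.
#' @export
combat_correct <- function(X, centers, conv = 1e-4) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(centers) != n)
    stop_invalid("'centers' must have one label per sample (row)")
  batch <- as.factor(centers)
  n_batch <- nlevels(batch)
  if (n_batch < 2)
    stop_invalid("batch correction needs >= 2 batches; single-center data must skip it")
  n_b <- tabulate(batch)
  if (any(n_b < 2))
    stop_invalid("every batch needs >= 2 samples")
  if (anyNA(X) || any(!is.finite(X)))
    stop_invalid("'X' must be finite")

  idx <- split(seq_len(n), batch)

  # gene-wise standardization against the weighted grand mean / pooled variance
  batch_means <- vapply(idx, function(i) colMeans(X[i, , drop = FALSE]),
                        numeric(ncol(X)))                  # genes x batches
  grand_mean <- as.vector(batch_means %*% (n_b / n))
  resid <- X - t(batch_means)[batch, , drop = FALSE]
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled == 0))
    stop_invalid("gene(s) constant within every batch: cannot batch-correct",
                 "centersim_degenerate_gene")
  s_data <- sweep(sweep(X, 2, grand_mean), 2, sqrt(var_pooled), "/")

  # batch-wise location/scale estimates on the standardized data
  gamma_hat <- t(vapply(idx, function(i) colMeans(s_data[i, , drop = FALSE]),
                        numeric(ncol(X))))                 # batches x genes
  delta_hat <- t(vapply(idx, function(i) {
    xi <- s_data[i, , drop = FALSE]
    colSums(sweep(xi, 2, colMeans(xi))^2) / (length(i) - 1)
  }, numeric(ncol(X))))

  # hyperpriors by method of moments
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1, var)
  d_m <- rowMeans(delta_hat)
  d_s2 <- apply(delta_hat, 1, var)
  a_prior <- (2 * d_s2 + d_m^2) / d_s2
  b_prior <- (d_m * d_s2 + d_m^3) / d_s2

  out <- s_data
  for (j in seq_len(n_batch)) {
    i <- idx[[j]]
    nj <- length(i)
    sd_j <- t(s_data[i, , drop = FALSE])                   # genes x samples
    g_hat <- gamma_hat[j, ]
    g_old <- g_hat
    d_old <- delta_hat[j, ]
    change <- 1
    while (change > conv) {
      g_new <- (t2[j] * nj * g_hat + d_old * gamma_bar[j]) /
        (t2[j] * nj + d_old)
      sum2 <- rowSums((sd_j - g_new)^2)
      d_new <- (0.5 * sum2 + b_prior[j]) / (nj / 2 + a_prior[j] - 1)
      change <- max(abs(g_new - g_old) / g_old, abs(d_new - d_old) / d_old)
      g_old <- g_new
      d_old <- d_new
    }
    out[i, ] <- sweep(sweep(s_data[i, , drop = FALSE], 2, g_old),
                      2, sqrt(d_old), "/")
  }
  sweep(sweep(out, 2, sqrt(var_pooled), "*"), 2, grand_mean, "+")
}

#' Normalize and batch-correct a generated cohort
#'
#' Applies the processing pipeline in the fixed order: per-sample
#' standardization first, then (for multi-center cohorts only) ComBat batch
#' correction using the cohort's own center labels.  Both matrices are kept:
#' predictions feeding the mean squared prediction error are made on the
#' normalized but uncorrected data (a single future sample cannot be
#' batch-corrected), while the other scores use the corrected data.
#'
#' @param dataset a `hornung_dataset` from [generate_dataset()].
#' @return A list of class `processed_dataset` with `X_norm`, `X_corrected`
#'   (identical to `X_norm` for SC cohorts), and `y`, `a`, `centers`,
#'   `design` carried over.
#' @export
preprocess_dataset <- function(dataset) {
  stopifnot(inherits(dataset, "hornung_dataset"))
  X_norm <- normalize_samples(dataset$X)
  X_corrected <- if (dataset$design == "MC")
    combat_correct(X_norm, dataset$centers) else X_norm
  structure(list(X_norm = X_norm, X_corrected = X_corrected,
                 y = dataset$y, a = dataset$a, centers = dataset$centers,
                 design = dataset$design),
            class = "processed_dataset")
}
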