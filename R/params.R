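#' Simulation parameters for the latent-state batch model
#'
#' Bundles the full parameter set of one simulation setting. The defaults are
#' the base configuration of the signal-strength scenario: cohorts of
#' `N_s = 100` samples with `N_g = 1000` genes of which the first
#' `n_inf = 300` are informative, a mean effect size `beta_mean` of 0.25,
#' multi-center cohorts spread over `N_c = 8` centers with at least
#' `n_min = 10` samples each, `m = 5` latent factors per center, and
#' observation noise with standard deviation `sigma_y = 0.1`.  All random
#' model parameters (basal levels, true states, batch shifts, factor
#' loadings, factor weights, noise scalings, noise) are standard normal.
#'
#' @param beta_mean mean effect size of the informative genes (unitless,
#'   >= 0). The per-gene effect sizes decrease linearly over the informative
#'   genes with this mean; see [effect_size_vector()].
#' @param n_inf number of informative genes (0 <= n_inf <= N_g).
#' @param N_s samples per generated cohort.
#' @param N_c number of centers in a multi-center cohort.
#' @param n_min minimum number of samples per center; requires
#'   `N_c * n_min <= N_s`.
#' @param N_g total number of genes.
#' @param m number of latent factors per center (>= 0).
#' @param sigma_y standard deviation of the additive observation noise on the
#'   outcome (> 0).
#'
#' @return An object of class `hornung_params` (a named list).
#' @examples
#' p <- hornung_params(beta_mean = 0.14)
#' p$N_s
#' @export
hornung_params <- function(beta_mean = 0.25, n_inf = 300, N_s = 100,
                           N_c = 8, n_min = 10, N_g = 1000, m = 5,
                           sigma_y = 0.1) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_invalid(sprintf("'%s' must be a single finite number", nm),
                   "centersim_invalid_parameter")
    x
  }
  for (nm in c("beta_mean", "n_inf", "N_s", "N_c", "n_min", "N_g", "m",
               "sigma_y"))
    num1(get(nm), nm)
  if (beta_mean < 0)
    stop_invalid("'beta_mean' must be >= 0", "centersim_invalid_parameter")
  if (n_inf < 0 || n_inf > N_g)
    stop_invalid("'n_inf' must satisfy 0 <= n_inf <= N_g",
                 "centersim_invalid_parameter")
  if (sigma_y <= 0)
    stop_invalid("'sigma_y' must be > 0", "centersim_invalid_parameter")
  if (m < 0)
    stop_invalid("'m' must be >= 0", "centersim_invalid_parameter")
  if (N_s < 2 || N_g < 2 || N_c < 1 || n_min < 1)
    stop_invalid("'N_s' and 'N_g' must be >= 2; 'N_c' and 'n_min' >= 1",
                 "centersim_invalid_parameter")
  if (N_c * n_min > N_s)
    stop_invalid(sprintf(
      "multi-center design infeasible: N_c * n_min = %d exceeds N_s = %d",
      N_c * n_min, N_s), "centersim_invalid_parameter")
  structure(list(beta_mean = beta_mean, n_inf = as.integer(n_inf),
                 N_s = as.integer(N_s), N_c = as.integer(N_c),
                 n_min = as.integer(n_min), N_g = as.integer(N_g),
                 m = as.integer(m), sigma_y = sigma_y),
            class = "hornung_params")
}

#' @exportS3Method base::print
print.hornung_params <- function(x, ...) {
  cat("Latent-state batch-model parameters\n")
  cat(sprintf("  mean effect size      : %g over %d informative / %d genes\n",
              x$beta_mean, x$n_inf, x$N_g))
  cat(sprintf("  cohort size           : %d samples (MC: %d centers, >= %d each)\n",
              x$N_s, x$N_c, x$n_min))
  cat(sprintf("  latent factors/center : %d\n", x$m))
  cat(sprintf("  outcome noise SD      : %g\n", x$sigma_y))
  invisible(x)
}

#' Linearly graded per-gene effect sizes
#'
#' The effect size of informative gene `g` (1-based, `g <= n_inf`) is
#' `2 * beta_mean * (1 - g / (n_inf + 1))`; genes beyond `n_inf` have effect
#' size zero.  The grading is symmetric about its mean, so the average over
#' the informative genes equals `beta_mean` exactly and the total signal is
#' `beta_mean * n_inf`.
#'
#' @param beta_mean mean effect size over the informative genes (>= 0).
#' @param n_inf number of informative genes.
#' @param N_g total number of genes.
#' @return Numeric vector of length `N_g`, non-increasing and strictly
#'   positive over `1:n_inf` (when `beta_mean > 0`), zero elsewhere.
#' @examples
#' b <- effect_size_vector(0.25, 300, 1000)
#' mean(b[1:300])   # 0.25
#' @export
effect_size_vector <- function(beta_mean, n_inf, N_g) {
  if (!is.numeric(beta_mean) || length(beta_mean) != 1L || beta_mean < 0)
    stop_invalid("'beta_mean' must be a single number >= 0",
                 "centersim_invalid_parameter")
  if (n_inf < 0 || n_inf > N_g)
    stop_invalid("'n_inf' must satisfy 0 <= n_inf <= N_g",
                 "centersim_invalid_parameter")
  beta <- numeric(N_g)
  if (n_inf >= 1) {
    g <- seq_len(n_inf)
    beta[g] <- 2 * beta_mean * (1 - g / (n_inf + 1))
  }
  beta
}
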