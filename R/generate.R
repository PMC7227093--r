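#' Allocate samples to centers
#'
#' Assigns `n_min` samples to every center and distributes the remaining
#' `N_s - N_c * n_min` samples independently with equal probability across
#' centers, consuming the current RNG stream.
#'
#' @param N_s total number of samples.
#' @param N_c number of centers.
#' @param n_min minimum samples per center.
#' @return Integer vector of length `N_s` with center labels in `1:N_c`;
#'   every center occurs at least `n_min` times.
#' @export
allocate_centers <- function(N_s, N_c, n_min) {
  if (N_c * n_min > N_s)
    stop_invalid(sprintf(
      "cannot place %d centers with >= %d samples each into %d samples",
      N_c, n_min, N_s), "centersim_invalid_parameter")
  centers <- rep(seq_len(N_c), each = n_min)
  extra <- N_s - N_c * n_min
  if (extra > 0)
    centers <- c(centers, sample.int(N_c, extra, replace = TRUE))
  sort(centers)
}

#' Generate one cohort from the latent-state batch model
#'
#' Builds the expression matrix
#' \deqn{x_{ijg} = \alpha_g + a_{ij}\,\beta_g + \gamma_{jg}
#'       + \sum_{l=1}^{m} b_{jgl} Z_{ijl} + \delta_{jg}\,\epsilon_{ijg}}
#' and the outcome \eqn{y_{ij} = a_{ij} + \eta_{ij}},
#' \eqn{\eta \sim N(0, \sigma_y^2)}.  The true states `a`, factor weights
#' `Z` and noise `eps` are drawn per sample; the batch parameters
#' (`gamma`, `b`, `delta`, all standard normal) are drawn freshly for every
#' center so that each center carries a unique batch pattern shared by its
#' samples.  A single-center cohort uses one such pattern for all samples.
#'
#' The basal levels `alpha` are passed in (rather than drawn here) so that
#' the four cohorts of one Monte-Carlo iteration can share the same gene-level
#' biology.
#'
#' @param params a [hornung_params()] object.
#' @param effect_sizes per-gene effect sizes, length `N_g`
#'   (see [effect_size_vector()]).
#' @param alpha per-gene basal expression levels, length `N_g`.
#' @param design `"SC"` (one center) or `"MC"` (`N_c` centers with at least
#'   `n_min` samples each).
#' @param gamma_sd,delta_sd standard deviations of the batch shift and noise
#'   scaling draws.  Both are 1 in the model; setting them to 0 switches the
#'   corresponding term off, which is useful only for diagnostics and tests.
#' @return A list of class `hornung_dataset` with elements `X` (samples x
#'   genes), `y`, `a`, `centers`, and `design`.
#' @examples
#' set.seed(1)
#' p <- hornung_params(N_s = 20, N_g = 50, n_inf = 10, N_c = 2, n_min = 5)
#' d <- generate_dataset(p, effect_size_vector(0.25, 10, 50), rnorm(50), "MC")
#' dim(d$X)
#' @export
generate_dataset <- function(params, effect_sizes, alpha, design = c("SC", "MC"),
                             gamma_sd = 1, delta_sd = 1) {
  design <- match.arg(design)
  stopifnot(inherits(params, "hornung_params"))
  N_g <- params$N_g
  N_s <- params$N_s
  if (length(effect_sizes) != N_g || length(alpha) != N_g)
    stop_invalid("'effect_sizes' and 'alpha' must have length N_g")
  if (anyNA(effect_sizes) || anyNA(alpha))
    stop_invalid("'effect_sizes' and 'alpha' must be finite")

  centers <- if (design == "SC") rep(1L, N_s)
             else allocate_centers(N_s, params$N_c, params$n_min)
  a <- rnorm(N_s)
  y <- a + rnorm(N_s, sd = params$sigma_y)

  m <- params$m
  X <- matrix(0, N_s, N_g)
  for (j in unique(centers)) {
    idx <- which(centers == j)
    nj <- length(idx)
    gamma_j <- if (gamma_sd > 0) rnorm(N_g, sd = gamma_sd) else numeric(N_g)
    Xj <- outer(a[idx], effect_sizes) +
      matrix(alpha, nj, N_g, byrow = TRUE) +
      matrix(gamma_j, nj, N_g, byrow = TRUE)
    if (m > 0) {
      b_j <- matrix(rnorm(N_g * m), N_g, m)      # loadings, one per center
      Z <- matrix(rnorm(nj * m), nj, m)          # weights, one per sample
      Xj <- Xj + tcrossprod(Z, b_j)
    }
    if (delta_sd > 0) {
      delta_j <- rnorm(N_g, sd = delta_sd)
      eps <- matrix(rnorm(nj * N_g), nj, N_g)
      Xj <- Xj + eps * matrix(delta_j, nj, N_g, byrow = TRUE)
    }
    X[idx, ] <- Xj
  }
  structure(list(X = X, y = y, a = a, centers = centers, design = design),
            class = "hornung_dataset")
}

#' Derive reproducible per-iteration seeds from a root seed
#'
#' Monte-Carlo iterations each reseed the RNG with their own child seed, so a
#' run is reproducible from its root seed alone and is invariant to the
#' number of workers executing it.
#'
#' @param root_seed single integer seed.
#' @param n number of child seeds.
#' @return Integer vector of length `n` with values in `[1, 2^31 - 2]`.
#' @export
iteration_seeds <- function(root_seed, n) {
  stopifnot(length(root_seed) == 1L, is.finite(root_seed), n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(root_seed))
  sample.int(.Machine$integer.max - 1L, n)
}
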