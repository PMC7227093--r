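#' Scenario grids of the parameter-sweep study
#'
#' Returns the three systematic parameter sweeps:
#' \describe{
#'   \item{1 (signal strength)}{mean effect size over
#'     `{0,1,...,9}/50, {8,9,...,15}/40, {40,43,46,50}/100`; `n_inf = 300`,
#'     `N_s = 100`, `n_min = 10`.}
#'   \item{2 (number of informative genes)}{`n_inf` over 21 values from 1 to
#'     1000 with the total signal held constant at `75 = 300 * 0.25`, i.e.
#'     `beta_mean = 75 / n_inf`; `N_s = 100`.}
#'   \item{3 (sample size)}{`N_s` over 12 values from 40 to 500 with
#'     `beta_mean = 0.125`, `n_inf = 300`, `n_min = 5`.}
#' }
#'
#' @param scenario 1, 2 or 3.
#' @return List of class `scenario_grid` with `scenario`, `varied` (parameter
#'   name), `values`, and `make_params(value)` building the
#'   [hornung_params()] for one grid value.
#' @export
scenario_grid <- function(scenario) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop_invalid("'scenario' must be 1, 2 or 3")
  g <- switch(scenario,
    list(varied = "beta_mean",
         values = c(0:9 / 50, 8:15 / 40, c(40, 43, 46, 50) / 100),
         make_params = function(v) hornung_params(beta_mean = v)),
    list(varied = "n_inf",
         values = c(1, 5, 10, 25, 50, 75, 100, 150, 200, 250, 300, 350,
                    400, 450, 500, 550, 600, 670, 750, 850, 1000),
         make_params = function(v)
           hornung_params(beta_mean = 75 / v, n_inf = v)),
    list(varied = "N_s",
         values = c(40, 45, 50, 60, 80, 100, 125, 150, 200, 250, 350, 500),
         make_params = function(v)
           hornung_params(beta_mean = 0.125, N_s = v, n_min = 5))
  )
  structure(c(list(scenario = scenario), g), class = "scenario_grid")
}

#' Run one Monte-Carlo iteration
#'
#' Performs a full discovery/validation cycle at one parameter setting:
#' draws fresh basal levels `alpha` (shared by the iteration's four cohorts),
#' generates SC discovery, MC discovery, SC validation and MC validation
#' cohorts (each center with its own freshly drawn batch pattern), normalizes
#' all four and ComBat-corrects the MC ones, fits one SC and one MC lasso
#' signature, and scores all four discovery x validation combinations.
#'
#' @param params a [hornung_params()] object.
#' @param seed optional integer; when given, the RNG is seeded so the
#'   iteration is fully reproducible in isolation.
#' @param n_folds CV folds passed to [fit_signature()].
#' @return `data.frame` with 4 rows (combinations `(SC,SC)`, `(SC,MC)`,
#'   `(MC,SC)`, `(MC,MC)`) and the score columns of [score_combination()].
#' @export
run_iteration <- function(params, seed = NULL, n_folds = 10) {
  stopifnot(inherits(params, "hornung_params"))
  if (!is.null(seed)) set.seed(seed)
  alpha <- rnorm(params$N_g)
  beta <- effect_size_vector(params$beta_mean, params$n_inf, params$N_g)

  cohorts <- list(
    sc_disc = generate_dataset(params, beta, alpha, "SC"),
    mc_disc = generate_dataset(params, beta, alpha, "MC"),
    sc_val  = generate_dataset(params, beta, alpha, "SC"),
    mc_val  = generate_dataset(params, beta, alpha, "MC")
  )
  proc <- lapply(cohorts, preprocess_dataset)

  sig <- list(
    SC = fit_signature(proc$sc_disc$X_corrected, proc$sc_disc$y, n_folds),
    MC = fit_signature(proc$mc_disc$X_corrected, proc$mc_disc$y, n_folds)
  )
  vals <- list(SC = proc$sc_val, MC = proc$mc_val)

  combos <- expand.grid(disc_design = c("SC", "MC"),
                        val_design = c("SC", "MC"),
                        stringsAsFactors = FALSE)
  combos <- combos[order(combos$disc_design, decreasing = TRUE), ]
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    cbind(combos[k, , drop = FALSE],
          score_combination(sig[[combos$disc_design[k]]],
                            vals[[combos$val_design[k]]], params$n_inf))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(seed)) res$seed <- seed
  res
}

#' Run Monte-Carlo iterations at one parameter setting
#'
#' @param params a [hornung_params()] object.
#' @param n_reps number of iterations.
#' @param root_seed integer root seed; per-iteration child seeds are derived
#'   with [iteration_seeds()], so results are independent of `n_workers`.
#' @param n_workers forked workers (`parallel::mclapply`); 1 = serial.
#' @return Iteration-level `data.frame` (4 rows per iteration) with an
#'   `iteration` column.
#' @export
run_grid_point <- function(params, n_reps, root_seed, n_workers = 1) {
  if (n_reps < 1) stop_invalid("'n_reps' must be >= 1")
  seeds <- iteration_seeds(root_seed, n_reps)
  one <- function(i) {
    out <- run_iteration(params, seed = seeds[i])
    out$iteration <- i
    out
  }
  res <- if (n_workers > 1)
    parallel::mclapply(seq_len(n_reps), one, mc.cores = n_workers,
                       mc.preschedule = TRUE)
  else lapply(seq_len(n_reps), one)
  do.call(rbind, res)
}

#' Run a full scenario sweep
#'
#' Runs `n_reps` Monte-Carlo iterations at every value of a scenario grid and
#' aggregates the four scores per discovery x validation combination.
#'
#' @param grid a [scenario_grid()] (or scenario number 1/2/3).
#' @param n_reps iterations per grid value (the full study used 1000).
#' @param root_seed integer root seed.
#' @param n_workers forked workers for the iteration loop.
#' @param values optional subset of grid values to run.
#' @param verbose print progress every 50 iterations' worth of work.
#' @return List of class `scenario_result`: `scenario`, `varied`,
#'   `iterations` (long iteration-level table), `summary` (per value x
#'   combination x score: mean, SEM, 99% CI), `supplementary`
#'   (see [supplementary_summaries()]), `n_reps`, `root_seed`.
#' @export
run_scenario <- function(grid, n_reps = 1000, root_seed = 1, n_workers = 1,
                         values = NULL, verbose = FALSE) {
  if (!inherits(grid, "scenario_grid")) grid <- scenario_grid(grid)
  vals <- if (is.null(values)) grid$values else values
  point_seeds <- iteration_seeds(root_seed, length(vals))
  iter <- lapply(seq_along(vals), function(k) {
    if (verbose)
      message(sprintf("[%s] %s = %g (%d reps)", format(Sys.time(), "%H:%M:%S"),
                      grid$varied, vals[k], n_reps))
    out <- run_grid_point(grid$make_params(vals[k]), n_reps,
                          root_seed = point_seeds[k], n_workers = n_workers)
    out$param_value <- vals[k]
    out$scenario <- grid$scenario
    out
  })
  iterations <- do.call(rbind, iter)
  structure(list(scenario = grid$scenario, varied = grid$varied,
                 iterations = iterations,
                 summary = aggregate_scores(iterations),
                 supplementary = supplementary_summaries(iterations),
                 n_reps = n_reps, root_seed = root_seed),
            class = "scenario_result")
}

#' Aggregate iteration-level scores
#'
#' Means, standard errors of the mean (`SD / sqrt(n)`) and normal-theory 99%
#' confidence intervals (`mean +/- 2.576 SEM`) per parameter value, design
#' combination and score.
#'
#' @param iterations iteration-level table from [run_grid_point()] /
#'   [run_scenario()]; must contain the four score columns. A missing
#'   `param_value` column is treated as a single setting.
#' @return Long `data.frame`: `param_value`, `disc_design`, `val_design`,
#'   `score`, `mean`, `sem`, `ci_lo`, `ci_hi`, `n_reps`.
#' @export
aggregate_scores <- function(iterations) {
  if (is.null(iterations$param_value)) iterations$param_value <- NA_real_
  scores <- c("fdr", "mspe", "sv", "cs")
  z99 <- 2.576
  key <- paste(iterations$param_value, iterations$disc_design,
               iterations$val_design)
  groups <- split(iterations, key)
  rows <- lapply(groups, function(gdf) {
    do.call(rbind, lapply(scores, function(s) {
      x <- gdf[[s]]
      n <- length(x)
      sem <- sd(x) / sqrt(n)
      data.frame(param_value = gdf$param_value[1],
                 disc_design = gdf$disc_design[1],
                 val_design = gdf$val_design[1],
                 score = s, mean = mean(x), sem = sem,
                 ci_lo = mean(x) - z99 * sem, ci_hi = mean(x) + z99 * sem,
                 n_reps = n)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$param_value, out$disc_design, out$val_design, out$score), ]
}

#' Supplementary signature summaries
#'
#' Per parameter value and discovery design: the frequency of non-empty
#' signatures, the mean signature length, and the mean of each score
#' restricted to iterations with a non-empty signature (reported as `NA`
#' when every signature in a cell is empty).
#'
#' @param iterations iteration-level table (see [aggregate_scores()]).
#' @return `data.frame` with one row per parameter value x design
#'   combination: `freq_nonempty`, `mean_length`, and `fdr_ne`, `mspe_ne`,
#'   `sv_ne`, `cs_ne` conditional means.
#' @export
supplementary_summaries <- function(iterations) {
  if (is.null(iterations$param_value)) iterations$param_value <- NA_real_
  key <- paste(iterations$param_value, iterations$disc_design,
               iterations$val_design)
  groups <- split(iterations, key)
  rows <- lapply(groups, function(gdf) {
    ne <- gdf$nonempty == 1
    cond <- function(x) if (any(ne)) mean(x[ne]) else NA_real_
    data.frame(param_value = gdf$param_value[1],
               disc_design = gdf$disc_design[1],
               val_design = gdf$val_design[1],
               freq_nonempty = mean(ne),
               mean_length = mean(gdf$sig_length),
               fdr_ne = cond(gdf$fdr), mspe_ne = cond(gdf$mspe),
               sv_ne = cond(gdf$sv), cs_ne = cond(gdf$cs))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$param_value, out$disc_design, out$val_design), ]
}

# Approximate the true single-sample MSPE of a signature: fresh samples, each
# one its own center (own batch pattern), normalized but never batch-corrected.
# For per-sample loadings b (iid standard normal, unique to the sample), the
# latent-factor term sum_l b_gl Z_l equals sqrt(sum_l Z_l^2) * N(0,1) per gene
# in distribution, which is drawn directly for speed.
approximate_true_mspe <- function(signature, params, effect_sizes, alpha,
                                  n_samples, chunk = 2500L) {
  N_g <- params$N_g
  total <- 0
  done <- 0L
  while (done < n_samples) {
    k <- min(chunk, n_samples - done)
    a <- rnorm(k)
    y <- a + rnorm(k, sd = params$sigma_y)
    zsc <- if (params$m > 0)
      sqrt(rowSums(matrix(rnorm(k * params$m), k)^2)) else numeric(k)
    X <- outer(a, effect_sizes) + matrix(alpha, k, N_g, byrow = TRUE) +
      matrix(rnorm(k * N_g), k) +                    # per-sample gamma
      matrix(rnorm(k * N_g), k) * zsc +              # latent-factor term
      matrix(rnorm(k * N_g), k) * matrix(rnorm(k * N_g), k)  # delta * eps
    y_hat <- predict_outcome(signature, normalize_samples(X))
    total <- total + sum((y_hat - y)^2)
    done <- done + k
  }
  total / n_samples
}

#' Quality of the MSPE estimator under SC and MC validation
#'
#' For each discovery design the "true" expected squared prediction error of
#' a fitted signature on single future samples is approximated on `approx_n`
#' fresh samples, each carrying its own independently drawn batch pattern and
#' no batch correction.  The estimator under study is the MSPE computed from
#' one validation cohort (standard pipeline; predictions on normalized,
#' uncorrected expression).  Its quality is measured by the squared error
#' `(MSPE_estim - MSPE_approx)^2` of the single-cohort estimate, averaged
#' over `n_val_sets` independent validation cohorts of each design per
#' iteration.  The full-scale experiment used 1000 iterations, 1e5
#' approximation samples and 100 validation sets of each design.
#'
#' @param params a [hornung_params()] object (defaults of the
#'   signal-strength scenario with `beta_mean = 0.25`).
#' @param n_iter number of discovery iterations.
#' @param n_val_sets validation cohorts of each design per iteration (0 skips
#'   the estimation arm and reports only the approximated truth).
#' @param approx_n fresh single samples used to approximate the true MSPE.
#' @param root_seed integer root seed.
#' @param n_workers forked workers.
#' @param designs discovery designs to evaluate (default both `"SC"` and
#'   `"MC"`); restricting to one halves the cost when only one arm is needed.
#' @return List of class `mspe_quality_result` with `summary` (per discovery
#'   design: mean approximated MSPE and SEM; per validation design: mean
#'   estimated MSPE, SEM, mean squared estimator error, SEM) and `iterations`
#'   (per-iteration quantities).
#' @export
mspe_estimator_quality <- function(params = hornung_params(beta_mean = 0.25),
                                   n_iter = 1000, n_val_sets = 100,
                                   approx_n = 1e5, root_seed = 1,
                                   n_workers = 1, designs = c("SC", "MC")) {
  stopifnot(inherits(params, "hornung_params"),
            all(designs %in% c("SC", "MC")), length(designs) >= 1)
  seeds <- iteration_seeds(root_seed, n_iter)
  one <- function(it) {
    set.seed(seeds[it])
    alpha <- rnorm(params$N_g)
    beta <- effect_size_vector(params$beta_mean, params$n_inf, params$N_g)
    disc <- sapply(designs, function(d)
      generate_dataset(params, beta, alpha, d), simplify = FALSE)
    proc <- lapply(disc, preprocess_dataset)
    rows <- lapply(designs, function(d) {
      sig <- fit_signature(proc[[d]]$X_corrected, proc[[d]]$y)
      approx <- approximate_true_mspe(sig, params, beta, alpha, approx_n)
      row <- data.frame(iteration = it, disc_design = d, mspe_approx = approx,
                        mspe_estim_SC = NA_real_, mspe_estim_MC = NA_real_,
                        sq_error_SC = NA_real_, sq_error_MC = NA_real_)
      if (n_val_sets > 0) {
        for (v in c("SC", "MC")) {
          est <- vapply(seq_len(n_val_sets), function(s) {
            val <- generate_dataset(params, beta, alpha, v)
            mean_square_prediction_error(
              predict_outcome(sig, normalize_samples(val$X)), val$y)
          }, numeric(1))
          row[[paste0("mspe_estim_", v)]] <- mean(est)
          row[[paste0("sq_error_", v)]] <- mean((est - approx)^2)
        }
      }
      row
    })
    do.call(rbind, rows)
  }
  res <- if (n_workers > 1)
    parallel::mclapply(seq_len(n_iter), one, mc.cores = n_workers)
  else lapply(seq_len(n_iter), one)
  iterations <- do.call(rbind, res)

  summ <- do.call(rbind, lapply(designs, function(d) {
    sub <- iterations[iterations$disc_design == d, ]
    msem <- function(x) c(mean(x), sd(x) / sqrt(length(x)))
    ap <- msem(sub$mspe_approx)
    out <- data.frame(disc_design = d, mspe_approx = ap[1],
                      mspe_approx_sem = ap[2])
    for (v in c("SC", "MC")) {
      est <- sub[[paste0("mspe_estim_", v)]]
      if (all(is.na(est))) next
      e <- msem(est)
      sq <- msem(sub[[paste0("sq_error_", v)]])
      out[[paste0("mspe_estim_", v)]] <- e[1]
      out[[paste0("mspe_estim_", v, "_sem")]] <- e[2]
      out[[paste0("sq_error_", v)]] <- sq[1]
      out[[paste0("sq_error_", v, "_sem")]] <- sq[2]
    }
    out
  }))
  structure(list(summary = summ, iterations = iterations,
                 n_iter = n_iter, n_val_sets = n_val_sets,
                 approx_n = approx_n, root_seed = root_seed),
            class = "mspe_quality_result")
}
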