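# small but non-trivial configuration used for engine-level checks
engine_test_params <- function()
  hornung_params(beta_mean = 0.4, N_s = 40, N_g = 60, n_inf = 20,
                 N_c = 4, n_min = 5, m = 2)

test_that("one iteration scores all four design combinations coherently", {
  res <- run_iteration(engine_test_params(), seed = 101)
  expect_equal(nrow(res), 4)
  expect_setequal(paste(res$disc_design, res$val_design),
                  c("SC SC", "SC MC", "MC SC", "MC MC"))
  # FDR is a property of the discovery fit alone: identical across val designs
  for (d in c("SC", "MC")) {
    sub <- res[res$disc_design == d, ]
    expect_equal(sub$fdr[1], sub$fdr[2])
    expect_equal(sub$sig_length[1], sub$sig_length[2])
  }
  expect_true(all(res$fdr >= 0 & res$fdr <= 1))
  expect_true(all(res$mspe >= 0))
  expect_true(all(res$sv %in% c(0L, 1L)))
  # reproducibility contract
  expect_identical(res, run_iteration(engine_test_params(), seed = 101))
})

test_that("grid-point runs are invariant to the worker count", {
  p <- engine_test_params()
  r1 <- run_grid_point(p, 6, root_seed = 55, n_workers = 1)
  r2 <- run_grid_point(p, 6, root_seed = 55, n_workers = 2)
  expect_equal(r1, r2)
})

test_that("aggregation arithmetic is exact at two repetitions", {
  p <- engine_test_params()
  iters <- run_grid_point(p, 2, root_seed = 9)
  agg <- aggregate_scores(iters)
  expect_equal(nrow(agg), 16)  # 4 combos x 4 scores
  row <- agg[agg$disc_design == "SC" & agg$val_design == "SC" &
               agg$score == "mspe", ]
  x <- iters$mspe[iters$disc_design == "SC" & iters$val_design == "SC"]
  expect_equal(row$mean, mean(x))
  expect_equal(row$sem, sd(x) / sqrt(2))
  expect_equal(row$ci_lo, mean(x) - 2.576 * sd(x) / sqrt(2))
  expect_true(all(agg$ci_lo <= agg$mean & agg$mean <= agg$ci_hi))
})

test_that("supplementary summaries handle empty and mixed cells", {
  base <- data.frame(disc_design = "SC", val_design = "SC",
                     fdr = c(1, 0.25), mspe = c(1.0, 2.0), sv = c(0L, 1L),
                     cs = c(0, 0.8), sig_length = c(0L, 4L),
                     nonempty = c(0L, 1L))
  s <- supplementary_summaries(base)
  expect_equal(s$freq_nonempty, 0.5)
  expect_equal(s$mean_length, 2)
  expect_equal(s$fdr_ne, 0.25)   # conditional on non-emptiness
  expect_equal(s$cs_ne, 0.8)
  all_empty <- base
  all_empty$nonempty <- 0L
  all_empty$sig_length <- 0L
  s0 <- supplementary_summaries(all_empty)
  expect_equal(s0$freq_nonempty, 0)
  expect_true(is.na(s0$fdr_ne) && is.na(s0$mspe_ne))
})

test_that("scenario grids match the study design", {
  g1 <- scenario_grid(1)
  expect_equal(g1$values, c(0:9 / 50, 8:15 / 40, c(40, 43, 46, 50) / 100))
  expect_equal(g1$make_params(0.14)$beta_mean, 0.14)
  expect_equal(g1$make_params(0.14)$n_min, 10L)
  g2 <- scenario_grid(2)
  expect_length(g2$values, 21)
  expect_equal(range(g2$values), c(1, 1000))
  p2 <- g2$make_params(10)
  expect_equal(p2$beta_mean, 7.5)    # constant total information 75
  expect_equal(g2$make_params(600)$beta_mean, 0.125)
  g3 <- scenario_grid(3)
  expect_equal(range(g3$values), c(40, 500))
  p3 <- g3$make_params(40)
  expect_equal(p3$n_min, 5L)
  expect_equal(p3$beta_mean, 0.125)
  expect_error(scenario_grid(4), class = "centersim_invalid_input")
})

test_that("a tiny scenario sweep returns a coherent result object", {
  g <- structure(list(scenario = 1L, varied = "beta_mean",
                      values = c(0, 0.5),
                      make_params = function(v)
                        hornung_params(beta_mean = v, N_s = 40, N_g = 60,
                                       n_inf = 20, N_c = 4, n_min = 5, m = 2)),
                 class = "scenario_grid")
  res <- run_scenario(g, n_reps = 3, root_seed = 77)
  expect_s3_class(res, "scenario_result")
  expect_equal(sort(unique(res$iterations$param_value)), c(0, 0.5))
  expect_equal(nrow(res$iterations), 2 * 3 * 4)
  expect_equal(nrow(res$summary), 2 * 4 * 4)
  # identical root seed reproduces the sweep exactly
  res2 <- run_scenario(g, n_reps = 3, root_seed = 77)
  expect_equal(res$iterations, res2$iterations)
})

test_that("99% confidence intervals cover a known mean", {
  set.seed(88)
  mu <- 0.3
  n_rep <- 1000
  covered <- vapply(1:400, function(i) {
    x <- rnorm(n_rep, mean = mu, sd = 1)
    sem <- sd(x) / sqrt(n_rep)
    mu >= mean(x) - 2.576 * sem && mu <= mean(x) + 2.576 * sem
  }, logical(1))
  expect_gte(mean(covered), 0.97)
})

test_that("the estimator-quality experiment has the right structure", {
  p <- hornung_params(beta_mean = 0.5, N_s = 30, N_g = 50, n_inf = 15,
                      N_c = 3, n_min = 5, m = 2)
  q <- mspe_estimator_quality(p, n_iter = 2, n_val_sets = 2, approx_n = 300,
                              root_seed = 5)
  expect_s3_class(q, "mspe_quality_result")
  expect_equal(q$summary$disc_design, c("SC", "MC"))
  expect_true(all(q$summary$mspe_approx > 0))
  expect_true(all(c("mspe_estim_SC", "sq_error_MC") %in% names(q$summary)))
  # restricting designs halves the work and keeps the same MC arm shape
  q_mc <- mspe_estimator_quality(p, n_iter = 2, n_val_sets = 0, approx_n = 300,
                                 root_seed = 5, designs = "MC")
  expect_equal(q_mc$summary$disc_design, "MC")
  expect_true(is.finite(q_mc$summary$mspe_approx))
})

test_that("true-MSPE approximation hits the analytic floor for empty signatures", {
  # constant-zero prediction: expected squared error = Var(y) = 1 + sigma_y^2
  p <- hornung_params(N_s = 30, N_g = 50, n_inf = 15, N_c = 3, n_min = 5)
  empty <- structure(list(intercept = 0, coefficients = numeric(50),
                          selected = integer(0)), class = "signature_fit")
  set.seed(6)
  approx <- centersim:::approximate_true_mspe(
    empty, p, effect_size_vector(0.25, 15, 50), rnorm(50), n_samples = 20000)
  expect_equal(approx, 1.01, tolerance = 0.03)
})
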