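test_that("FDR counts non-informative selections, empty set scores 1", {
  expect_equal(false_discovery_rate(integer(0), 300), 1)
  expect_equal(false_discovery_rate(c(1, 2, 301, 302), 300), 0.5)
  expect_equal(false_discovery_rate(c(5, 17, 250), 300), 0)
  # brute-force oracle over random selected sets
  set.seed(41)
  for (i in 1:50) {
    n_inf <- sample(0:50, 1)
    sel <- sample(1:100, sample(1:20, 1))
    brute <- sum(vapply(sel, function(g) g > n_inf, logical(1))) / length(sel)
    expect_identical(false_discovery_rate(sel, n_inf), brute)
  }
})

test_that("MSPE is the mean squared deviation", {
  expect_equal(mean_square_prediction_error(c(1, 2), c(1, 2)), 0)
  expect_equal(mean_square_prediction_error(c(0, 0), c(1, -1)), 1)
  expect_error(mean_square_prediction_error(1:3, 1:4),
               class = "centersim_invalid_input")
  # expected MSPE of a constant-zero prediction is Var(y) = 1 + sigma_y^2
  set.seed(42)
  y <- rnorm(1e5) + rnorm(1e5, sd = 0.1)
  expect_equal(mean_square_prediction_error(rep(0, 1e5), y), 1.01,
               tolerance = 0.02)
})

test_that("successful validation is a one-sided correlation test", {
  set.seed(43)
  y <- rnorm(100)
  expect_identical(successful_validation(y, y), 1L)
  expect_identical(successful_validation(-y, y), 0L)      # one-sided
  expect_identical(successful_validation(rep(0.5, 100), y), 0L)  # constants
  # matches stats::cor.test on non-degenerate input
  for (i in 1:20) {
    a <- rnorm(30); b <- 0.3 * a + rnorm(30)
    ref <- as.integer(stats::cor.test(a, b, alternative = "greater")$p.value < 0.05)
    expect_identical(successful_validation(a, b), ref)
  }
})

test_that("calibration slope is the OLS slope with the empty convention", {
  set.seed(44)
  y <- rnorm(50)
  expect_equal(calibration_slope(y, y), 1)
  expect_equal(calibration_slope(2 * y, y), 0.5)
  expect_equal(calibration_slope(rep(3, 50), y), 0)
  # invariant to shifts of the prediction; inverse to its scaling
  yh <- 0.5 * y + rnorm(50, sd = 0.3)
  cs <- calibration_slope(yh, y)
  expect_equal(calibration_slope(yh + 7, y), cs, tolerance = 1e-12)
  expect_equal(calibration_slope(3 * yh, y), cs / 3, tolerance = 1e-12)
  # agrees with lm()
  expect_equal(cs, unname(coef(stats::lm(y ~ yh))[2]), tolerance = 1e-12)
})

test_that("score_combination applies the empty-signature conventions jointly", {
  p <- hornung_params(N_s = 30, N_g = 40, n_inf = 10, N_c = 2, n_min = 5)
  set.seed(45)
  val <- preprocess_dataset(generate_dataset(
    p, effect_size_vector(0.25, 10, 40), rnorm(40), "SC"))
  empty <- structure(list(intercept = 0.2, coefficients = numeric(40),
                          selected = integer(0)), class = "signature_fit")
  row <- score_combination(empty, val, n_inf = 10)
  expect_equal(row$fdr, 1)
  expect_identical(row$sv, 0L)
  expect_equal(row$cs, 0)
  expect_equal(row$sig_length, 0)
  expect_identical(row$nonempty, 0L)
  expect_equal(row$mspe,
               mean_square_prediction_error(rep(0.2, 30), val$y))
})

test_that("an oracle-calibrated signature beats the empty one on MSPE", {
  p <- hornung_params(beta_mean = 0.5, N_s = 200, N_g = 300, n_inf = 90,
                      N_c = 4, n_min = 10)
  beta <- effect_size_vector(0.5, 90, 300)
  set.seed(46)
  alpha <- rnorm(300)
  disc <- preprocess_dataset(generate_dataset(p, beta, alpha, "SC"))
  # calibrate the true-coefficient score on discovery data (slope+intercept)
  s_disc <- drop(disc$X_norm %*% beta)
  fit <- stats::lm(disc$y ~ s_disc)
  oracle <- structure(list(intercept = coef(fit)[1],
                           coefficients = beta * coef(fit)[2],
                           selected = which(beta != 0)),
                      class = "signature_fit")
  empty <- structure(list(intercept = mean(disc$y),
                          coefficients = numeric(300),
                          selected = integer(0)), class = "signature_fit")
  mspe_oracle <- mspe_empty <- numeric(20)
  for (i in 1:20) {
    val <- generate_dataset(p, beta, alpha, "SC")
    Xn <- normalize_samples(val$X)
    mspe_oracle[i] <- mean_square_prediction_error(predict_outcome(oracle, Xn), val$y)
    mspe_empty[i] <- mean_square_prediction_error(predict_outcome(empty, Xn), val$y)
  }
  expect_lt(mean(mspe_oracle), mean(mspe_empty))
})
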