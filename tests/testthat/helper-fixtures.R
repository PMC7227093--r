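# Deterministic input matrix for the frozen batch-correction reference.
# The expected output in fixtures/combat_reference_synthetic_20x80.csv was
# computed once with sva::ComBat 3.54.0 (parametric priors, no covariates)
# on exactly this matrix; the file is a synthetic stand-in frozen to full
# double precision.
make_combat_fixture_input <- function() {
  set.seed(420042)
  n <- 20L; g <- 80L
  batch <- rep(1:2, each = 10L)
  X <- matrix(rnorm(n * g), n, g)
  shift <- rnorm(g, sd = 1.5)          # batch-2 location offsets
  scale2 <- exp(rnorm(g, sd = 0.4))    # batch-2 scale distortions
  X[batch == 2, ] <- sweep(sweep(X[batch == 2, ], 2, scale2, "*"), 2, shift, "+")
  list(X = X, batch = batch)
}
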