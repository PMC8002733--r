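# Independent oracles used across tests.

# Brute-force OLS of lai on vi via stats::lm (the normal-equations route
# the package's closed form must reproduce).
lm_oracle <- function(vi, lai) {
  f <- stats::lm(lai ~ vi)
  s <- summary(f)
  list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
       r2 = s$r.squared, p = s$coefficients[2, 4])
}

# Random reflectance samples with all four bands strictly inside (0, 1).
random_samples <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(blue = runif(n, 0.01, 0.4), green = runif(n, 0.01, 0.5),
             red = runif(n, 0.01, 0.6), nir = runif(n, 0.05, 0.95))
}
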