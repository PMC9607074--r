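# Shared fixtures: everything is generated in code at test time.

epoc_stimulus <- function(n_samples = 64, n_harmonics = 3)
  stimulus_set(c(6.66, 7.50, 8.57, 10.00, 12.00), n_harmonics,
               sampling_rate = 128, n_samples = n_samples)

# small random SPD matrix
random_spd <- function(d, seed = NULL) {
  draw <- function() {
    A <- matrix(rnorm(d * d), d)
    crossprod(A) + diag(0.1, d)
  }
  if (is.null(seed)) draw() else adtrca:::with_seed(seed, draw())
}

# quick synthetic dataset, centered, with its dictionary
quick_dataset <- function(seed, n_samples = 64, snr_db = 0, n_channels = 4,
                          n_blocks = 6, stim = NULL, ...) {
  if (is.null(stim)) stim <- epoc_stimulus(n_samples)
  cfg <- sim_config(stim, n_channels = n_channels, n_blocks = n_blocks,
                    snr_db = snr_db, spatial_pattern_seed = 2L * seed,
                    noise_seed = 2L * seed + 1L, ...)
  sim <- simulate_dataset(cfg)
  list(trials = centralize(sim$trials), truth = sim$truth,
       dict = build_dictionary(stim), stim = stim)
}

# Independent dense oracle for the Gaussian weight posterior: direct
# textbook evaluation with solve(), no shared code with the implementation.
oracle_posterior <- function(B, Phi, alpha, alpha0) {
  Sigma <- solve(alpha0 * t(Phi) %*% Phi + diag(alpha))
  means <- apply(B, 2, function(y) alpha0 * Sigma %*% t(Phi) %*% y)
  list(means = matrix(means, ncol = ncol(B)), covariance = Sigma)
}

# Independent dense oracle for the pooled log marginal likelihood:
# direct evaluation of sum_i log N(y_i | 0, a0^-1 I + Phi diag(1/alpha) Phi').
oracle_log_marginal <- function(B, Phi, alpha, alpha0) {
  Nt <- nrow(B)
  C <- diag(Nt) / alpha0 + Phi %*% diag(1 / alpha, length(alpha)) %*% t(Phi)
  ld <- determinant(C, logarithm = TRUE)$modulus
  Ci <- solve(C)
  -0.5 * sum(apply(B, 2, function(y)
    Nt * log(2 * pi) + ld + t(y) %*% Ci %*% y))
}
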