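test_that("task stacking is trial-major then channel and invertible", {
  set.seed(1)
  dat <- array(rnorm(6 * 3 * 20), c(6, 3, 20))
  tr <- epoched_trials(dat, rep(1:2, each = 3), NULL, 100)
  stk <- stack_tasks(tr, 1)
  expect_equal(ncol(stk$tasks), 3 * 3)  # M = 3 trials x Nch = 3
  # column (m-1)*Nch + ch is channel ch of the m-th trial of the class
  idx <- which(tr$labels == 1)
  for (m in seq_along(idx)) for (ch in 1:3)
    expect_identical(stk$tasks[, (m - 1) * 3 + ch], dat[idx[m], ch, ])
  # single trial, single channel: the time course itself
  tr1 <- epoched_trials(dat[1, 1, , drop = FALSE][, 1, , drop = FALSE],
                        1, NULL, 100)
  expect_identical(as.numeric(stack_tasks(tr1, 1)$tasks), dat[1, 1, ])
  expect_error(stack_tasks(tr, 7), "no trials")
})

test_that("posterior matches an independent dense oracle", {
  set.seed(42)
  Nt <- 16; K <- 4; L <- 3
  Phi <- matrix(rnorm(Nt * K), Nt)
  B <- matrix(rnorm(Nt * L), Nt)
  alpha <- runif(K, 0.5, 2)
  alpha0 <- 1.7
  got <- posterior_update(B, Phi, alpha, alpha0)
  want <- oracle_posterior(B, Phi, alpha, alpha0)
  expect_equal(got$covariance, want$covariance, tolerance = 1e-10)
  expect_equal(got$means, want$means, tolerance = 1e-10)
  # covariance is shared across tasks by construction (one matrix)
  expect_true(isSymmetric(got$covariance, tol = 1e-12))
  expect_true(all(eigen(got$covariance, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("posterior limits: infinite prior pins weights, vanishing prior gives least squares", {
  set.seed(7)
  Nt <- 32
  Phi <- qr.Q(qr(matrix(rnorm(Nt * 5), Nt)))  # orthonormal columns
  B <- matrix(rnorm(Nt * 2), Nt)
  hi <- posterior_update(B, Phi, rep(1e12, 5), 1)
  expect_lt(max(abs(hi$means)), 1e-6 * sqrt(sum(B^2)))
  lo <- posterior_update(B, Phi, rep(1e-12, 5), 1)
  expect_equal(lo$means, crossprod(Phi, B), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("precision update prunes unsupported atoms and clips to the ceiling", {
  means <- rbind(c(1, 2), c(0, 0))
  covariance <- diag(c(0.1, 0.5))
  a <- hyperparameter_update(means, covariance, c(1, 1), alpha_max = 1e12)
  expect_equal(a[2], 1e12)      # no posterior mass on atom 2
  expect_true(all(a > 0 & a <= 1e12))
})

test_that("noise update matches a direct evaluation and flags perfect fits", {
  set.seed(11)
  Nt <- 20; K <- 3; L <- 4
  Phi <- matrix(rnorm(Nt * K), Nt)
  B <- matrix(rnorm(Nt * L), Nt)
  alpha <- runif(K, 0.5, 2); alpha0 <- 2.2
  p <- posterior_update(B, Phi, alpha, alpha0)
  got <- noise_update(B, Phi, p$means, p$covariance, alpha)
  # direct form: L*(Nt - K + sum_j alpha_j Sigma_jj) / sum_i ||y_i-Phi mu_i||^2
  want <- L * (Nt - K + sum(alpha * diag(p$covariance))) /
    sum((B - Phi %*% p$means)^2)
  expect_equal(as.numeric(got), want, tolerance = 1e-10)
  # tasks exactly in span(Phi) with near-zero prior precision: perfect fit
  Bfit <- Phi %*% matrix(rnorm(K * 2), K)
  pf <- posterior_update(Bfit, Phi, rep(1e-300, K), 1e290)
  resid <- Bfit - Phi %*% pf$means
  a0 <- noise_update(Bfit, Phi, pf$means, pf$covariance, rep(1e-300, K))
  expect_true(as.numeric(a0) == 1e12 || max(abs(resid)) > 0)
})

test_that("white-noise tasks with a fully pruned model recover the noise precision", {
  set.seed(3)
  Nt <- 400; L <- 6
  sigma <- 0.7
  B <- matrix(rnorm(Nt * L, sd = sigma), Nt)
  Phi <- matrix(rnorm(Nt * 4), Nt)
  alpha <- rep(1e12, 4)
  p <- posterior_update(B, Phi, alpha, 1)
  a0 <- noise_update(B, Phi, p$means, p$covariance, alpha)
  expect_equal(as.numeric(a0), 1 / sigma^2, tolerance = 0.1)
})

test_that("the fitted model reconstructs noise-free tones and reaches a fixed point", {
  stim <- stimulus_set(10, 2, 128, 64)
  dict <- build_dictionary(stim)
  t <- (0:63) / 128
  y <- sin(2 * pi * 10 * t + 0.4)
  B <- cbind(y, 0.5 * y, 2 * y)
  fit <- fit_multitask(B, dict, mtl_control(tol = 1e-6, max_iter = 500))
  expect_true(fit$converged)
  expect_lt(sqrt(sum((dict$full %*% fit$means[, 1] - y)^2)) /
              sqrt(sum(y^2)), 1e-3)
  # self-consistency: one more sweep barely moves alpha
  p <- posterior_update(B, dict$full, fit$alpha, fit$alpha0)
  a2 <- hyperparameter_update(p$means, p$covariance, fit$alpha)
  expect_lt(max(abs(a2 - fit$alpha) / fit$alpha), 1e-5)
  # degenerate stopping rule: infinite tolerance returns after one sweep
  one <- fit_multitask(B, dict, mtl_control(tol = Inf))
  expect_equal(one$n_iterations, 1)
})

test_that("converged precisions maximize the evidence (grid-search oracle)", {
  # single task, single atom: compare against a dense 1-D grid search
  set.seed(5)
  Nt <- 40
  phi <- matrix(rnorm(Nt), ncol = 1); phi <- phi / sqrt(sum(phi^2))
  y <- matrix(3 * phi + rnorm(Nt, sd = 0.5), ncol = 1)
  a0 <- 1 / 0.25
  fit <- fit_multitask(y, phi, mtl_control(tol = 1e-8, max_iter = 2000,
                                           alpha0_init = a0,
                                           fix_alpha0 = TRUE))
  grid <- 10^seq(-6, 6, by = 0.001)
  lm <- vapply(grid, function(a) oracle_log_marginal(y, phi, a, a0),
               numeric(1))
  expect_equal(fit$alpha, grid[which.max(lm)], tolerance = 0.01)

  # several atoms, several tasks: cyclic coordinate-wise grid ascent oracle
  set.seed(6)
  K <- 4; L <- 3
  Phi <- matrix(rnorm(Nt * K), Nt)
  W <- matrix(rnorm(K * L), K)
  B <- Phi %*% W + matrix(rnorm(Nt * L, sd = 0.4), Nt)
  fit <- fit_multitask(B, Phi, mtl_control(tol = 1e-8, max_iter = 5000,
                                           alpha0_init = 1 / 0.16,
                                           fix_alpha0 = TRUE))
  agrid <- 10^seq(-6, 12, by = 0.01)
  alpha <- rep(1, K)
  for (sweep in 1:30) {
    prev <- alpha
    for (j in 1:K) {
      lms <- vapply(agrid, function(a) {
        aa <- alpha; aa[j] <- a
        oracle_log_marginal(B, Phi, aa, 1 / 0.16)
      }, numeric(1))
      alpha[j] <- agrid[which.max(lms)]
    }
    if (max(abs(alpha - prev) / prev) < 1e-4) break
  }
  expect_equal(fit$alpha, alpha, tolerance = 0.05)
})

test_that("sparse support is recovered from multi-task evidence", {
  # frequencies chosen so no two harmonics coincide (coinciding harmonics
  # give duplicate dictionary columns and an unidentifiable support)
  stim <- stimulus_set(c(8, 9.25, 10.5, 11.75, 13), 4, 250, 250)
  dict <- build_dictionary(stim)  # 40 atoms
  K <- ncol(dict$full)
  gen <- adtrca:::with_seed(8201, {
    truth <- sample(K, 3)
    W <- matrix(0, K, 27)
    W[truth, ] <- rnorm(3 * 27, sd = 1)
    S <- dict$full %*% W
    noise_sd <- sqrt(mean(S^2) / 10^(10 / 10))  # 10 dB
    list(truth = truth, B = S + matrix(rnorm(length(S), sd = noise_sd),
                                       nrow(S)))
  })
  fit <- fit_multitask(gen$B, dict)
  expect_setequal(order(fit$alpha)[1:3], gen$truth)
})

test_that("fast greedy fit agrees with the full algorithm on dominant atoms", {
  stim <- stimulus_set(c(8, 13), 2, 128, 64)
  dict <- build_dictionary(stim)
  t <- (0:63) / 128
  set.seed(21)
  y <- sin(2 * pi * 8 * t + 1.1)
  B <- cbind(y, y, y) + matrix(rnorm(64 * 3, sd = 0.05), 64)
  full <- fit_multitask(B, dict, mtl_control(tol = 1e-6, max_iter = 1000))
  fast <- fit_multitask_fast(B, dict)
  # the same leading atom carries the most evidence in both fits
  expect_equal(which.min(fast$alpha), which.min(full$alpha))
  expect_true(all(which.min(fast$alpha) %in% fast$active_set))
  # greedy ascent: final evidence is at least the empty model's
  empty_lm <- adtrca:::log_marginal(B, dict$full[, 0, drop = FALSE],
                                    numeric(0), fast$alpha0)
  expect_gte(fast$log_marginal, empty_lm)
  # all-noise tasks: near-empty active set (a few marginal atoms are
  # expected — null-atom evidence gains are O(1) chi-square fluctuations)
  set.seed(22)
  N <- matrix(rnorm(64 * 3), 64)
  nf <- fit_multitask_fast(N, dict)
  expect_lte(length(nf$active_set), 3)
})

test_that("pooled log marginal matches the dense oracle", {
  set.seed(13)
  Nt <- 18; K <- 5; L <- 4
  Phi <- matrix(rnorm(Nt * K), Nt)
  B <- matrix(rnorm(Nt * L), Nt)
  alpha <- runif(K, 0.1, 10); alpha0 <- 3
  expect_equal(adtrca:::log_marginal(B, Phi, alpha, alpha0),
               oracle_log_marginal(B, Phi, alpha, alpha0),
               tolerance = 1e-10)
})

test_that("smoothing matrices are symmetric shrunk projections", {
  set.seed(31)
  # ridge-free limit with orthonormal dictionary: exact projector
  Nt <- 30
  Phi <- qr.Q(qr(matrix(rnorm(Nt * 6), Nt)))
  post <- structure(list(alpha0 = 1,
                         covariance = solve(crossprod(Phi) +
                                              diag(1e-12, 6))),
                    class = "mtl_posterior")
  F1 <- smoothing_matrix(post, Phi)$matrix
  expect_equal(F1 %*% F1, F1, tolerance = 1e-8)
  # fully pruned model: F ~ 0
  post2 <- structure(list(alpha0 = 1,
                          covariance = diag(1e-12, 6)),
                     class = "mtl_posterior")
  expect_lt(max(abs(smoothing_matrix(post2, Phi)$matrix)), 1e-6)
  # generic converged fit: symmetric, eigenvalues in [0, 1]
  stim <- stimulus_set(c(9, 14), 2, 128, 48)
  dict <- build_dictionary(stim)
  B <- matrix(rnorm(48 * 5), 48)
  fit <- fit_multitask(B, dict)
  Fm <- smoothing_matrix(fit, dict)$matrix
  expect_lt(max(abs(Fm - t(Fm))), 1e-10)
  ev <- eigen(Fm, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8 & ev < 1 + 1e-8))
})
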