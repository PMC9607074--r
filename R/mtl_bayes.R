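# Multi-task sparse Bayesian linear regression on the harmonic dictionary.
#
# Every single-channel time course of every training trial of one stimulus
# class is a regression task y_i = Phi w_i + e_i. All tasks share one set of
# precision hyperparameters alpha (one per dictionary column) and one noise
# precision alpha0, so evidence about which sinusoids are active is pooled
# across channels and trials. Hyperparameters are estimated by type-II
# maximum likelihood (evidence maximization); the converged posterior yields
# the class-specific temporal smoothing matrix F = alpha0 * Phi Sigma Phi'.

#' Control parameters for the multi-task Bayesian fit
#'
#' @param tol convergence tolerance: maximum relative change in `alpha`
#'   between sweeps.
#' @param max_iter maximum number of update sweeps.
#' @param alpha_max precision ceiling; an atom whose precision reaches it is
#'   effectively pruned from the model.
#' @param alpha0_max noise-precision ceiling (noise-free limit).
#' @param alpha_init initial value for every `alpha_j`.
#' @param alpha0_init initial noise precision; default `1 / (0.1 * var(y))`
#'   averaged over tasks.
#' @param fix_alpha0 keep the noise precision fixed at its initial value
#'   (useful when it is known).
#' @export
mtl_control <- function(tol = 1e-3, max_iter = 200, alpha_max = 1e12,
                        alpha0_max = 1e12, alpha_init = 1,
                        alpha0_init = NULL, fix_alpha0 = FALSE) {
  stopifnot(tol > 0 || is.infinite(tol), max_iter >= 1, alpha_max > 0,
            alpha0_max > 0, alpha_init > 0)
  list(tol = tol, max_iter = max_iter, alpha_max = alpha_max,
       alpha0_max = alpha0_max, alpha_init = alpha_init,
       alpha0_init = alpha0_init, fix_alpha0 = fix_alpha0)
}

#' Stack all single-channel time courses of one class into regression tasks
#'
#' Collects the `M` training trials of class `class_index` into an
#' `Nt x (Nch*M)` matrix whose columns are the regression tasks, ordered
#' trial-major (trial 1 channels `1..Nch`, then trial 2, ...).
#'
#' @param trials an [epoched_trials()] object (centered).
#' @param class_index 1-based stimulus class.
#' @return object of class `task_stack` with elements `tasks` (the matrix),
#'   `class_index`, `n_channels`, `n_trials`.
#' @export
stack_tasks <- function(trials, class_index) {
  stopifnot(inherits(trials, "epoched_trials"))
  idx <- which(trials$labels == class_index)
  if (length(idx) == 0)
    stop(sprintf("no trials with class %d", class_index))
  cols <- lapply(idx, function(m) t(trial_matrix(trials, m)))
  structure(list(tasks = do.call(cbind, cols),
                 class_index = as.integer(class_index),
                 n_channels = dim(trials$data)[2],
                 n_trials = length(idx)),
            class = "task_stack")
}

as_task_matrix <- function(stack) {
  if (inherits(stack, "task_stack")) stack$tasks else as.matrix(stack)
}

as_dictionary_matrix <- function(dictionary) {
  if (inherits(dictionary, "harmonic_dictionary")) dictionary$full
  else as.matrix(dictionary)
}

# Symmetric factorization of the posterior precision H = a0 Phi'Phi + diag(a);
# adds jitter 1e-10 * trace(H) once if the Cholesky fails.
chol_precision <- function(PtP, alpha, alpha0) {
  H <- alpha0 * PtP
  diag(H) <- diag(H) + alpha
  R <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(R)) {
    message("posterior precision factorization failed; adding jitter")
    diag(H) <- diag(H) + 1e-10 * sum(diag(H))
    R <- tryCatch(chol(H), error = function(e)
      stop(sprintf("posterior precision singular (condition ~ %.3g)",
                   kappa(H))))
  }
  R
}

#' Posterior mean and covariance of the task weights
#'
#' Given hyperparameters, the weight posterior of each task is Gaussian with
#' shared covariance `Sigma = (alpha0 Phi'Phi + diag(alpha))^-1` and per-task
#' mean `mu_i = alpha0 Sigma Phi' y_i`. The covariance is shared because the
#' dictionary and the hyperparameters are shared by all tasks.
#'
#' @param stack a [stack_tasks()] result or plain `Nt x L` matrix.
#' @param dictionary a [build_dictionary()] result or plain `Nt x K` matrix.
#' @param alpha positive precision vector (length `K`).
#' @param alpha0 positive noise precision.
#' @return list with `means` (`K x L` matrix of posterior means) and
#'   `covariance` (`K x K`).
#' @export
posterior_update <- function(stack, dictionary, alpha, alpha0) {
  B <- as_task_matrix(stack)
  Phi <- as_dictionary_matrix(dictionary)
  stopifnot(all(alpha > 0), alpha0 > 0, length(alpha) == ncol(Phi))
  R <- chol_precision(crossprod(Phi), alpha, alpha0)
  Sigma <- chol2inv(R)
  means <- alpha0 * (Sigma %*% crossprod(Phi, B))
  list(means = means, covariance = Sigma)
}

#' Evidence update of the shared precision hyperparameters
#'
#' One type-II maximum-likelihood step:
#' `alpha_j <- L * (1 - alpha_j * Sigma_jj) / sum_i mu_ij^2`, where the
#' numerator uses the shared covariance (`sum_i Sigma_jj = L * Sigma_jj`).
#' Atoms with no posterior mass (`sum_i mu_ij^2 = 0`) are pruned by setting
#' their precision to `alpha_max`; results are clipped to `(0, alpha_max]`.
#'
#' @param means `K x L` posterior means.
#' @param covariance shared `K x K` posterior covariance.
#' @param alpha current precision vector.
#' @param alpha_max pruning ceiling.
#' @export
hyperparameter_update <- function(means, covariance, alpha,
                                  alpha_max = 1e12) {
  L <- ncol(means)
  gamma <- pmax(1 - alpha * diag(covariance), 0)
  denom <- rowSums(means^2)
  anew <- L * gamma / denom
  anew[denom == 0 | !is.finite(anew)] <- alpha_max
  pmin(pmax(anew, .Machine$double.eps), alpha_max)
}

#' Evidence update of the shared noise precision
#'
#' `alpha0 <- L * (Nt - sum_j gamma_j) / sum_i ||y_i - Phi mu_i||^2` with
#' `gamma_j = 1 - alpha_j Sigma_jj` (the well-determinedness of atom `j`).
#' A zero residual over all tasks returns `alpha0_max` flagged via the
#' `"noise_free"` attribute.
#'
#' @inheritParams posterior_update
#' @param means,covariance current posterior.
#' @param alpha0_max noise-free ceiling.
#' @export
noise_update <- function(stack, dictionary, means, covariance, alpha,
                         alpha0_max = 1e12) {
  B <- as_task_matrix(stack)
  Phi <- as_dictionary_matrix(dictionary)
  L <- ncol(B)
  gamma <- pmax(1 - alpha * diag(covariance), 0)
  rss <- sum((B - Phi %*% means)^2)
  if (rss == 0) {
    a0 <- alpha0_max
    attr(a0, "noise_free") <- TRUE
    return(a0)
  }
  min(L * max(nrow(B) - sum(gamma), .Machine$double.eps) / rss, alpha0_max)
}

# Log marginal likelihood L(alpha, alpha0) = sum_i log N(y_i | 0, C) with
# C = alpha0^-1 I + Phi diag(alpha)^-1 Phi', evaluated via the Woodbury
# identity so only K x K factorizations are needed.
log_marginal <- function(B, Phi, alpha, alpha0) {
  Nt <- nrow(B); L <- ncol(B)
  if (ncol(Phi) == 0 || length(alpha) == 0) {
    logdetC <- -Nt * log(alpha0)
    quad <- alpha0 * colSums(B^2)
  } else {
    R <- chol_precision(crossprod(Phi), alpha, alpha0)
    Sigma <- chol2inv(R)
    logdetC <- -Nt * log(alpha0) - sum(log(alpha)) + 2 * sum(log(diag(R)))
    P <- crossprod(Phi, B)
    quad <- alpha0 * colSums(B^2) - alpha0^2 * colSums(P * (Sigma %*% P))
  }
  -0.5 * (L * Nt * log(2 * pi) + L * logdetC + sum(quad))
}

new_mtl_posterior <- function(alpha, alpha0, post, n_iter, converged, lm,
                              noise_free = FALSE) {
  structure(list(alpha = alpha, alpha0 = as.numeric(alpha0),
                 means = post$means, covariance = post$covariance,
                 n_iterations = n_iter, converged = converged,
                 log_marginal = lm, noise_free = noise_free),
            class = "mtl_posterior")
}

#' @export
print.mtl_posterior <- function(x, ...) {
  cat(sprintf(paste0("mtl_posterior: %d atoms (%d active), %d tasks, ",
                     "alpha0=%.3g, %d iterations, converged=%s\n"),
              length(x$alpha), sum(x$alpha < max(x$alpha) / 2),
              ncol(x$means), x$alpha0, x$n_iterations, x$converged))
  invisible(x)
}

#' Fit the multi-task sparse Bayesian model (full iterative algorithm)
#'
#' Iterates posterior update, precision update, and noise update until the
#' maximum relative change in `alpha` drops below `control$tol` or
#' `control$max_iter` sweeps are reached.
#'
#' @param stack a [stack_tasks()] result or `Nt x L` task matrix.
#' @param dictionary a [build_dictionary()] result or `Nt x K` matrix.
#' @param control a [mtl_control()] list.
#' @return an object of class `mtl_posterior` with elements `alpha`,
#'   `alpha0`, `means`, `covariance`, `n_iterations`, `converged`,
#'   `log_marginal`, `noise_free`.
#' @export
fit_multitask <- function(stack, dictionary, control = mtl_control()) {
  B <- as_task_matrix(stack)
  Phi <- as_dictionary_matrix(dictionary)
  if (nrow(B) < 2) stop("need at least 2 samples per task")
  if (ncol(Phi) == 0) stop("empty dictionary")
  if (nrow(Phi) != nrow(B)) stop("dictionary rows must match task length")
  K <- ncol(Phi)
  alpha <- rep(control$alpha_init, K)
  alpha0 <- control$alpha0_init %||%
    (1 / max(0.1 * mean(apply(B, 2, stats::var)), 1e-12))
  noise_free <- FALSE
  converged <- FALSE
  it <- 0
  post <- NULL
  while (it < control$max_iter) {
    it <- it + 1
    post <- posterior_update(B, Phi, alpha, alpha0)
    anew <- hyperparameter_update(post$means, post$covariance, alpha,
                                  control$alpha_max)
    if (!control$fix_alpha0) {
      a0new <- noise_update(B, Phi, post$means, post$covariance, anew,
                            control$alpha0_max)
      noise_free <- isTRUE(attr(a0new, "noise_free"))
      alpha0 <- as.numeric(a0new)
    }
    if (any(!is.finite(anew)) || !is.finite(alpha0))
      stop(sprintf("non-finite hyperparameters at iteration %d", it))
    rel <- max(abs(anew - alpha) / alpha)
    alpha <- anew
    if (rel < control$tol) { converged <- TRUE; break }
  }
  post <- posterior_update(B, Phi, alpha, alpha0)
  lm <- log_marginal(B, Phi, alpha, alpha0)
  new_mtl_posterior(alpha, alpha0, post, it, converged, lm, noise_free)
}

# Optimal precision for one atom given its sparsity factor s and quality
# factors q_i (Tipping-Faul style, pooled over L tasks):
# alpha* = L s^2 / (sum_i q_i^2 - L s), defined when sum q^2 > L s.
atom_alpha_opt <- function(s, qsum2, L) L * s^2 / (qsum2 - L * s)

#' Fit the multi-task model by fast greedy evidence maximization
#'
#' Sequential version of [fit_multitask()]: starting from an empty model,
#' each step considers adding an inactive atom, deleting an active one, or
#' re-estimating an active precision, choosing the action that most
#' increases the pooled log marginal likelihood (evaluated exactly). Atoms
#' outside the active set are reported at `alpha_max`.
#'
#' @inheritParams fit_multitask
#' @export
fit_multitask_fast <- function(stack, dictionary, control = mtl_control()) {
  B <- as_task_matrix(stack)
  Phi <- as_dictionary_matrix(dictionary)
  if (nrow(B) < 2) stop("need at least 2 samples per task")
  if (ncol(Phi) == 0) stop("empty dictionary")
  K <- ncol(Phi); L <- ncol(B)
  alpha0 <- control$alpha0_init %||%
    (1 / max(0.1 * mean(apply(B, 2, stats::var)), 1e-12))
  active <- integer(0)
  alpha_act <- numeric(0)
  PtP <- crossprod(Phi)
  PtB <- crossprod(Phi, B)
  lm_of <- function(act, a_act) {
    log_marginal(B, Phi[, act, drop = FALSE], a_act, alpha0)
  }
  lm_cur <- lm_of(active, alpha_act)
  tol <- if (is.finite(control$tol)) control$tol else 1e-6
  it <- 0
  while (it < control$max_iter) {
    it <- it + 1
    # S_j = phi_j' C^-1 phi_j and Q_ij = phi_j' C^-1 y_i for all atoms,
    # via Woodbury on the current active model.
    if (length(active)) {
      Ra <- chol_precision(PtP[active, active, drop = FALSE], alpha_act,
                           alpha0)
      Sa <- chol2inv(Ra)
      PtPa <- PtP[, active, drop = FALSE]
      S_all <- alpha0 * diag(PtP) -
        alpha0^2 * rowSums((PtPa %*% Sa) * PtPa)
      Q_all <- alpha0 * PtB -
        alpha0^2 * PtPa %*% (Sa %*% PtB[active, , drop = FALSE])
    } else {
      S_all <- alpha0 * diag(PtP)
      Q_all <- alpha0 * PtB
    }
    best <- list(gain = 0)
    for (j in seq_len(K)) {
      in_act <- j %in% active
      if (in_act) {
        aj <- alpha_act[match(j, active)]
        denom <- aj - S_all[j]
        if (abs(denom) < 1e-12) next
        s <- aj * S_all[j] / denom
        q2 <- sum((aj * Q_all[j, ] / denom)^2)
      } else {
        s <- S_all[j]
        q2 <- sum(Q_all[j, ]^2)
      }
      if (s <= 0) next
      cand <- list()
      if (q2 > L * s) {
        astar <- atom_alpha_opt(s, q2, L)
        if (in_act) {
          a2 <- alpha_act; a2[match(j, active)] <- astar
          cand <- list(list(active = active, alpha = a2))
        } else {
          cand <- list(list(active = c(active, j),
                            alpha = c(alpha_act, astar)))
        }
      } else if (in_act) {
        keep <- active != j
        cand <- list(list(active = active[keep], alpha = alpha_act[keep]))
      }
      for (cd in cand) {
        lm_new <- lm_of(cd$active, cd$alpha)
        if (lm_new - lm_cur > best$gain)
          best <- list(gain = lm_new - lm_cur, active = cd$active,
                       alpha = cd$alpha, lm = lm_new)
      }
    }
    if (best$gain <= tol) break
    active <- best$active
    alpha_act <- best$alpha
    lm_cur <- best$lm
    if (!control$fix_alpha0 && length(active)) {
      post_a <- posterior_update(B, Phi[, active, drop = FALSE], alpha_act,
                                 alpha0)
      a0new <- noise_update(B, Phi[, active, drop = FALSE], post_a$means,
                            post_a$covariance, alpha_act,
                            control$alpha0_max)
      alpha0 <- as.numeric(a0new)
      lm_cur <- lm_of(active, alpha_act)
    }
  }
  alpha <- rep(control$alpha_max, K)
  alpha[active] <- pmin(alpha_act, control$alpha_max)
  post <- posterior_update(B, Phi, alpha, alpha0)
  out <- new_mtl_posterior(alpha, alpha0, post, it, TRUE,
                           log_marginal(B, Phi, alpha, alpha0))
  out$active_set <- sort(active)
  out
}

#' Temporal smoothing matrix of a fitted class model
#'
#' The posterior-mean reconstruction of every task is `Phi mu_i`; applied to
#' a trial row-wise this is multiplication by
#' `F = alpha0 * Phi Sigma Phi'`, an `Nt x Nt` symmetric operator with
#' eigenvalues in `[0, 1]` that shrinks each trial toward the learned
#' sinusoidal subspace of its class.
#'
#' @param posterior an `mtl_posterior` from [fit_multitask()] or
#'   [fit_multitask_fast()].
#' @param dictionary the dictionary used for the fit.
#' @return object of class `smoothing_filter` with elements `matrix` and
#'   `class_index`.
#' @export
smoothing_matrix <- function(posterior, dictionary, class_index = NA_integer_) {
  stopifnot(inherits(posterior, "mtl_posterior"))
  Phi <- as_dictionary_matrix(dictionary)
  F <- posterior$alpha0 * (Phi %*% posterior$covariance %*% t(Phi))
  F <- (F + t(F)) / 2
  structure(list(matrix = F, class_index = as.integer(class_index)),
            class = "smoothing_filter")
}
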