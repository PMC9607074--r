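# CCA, TRCA and adaptive TRCA recognizers. All three reduce to the same
# primitive: the dominant eigenvector of a symmetric generalized eigenvalue
# problem (Rayleigh quotient), differing only in how the matrix pencil is
# built from the data.

#' Dominant generalized eigenvector of a symmetric pencil
#'
#' Maximizes the Rayleigh quotient `w'Sw / w'Qw` for symmetric `S` and
#' symmetric positive-definite `Q` by Cholesky whitening of `Q`. If `Q` is
#' not positive definite, a ridge `1e-9 * trace(Q) * I` is added once (and
#' logged); failure after that is an error reporting the condition number.
#'
#' @param S,Q symmetric matrices of equal dimension.
#' @return list with `w` (unit-norm eigenvector, sign fixed so its
#'   largest-magnitude entry is positive) and `lambda` (the maximal
#'   quotient).
#' @export
solve_rayleigh <- function(S, Q) {
  S <- (S + t(S)) / 2
  Q <- (Q + t(Q)) / 2
  R <- tryCatch(chol(Q), error = function(e) NULL)
  if (is.null(R)) {
    message("singular denominator matrix; adding ridge 1e-9 * trace")
    Qr <- Q + diag(1e-9 * sum(diag(Q)), nrow(Q))
    R <- tryCatch(chol(Qr), error = function(e)
      stop(sprintf("denominator not positive definite (condition ~ %.3g)",
                   kappa(Q))))
    Q <- Qr
  }
  # whiten: M = R^-T S R^-1, symmetric; top eigenvector back-transformed
  Rinv <- backsolve(R, diag(nrow(R)))
  M <- crossprod(Rinv, S %*% Rinv)
  es <- eigen((M + t(M)) / 2, symmetric = TRUE)
  w <- Rinv %*% es$vectors[, 1]
  w <- w / sqrt(sum(w^2))
  if (w[which.max(abs(w))] < 0) w <- -w
  lambda <- as.numeric(crossprod(w, S %*% w) / crossprod(w, Q %*% w))
  list(w = as.numeric(w), lambda = lambda)
}

new_recognition <- function(scores, trial_index = NA_integer_) {
  scores <- as.numeric(scores)
  top <- which(scores == max(scores))
  if (length(top) > 1)
    message(sprintf("tie between classes %s; lowest index chosen",
                    paste(top, collapse = ", ")))
  structure(list(scores = scores, predicted = which.max(scores),
                 trial_index = trial_index),
            class = "recognition_result")
}

#' @export
print.recognition_result <- function(x, ...) {
  cat(sprintf("recognition_result: predicted class %d (scores: %s)\n",
              x$predicted, paste(sprintf("%.3f", x$scores), collapse = " ")))
  invisible(x)
}

#' Canonical correlation between a trial and one reference template
#'
#' Largest canonical correlation between the channel-space projections of a
#' centered `Nch x Nt` trial and the time-projections of the `Nt x 2Nh`
#' sinusoidal reference, computed through the generalized eigenvalue problem
#' `X Y (Y'Y)^-1 Y' X' w = lambda X X' w` (the eigenvalue is the squared
#' correlation).
#'
#' @param trial centered `Nch x Nt` matrix.
#' @param reference `Nt x 2Nh` reference matrix.
#' @return the canonical correlation in `[0, 1]`.
#' @export
cca_score <- function(trial, reference) {
  X <- as.matrix(trial)
  Y <- as.matrix(reference)
  stopifnot(ncol(X) == nrow(Y))
  XY <- X %*% Y
  S <- XY %*% solve(crossprod(Y), t(XY))
  Q <- tcrossprod(X)
  r <- solve_rayleigh(S, Q)
  sqrt(min(max(r$lambda, 0), 1))
}

#' Training-free CCA classification of one trial
#'
#' Scores the trial against every per-stimulus reference and picks the
#' argmax; ties go to the lowest class index. An all-zero (degenerate) trial
#' yields uniform zero scores and is flagged via the `"degenerate"`
#' attribute.
#'
#' @param trial centered `Nch x Nt` matrix.
#' @param dictionary a [build_dictionary()] result.
#' @param trial_index optional bookkeeping index.
#' @return a `recognition_result` (fields `scores`, `predicted`,
#'   `trial_index`).
#' @export
cca_classify <- function(trial, dictionary, trial_index = NA_integer_) {
  stopifnot(inherits(dictionary, "harmonic_dictionary"))
  X <- as.matrix(trial)
  if (all(X == 0)) {
    message("degenerate all-zero trial; uniform zero scores")
    out <- new_recognition(rep(0, length(dictionary$per_stimulus)),
                           trial_index)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  scores <- vapply(dictionary$per_stimulus,
                   function(Y) cca_score(X, Y), numeric(1))
  new_recognition(scores, trial_index)
}

new_class_model <- function(class_index, w, lambda, template,
                            smoothing = NULL) {
  structure(list(class_index = as.integer(class_index),
                 spatial_filter = w, eigenvalue = lambda,
                 template = template, smoothing = smoothing),
            class = "class_model")
}

new_filter_bank <- function(models, method, sampling_rate) {
  W <- vapply(models, function(m) m$spatial_filter,
              numeric(length(models[[1]]$spatial_filter)))
  W <- matrix(W, ncol = length(models))
  structure(list(models = models, ensemble = W, method = method,
                 sampling_rate = sampling_rate),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("filter_bank (%s): %d classes, %d channels\n", x$method,
              length(x$models), nrow(x$ensemble)))
  invisible(x)
}

#' Fit TRCA spatial filters
#'
#' Per class `s`, maximizes the cross-trial reproducibility of the spatially
#' filtered signal: `w_s` solves the pencil `(A A', B B')` where `A` is the
#' trial mean and `B` the horizontal concatenation of all trials of the
#' class. The class template is `A`.
#'
#' @param trials centered [epoched_trials()] with at least 2 trials per
#'   class.
#' @return a `filter_bank` with one `class_model` per stimulus and the
#'   ensemble matrix `W` (`Nch x Ns`) of all filters.
#' @export
trca_fit <- function(trials) {
  stopifnot(inherits(trials, "epoched_trials"))
  classes <- sort(unique(trials$labels))
  models <- lapply(classes, function(s) {
    idx <- which(trials$labels == s)
    if (length(idx) < 2)
      stop(sprintf(
        "class %d has %d trial(s); TRCA needs at least 2 (add trials)",
        s, length(idx)))
    Xs <- lapply(idx, function(m) trial_matrix(trials, m))
    A <- Reduce(`+`, Xs) / length(Xs)
    B <- do.call(cbind, Xs)
    r <- solve_rayleigh(tcrossprod(A), tcrossprod(B))
    new_class_model(s, r$w, r$lambda, A)
  })
  new_filter_bank(models, "trca", trials$sampling_rate)
}

#' Classify one trial with a fitted TRCA bank
#'
#' Score of class `s` is the Pearson correlation between the spatially
#' filtered test trial `w_s' X` and the filtered template `w_s' A_s`;
#' decision is the argmax.
#'
#' @param trial centered `Nch x Nt` matrix.
#' @param bank a [trca_fit()] result.
#' @param trial_index optional bookkeeping index.
#' @export
trca_classify <- function(trial, bank, trial_index = NA_integer_) {
  stopifnot(inherits(bank, "filter_bank"))
  X <- as.matrix(trial)
  scores <- vapply(bank$models, function(m) {
    safe_cor(crossprod(m$spatial_filter, X),
             crossprod(m$spatial_filter, m$template))
  }, numeric(1))
  new_recognition(scores, trial_index)
}

#' Fit adaptive TRCA (temporal smoothing + spatial filtering)
#'
#' Per class `s`: (i) all single-channel time courses of the class's
#' training trials are stacked as regression tasks, (ii) the multi-task
#' sparse Bayesian model is fitted on the harmonic dictionary, (iii) the
#' temporal smoothing matrix `F_s` is formed, (iv) every trial is filtered
#' in time, `X_m F_s`, and (v) the spatial filter solves the pencil
#' `(A_f A_f', B_f B_f')` built from the filtered mean and concatenation.
#' With every `F_s` forced to the identity (`smoothing = "identity"`), the
#' procedure reduces exactly to TRCA.
#'
#' @param trials centered [epoched_trials()], at least 2 trials per class.
#' @param dictionary a [build_dictionary()] matching the trial length.
#' @param control a [mtl_control()] list for the Bayesian fit.
#' @param smoothing `"bayes"` (learned filters) or `"identity"` (the TRCA
#'   limiting case).
#' @param fast use [fit_multitask_fast()] instead of the full iteration.
#' @return a `filter_bank` whose models carry the filtered template and the
#'   class smoothing filter.
#' @export
adtrca_fit <- function(trials, dictionary, control = mtl_control(),
                       smoothing = c("bayes", "identity"), fast = FALSE) {
  stopifnot(inherits(trials, "epoched_trials"),
            inherits(dictionary, "harmonic_dictionary"))
  smoothing <- match.arg(smoothing)
  Nt <- dim(trials$data)[3]
  if (nrow(dictionary$full) != Nt)
    stop("dictionary row count must equal the trial sample count")
  classes <- sort(unique(trials$labels))
  models <- lapply(classes, function(s) {
    idx <- which(trials$labels == s)
    if (length(idx) < 2)
      stop(sprintf(
        "class %d has %d trial(s); adTRCA needs at least 2 (add trials)",
        s, length(idx)))
    if (smoothing == "identity") {
      Fs <- structure(list(matrix = diag(Nt), class_index = s),
                      class = "smoothing_filter")
    } else {
      stk <- stack_tasks(trials, s)
      post <- if (fast) fit_multitask_fast(stk, dictionary, control)
              else fit_multitask(stk, dictionary, control)
      Fs <- smoothing_matrix(post, dictionary, s)
      if (max(abs(Fs$matrix)) < .Machine$double.eps)
        stop(sprintf("temporal model empty for class %d (all atoms pruned)",
                     s))
    }
    Xf <- lapply(idx, function(m) trial_matrix(trials, m) %*% Fs$matrix)
    Af <- Reduce(`+`, Xf) / length(Xf)
    Bf <- do.call(cbind, Xf)
    r <- solve_rayleigh(tcrossprod(Af), tcrossprod(Bf))
    new_class_model(s, r$w, r$lambda, Af, Fs)
  })
  new_filter_bank(models, "adtrca", trials$sampling_rate)
}

#' Classify one trial with a fitted adTRCA bank
#'
#' For each candidate class `s`, the test trial is first temporally filtered
#' with that class's smoothing matrix (`X F_s`) — the only class-specific
#' temporal model available at test time — then correlated with the class's
#' filtered template through `w_s`. Decision is the argmax.
#'
#' @inheritParams trca_classify
#' @param bank an [adtrca_fit()] result.
#' @export
adtrca_classify <- function(trial, bank, trial_index = NA_integer_) {
  stopifnot(inherits(bank, "filter_bank"))
  X <- as.matrix(trial)
  scores <- vapply(bank$models, function(m) {
    Xf <- if (is.null(m$smoothing)) X else X %*% m$smoothing$matrix
    safe_cor(crossprod(m$spatial_filter, Xf),
             crossprod(m$spatial_filter, m$template))
  }, numeric(1))
  new_recognition(scores, trial_index)
}

#' Ensemble classification through all class filters at once
#'
#' Stacks the spatial filters of all `Ns` classes into `W` (`Nch x Ns`) and
#' scores class `s` as the Pearson correlation between the flattened matrix
#' projections `W' X_f` and `W' A_f` (the "2-D correlation" convention of
#' ensemble TRCA). Applies to TRCA banks (no temporal filtering) and adTRCA
#' banks (per-candidate-class `F_s`).
#'
#' @inheritParams trca_classify
#' @param bank a fitted `filter_bank` of either method.
#' @export
ensemble_classify <- function(trial, bank, trial_index = NA_integer_) {
  stopifnot(inherits(bank, "filter_bank"))
  X <- as.matrix(trial)
  W <- bank$ensemble
  scores <- vapply(bank$models, function(m) {
    Xf <- if (is.null(m$smoothing)) X else X %*% m$smoothing$matrix
    safe_cor(crossprod(W, Xf), crossprod(W, m$template))
  }, numeric(1))
  new_recognition(scores, trial_index)
}

#' Classify every trial in a set
#'
#' Convenience wrapper running the chosen classifier over all trials.
#' Method `"cca"` needs `dictionary`; `"trca"`/`"adtrca"` need a fitted
#' `bank`.
#'
#' @param trials centered [epoched_trials()].
#' @param method `"cca"`, `"trca"` or `"adtrca"`.
#' @param bank fitted `filter_bank` (trca/adtrca).
#' @param dictionary a [build_dictionary()] (cca).
#' @param ensemble use the ensemble discriminant.
#' @return data.frame with `trial`, `true`, `predicted`.
#' @export
classify_trials <- function(trials, method, bank = NULL, dictionary = NULL,
                            ensemble = FALSE) {
  n <- n_trials(trials)
  pred <- integer(n)
  for (m in seq_len(n)) {
    X <- trial_matrix(trials, m)
    res <- if (method == "cca") cca_classify(X, dictionary, m)
      else if (ensemble) ensemble_classify(X, bank, m)
      else if (method == "trca") trca_classify(X, bank, m)
      else adtrca_classify(X, bank, m)
    pred[m] <- if (method == "cca") res$predicted
      else bank$models[[res$predicted]]$class_index
  }
  data.frame(trial = seq_len(n), true = trials$labels, predicted = pred)
}
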