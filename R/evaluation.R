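# Leave-one-block-out evaluation, accuracy, information transfer rate,
# experiment grids and paired significance tests.

#' Leave-one-block-out cross-validation
#'
#' Each block is held out for testing in turn while the remaining blocks
#' train the recognizer (CCA needs no training and is simply applied to the
#' held-out block). Per-fold accuracy and ITR are reported together with a
#' per-trial detail table.
#'
#' @param trials a block-indexed, centered [epoched_trials()] with >= 2
#'   blocks and every class present in every block.
#' @param method `"cca"`, `"trca"` or `"adtrca"`.
#' @param dictionary a [build_dictionary()] (required for cca/adtrca).
#' @param ensemble use the ensemble discriminant (trca/adtrca only).
#' @param control [mtl_control()] for the adTRCA Bayesian fit.
#' @param smoothing,fast passed to [adtrca_fit()].
#' @param gaze_shift_s gaze-shift time added to the selection window in the
#'   ITR (s).
#' @param train_blocks optionally use only the first `train_blocks` of the
#'   remaining blocks in each fold (few-shot calibration experiments).
#' @return list of class `lobo_result`: `folds` (data.frame with block,
#'   accuracy, itr), `detail` (per-trial), `accuracy` and `itr` (means over
#'   folds).
#' @export
lobo_cv <- function(trials, method = c("cca", "trca", "adtrca"),
                    dictionary = NULL, ensemble = FALSE,
                    control = mtl_control(), smoothing = "bayes",
                    fast = FALSE, gaze_shift_s = 0.5, train_blocks = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(trials, "epoched_trials"))
  if (is.null(trials$blocks)) stop("trials carry no block indices")
  blocks <- sort(unique(trials$blocks))
  if (length(blocks) < 2) stop("leave-one-block-out needs at least 2 blocks")
  if (method != "trca" && is.null(dictionary))
    stop("dictionary required for method ", method)
  classes <- sort(unique(trials$labels))
  window_s <- dim(trials$data)[3] / trials$sampling_rate
  detail <- list()
  folds <- data.frame(block = blocks, accuracy = NA_real_, itr = NA_real_)
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    test <- subset_trials(trials, trials$blocks == b)
    bank <- NULL
    if (method != "cca") {
      tr_idx <- which(trials$blocks != b)
      if (!is.null(train_blocks)) {
        keep <- utils::head(setdiff(blocks, b), train_blocks)
        tr_idx <- which(trials$blocks %in% keep)
      }
      train <- subset_trials(trials, tr_idx)
      for (s in classes)
        if (!any(train$labels == s))
          stop(sprintf("class %d missing from training split of block %d",
                       s, b))
      bank <- if (method == "trca") trca_fit(train)
        else adtrca_fit(train, dictionary, control, smoothing, fast)
    }
    res <- classify_trials(test, method, bank, dictionary, ensemble)
    res$block <- b
    detail[[i]] <- res
    acc <- mean(res$predicted == res$true)
    folds$accuracy[i] <- acc
    folds$itr[i] <- itr(acc, length(classes), window_s, gaze_shift_s)
  }
  structure(list(folds = folds, detail = do.call(rbind, detail),
                 accuracy = mean(folds$accuracy), itr = mean(folds$itr),
                 method = method, ensemble = ensemble),
            class = "lobo_result")
}

#' @export
print.lobo_result <- function(x, ...) {
  cat(sprintf("lobo_result (%s%s): %d folds, accuracy %.3f, ITR %.2f bits/min\n",
              x$method, if (x$ensemble) ", ensemble" else "",
              nrow(x$folds), x$accuracy, x$itr))
  invisible(x)
}

#' Classification accuracy
#'
#' Fraction of correctly recognized targets. Accepts a [lobo_cv()] result or
#' any data.frame with `true` and `predicted` columns.
#'
#' @param results classification results.
#' @export
accuracy <- function(results) {
  if (inherits(results, "lobo_result")) results <- results$detail
  if (!NROW(results)) stop("no classification results")
  mean(results$predicted == results$true)
}

#' Information transfer rate (bits per minute)
#'
#' The standard Wolpaw ITR:
#' `(60 / T) * (log2 N + P log2 P + (1 - P) log2((1 - P) / (N - 1)))` with
#' `T = selection_time_s + gaze_shift_s` and the convention
#' `0 * log2(0) = 0`; clipped below at 0 (sub-chance accuracy conveys no
#' usable rate).
#'
#' @param p accuracy in `[0, 1]`.
#' @param n_classes number of selectable targets (>= 2).
#' @param selection_time_s length of the analyzed EEG window (s).
#' @param gaze_shift_s gaze-shift overhead per selection (s); 0.5 s is the
#'   community convention for speller protocols.
#' @export
itr <- function(p, n_classes, selection_time_s, gaze_shift_s = 0.5) {
  if (n_classes < 2) stop("ITR needs at least 2 classes")
  stopifnot(p >= 0, p <= 1, selection_time_s > 0, gaze_shift_s >= 0)
  xlx <- function(x) ifelse(x > 0, x * log2(x), 0)
  bits <- log2(n_classes) + xlx(p) +
    ifelse(p < 1, (1 - p) * log2(max((1 - p), 0) / (n_classes - 1)), 0)
  max(60 / (selection_time_s + gaze_shift_s) * bits, 0)
}

#' Factorial experiment grid over window, channels and training blocks
#'
#' Sweeps time-window lengths (cropped from the epoch start, i.e. after any
#' latency correction), channel subsets and training-block counts, running
#' [lobo_cv()] in every cell. The dictionary is rebuilt per window length.
#'
#' @param trials centered, block-indexed [epoched_trials()].
#' @param methods character vector of recognizer names.
#' @param windows_s numeric vector of window lengths (s).
#' @param channel_subsets list of channel-name (or index) vectors; `NULL`
#'   entries mean all channels.
#' @param train_block_counts integer vector; `NA` means all available.
#' @param stim the [stimulus_set()] describing the stimuli (its `n_samples`
#'   is replaced per window).
#' @param ... passed to [lobo_cv()].
#' @return data.frame, one row per (method, window, subset, train count,
#'   fold), with accuracy and ITR; invalid cells (window longer than the
#'   epoch) carry `NA` and `note = "invalid"`.
#' @export
experiment_grid <- function(trials, methods, windows_s,
                            channel_subsets = list(NULL),
                            train_block_counts = NA, stim, ...) {
  out <- list()
  for (wi in seq_along(windows_s)) {
    w <- windows_s[wi]
    nkeep <- round(w * trials$sampling_rate)
    valid <- nkeep >= 2 && nkeep <= dim(trials$data)[3]
    for (ci in seq_along(channel_subsets)) for (tb in train_block_counts) {
      tag <- data.frame(method = NA_character_, window_s = w,
                        channels = if (is.null(channel_subsets[[ci]])) "all"
                          else paste(channel_subsets[[ci]], collapse = "+"),
                        train_blocks = tb)
      for (method in methods) {
        tag$method <- method
        if (!valid) {
          out[[length(out) + 1]] <- cbind(tag, data.frame(
            block = NA, accuracy = NA_real_, itr = NA_real_,
            note = "invalid"))
          next
        }
        tr <- crop_samples(trials, nkeep)
        if (!is.null(channel_subsets[[ci]]))
          tr <- select_channels(tr, channel_subsets[[ci]])
        stim_w <- stimulus_set(stim$frequencies, stim$n_harmonics,
                               stim$sampling_rate, nkeep)
        dict_w <- build_dictionary(stim_w)
        res <- lobo_cv(tr, method, dictionary = dict_w,
                       train_blocks = if (is.na(tb)) NULL else tb, ...)
        out[[length(out) + 1]] <- cbind(
          tag[rep(1, nrow(res$folds)), , drop = FALSE],
          cbind(res$folds, note = ""))
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Paired comparison of two accuracy vectors
#'
#' Reports both the paired t-test and the Wilcoxon signed-rank test
#' (two-sided) on paired per-subject or per-seed accuracies. Identical
#' vectors are flagged degenerate with `p = 1`.
#'
#' @param acc_a,acc_b equal-length paired samples (n >= 5).
#' @return list with `t_statistic`, `t_p`, `wilcox_statistic`, `wilcox_p`,
#'   `degenerate`.
#' @export
paired_comparison <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b))
  if (length(acc_a) < 5) stop("need at least 5 pairs")
  d <- acc_b - acc_a
  if (all(d == 0)) {
    message("all paired differences are zero; tests degenerate")
    return(list(t_statistic = NA_real_, t_p = 1, wilcox_statistic = NA_real_,
                wilcox_p = 1, degenerate = TRUE))
  }
  if (stats::sd(d) < 1e-10 * max(abs(d))) {
    # constant nonzero shift: the t statistic diverges
    message("constant paired difference; t statistic infinite")
    wt0 <- suppressWarnings(stats::wilcox.test(acc_b, acc_a, paired = TRUE,
                                               exact = FALSE))
    return(list(t_statistic = sign(mean(d)) * Inf, t_p = 0,
                wilcox_statistic = unname(wt0$statistic),
                wilcox_p = wt0$p.value, degenerate = FALSE))
  }
  tt <- stats::t.test(acc_b, acc_a, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(acc_b, acc_a, paired = TRUE,
                                            exact = FALSE))
  list(t_statistic = unname(tt$statistic), t_p = tt$p.value,
       wilcox_statistic = unname(wt$statistic), wilcox_p = wt$p.value,
       degenerate = FALSE)
}
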