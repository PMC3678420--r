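#' Build per-trial feature vectors from binned rates
#'
#' Flattens the firing rates of a neuron subset over a slice of 100-ms bins
#' into one vector per trial (neuron-major ordering: all bins of the first
#' neuron, then the second, ...). The default slice keeps the last
#' `n_bins - 4` bins of the analysis window, reproducing the published
#' feature dimensionality (m = 18 of 22 bins for a 2.2-s window, m = 14 of
#' 18 for 1.8 s); the exact epoch those m bins cover is not documented, so
#' the slice is configurable.
#'
#' @param binned a `binned_rates` object.
#' @param subset neuron ids to include (default all).
#' @param feature_bins integer bin indices to use as features, or `NULL` for
#'   the default slice.
#' @return list with `X` (trials x (neurons x m) matrix), `y` (labels),
#'   `feature_bins`, `neuron_ids`.
#' @export
build_features <- function(binned, subset = binned$neuron_ids,
                           feature_bins = NULL) {
  if (!inherits(binned, "binned_rates")) stop("not a binned_rates")
  if (!length(subset)) stop("neuron subset is empty")
  unknown <- setdiff(subset, binned$neuron_ids)
  if (length(unknown)) stop("unknown neuron id(s): ",
                            paste(unknown, collapse = ", "))
  n_bins <- dim(binned$values)[3]
  if (is.null(feature_bins)) {
    m <- if (n_bins > 4L) n_bins - 4L else n_bins
    feature_bins <- seq.int(n_bins - m + 1L, n_bins)
  }
  if (any(feature_bins < 1L | feature_bins > n_bins))
    stop("feature_bins out of range")
  cols <- match(subset, binned$neuron_ids)
  mats <- lapply(cols, function(j)
    binned$values[, j, feature_bins, drop = FALSE])
  X <- do.call(cbind, lapply(mats, function(a)
    matrix(a, nrow = dim(a)[1], ncol = length(feature_bins))))
  list(X = X, y = binned$labels, feature_bins = feature_bins,
       neuron_ids = subset)
}

#' Grid-searched RBF-SVM classification with stratified cross-validation
#'
#' Runs a one-vs-one soft-margin SVM with RBF kernel over a `(C, gamma)`
#' grid. Hyperparameters are chosen by stratified 2-fold cross-validated
#' accuracy. Two evaluation schemes are available: `"cv"` (default) reports
#' the same 2-fold CV accuracy at the best grid point; `"held_out"` selects
#' the grid point by an inner 2-fold CV inside fold 1, then trains on fold 1
#' and scores on fold 2 only. Features are standardized per dimension using
#' training-fold statistics.
#'
#' @param X trials x features matrix.
#' @param y per-trial class labels (integers).
#' @param hyper_grid list with vectors `C` and `gamma`
#'   (default [default_svm_grid()]).
#' @param cv_folds number of folds (default 2).
#' @param eval_scheme `"cv"` or `"held_out"`.
#' @param seed integer seed for the fold assignment.
#' @param subset_name label stored on the result.
#' @return list of class `decoding_result`: `accuracy`, `C`, `gamma`,
#'   `confusion` (true x predicted counts), `folds`, `subset_name`,
#'   `neuron_ids`, `eval_scheme`.
#' @export
fit_and_score <- function(X, y, hyper_grid = default_svm_grid(),
                          cv_folds = 2L, eval_scheme = c("cv", "held_out"),
                          seed = 1L, subset_name = "subset") {
  eval_scheme <- match.arg(eval_scheme)
  if (!length(hyper_grid$C) || !length(hyper_grid$gamma))
    stop("hyperparameter grid is empty")
  y <- as.integer(y)
  classes <- sort(unique(y))
  fold <- stratified_folds(y, cv_folds, seed)
  if (any(table(y, fold) < 2L))
    stop("every class needs at least 2 trials in every fold")

  if (eval_scheme == "held_out") {
    train_idx <- which(fold == 1L)
    inner <- fit_and_score(X[train_idx, , drop = FALSE], y[train_idx],
                           hyper_grid, cv_folds = 2L, eval_scheme = "cv",
                           seed = seed + 1L, subset_name = subset_name)
    Z <- fold_standardize(X, train_idx)
    test_idx <- which(fold != 1L)
    K <- rbf_kernel(Z[train_idx, , drop = FALSE],
                    Z[train_idx, , drop = FALSE], inner$gamma)
    model <- ovo_train(K, y[train_idx], inner$C, classes)
    Kx <- rbf_kernel(Z[train_idx, , drop = FALSE],
                     Z[test_idx, , drop = FALSE], inner$gamma)
    pred <- ovo_predict(model, Kx)
    conf <- table(factor(y[test_idx], classes), factor(pred, classes))
    return(structure(list(accuracy = mean(pred == y[test_idx]),
                          C = inner$C, gamma = inner$gamma,
                          confusion = unclass(conf), folds = fold,
                          subset_name = subset_name,
                          neuron_ids = NULL, eval_scheme = "held_out"),
                     class = "decoding_result"))
  }

  n_grid <- length(hyper_grid$gamma) * length(hyper_grid$C)
  correct <- matrix(0, nrow = n_grid, ncol = 2L,
                    dimnames = list(NULL, c("correct", "n")))
  preds <- vector("list", n_grid)  # per grid point: predictions for all trials
  for (g in seq_len(n_grid)) preds[[g]] <- integer(length(y))
  for (f in seq_len(cv_folds)) {
    train_idx <- which(fold != f)
    test_idx <- which(fold == f)
    Z <- fold_standardize(X, train_idx)
    Ztr <- Z[train_idx, , drop = FALSE]
    Zte <- Z[test_idx, , drop = FALSE]
    Dtt <- sq_dist(Ztr, Ztr)
    Dtx <- sq_dist(Ztr, Zte)
    g <- 0L
    for (gamma in hyper_grid$gamma) {
      K <- exp(-gamma * Dtt)
      Kx <- exp(-gamma * Dtx)
      for (C in hyper_grid$C) {
        g <- g + 1L
        model <- ovo_train(K, y[train_idx], C, classes)
        pred <- ovo_predict(model, Kx)
        preds[[g]][test_idx] <- pred
        correct[g, ] <- correct[g, ] + c(sum(pred == y[test_idx]),
                                         length(test_idx))
      }
    }
  }
  acc <- correct[, "correct"] / correct[, "n"]
  best <- which.max(acc)  # ties: first grid point (smallest gamma, then C)
  grid_gamma <- rep(hyper_grid$gamma, each = length(hyper_grid$C))
  grid_C <- rep(hyper_grid$C, times = length(hyper_grid$gamma))
  pred_best <- preds[[best]]
  conf <- table(factor(y, classes), factor(pred_best, classes))
  structure(list(accuracy = acc[best], C = grid_C[best],
                 gamma = grid_gamma[best], confusion = unclass(conf),
                 folds = fold, subset_name = subset_name, neuron_ids = NULL,
                 eval_scheme = "cv"),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("decoding_result [%s]: accuracy %.3f (C = %g, gamma = %g, %s)\n",
              x$subset_name, x$accuracy, x$C, x$gamma, x$eval_scheme))
  invisible(x)
}

decode_subset <- function(binned, subset, subset_name, feature_bins = NULL,
                          hyper_grid = default_svm_grid(), seed = 1L,
                          eval_scheme = "cv") {
  feats <- build_features(binned, subset, feature_bins)
  res <- fit_and_score(feats$X, feats$y, hyper_grid, cv_folds = 2L,
                       eval_scheme = eval_scheme, seed = seed,
                       subset_name = subset_name)
  res$neuron_ids <- subset
  res
}

#' Ensemble-comparison decoding experiment
#'
#' Decodes the session's four actions three times: from the full ensemble,
#' from the tuned subset (neurons whose MI meets the task's
#' cumulative-information threshold: one-property-only plus BOTH), and from
#' the top 10 neurons by that task's MI (all neurons when fewer than 10).
#'
#' @param binned `binned_rates` for the session being decoded.
#' @param profile `mi_profile` for the recording day.
#' @param feature_bins,hyper_grid,seed,eval_scheme passed to the decoder.
#' @return named list of `decoding_result`s (`full`, `tuned`, `top10`); a
#'   component is `NULL` with a warning when its subset is empty.
#' @export
experiment_ensembles <- function(binned, profile, feature_bins = NULL,
                                 hyper_grid = default_svm_grid(), seed = 1L,
                                 eval_scheme = "cv") {
  task <- binned$task
  mi <- if (task == "reach") profile$mi_reach else profile$mi_grasp
  thr <- attr(profile, if (task == "reach") "thr_reach" else "thr_grasp")
  tuned <- profile$neuron[mi >= thr]
  top10 <- profile$neuron[order(mi, decreasing = TRUE)][
    seq_len(min(10L, nrow(profile)))]
  out <- list(
    full = decode_subset(binned, profile$neuron, "full_ensemble",
                         feature_bins, hyper_grid, seed, eval_scheme),
    tuned = NULL, top10 = NULL
  )
  if (length(tuned)) {
    out$tuned <- decode_subset(binned, tuned, "tuned_subset", feature_bins,
                               hyper_grid, seed, eval_scheme)
  } else warning("tuned subset is empty; decoding skipped")
  out$top10 <- decode_subset(binned, top10, "top10", feature_bins,
                             hyper_grid, seed, eval_scheme)
  out
}

#' Subset-addition decoding experiment
#'
#' Compares decoding by the neurons tuned to one property only against the
#' same subset plus the neurons tuned to both tasks: subset a (reach-only)
#' versus a + c in the reach session, and subset b (grasp-only) versus
#' b + c in the grasp session, where c is the BOTH category. Reports the
#' relative accuracy improvement `(acc2 - acc1)/acc1 x 100%`.
#'
#' @param binned_reach,binned_grasp `binned_rates` of the two sessions.
#' @param profile `mi_profile` for the recording day.
#' @param feature_bins,hyper_grid,seed,eval_scheme passed to the decoder.
#' @return list with components `reach` and `grasp`, each holding `base`,
#'   `combined` (`decoding_result`s) and `improvement_pct`; a component is
#'   `NULL` with a warning when the single-property subset is empty.
#' @export
experiment_addition <- function(binned_reach, binned_grasp, profile,
                                feature_bins = NULL,
                                hyper_grid = default_svm_grid(), seed = 1L,
                                eval_scheme = "cv") {
  if (binned_reach$task != "reach" || binned_grasp$task != "grasp")
    stop("binned_reach/binned_grasp task mismatch")
  subset_c <- profile$neuron[profile$category == "BOTH"]
  one_task <- function(binned, only_cat, name) {
    base_ids <- profile$neuron[profile$category == only_cat]
    if (!length(base_ids)) {
      warning("subset ", name, " is empty; comparison skipped")
      return(NULL)
    }
    base <- decode_subset(binned, base_ids, name, feature_bins, hyper_grid,
                          seed, eval_scheme)
    comb <- decode_subset(binned, c(base_ids, subset_c),
                          paste0(name, "+both"), feature_bins, hyper_grid,
                          seed, eval_scheme)
    list(base = base, combined = comb,
         improvement_pct = (comb$accuracy - base$accuracy) /
           base$accuracy * 100)
  }
  list(reach = one_task(binned_reach, "REACH_ONLY", "a"),
       grasp = one_task(binned_grasp, "GRASP_ONLY", "b"))
}
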