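#' Default hyperparameter grid for the RBF SVM
#'
#' The classic LIBSVM-style grid: `log2(C)` from -5 to 15 and `log2(gamma)`
#' from -15 to 3, both in steps of 2.
#'
#' @return list with numeric vectors `C` and `gamma`.
#' @export
default_svm_grid <- function() {
  list(C = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

# Squared Euclidean distances between rows of A and rows of B.
sq_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

rbf_kernel <- function(A, B, gamma) exp(-gamma * sq_dist(A, B))

# Train a one-vs-one multiclass C-SVC on a precomputed kernel matrix of the
# training trials. Returns the 6 pairwise machines.
ovo_train <- function(K, y, C, classes = sort(unique(y))) {
  pairs <- utils::combn(classes, 2L)
  machines <- vector("list", ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    c1 <- pairs[1, p]; c2 <- pairs[2, p]
    idx <- which(y == c1 | y == c2)
    yy <- ifelse(y[idx] == c1, 1L, -1L)
    fit <- smo_train(K[idx, idx, drop = FALSE], yy, C)
    machines[[p]] <- list(c1 = c1, c2 = c2, idx = idx, yy = yy,
                          alpha = fit$alpha, b = fit$b)
  }
  list(machines = machines, classes = classes)
}

# Predict classes by majority vote over the pairwise machines; Kx is the
# n_train x n_new kernel matrix. Ties go to the lowest class index.
ovo_predict <- function(model, Kx) {
  n_new <- ncol(Kx)
  votes <- matrix(0L, nrow = n_new, ncol = length(model$classes))
  for (m in model$machines) {
    f <- colSums(m$alpha * m$yy * Kx[m$idx, , drop = FALSE]) + m$b
    winner <- ifelse(f >= 0, m$c1, m$c2)
    for (cl in c(m$c1, m$c2)) {
      ci <- match(cl, model$classes)
      votes[, ci] <- votes[, ci] + (winner == cl)
    }
  }
  model$classes[max.col(votes, ties.method = "first")]
}

# Standardize columns of X with mean/sd estimated on the training rows only;
# constant columns get unit scale.
fold_standardize <- function(X, train_idx) {
  mu <- colMeans(X[train_idx, , drop = FALSE])
  sdv <- apply(X[train_idx, , drop = FALSE], 2, sd)
  sdv[sdv == 0 | is.na(sdv)] <- 1
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}

# Seeded stratified fold assignment: within each class, trials are shuffled
# and dealt round-robin across folds.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_local_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}
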