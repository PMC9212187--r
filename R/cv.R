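# Stratified cross-validation of the MLP classifier.

# Stratified fold assignment: within each class, indices are shuffled by
# the seeded generator and dealt round-robin over folds.  The dealing
# pointer carries over between classes so the per-class remainders land
# on different folds and total fold sizes stay as equal as possible.
stratified_folds <- function(y, n_folds, seed) {
  y <- as.integer(y)
  fold <- integer(length(y))
  with_seed(seed, {
    start <- 0L
    for (cls in sort(unique(y))) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((start + seq_along(idx) - 1L) %% n_folds) + 1L
      start <- start + length(idx)
    }
  })
  fold
}

# z-score columns by training-set mean/sd; zero-variance columns are
# centred only
standardize_train_test <- function(X_train, X_test) {
  mu <- colMeans(X_train)
  sdv <- apply(X_train, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1
  list(train = sweep(sweep(X_train, 2, mu), 2, sdv, "/"),
       test = sweep(sweep(X_test, 2, mu), 2, sdv, "/"))
}

#' Cross-validated accuracy of the LM-trained MLP
#'
#' Stratified k-fold cross-validation: folds preserve the group
#' proportions, each fold serves once as the held-out validation set (so
#' with 10 folds every evaluation is a 90/10 train/validation split).  A
#' fresh MLP is initialised per fold from a seed-derived stream, trained
#' with Levenberg-Marquardt backpropagation, and scored on the held-out
#' subjects.  Accuracy is reported in percent; `mean_accuracy` is the
#' fold-mean, `pooled_accuracy` pools all held-out predictions.
#'
#' @param X Numeric matrix, subjects by features.
#' @param y 0/1 group labels, each class at least `n_folds` subjects.
#' @param n_folds Number of folds (default 10).
#' @param repeats Number of independent fold-assignment repeats whose
#'   results are averaged (default 1).
#' @param seed Integer seed controlling folds and weight initialisation.
#' @param cfg A [train_config()].
#' @param standardize z-score each feature on the training part of every
#'   fold (default `TRUE`).
#'
#' @return A `cv_result`: tibble of per-fold rows (`repeat`, `fold`,
#'   `n_test`, `n_correct`, `accuracy`, `mse`) with the summary accuracies
#'   as attributes; see [glance.cv_result()].
#' @export
cross_validate <- function(X, y, n_folds = 10, repeats = 1, seed = 1L,
                           cfg = train_config(), standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(factor(y, levels = c(0L, 1L)))
  if (any(counts < n_folds)) {
    abort(sprintf(
      "Each class needs at least n_folds = %d subjects (have %s).",
      n_folds, paste(counts, collapse = "/")))
  }
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    fold <- stratified_folds(y, n_folds, derive_seed(seed, "folds", rep_i))
    for (f in seq_len(n_folds)) {
      te <- fold == f
      Xtr <- X[!te, , drop = FALSE]; Xte <- X[te, , drop = FALSE]
      if (standardize) {
        std <- standardize_train_test(Xtr, Xte)
        Xtr <- std$train; Xte <- std$test
      }
      model <- init_mlp(ncol(X), seed = derive_seed(seed, "init", rep_i * 1000L + f))
      fit <- train_mlp(model, Xtr, y[!te], cfg)
      pred <- predict(fit, Xte)
      err <- y[te] - pred$score
      rows[[length(rows) + 1L]] <- tibble::tibble(
        rep = rep_i, fold = f, n_test = sum(te),
        n_correct = sum(pred$label == y[te]),
        accuracy = 100 * mean(pred$label == y[te]),
        mse = mean(err^2))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_accuracy") <- mean(out$accuracy)
  attr(out, "pooled_accuracy") <- 100 * sum(out$n_correct) / sum(out$n_test)
  attr(out, "mse") <- mean(out$mse)
  attr(out, "n_folds") <- n_folds
  attr(out, "seed") <- seed
  class(out) <- c("cv_result", class(out))
  out
}

#' One-row summary of a cross-validation result
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return Tibble with `mean_accuracy` (fold-mean, %), `pooled_accuracy`
#'   (all held-out predictions pooled, %), and `mse`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(mean_accuracy = attr(x, "mean_accuracy"),
                 pooled_accuracy = attr(x, "pooled_accuracy"),
                 mse = attr(x, "mse"))
}
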