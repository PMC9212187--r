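#' Wrapper-fitness configuration
#'
#' How a candidate feature subset is scored: restrict the feature table to
#' the subset, z-score each column on the training part of every fold,
#' and evaluate the MLP by stratified cross-validation.  `mode = "cv"`
#' runs the full k-fold cross-validation; `mode = "split"` evaluates a
#' single stratified 90/10 split (the first fold), which is the fast
#' setting intended for the inner loop of the evolutionary search.
#'
#' @param mode `"split"` (default, fast) or `"cv"`.
#' @param n_folds Folds for `"cv"`; also sets the split ratio for
#'   `"split"` (1/n_folds held out). Default 10.
#' @param seed Integer seed for folds and weight initialisation; fixed per
#'   search run so cached evaluations are consistent and elitism is
#'   well-defined.
#' @param cfg A [train_config()]; the inner-loop default caps LM epochs at
#'   30, which is ample for the small networks involved.
#' @param repeats Fold-assignment repeats averaged in `"cv"` mode.
#'
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(mode = c("split", "cv"), n_folds = 10, seed = 1L,
                           cfg = train_config(max_epochs = 30), repeats = 1) {
  mode <- match.arg(mode)
  structure(list(mode = mode, n_folds = n_folds, seed = as.integer(seed),
                 cfg = cfg, repeats = repeats),
            class = "fitness_config")
}

new_fitness_cache <- function() {
  env <- new.env(parent = emptyenv())
  env$hits <- 0L
  env$misses <- 0L
  env
}

#' Cross-validated accuracy of a feature subset
#'
#' The wrapper objective used by every selection algorithm: mean accuracy
#' (percent) of the two-hidden-layer MLP on the columns named by `subset`.
#' Deterministic given `(subset, fitness$seed)`; repeated queries with the
#' same subset are answered from `cache` when one is supplied.
#'
#' @param table A feature table (see [feature_names()]).
#' @param subset Integer vector of distinct feature indices (1-based,
#'   referring to the feature columns in order).
#' @param fitness A [fitness_config()].
#' @param cache Optional cache environment from inside a search run.
#'
#' @return Accuracy in percent.
#' @export
evaluate_fitness <- function(table, subset, fitness = fitness_config(),
                             cache = NULL) {
  subset <- sort(unique(as.integer(subset)))
  fn <- feature_names(table)
  if (length(subset) == 0 || any(subset < 1 | subset > length(fn))) {
    abort("`subset` must be non-empty with indices inside the feature columns.")
  }
  key <- paste(subset, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) {
    cache$hits <- cache$hits + 1L
    return(cache[[key]])
  }
  X <- feature_matrix(table)[, subset, drop = FALSE]
  y <- as.integer(table$group)
  acc <- if (fitness$mode == "cv") {
    cv <- cross_validate(X, y, n_folds = fitness$n_folds,
                         repeats = fitness$repeats, seed = fitness$seed,
                         cfg = fitness$cfg, standardize = TRUE)
    attr(cv, "mean_accuracy")
  } else {
    single_split_accuracy(X, y, fitness)
  }
  if (!is.null(cache)) {
    cache$misses <- cache$misses + 1L
    cache[[key]] <- acc
  }
  acc
}

# one stratified (n_folds-1)/n_folds train/validation split
single_split_accuracy <- function(X, y, fitness) {
  fold <- stratified_folds(y, fitness$n_folds,
                           derive_seed(fitness$seed, "folds", 1L))
  te <- fold == 1L
  std <- standardize_train_test(X[!te, , drop = FALSE], X[te, , drop = FALSE])
  model <- init_mlp(ncol(X), seed = derive_seed(fitness$seed, "init", 1001L))
  fit <- train_mlp(model, std$train, y[!te], fitness$cfg)
  pred <- predict(fit, std$test)
  100 * mean(pred$label == y[te])
}
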