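#' Configuration for the subset-search algorithms
#'
#' Collects the iteration budget, RNG seed and per-algorithm constants.
#' Defaults are the published settings of each algorithm:
#' * GA: population 20, mutation percentage 0.3, mutation rate 0.1,
#'   14 crossover offspring per generation, Boltzmann selection pressure 8;
#' * NSGA-II: population 25, mutation percentage 0.4, mutation rate 0.1,
#'   14 crossover offspring;
#' * ACO: 10 ants, evaporation 0.05, initial / exponential / heuristic
#'   weights 1, 1, 1;
#' * SA: initial temperature 10, temperature reduction rate 0.99;
#' * PSO: swarm 20, cognitive and social coefficients 1.5, inertia 0.72.
#'
#' @param algorithm One of `"ga"`, `"nsga2"`, `"aco"`, `"sa"`, `"pso"`,
#'   `"stat"`.
#' @param iterations Search iterations / generations (default 200).
#' @param seed Integer seed; the whole run is bit-reproducible given
#'   `(seed, config, table)`.
#' @param ... Overrides for the per-algorithm constants listed above.
#'
#' @return An `ea_config` list.
#' @export
ea_config <- function(algorithm = c("ga", "nsga2", "aco", "sa", "pso", "stat"),
                      iterations = 200, seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    ga = list(pop = 20, mutation_percentage = 0.3, mutation_rate = 0.1,
              crossover_count = 14, selection_pressure = 8),
    nsga2 = list(pop = 25, mutation_percentage = 0.4, mutation_rate = 0.1,
                 crossover_count = 14),
    aco = list(n_ants = 10, evaporation = 0.05, initial_weight = 1,
               exponential_weight = 1, heuristic_weight = 1),
    sa = list(T0 = 10, cooling = 0.99),
    pso = list(swarm = 20, c1 = 1.5, c2 = 1.5, inertia = 0.72),
    stat = list()
  )
  extra <- list(...)
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown %s parameter(s): %s.", algorithm,
                  paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(defaults, extra)
  structure(c(list(algorithm = algorithm,
                   iterations = as.integer(iterations),
                   seed = as.integer(seed)), cfg),
            class = "ea_config")
}

new_selection_result <- function(algorithm, table, best_subset, best_fitness,
                                 history, evaluations, config, extra = list()) {
  fn <- feature_names(table)
  structure(
    c(list(algorithm = algorithm,
           k = length(best_subset),
           best_subset = as.integer(best_subset),
           best_feature_names = fn[best_subset],
           best_fitness = best_fitness,
           history = as.numeric(history),
           evaluations = as.integer(evaluations),
           seed = config$seed,
           config = unclass(config)),
      extra),
    class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: k = %d, best fitness %.2f%% (%d evaluations)\n",
              toupper(x$algorithm), x$k, x$best_fitness, x$evaluations))
  invisible(x)
}

#' Per-iteration best fitness of a selection run
#' @param x A `selection_result`.
#' @param ... Unused.
#' @return Tibble with `iteration` and `best_fitness` (best-so-far, %).
#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$history),
                 best_fitness = x$history)
}

#' One-row summary of a selection run
#' @param x A `selection_result`.
#' @param ... Unused.
#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, k = x$k,
                 best_fitness = x$best_fitness,
                 evaluations = x$evaluations, seed = x$seed)
}

#' Search for the best feature subset of size k
#'
#' Front door to the six subset-selection methods: the five evolutionary
#' searches, each using the cross-validated MLP accuracy of a candidate
#' subset as its fitness, and the Welch t-test statistical baseline which
#' ranks features by p-value without touching the classifier.
#'
#' @param table A feature table.
#' @param algorithm `"ga"`, `"nsga2"`, `"aco"`, `"sa"`, `"pso"` or
#'   `"stat"`.
#' @param k Subset cardinality (for `"nsga2"` the maximum cardinality).
#' @param config An [ea_config()] for the chosen algorithm; created from
#'   `iterations` and `seed` when omitted.
#' @param fitness A [fitness_config()]; by default a single-split fitness
#'   seeded from `config$seed`.
#' @param iterations,seed Convenience arguments used when `config` is
#'   omitted.
#'
#' @return A `selection_result` (for `"nsga2"`, an `nsga2_result`; see
#'   [nsga2_select()]).
#' @export
select_features <- function(table, algorithm = c("ga", "nsga2", "aco", "sa",
                                                 "pso", "stat"),
                            k, config = NULL, fitness = NULL,
                            iterations = 200, seed = 1L) {
  algorithm <- match.arg(algorithm)
  if (is.null(config)) {
    config <- ea_config(algorithm, iterations = iterations, seed = seed)
  }
  stopifnot(config$algorithm == algorithm)
  switch(algorithm,
    ga = ga_select(table, k, config, fitness),
    nsga2 = nsga2_select(table, k, config, fitness),
    aco = aco_select(table, k, config, fitness),
    sa = sa_select(table, k, config, fitness),
    pso = pso_select(table, k, config, fitness),
    stat = ttest_select(table, k, fitness = fitness))
}

#' Serialize / restore a selection result as JSON
#'
#' The file records the algorithm, full configuration, seed, best subset
#' (indices and names), fitness history and evaluation count; identical
#' `(config, seed, table)` produce byte-identical files.
#'
#' @param result A `selection_result`.
#' @param path File path.
#' @rdname selection_result_io
#' @export
write_selection_result <- function(result, path) {
  stopifnot(inherits(result, "selection_result"))
  obj <- unclass(result)
  obj$config <- obj$config[setdiff(names(obj$config), "algorithm")]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname selection_result_io
#' @export
read_selection_result <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$best_subset <- as.integer(obj$best_subset)
  structure(obj, class = "selection_result")
}
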