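# Result-generating experiment procedures: accuracy-versus-subset-size
# curves, moving-average filtering, baseline comparison, and
# feature-presence profiling.

#' Accuracy as a function of subset cardinality
#'
#' Runs the chosen selection algorithm once per cardinality in `k_range`,
#' each cell with a seed deterministically derived from
#' `(master_seed, algorithm, k)`, and records the best achieved accuracy.
#' With `repetitions > 1` each cell is restarted that many times from
#' independent derived seeds; the curve reports the best (default) or the
#' mean across restarts.
#'
#' @param table A feature table.
#' @param algorithm Selection algorithm (see [select_features()]).
#' @param k_range Integer cardinalities, e.g. `1:100`.
#' @param iterations Search iterations per run (default 200).
#' @param master_seed Master seed from which every cell's seed derives.
#' @param repetitions Independent restarts per cell (default 1).
#' @param summary `"best"` (default) or `"mean"` across restarts.
#' @param fitness Optional shared [fitness_config()]; by default each run
#'   derives its own from its cell seed.
#' @param config_args Extra per-algorithm constants passed to
#'   [ea_config()].
#'
#' @return An `accuracy_curve`: tibble with `k`, `accuracy`, `algorithm`,
#'   and the per-cell `selection_result`s in attribute `"results"`.
#' @export
accuracy_vs_k <- function(table, algorithm, k_range, iterations = 200,
                          master_seed = 1L, repetitions = 1,
                          summary = c("best", "mean"), fitness = NULL,
                          config_args = list()) {
  summary <- match.arg(summary)
  k_range <- as.integer(k_range)
  stopifnot(all(k_range >= 1), !is.unsorted(k_range, strictly = TRUE))
  results <- list()
  acc <- numeric(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    reps <- lapply(seq_len(repetitions), function(r) {
      seed_kr <- derive_seed(master_seed, algorithm, k * 1000L + r)
      cfg <- do.call(ea_config, c(list(algorithm = algorithm,
                                       iterations = iterations,
                                       seed = seed_kr), config_args))
      if (algorithm == "stat") {
        ttest_select(table, k,
                     fitness = fitness %||%
                       fitness_config(seed = derive_seed(seed_kr, "fitness")))
      } else if (algorithm == "nsga2") {
        nsga2_select(table, k, cfg, fitness)$best
      } else {
        select_features(table, algorithm, k, config = cfg, fitness = fitness)
      }
    })
    fits <- vapply(reps, function(r) r$best_fitness, numeric(1))
    best_i <- which.max(fits)
    acc[i] <- if (summary == "best") max(fits) else mean(fits)
    results[[i]] <- reps[[best_i]]
  }
  out <- tibble::tibble(k = k_range, accuracy = acc, algorithm = algorithm)
  attr(out, "results") <- results
  attr(out, "master_seed") <- master_seed
  attr(out, "repetitions") <- repetitions
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Moving average of an accuracy curve
#'
#' Point `i` becomes the mean of the points within `i - halfwidth` to
#' `i + halfwidth`, with the window shrinking at the curve's edges (no
#' padding).  The conventional smoothing for accuracy-versus-k curves
#' uses `halfwidth = 20` (a +/-20-point window).
#'
#' @param curve An `accuracy_curve`, or any tibble with `k` and
#'   `accuracy` columns.
#' @param halfwidth Window half-width in points (>= 0).
#' @return The curve with `accuracy` replaced by its moving average.
#' @export
moving_average <- function(curve, halfwidth = 20) {
  stopifnot(is.data.frame(curve), all(c("k", "accuracy") %in% names(curve)),
            halfwidth >= 0)
  x <- curve$accuracy
  n <- length(x)
  sm <- vapply(seq_len(n), function(i) {
    w <- max(1, i - halfwidth):min(n, i + halfwidth)
    mean(x[w])
  }, numeric(1))
  out <- curve
  out$accuracy <- sm
  out
}

#' Per-k superiority of an evolutionary curve over the statistical baseline
#'
#' @param ea_curve,stat_curve Accuracy curves on identical `k` grids.
#' @return A tibble with `k`, `ea`, `stat`, `difference`, and the mean
#'   difference as attribute `"mean_difference"`.
#' @export
baseline_superiority <- function(ea_curve, stat_curve) {
  if (!identical(as.integer(ea_curve$k), as.integer(stat_curve$k))) {
    abort("The two curves must share an identical k grid.")
  }
  out <- tibble::tibble(
    k = as.integer(ea_curve$k),
    ea = ea_curve$accuracy,
    stat = stat_curve$accuracy,
    difference = ea_curve$accuracy - stat_curve$accuracy)
  attr(out, "mean_difference") <- mean(out$difference)
  out
}

#' Feature-presence profile over a family of selection runs
#'
#' Counts, for every feature, in how many of the supplied selection
#' results it appears, and tracks the cumulative number of distinct
#' features used up to each result (results taken in the given order,
#' typically k = 1, 2, ...).
#'
#' @param results A list of `selection_result`s (e.g. attribute
#'   `"results"` of an [accuracy_vs_k()] curve).
#' @param n_features Total number of features; inferred from the results
#'   when omitted.
#' @return A `presence_profile`: list with `counts` (tibble `feature
#'   index` x `count`) and `cumulative` (tibble per result).
#' @export
feature_presence <- function(results, n_features = NULL) {
  stopifnot(length(results) > 0)
  subsets <- lapply(results, function(r) r$best_subset)
  if (is.null(n_features)) n_features <- max(unlist(subsets))
  counts <- integer(n_features)
  seen <- logical(n_features)
  cum <- integer(length(subsets))
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    counts[s] <- counts[s] + 1L
    seen[s] <- TRUE
    cum[i] <- sum(seen)
  }
  nm <- results[[1]]$best_feature_names
  structure(
    list(counts = tibble::tibble(index = seq_len(n_features),
                                 count = counts),
         cumulative = tibble::tibble(run = seq_along(subsets),
                                     k = lengths(subsets),
                                     unique_features = cum),
         n_runs = length(subsets)),
    class = "presence_profile")
}

#' @export
print.presence_profile <- function(x, ...) {
  cat(sprintf("<presence_profile> %d runs, %d/%d features ever selected\n",
              x$n_runs, sum(x$counts$count > 0), nrow(x$counts)))
  invisible(x)
}

#' Most frequently selected features
#'
#' Ranks features by how often they were selected across the runs of a
#' presence profile (ties broken by feature index) and reports the top
#' `top_n` with their node and measure parsed from the
#' `"<node>::<measure>"` feature name.
#'
#' @param profile A `presence_profile` from [feature_presence()].
#' @param feature_names Character vector naming all features in index
#'   order.
#' @param top_n How many features to report (default 5).
#' @return Tibble with `rank`, `index`, `feature`, `node`, `measure`,
#'   `count`, `presence_pct`.
#' @export
top_feature_report <- function(profile, feature_names, top_n = 5) {
  stopifnot(inherits(profile, "presence_profile"),
            top_n <= nrow(profile$counts))
  counts <- profile$counts$count
  ord <- order(-counts, profile$counts$index)[seq_len(top_n)]
  nm <- feature_names[ord]
  parts <- strsplit(nm, "::", fixed = TRUE)
  tibble::tibble(
    rank = seq_len(top_n),
    index = ord,
    feature = nm,
    node = vapply(parts, function(p) p[1], character(1)),
    measure = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                     character(1)),
    count = counts[ord],
    presence_pct = 100 * counts[ord] / profile$n_runs)
}
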