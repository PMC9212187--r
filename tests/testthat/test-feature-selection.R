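# Welch baseline, wrapper fitness, and the five evolutionary searches.

test_that("Welch t p-values match stats::t.test to 1e-10", {
  set.seed(17)
  tab <- toy_cohort(n_per = 12, n_features = 6, n_informative = 2,
                    effect = 1.5, seed = 3)
  tt <- welch_t_table(tab)
  X <- feature_matrix(tab)
  for (j in seq_len(ncol(X))) {
    ref <- stats::t.test(X[tab$group == 0, j], X[tab$group == 1, j])
    expect_lt(abs(tt$p_value[j] - ref$p.value), 1e-10)
    expect_lt(abs(tt$statistic[j] - unname(ref$statistic)), 1e-10)
  }
})

test_that("degenerate features rank last and ties break by index", {
  tab <- toy_cohort(n_per = 10, n_features = 5, n_informative = 1,
                    effect = 4, seed = 9)
  info <- ground_truth(tab)$informative
  noise_col <- feature_names(tab)[setdiff(1:5, info)[1]]
  flat <- tab
  flat[[noise_col]] <- 1 # identical in both groups
  tt <- welch_t_table(flat)
  expect_equal(tt$p_value[tt$feature == noise_col], 1)
  sel <- ttest_select(flat, k = 4)
  expect_false(match(noise_col, feature_names(flat)) %in% sel$best_subset)
  # planted informative feature ranks first
  sel1 <- ttest_select(flat, k = 1)
  expect_equal(sel1$best_subset, ground_truth(tab)$informative)
})

test_that("ttest_select is stable under feature column permutation", {
  tab <- toy_cohort(n_per = 15, n_features = 8, n_informative = 2,
                    effect = 2, seed = 5)
  fn <- feature_names(tab)
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  tab2 <- dplyr::select(tab, "subject_id", "group", dplyr::all_of(fn[perm]))
  class(tab2) <- class(tab)
  s1 <- ttest_select(tab, k = 3)
  s2 <- ttest_select(tab2, k = 3)
  expect_setequal(s1$best_feature_names, s2$best_feature_names)
})

test_that("a planted strong feature is found by the t-test at high power", {
  hits <- vapply(1:20, function(s) {
    tab <- generate_feature_cohort(n_group0 = 70, n_group1 = 70,
                                   n_features = 51, n_informative = 1,
                                   effect = 2, seed = 100 + s)
    sel <- ttest_select(tab, k = 1)
    identical(sel$best_subset, ground_truth(tab)$informative)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("fitness evaluation is cached, deterministic and subset-bound", {
  tab <- toy_cohort(n_per = 10, n_features = 5, n_informative = 1,
                    effect = 3, seed = 2)
  fit <- fast_fitness(seed = 7)
  cache <- connselect:::new_fitness_cache()
  a1 <- evaluate_fitness(tab, c(2, 4), fit, cache)
  a2 <- evaluate_fitness(tab, c(4, 2), fit, cache) # order-insensitive key
  expect_identical(a1, a2)
  expect_equal(cache$hits, 1L)
  expect_equal(cache$misses, 1L)
  expect_error(evaluate_fitness(tab, integer(0), fit), "non-empty")
  expect_error(evaluate_fitness(tab, 99, fit), "inside")
})

test_that("a perfectly separating feature reaches 100% fitness", {
  tab <- toy_cohort(n_per = 15, n_features = 6, n_informative = 1,
                    effect = 8, seed = 11)
  acc <- evaluate_fitness(tab, ground_truth(tab)$informative,
                          fitness_config(mode = "cv", n_folds = 5, seed = 1))
  expect_equal(acc, 100)
})

test_that("pure-noise fitness stays near chance", {
  accs <- vapply(1:20, function(s) {
    tab <- generate_feature_cohort(n_group0 = 20, n_group1 = 20,
                                   n_features = 6, n_informative = 0,
                                   effect = 0, seed = 300 + s)
    evaluate_fitness(tab, 1:3,
                     fitness_config(mode = "cv", n_folds = 5, seed = s,
                                    cfg = train_config(max_epochs = 20)))
  }, numeric(1))
  # 20 seeds x 40 held-out predictions; binomial 95% interval around 50%
  n_tot <- 20 * 40
  ci <- stats::qbinom(c(0.025, 0.975), n_tot, 0.5) / n_tot * 100
  expect_gte(mean(accs), ci[1])
  expect_lte(mean(accs), ci[2])
})

# shared toy for the EA-vs-exhaustive checks: 8 features, 1 strongly
# informative, k = 1 -> 8 candidate subsets
singleton_oracle <- function(tab, fit) {
  accs <- vapply(1:8, function(j) evaluate_fitness(tab, j, fit), numeric(1))
  which.max(accs)
}

test_that("GA matches the exhaustive singleton oracle across seeds", {
  wins <- 0L
  for (s in 1:10) {
    tab <- toy_cohort(n_per = 15, n_features = 8, n_informative = 1,
                      effect = 3, seed = 40 + s)
    cfg <- ea_config("ga", iterations = 30, seed = s)
    fit <- fast_fitness(seed = connselect:::derive_seed(s, "fit"))
    r <- ga_select(tab, k = 1, cfg, fit)
    best <- singleton_oracle(tab, fit)
    wins <- wins + (r$best_fitness >= evaluate_fitness(tab, best, fit))
  }
  expect_gte(wins, 9)
})

test_that("PSO matches the exhaustive singleton oracle across seeds", {
  wins <- 0L
  for (s in 1:10) {
    tab <- toy_cohort(n_per = 15, n_features = 8, n_informative = 1,
                      effect = 3, seed = 40 + s)
    cfg <- ea_config("pso", iterations = 30, seed = s)
    fit <- fast_fitness(seed = connselect:::derive_seed(s, "fit"))
    r <- pso_select(tab, k = 1, cfg, fit)
    best <- singleton_oracle(tab, fit)
    wins <- wins + (r$best_fitness >= evaluate_fitness(tab, best, fit))
  }
  expect_gte(wins, 9)
})

test_that("ACO concentrates pheromone on the informative feature", {
  wins <- 0L
  for (s in 1:10) {
    tab <- toy_cohort(n_per = 15, n_features = 8, n_informative = 1,
                      effect = 3, seed = 40 + s)
    cfg <- ea_config("aco", iterations = 30, seed = s)
    fit <- fast_fitness(seed = connselect:::derive_seed(s, "fit"))
    r <- aco_select(tab, k = 1, cfg, fit)
    info <- ground_truth(tab)$informative
    wins <- wins + (r$pheromone[info] > mean(r$pheromone))
  }
  expect_gte(wins, 9)
})

test_that("SA with zero temperature never accepts a worsening move", {
  tab <- toy_cohort(n_per = 12, n_features = 6, n_informative = 1,
                    effect = 3, seed = 13)
  cfg <- ea_config("sa", iterations = 40, seed = 3, T0 = 1e-12,
                   cooling = 0.5)
  r <- sa_select(tab, k = 2, cfg, fast_fitness(1))
  expect_true(all(diff(r$history) >= 0))
})

test_that("SA finds the exhaustive optimum over pairs in most seeds", {
  wins <- 0L
  for (s in 1:10) {
    tab <- toy_cohort(n_per = 12, n_features = 10, n_informative = 2,
                      effect = 3, seed = 60 + s)
    fit <- fast_fitness(seed = connselect:::derive_seed(s, "fit"))
    pairs <- utils::combn(10, 2)
    exh <- max(vapply(seq_len(ncol(pairs)), function(p) {
      evaluate_fitness(tab, pairs[, p], fit)
    }, numeric(1)))
    cfg <- ea_config("sa", iterations = 200, seed = s)
    r <- sa_select(tab, k = 2, cfg, fit)
    wins <- wins + (r$best_fitness >= exh)
  }
  expect_gte(wins, 8)
})

test_that("NSGA-II archives a nondominated front over cardinalities", {
  tab <- toy_cohort(n_per = 15, n_features = 6, n_informative = 2,
                    effect = 3, seed = 21)
  cfg <- ea_config("nsga2", iterations = 20, seed = 5)
  res <- nsga2_select(tab, k_max = 3, cfg, fast_fitness(2))
  arc <- res$archive
  expect_true(all(arc$k <= 3 & arc$k >= 1))
  expect_false(is.unsorted(arc$k, strictly = TRUE))
  # within the archive no member dominates another: accuracy must rise
  # with cardinality
  if (nrow(arc) > 1) expect_true(all(diff(arc$accuracy) > 0))
  expect_true(all(lengths(arc$subset) == arc$k))
  # per-k results mirror the archive
  expect_equal(as.integer(names(res$per_k)), arc$k)
})

test_that("every engine returns exactly k distinct in-range indices", {
  tab <- toy_cohort(n_per = 12, n_features = 7, n_informative = 2,
                    effect = 2.5, seed = 33)
  fit <- fast_fitness(3)
  for (alg in c("ga", "aco", "sa", "pso")) {
    cfg <- ea_config(alg, iterations = 8, seed = 2)
    r <- select_features(tab, alg, k = 3, config = cfg, fitness = fit)
    expect_length(r$best_subset, 3)
    expect_false(is.unsorted(r$best_subset, strictly = TRUE))
    expect_true(all(r$best_subset >= 1 & r$best_subset <= 7))
    expect_true(all(diff(r$history) >= 0)) # best-so-far non-decreasing
  }
})

test_that("searches are bit-reproducible given (seed, config, table)", {
  tab <- toy_cohort(n_per = 12, n_features = 6, n_informative = 1,
                    effect = 3, seed = 8)
  fit <- fast_fitness(9)
  for (alg in c("ga", "aco", "sa", "pso")) {
    cfg <- ea_config(alg, iterations = 6, seed = 17)
    r1 <- select_features(tab, alg, k = 2, config = cfg, fitness = fit)
    r2 <- select_features(tab, alg, k = 2, config = cfg, fitness = fit)
    expect_identical(r1$best_subset, r2$best_subset)
    expect_identical(r1$history, r2$history)
  }
})

test_that("k = F short-circuits to the full feature set", {
  tab <- toy_cohort(n_per = 12, n_features = 4, n_informative = 1,
                    effect = 3, seed = 19)
  r <- ga_select(tab, k = 4, ea_config("ga", iterations = 5, seed = 1),
                 fast_fitness(1))
  expect_equal(r$best_subset, 1:4)
  expect_error(ga_select(tab, k = 5), "must be in")
})

test_that("selection results round-trip through JSON byte-identically", {
  tab <- toy_cohort(n_per = 12, n_features = 6, n_informative = 1,
                    effect = 3, seed = 23)
  cfg <- ea_config("ga", iterations = 5, seed = 31)
  r1 <- ga_select(tab, k = 2, cfg, fast_fitness(4))
  r2 <- ga_select(tab, k = 2, cfg, fast_fitness(4))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  write_selection_result(r1, p1)
  write_selection_result(r2, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_selection_result(p1)
  expect_equal(back$best_subset, r1$best_subset)
  expect_equal(back$best_fitness, r1$best_fitness)
})
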