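# The five evolutionary subset searches and the t-test baseline.  All
# searches operate on fixed-cardinality subsets (NSGA-II excepted, which
# lets cardinality float up to k_max), use the wrapper fitness from
# evaluate_fitness(), share a per-run cache, and are bit-reproducible
# given (seed, config, table).

default_fitness <- function(config) {
  fitness_config(seed = derive_seed(config$seed, "fitness"))
}

check_k <- function(k, n_feat) {
  k <- as.integer(k)
  if (k < 1 || k > n_feat) {
    abort(sprintf("`k` must be in [1, %d], got %d.", n_feat, k))
  }
  k
}

random_subset <- function(n_feat, k) sort(sample.int(n_feat, k))

mask_of <- function(subset, n_feat) {
  m <- logical(n_feat); m[subset] <- TRUE; m
}

# force a mask to exactly k selected bits: drop random extras / add
# random missing
repair_mask <- function(mask, k) {
  sel <- which(mask)
  if (length(sel) > k) {
    drop <- sel[sample.int(length(sel), length(sel) - k)]
    mask[drop] <- FALSE
  } else if (length(sel) < k) {
    unsel <- which(!mask)
    add <- unsel[sample.int(length(unsel), k - length(sel))]
    mask[add] <- TRUE
  }
  mask
}

crossover_masks <- function(m1, m2) {
  n <- length(m1)
  op <- sample.int(3, 1)
  if (op == 1L && n >= 2) {            # single point
    c <- sample.int(n - 1, 1)
    list(c(m1[1:c], m2[(c + 1):n]), c(m2[1:c], m1[(c + 1):n]))
  } else if (op == 2L && n >= 3) {     # double point
    cs <- sort(sample.int(n - 1, 2))
    mid <- (cs[1] + 1):cs[2]
    c1 <- m1; c1[mid] <- m2[mid]
    c2 <- m2; c2[mid] <- m1[mid]
    list(c1, c2)
  } else {                             # uniform
    pick <- runif(n) < 0.5
    c1 <- ifelse(pick, m1, m2)
    c2 <- ifelse(pick, m2, m1)
    list(c1, c2)
  }
}

# swap mutation preserving cardinality: each selected bit is, with
# probability `rate`, exchanged with a uniformly chosen unselected bit
mutate_swap <- function(mask, rate) {
  sel <- which(mask)
  for (b in sel) {
    if (runif(1) < rate) {
      unsel <- which(!mask)
      if (length(unsel) == 0) break
      swap <- unsel[sample.int(length(unsel), 1)]
      mask[b] <- FALSE
      mask[swap] <- TRUE
    }
  }
  mask
}

#' Genetic-algorithm subset search
#'
#' Maintains a population of k-subsets encoded as binary masks.  Parents
#' are drawn by Boltzmann roulette (selection probability proportional to
#' `exp(beta * normalised fitness)` with pressure `beta`); each pair is
#' recombined by an operator chosen uniformly among single-point,
#' double-point and uniform crossover, repaired back to cardinality k,
#' and a fraction `mutation_percentage` of the offspring undergo swap
#' mutation in which every selected bit is exchanged with a random
#' unselected bit with probability `mutation_rate`.  Parents and
#' offspring compete for the `pop` survivor slots, so the best individual
#' is always retained (elitism) and the best-so-far history is
#' non-decreasing.
#'
#' @param table A feature table.
#' @param k Subset cardinality.
#' @param config An [ea_config()] for `"ga"`.
#' @param fitness A [fitness_config()]; defaults to a single-split
#'   fitness seeded from `config$seed`.
#'
#' @return A `selection_result`.
#' @export
ga_select <- function(table, k, config = ea_config("ga"), fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k <- check_k(k, n_feat)
  if (is.null(fitness)) fitness <- default_fitness(config)
  cache <- new_fitness_cache()
  fit_of <- function(subset) evaluate_fitness(table, subset, fitness, cache)

  with_seed(config$seed, {
    if (k == n_feat) {
      s <- seq_len(n_feat)
      return(new_selection_result("ga", table, s, fit_of(s), fit_of(s),
                                  cache$misses, config))
    }
    pop <- lapply(seq_len(config$pop), function(i) random_subset(n_feat, k))
    fits <- vapply(pop, fit_of, numeric(1))
    history <- max(fits)
    for (gen in seq_len(config$iterations)) {
      # Boltzmann roulette: P_i proportional to exp(beta * f_i / max f);
      # scaling by the best fitness keeps the pressure moderate and
      # scale-free instead of collapsing onto the current best
      fmax <- max(fits)
      probs <- exp(config$selection_pressure *
                     (if (fmax > 0) fits / fmax else rep(1, length(fits))))
      probs <- probs / sum(probs)
      n_pairs <- ceiling(config$crossover_count / 2)
      offspring <- list()
      for (p in seq_len(n_pairs)) {
        par <- sample.int(length(pop), 2, replace = TRUE, prob = probs)
        kids <- crossover_masks(mask_of(pop[[par[1]]], n_feat),
                                mask_of(pop[[par[2]]], n_feat))
        offspring <- c(offspring, lapply(kids, repair_mask, k = k))
      }
      offspring <- offspring[seq_len(min(config$crossover_count,
                                         length(offspring)))]
      n_mut <- round(config$mutation_percentage * length(offspring))
      if (n_mut > 0) {
        which_mut <- sample.int(length(offspring), n_mut)
        for (i in which_mut) {
          offspring[[i]] <- mutate_swap(offspring[[i]], config$mutation_rate)
        }
      }
      off_sets <- lapply(offspring, function(m) which(m))
      off_fits <- vapply(off_sets, fit_of, numeric(1))
      pool <- c(pop, off_sets)
      pool_fits <- c(fits, off_fits)
      keep <- order(-pool_fits)[seq_len(config$pop)]
      pop <- pool[keep]
      fits <- pool_fits[keep]
      history <- c(history, max(fits))
    }
    best <- which.max(fits)
    new_selection_result("ga", table, pop[[best]], fits[best], history,
                         cache$misses, config)
  })
}

#' Simulated-annealing subset search
#'
#' Random-restart-free annealing on k-subsets: the neighbour of the
#' current state exchanges one uniformly chosen selected feature with one
#' unselected feature.  Improving moves are always accepted; a worsening
#' move of size `delta` (accuracy points) is accepted with probability
#' `exp(-delta / T)`, and the temperature decays geometrically from `T0`
#' by the factor `cooling` each iteration.  The best state ever visited
#' is returned.
#'
#' @inheritParams ga_select
#' @param config An [ea_config()] for `"sa"`.
#' @return A `selection_result`.
#' @export
sa_select <- function(table, k, config = ea_config("sa"), fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k <- check_k(k, n_feat)
  if (is.null(fitness)) fitness <- default_fitness(config)
  cache <- new_fitness_cache()
  fit_of <- function(subset) evaluate_fitness(table, subset, fitness, cache)

  with_seed(config$seed, {
    cur <- random_subset(n_feat, k)
    cur_fit <- fit_of(cur)
    best <- cur; best_fit <- cur_fit
    temp <- config$T0
    history <- best_fit
    for (it in seq_len(config$iterations)) {
      if (k < n_feat) {
        out_f <- cur[sample.int(k, 1)]
        in_f <- setdiff(seq_len(n_feat), cur)
        in_f <- in_f[sample.int(length(in_f), 1)]
        cand <- sort(c(setdiff(cur, out_f), in_f))
        cand_fit <- fit_of(cand)
        delta <- cur_fit - cand_fit
        if (delta <= 0 || (temp > 0 && runif(1) < exp(-delta / temp))) {
          cur <- cand; cur_fit <- cand_fit
        }
        if (cur_fit > best_fit) { best <- cur; best_fit <- cur_fit }
      }
      temp <- temp * config$cooling
      history <- c(history, best_fit)
    }
    new_selection_result("sa", table, best, best_fit, history,
                         cache$misses, config)
  })
}

#' Ant-colony-optimization subset search
#'
#' Each of `n_ants` ants assembles a k-subset by sampling features
#' without replacement with probability proportional to
#' `tau^alpha * eta^beta`, where `tau` is the pheromone level
#' (initialised to `initial_weight`), `alpha = exponential_weight`,
#' `beta = heuristic_weight`, and the heuristic information `eta` is the
#' per-feature absolute Welch t statistic between the groups.  After each
#' iteration the pheromone evaporates by the factor `1 - evaporation` and
#' the iteration-best ant deposits pheromone proportional to its fitness
#' on its features.  The best-so-far subset is tracked and returned.
#'
#' @inheritParams ga_select
#' @param config An [ea_config()] for `"aco"`.
#' @return A `selection_result` with the final pheromone vector in
#'   `$pheromone`.
#' @export
aco_select <- function(table, k, config = ea_config("aco"), fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k <- check_k(k, n_feat)
  if (is.null(fitness)) fitness <- default_fitness(config)
  cache <- new_fitness_cache()
  fit_of <- function(subset) evaluate_fitness(table, subset, fitness, cache)

  eta <- abs(welch_t_table(table)$statistic)
  eta[eta == 0 | !is.finite(eta)] <- 1e-6

  with_seed(config$seed, {
    tau <- rep(config$initial_weight, n_feat)
    best <- NULL; best_fit <- -Inf
    history <- numeric(0)
    for (it in seq_len(config$iterations)) {
      weights <- tau^config$exponential_weight * eta^config$heuristic_weight
      ants <- lapply(seq_len(config$n_ants), function(a) {
        sort(sample.int(n_feat, k, prob = weights))
      })
      fits <- vapply(ants, fit_of, numeric(1))
      it_best <- which.max(fits)
      if (fits[it_best] > best_fit) {
        best <- ants[[it_best]]; best_fit <- fits[it_best]
      }
      tau <- (1 - config$evaporation) * tau
      tau[ants[[it_best]]] <- tau[ants[[it_best]]] + fits[it_best] / 100
      history <- c(history, best_fit)
    }
    new_selection_result("aco", table, best, best_fit, history,
                         cache$misses, config,
                         extra = list(pheromone = tau))
  })
}

#' Particle-swarm-optimization subset search
#'
#' Particles carry a continuous position over all features; the candidate
#' subset of a particle is the k features with the largest position
#' values (ties broken by feature index), a deterministic rank decoding
#' that keeps the cardinality fixed without stochastic binarisation.
#' Velocities follow the standard update
#' `v <- inertia * v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with
#' per-dimension uniform `r1, r2`; personal and global bests are tracked
#' on the decoded fitness, so the global-best history is non-decreasing.
#'
#' @inheritParams ga_select
#' @param config An [ea_config()] for `"pso"`.
#' @return A `selection_result`.
#' @export
pso_select <- function(table, k, config = ea_config("pso"), fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k <- check_k(k, n_feat)
  if (is.null(fitness)) fitness <- default_fitness(config)
  cache <- new_fitness_cache()
  fit_of <- function(subset) evaluate_fitness(table, subset, fitness, cache)

  decode <- function(x) sort(order(-x, seq_along(x))[seq_len(k)])

  with_seed(config$seed, {
    n <- config$swarm
    X <- matrix(runif(n * n_feat), n, n_feat)
    V <- matrix(0, n, n_feat)
    pbest <- X
    pbest_fit <- vapply(seq_len(n), function(i) fit_of(decode(X[i, ])),
                        numeric(1))
    g <- which.max(pbest_fit)
    gbest <- pbest[g, ]; gbest_fit <- pbest_fit[g]
    history <- gbest_fit
    for (it in seq_len(config$iterations)) {
      for (i in seq_len(n)) {
        r1 <- runif(n_feat); r2 <- runif(n_feat)
        V[i, ] <- config$inertia * V[i, ] +
          config$c1 * r1 * (pbest[i, ] - X[i, ]) +
          config$c2 * r2 * (gbest - X[i, ])
        X[i, ] <- X[i, ] + V[i, ]
        f <- fit_of(decode(X[i, ]))
        if (f > pbest_fit[i]) { pbest[i, ] <- X[i, ]; pbest_fit[i] <- f }
        if (f > gbest_fit) { gbest <- X[i, ]; gbest_fit <- f }
      }
      history <- c(history, gbest_fit)
    }
    new_selection_result("pso", table, decode(gbest), gbest_fit, history,
                         cache$misses, config)
  })
}

#' Welch t-test baseline selection
#'
#' The statistical (filter) baseline: every feature is compared between
#' the two groups with a Welch two-sample t-test and the k features with
#' the smallest p-values are selected (ties broken by feature index).
#' Deterministic; the classifier is not consulted.
#'
#' @inheritParams ga_select
#' @param fitness Optional [fitness_config()]; when supplied, the chosen
#'   subset is evaluated with it so the baseline is comparable to the
#'   evolutionary searches, otherwise `best_fitness` is `NA`.
#'
#' @return A `selection_result` with the per-feature test table in
#'   `$t_table`.
#' @export
ttest_select <- function(table, k, fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k <- check_k(k, n_feat)
  tt <- welch_t_table(table)
  ord <- order(tt$p_value, tt$index)
  subset <- sort(ord[seq_len(k)])
  fit <- if (!is.null(fitness)) {
    evaluate_fitness(table, subset, fitness)
  } else NA_real_
  config <- ea_config("stat", iterations = 0, seed = 0L)
  new_selection_result("stat", table, subset, fit, numeric(0),
                       if (is.na(fit)) 0L else 1L, config,
                       extra = list(t_table = tt))
}
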