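# NSGA-II: multi-objective subset search maximising cross-validated
# accuracy while minimising subset cardinality.

# fast nondominated sort on (maximise acc, minimise k); returns integer
# rank per individual (1 = first front)
nds_rank <- function(acc, k) {
  n <- length(acc)
  dominates <- function(i, j) {
    (acc[i] >= acc[j] && k[i] <= k[j]) && (acc[i] > acc[j] || k[i] < k[j])
  }
  rank <- integer(n)
  dominated_by <- vector("list", n)
  n_dom <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (dominates(i, j)) dominated_by[[i]] <- c(dominated_by[[i]], j)
      else if (dominates(j, i)) n_dom[i] <- n_dom[i] + 1L
    }
  }
  front <- which(n_dom == 0L)
  r <- 1L
  while (length(front) > 0) {
    rank[front] <- r
    nxt <- integer(0)
    for (i in front) {
      for (j in dominated_by[[i]]) {
        n_dom[j] <- n_dom[j] - 1L
        if (n_dom[j] == 0L) nxt <- c(nxt, j)
      }
    }
    front <- unique(nxt)
    r <- r + 1L
  }
  rank
}

# crowding distance within one front over the two objectives
crowding <- function(acc, k) {
  n <- length(acc)
  if (n <= 2) return(rep(Inf, n))
  d <- rep(0, n)
  for (obj in list(acc, k)) {
    ord <- order(obj)
    rng <- obj[ord[n]] - obj[ord[1]]
    d[ord[c(1, n)]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1)) {
        d[ord[i]] <- d[ord[i]] + (obj[ord[i + 1]] - obj[ord[i - 1]]) / rng
      }
    }
  }
  d
}

clamp_mask <- function(mask, k_max) {
  s <- sum(mask)
  if (s == 0) mask[sample.int(length(mask), 1)] <- TRUE
  else if (s > k_max) mask <- repair_mask(mask, k_max)
  mask
}

#' NSGA-II multi-objective subset search
#'
#' Searches subsets of cardinality 1 to `k_max` under two objectives:
#' maximise the cross-validated classifier accuracy and minimise the
#' subset cardinality.  Uses the standard NSGA-II machinery - fast
#' nondominated sorting, crowding-distance truncation, binary-tournament
#' mating selection on (rank, crowding) - with the same mask crossover
#' operators as the GA and per-bit flip mutation applied to a
#' `mutation_percentage` fraction of offspring, each bit flipping with
#' probability `mutation_rate` (cardinality clamped back into
#' `[1, k_max]`).
#'
#' @inheritParams ga_select
#' @param k_max Maximum subset cardinality.
#' @param config An [ea_config()] for `"nsga2"`.
#'
#' @return An `nsga2_result`: the final nondominated `archive` (a tibble
#'   with `k`, `accuracy` and a `subset` list column) plus, in `$per_k`, a
#'   `selection_result` for the best archived subset of each cardinality.
#' @export
nsga2_select <- function(table, k_max, config = ea_config("nsga2"),
                         fitness = NULL) {
  validate_feature_table(table)
  n_feat <- length(feature_names(table))
  k_max <- check_k(k_max, n_feat)
  if (is.null(fitness)) fitness <- default_fitness(config)
  cache <- new_fitness_cache()
  fit_of <- function(subset) evaluate_fitness(table, subset, fitness, cache)

  with_seed(config$seed, {
    pop <- lapply(seq_len(config$pop), function(i) {
      random_subset(n_feat, sample.int(k_max, 1))
    })
    fits <- vapply(pop, fit_of, numeric(1))
    ks <- lengths(pop)
    history <- max(fits)

    tournament <- function(rank, crowd) {
      a <- sample.int(length(rank), 1); b <- sample.int(length(rank), 1)
      if (rank[a] < rank[b]) a
      else if (rank[b] < rank[a]) b
      else if (crowd[a] >= crowd[b]) a else b
    }

    for (gen in seq_len(config$iterations)) {
      rank <- nds_rank(fits, ks)
      crowd <- rep(0, length(pop))
      for (r in unique(rank)) {
        idx <- which(rank == r)
        crowd[idx] <- crowding(fits[idx], ks[idx])
      }
      offspring <- list()
      n_pairs <- ceiling(config$crossover_count / 2)
      for (p in seq_len(n_pairs)) {
        i <- tournament(rank, crowd); j <- tournament(rank, crowd)
        kids <- crossover_masks(mask_of(pop[[i]], n_feat),
                                mask_of(pop[[j]], n_feat))
        offspring <- c(offspring, lapply(kids, clamp_mask, k_max = k_max))
      }
      offspring <- offspring[seq_len(min(config$crossover_count,
                                         length(offspring)))]
      n_mut <- round(config$mutation_percentage * length(offspring))
      if (n_mut > 0) {
        for (i in sample.int(length(offspring), n_mut)) {
          m <- offspring[[i]]
          flip <- runif(n_feat) < config$mutation_rate
          m <- xor(m, flip)
          offspring[[i]] <- clamp_mask(m, k_max)
        }
      }
      off_sets <- lapply(offspring, which)
      off_fits <- vapply(off_sets, fit_of, numeric(1))
      pool <- c(pop, off_sets)
      pool_fits <- c(fits, off_fits)
      pool_ks <- lengths(pool)
      prank <- nds_rank(pool_fits, pool_ks)
      pcrowd <- rep(0, length(pool))
      for (r in unique(prank)) {
        idx <- which(prank == r)
        pcrowd[idx] <- crowding(pool_fits[idx], pool_ks[idx])
      }
      keep <- order(prank, -pcrowd)[seq_len(config$pop)]
      pop <- pool[keep]; fits <- pool_fits[keep]; ks <- pool_ks[keep]
      history <- c(history, max(fits))
    }

    rank <- nds_rank(fits, ks)
    front <- which(rank == 1L)
    archive <- tibble::tibble(
      k = ks[front], accuracy = fits[front],
      subset = pop[front]) |>
      dplyr::arrange(.data$k, dplyr::desc(.data$accuracy)) |>
      dplyr::distinct(.data$k, .keep_all = TRUE)

    per_k <- purrr::pmap(
      list(archive$k, archive$accuracy, archive$subset),
      function(kk, acc, sub) {
        new_selection_result("nsga2", table, sub, acc, history,
                             cache$misses, config)
      })
    names(per_k) <- as.character(archive$k)

    best <- which.max(fits)
    structure(
      list(archive = archive, per_k = per_k,
           best = new_selection_result("nsga2", table, pop[[best]],
                                       fits[best], history, cache$misses,
                                       config),
           history = history, evaluations = cache$misses,
           seed = config$seed, config = unclass(config)),
      class = "nsga2_result")
  })
}

#' @export
print.nsga2_result <- function(x, ...) {
  cat(sprintf("<nsga2_result> archive of %d nondominated subsets (k = %s), best %.2f%%\n",
              nrow(x$archive), paste(range(x$archive$k), collapse = ".."),
              x$best$best_fitness))
  invisible(x)
}

#' Tidy the NSGA-II archive
#' @param x An `nsga2_result`.
#' @param ... Unused.
#' @return Tibble with one row per archived cardinality (`k`, `accuracy`).
#' @export
tidy.nsga2_result <- function(x, ...) {
  dplyr::select(x$archive, "k", "accuracy")
}
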