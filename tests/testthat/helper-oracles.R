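# Independent brute-force oracles used across the graph-measure and
# classifier tests.  These never call the package's measure code.

# Floyd-Warshall all-pairs shortest paths on a binary adjacency matrix
fw_dist <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# number of distinct shortest paths between every ordered pair, by
# dynamic programming over increasing distance
count_shortest <- function(a, d) {
  n <- nrow(a)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  finite <- sort(unique(d[is.finite(d) & d > 0]))
  for (len in finite) {
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (d[s, t] == len) {
          pred <- which(a[, t] == 1 & d[s, ] == len - 1)
          sigma[s, t] <- sum(sigma[s, pred])
        }
      }
    }
  }
  sigma
}

# all seven node measures from first principles
oracle_measures <- function(a) {
  n <- nrow(a)
  d <- fw_dist(a)
  sigma <- count_shortest(a, d)
  deg <- rowSums(a)

  btw <- numeric(n)
  if (n >= 3) {
    for (v in seq_len(n)) {
      tot <- 0
      pairs <- utils::combn(setdiff(seq_len(n), v), 2)
      for (p in seq_len(ncol(pairs))) {
        s <- pairs[1, p]; t <- pairs[2, p]
        if (is.finite(d[s, t]) && sigma[s, t] > 0) {
          through <- if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
                         d[s, v] + d[v, t] == d[s, t]) {
            sigma[s, v] * sigma[v, t]
          } else 0
          tot <- tot + through / sigma[s, t]
        }
      }
      btw[v] <- tot / ((n - 1) * (n - 2) / 2)
    }
  }

  apl <- vapply(seq_len(n), function(v) {
    dv <- d[v, -v]
    dv <- dv[is.finite(dv)]
    if (length(dv) == 0) 0 else mean(dv)
  }, numeric(1))

  clu <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))

  geff <- vapply(seq_len(n), function(v) {
    inv <- 1 / d[v, -v]
    mean(ifelse(is.finite(inv), inv, 0))
  }, numeric(1))

  leff <- vapply(seq_len(n), function(v) {
    nb <- which(a[v, ] == 1)
    if (length(nb) < 2) return(0)
    dd <- fw_dist(a[nb, nb, drop = FALSE])
    inv <- 1 / dd[upper.tri(dd)]
    mean(ifelse(is.finite(inv), inv, 0))
  }, numeric(1))

  data.frame(degree_centrality = deg, betweenness_centrality = btw,
             average_path_length = apl, clustering_coefficient = clu,
             cost = deg / (n - 1), local_efficiency = leff,
             global_efficiency = geff)
}

rand_adj <- function(n, p) {
  a <- matrix(0L, n, n)
  a[upper.tri(a)] <- as.integer(runif(n * (n - 1) / 2) < p)
  a + t(a)
}

# adjacency from an edge list over labelled nodes
adj_from_edges <- function(labels, edges) {
  n <- length(labels)
  a <- matrix(0L, n, n, dimnames = list(labels, labels))
  for (e in edges) {
    i <- match(e[1], labels); j <- match(e[2], labels)
    a[i, j] <- 1L; a[j, i] <- 1L
  }
  a
}

graph_of <- function(labels, edges) {
  brain_graph(adj_from_edges(labels, edges), labels)
}

# small feature cohort used by several selection tests
toy_cohort <- function(n_per = 20, n_features = 8, n_informative = 1,
                       effect = 3, seed = 1) {
  generate_feature_cohort(n_group0 = n_per, n_group1 = n_per,
                          n_features = n_features,
                          n_informative = n_informative,
                          effect = effect, seed = seed)
}

fast_fitness <- function(seed = 1) {
  fitness_config(mode = "split", n_folds = 5, seed = seed,
                 cfg = train_config(max_epochs = 15))
}
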