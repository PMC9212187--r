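# The seven node-level measures and feature assembly.

k3 <- graph_of(c("a", "b", "c"), list(c("a", "b"), c("a", "c"), c("b", "c")))
p3 <- graph_of(c("a", "b", "c"), list(c("a", "b"), c("b", "c")))
paw <- graph_of(c("a", "b", "c", "d"),
                list(c("a", "b"), c("a", "c"), c("b", "c"), c("c", "d")))

test_that("single-node measures reproduce hand-worked values", {
  # triangle K3
  expect_equal(degree_centrality(k3, "a"), 2)
  expect_equal(betweenness_centrality(k3, "a"), 0)
  expect_equal(average_path_length(k3, "b"), 1)
  expect_equal(clustering_coefficient(k3, "c"), 1)
  expect_equal(cost(k3, "a"), 1)
  expect_equal(local_efficiency(k3, "a"), 1)
  expect_equal(global_efficiency(k3, "a"), 1)

  # path a-b-c
  expect_equal(betweenness_centrality(p3, "b"), 1) # only pair (a,c) passes b
  expect_equal(betweenness_centrality(p3, "a"), 0)
  expect_equal(average_path_length(p3, "a"), 1.5) # (1+2)/2
  expect_equal(clustering_coefficient(p3, "b"), 0)
  expect_equal(cost(p3, "a"), 0.5)
  expect_equal(local_efficiency(p3, "b"), 0)
  expect_equal(global_efficiency(p3, "a"), 0.75) # (1 + 1/2)/2

  # triangle plus pendant: node c has neighbours a, b, d
  expect_equal(degree_centrality(paw, "c"), 3)
  expect_equal(clustering_coefficient(paw, "c"), 1 / 3)

  # star s-{a,b,c} with one rim edge ab: local efficiency of s
  star <- graph_of(c("s", "a", "b", "c"),
                   list(c("s", "a"), c("s", "b"), c("s", "c"), c("a", "b")))
  expect_equal(local_efficiency(star, "s"), 1 / 3) # pairs ab:1, ac:0, bc:0

  expect_error(degree_centrality(k3, "zz"), "Unknown node")
})

test_that("isolated and edgeless nodes follow the finite conventions", {
  empty <- brain_graph(matrix(0L, 3, 3), c("a", "b", "c"))
  ms <- compute_measure_set(empty)
  expect_true(all(as.matrix(ms[, -1]) == 0))
  # one isolated node next to an edge
  g <- graph_of(c("a", "b", "c"), list(c("a", "b")))
  expect_equal(average_path_length(g, "c"), 0)
  expect_equal(global_efficiency(g, "c"), 0)
  expect_equal(average_path_length(g, "a"), 1) # unreachable c ignored
  expect_equal(global_efficiency(g, "a"), 0.5) # (1 + 0)/2
})

test_that("compute_measure_set equals the brute-force oracle exactly", {
  # exhaustive over all labelled graphs on 4 nodes, then random 5..8-node
  # graphs across densities
  combos <- expand.grid(rep(list(0:1), 6))
  for (row in seq_len(nrow(combos))) {
    bits <- as.integer(combos[row, ])
    a <- matrix(0L, 4, 4)
    a[upper.tri(a)] <- bits
    a <- a + t(a)
    g <- brain_graph(a, paste0("n", 1:4))
    got <- as.data.frame(compute_measure_set(g)[, -1])
    want <- oracle_measures(a)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(5:8, 1)
    a <- rand_adj(n, runif(1, 0.1, 0.9))
    g <- brain_graph(a, paste0("n", seq_len(n)))
    got <- as.data.frame(compute_measure_set(g)[, -1])
    want <- oracle_measures(a)
    expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("measures agree with their single-node counterparts", {
  set.seed(9)
  a <- rand_adj(7, 0.4)
  g <- brain_graph(a, paste0("n", 1:7))
  ms <- compute_measure_set(g)
  for (v in g$roi_labels) {
    row <- ms[ms$node == v, ]
    expect_equal(row$degree_centrality, degree_centrality(g, v))
    expect_equal(row$betweenness_centrality, betweenness_centrality(g, v))
    expect_equal(row$average_path_length, average_path_length(g, v))
    expect_equal(row$clustering_coefficient, clustering_coefficient(g, v))
    expect_equal(row$cost, cost(g, v))
    expect_equal(row$local_efficiency, local_efficiency(g, v))
    expect_equal(row$global_efficiency, global_efficiency(g, v))
  }
})

test_that("measures are equivariant under node relabelling", {
  set.seed(21)
  a <- rand_adj(6, 0.5)
  labs <- paste0("n", 1:6)
  g <- brain_graph(a, labs)
  perm <- sample(6)
  g2 <- brain_graph(a[perm, perm], labs[perm])
  m1 <- compute_measure_set(g)
  m2 <- compute_measure_set(g2)
  m2 <- m2[match(m1$node, m2$node), ]
  expect_equal(as.data.frame(m1), as.data.frame(m2), ignore_attr = TRUE)
})

test_that("adding an edge never decreases degree, cost or global efficiency", {
  set.seed(13)
  for (rep in 1:10) {
    a <- rand_adj(7, 0.3)
    holes <- which(upper.tri(a) & a == 0L, arr.ind = TRUE)
    if (nrow(holes) == 0) next
    e <- holes[sample.int(nrow(holes), 1), ]
    a2 <- a
    a2[e[1], e[2]] <- a2[e[2], e[1]] <- 1L
    m1 <- compute_measure_set(brain_graph(a, paste0("n", 1:7)))
    m2 <- compute_measure_set(brain_graph(a2, paste0("n", 1:7)))
    expect_true(all(m2$degree_centrality >= m1$degree_centrality))
    expect_true(all(m2$cost >= m1$cost))
    expect_true(all(m2$global_efficiency >= m1$global_efficiency - 1e-12))
  }
})

test_that("global efficiency is 1 exactly for nodes adjacent to all others", {
  set.seed(31)
  a <- rand_adj(6, 0.5)
  a[1, -1] <- 1L; a[-1, 1] <- 1L # node 1 adjacent to everyone
  g <- brain_graph(a, paste0("n", 1:6))
  ms <- compute_measure_set(g)
  expect_equal(ms$global_efficiency[1], 1)
  full_deg <- ms$degree_centrality == 5
  expect_equal(ms$global_efficiency == 1, full_deg)
  expect_true(all(ms$global_efficiency <= 1))
})

test_that("assemble_features produces the documented layout and count", {
  atlas <- atlas_config(sprintf("R%03d", 1:132), sprintf("N%02d", 1:32),
                        networks = rep(paste0("net", 1:8), each = 4))
  expect_equal(n_features(atlas), 1155L)

  # small concrete case: 2 ROIs + 2 network nodes + global
  small <- atlas_config(c("r1", "r2"), c("w1", "w2"))
  g <- graph_of(c("r1", "r2", "w1", "w2"),
                list(c("r1", "r2"), c("r1", "w1"), c("w1", "w2")))
  ms <- compute_measure_set(g)
  f <- assemble_features(ms, ms, small)
  expect_length(f, (2 + 2 + 1) * 7)
  expect_equal(names(f)[1], "r1::degree_centrality")
  expect_equal(unname(f["w1::degree_centrality"]),
               degree_centrality(g, "w1"))
  # global aggregate = mean over the network nodes
  expect_equal(unname(f["GLOBAL::cost"]),
               mean(c(cost(g, "w1"), cost(g, "w2"))))

  tiny <- atlas_config("r1", character(0))
  f14 <- assemble_features(ms, ms, tiny)
  expect_length(f14, 14) # (1 + 0 + 1) x 7; global falls back to all nodes

  bad <- atlas_config(c("r1", "nope"), character(0), include_global = FALSE)
  expect_error(assemble_features(ms, ms, bad), "nope")
})

test_that("the global aggregate is the arithmetic mean of network nodes", {
  vals <- c(0, 0.5, 1.0, 0.5)
  ms <- tibble::tibble(node = paste0("w", 1:4),
                       degree_centrality = 0,
                       betweenness_centrality = 0,
                       average_path_length = 0,
                       clustering_coefficient = vals,
                       cost = 0, local_efficiency = 0,
                       global_efficiency = 0)
  atlas <- atlas_config(character(0), paste0("w", 1:4))
  f <- assemble_features(ms, ms, atlas)
  expect_equal(unname(f["GLOBAL::clustering_coefficient"]), 0.5)
})

test_that("feature tables round-trip through TSV", {
  tab <- toy_cohort(n_per = 5, n_features = 6, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_equal(feature_names(back), feature_names(tab))
  expect_equal(feature_matrix(back), feature_matrix(tab), tolerance = 1e-12)
  expect_equal(back$group, tab$group)
})
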