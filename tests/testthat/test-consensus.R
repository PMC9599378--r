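part <- function(labels, name = "m", cells = paste0("c", seq_along(labels))) {
  Partition(labels, methodName = name, cells = cells)
}

test_that("ari matches hand-derived and degenerate cases", {
  p <- part(c(1, 1, 2, 2))
  q <- part(c(1, 2, 1, 2))
  # {a,b|c,d} vs {a,c|b,d}: value frozen from the pair-counting oracle
  expect_equal(ari(p, q), brute_ari(c(1, 1, 2, 2), c(1, 2, 1, 2)))
  expect_equal(ari(p, q), -0.5)

  expect_identical(ari(p, p), 1)
  expect_identical(ari(p, part(rep(1, 4))), 0)
  expect_identical(ari(part(rep(1, 4)), part(rep(1, 4))), 1)
  expect_error(ari(p, part(c(1, 2), cells = c("x", "y"))), "different cell")
})

test_that("ari agrees with pair-counting oracle and mclust on random partitions", {
  set.seed(101)
  for (rep_i in 1:40) {
    n <- sample(5:30, 1)
    x <- random_partition(n)
    y <- random_partition(n)
    p <- part(x); q <- part(y)
    a <- ari(p, q)
    expect_equal(a, brute_ari(x, y), tolerance = 1e-12)
    expect_equal(a, mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    # symmetry and label-permutation invariance
    expect_equal(a, ari(q, p), tolerance = 1e-12)
    relab <- sample(max(y))[y]
    expect_equal(ari(p, part(relab)), a, tolerance = 1e-12)
  }
})

test_that("selectDiverse removes the minimum-row-variance method", {
  set.seed(202)
  base <- random_partition(40)
  dissident <- random_partition(40)
  parts <- c(lapply(1:4, function(i) part(base, name = paste0("m", i))),
             list(part(dissident, name = "m5")))
  rv <- brute_row_variances(parts)
  kept <- suppressMessages(selectDiverse(parts))
  expect_identical(attr(kept, "removed"), which.min(rv))
  expect_length(kept, 4)

  # identical partitions: all variances zero, tie removes the first
  same <- lapply(1:3, function(i) part(base, name = paste0("s", i)))
  kept2 <- suppressMessages(selectDiverse(same))
  expect_identical(attr(kept2, "removed"), 1L)
  expect_identical(vapply(kept2, function(p) p@methodName, ""),
                   c("s2", "s3"))
  expect_error(selectDiverse(same[1:2]), "at least 3")
})

test_that("selectDiverse matches the brute-force oracle on random 5-sets", {
  set.seed(303)
  for (rep_i in 1:25) {
    n <- sample(10:40, 1)
    parts <- lapply(1:5, function(i)
      part(random_partition(n), name = paste0("m", i)))
    kept <- suppressMessages(selectDiverse(parts))
    expect_identical(attr(kept, "removed"),
                     which.min(brute_row_variances(parts)))
    expect_length(kept, 4)
  }
})

test_that("consensus graph is the unanimous AND of co-clustering relations", {
  # ab|cd three times, a|bcd once: only c-d survives
  p123 <- lapply(1:3, function(i)
    part(c(1, 1, 2, 2), name = paste0("m", i),
         cells = c("a", "b", "c", "d")))
  p4 <- part(c(1, 2, 2, 2), name = "m4", cells = c("a", "b", "c", "d"))
  g <- consensusAdjacency(c(p123, list(p4)))
  expect_identical(graph_edge_keys(g), "c|d")

  # identical partitions give disjoint cliques
  g2 <- consensusAdjacency(p123)
  expect_identical(graph_edge_keys(g2), c("a|b", "c|d"))
})

test_that("consensus edges equal the exhaustive pairwise AND on random sets", {
  set.seed(404)
  for (rep_i in 1:8) {
    n <- sample(30:120, 1)
    cells <- paste0("c", 1:n)
    parts <- lapply(1:4, function(i)
      part(random_partition(n, kmax = 4), name = paste0("m", i),
           cells = cells))
    g <- consensusAdjacency(parts)
    expect_identical(graph_edge_keys(g), brute_consensus_pairs(parts))
  }
})

test_that("representative clusters respect the strict size threshold", {
  cells <- c(paste0("big", 1:30), paste0("small", 1:4))
  p <- lapply(1:4, function(i)
    part(rep(c(1, 2), c(30, 4)), name = paste0("m", i), cells = cells))
  g <- consensusAdjacency(p)

  reps <- representativeClusters(g, threshold = 10, seed = 1)
  expect_length(repClusters(reps), 1)
  expect_setequal(repClusters(reps)[[1]], paste0("big", 1:30))
  expect_setequal(leftoverCells(reps), paste0("small", 1:4))

  reps3 <- representativeClusters(g, threshold = 3, seed = 1)
  expect_length(repClusters(reps3), 2)
  expect_length(leftoverCells(reps3), 0)

  expect_error(representativeClusters(g, threshold = 50, seed = 1),
               "threshold")
})

test_that("Louvain recovers disjoint cliques exactly, any seed", {
  cells <- paste0("c", 1:60)
  labs <- rep(1:3, each = 20)
  p <- lapply(1:4, function(i) part(labs, name = paste0("m", i),
                                    cells = cells))
  g <- consensusAdjacency(p)
  for (s in c(1, 99, 2024)) {
    reps <- representativeClusters(g, threshold = 10, seed = s)
    got <- lapply(repClusters(reps), sort)
    want <- lapply(split(cells, labs), sort)
    expect_length(got, 3)
    expect_setequal(unname(vapply(got, paste, "", collapse = ",")),
                    unname(vapply(want, paste, "", collapse = ",")))
  }
})

test_that("every representative cluster is connected in the consensus graph", {
  set.seed(505)
  cells <- paste0("c", 1:150)
  parts <- lapply(1:4, function(i)
    part(random_partition(150, kmax = 3), name = paste0("m", i),
         cells = cells))
  g <- consensusAdjacency(parts)
  reps <- tryCatch(representativeClusters(g, threshold = 5, seed = 1),
                   error = function(e) NULL)
  if (!is.null(reps)) {
    for (cl in repClusters(reps)) {
      sub <- igraph::induced_subgraph(g, cl)
      expect_true(igraph::is_connected(sub))
    }
  } else {
    succeed("no community above threshold in this random draw")
  }
})
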