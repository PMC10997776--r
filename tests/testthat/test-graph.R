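test_that("pairwise distances match direct evaluation and a brute-force loop", {
  expect_equal(pairwise_distances(rbind(0, 3)), rbind(c(0, 3), c(3, 0)))
  expect_equal(pairwise_distances(matrix(5)), matrix(0))

  set.seed(7)
  X <- matrix(rnorm(15), 5, 3)
  D <- pairwise_distances(X)
  ora <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) ora[i, j] <- sqrt(sum((X[i, ] - X[j, ])^2))
  expect_equal(D, ora)

  # custom metric contract
  Dm <- pairwise_distances(X, function(a, b) sum(abs(a - b)))
  expect_equal(Dm, pairwise_distances(X, "manhattan"))

  expect_error(pairwise_distances(rbind(c(0, NA))), "non-finite")
})

test_that("natural neighbors are the k closest, with index tie-breaking", {
  # line {0, 1, 3}: forced by distances
  g <- neighbor_graph(cbind(c(0, 1, 3)), k = 1)
  expect_equal(g$natural, list(2L, 1L, 2L))

  # full-sort oracle on random points
  set.seed(11)
  X <- matrix(rnorm(40), 20, 2)
  D <- pairwise_distances(X)
  g <- neighbor_graph(X, k = 4)
  for (i in 1:20) {
    expect_equal(g$natural[[i]], setdiff(order(D[i, ]), i)[1:4])
  }

  # k = n - 1: complete neighborhoods
  g <- neighbor_graph(X[1:6, ], k = 5)
  expect_true(all(lengths(g$natural) == 5))
  expect_equal(nrow(g$edges), choose(6, 2))

  expect_warning(neighbor_graph(X[1:4, ], k = 10), "clamped")
})

test_that("symmetrization yields enforced neighbors and a symmetric relation", {
  # line {0, 1, 3}, k = 1: c gains b, b gains c as enforced
  g <- neighbor_graph(cbind(c(0, 1, 3)), k = 1)
  expect_equal(g$enforced[[2]], 3L)   # b <- c enforced
  expect_equal(g$enforced[[3]], integer(0))  # b already natural for c
  ekey <- paste(g$edges$from, g$edges$to)
  expect_setequal(ekey, c("1 2", "2 3"))

  # symmetry invariant on random data
  set.seed(5)
  g <- neighbor_graph(matrix(rnorm(60), 30, 2), k = 3)
  for (i in 1:30) {
    for (j in g$neighbors[[i]]) expect_true(i %in% g$neighbors[[j]])
  }

  # a symmetric configuration has no enforced neighbors
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g <- neighbor_graph(sq, k = 2)
  expect_true(all(lengths(g$enforced) == 0))
})

test_that("connected components agree with a transitive-closure oracle", {
  # two far pairs: 2 components
  X <- cbind(c(0, 1, 100, 101))
  g <- neighbor_graph(X, k = 1, connect = FALSE)
  expect_equal(g$n_components0, 2L)

  set.seed(9)
  X <- matrix(rnorm(50), 25, 2)
  g <- neighbor_graph(X, k = 2, connect = FALSE)
  ora <- closure_components(25, g$edges)
  # same partition (labels may differ)
  expect_equal(length(unique(ora)), g$n_components0)
  expect_true(all(tapply(ora, g$components0, function(v) length(unique(v))) == 1))
})

test_that("connecting edges form the minimum-weight reconnection", {
  # single component: no connecting edges
  g <- neighbor_graph(matrix(rnorm(20), 10, 2), k = 9)
  expect_false(any(g$edges$provenance == "connecting"))

  # three collinear clusters at 0, 10, 25: bridges 0-10 and 10-25, never 0-25
  X <- cbind(c(0, 0.1, 10, 10.1, 25, 25.1))
  g <- neighbor_graph(X, k = 1)
  con <- g$edges[g$edges$provenance == "connecting", ]
  expect_equal(nrow(con), 2L)
  expect_equal(sort(con$weight), c(9.9, 14.9))
  expect_equal(igraph::components(g$graph)$no, 1L)

  # brute-force over all spanning subsets of candidate edges, 5 clusters
  set.seed(21)
  centers <- matrix(runif(10, 0, 50), 5, 2)
  X <- do.call(rbind, lapply(1:5, function(c)
    sweep(matrix(rnorm(8, sd = 0.1), 4, 2), 2, centers[c, ], "+")))
  g <- neighbor_graph(X, k = 2)
  m <- g$n_components0
  expect_gte(m, 2)
  D <- pairwise_distances(X)
  comp <- g$components0
  cand <- do.call(rbind, lapply(seq_len(m - 1), function(a) {
    do.call(rbind, lapply((a + 1):m, function(b) {
      data.frame(a = a, b = b, w = min(D[comp == a, comp == b]))
    }))
  }))
  added <- sum(g$edges$weight[g$edges$provenance == "connecting"])
  expect_equal(added, brute_min_connection(m, cand), tolerance = 1e-12)
})

test_that("graph invariants hold on assembled builds", {
  # n = 1 degenerate graph
  g1 <- suppressWarnings(neighbor_graph(matrix(0, 1, 2), k = 1))
  expect_equal(nrow(g1$edges), 0L)

  # unit-square corners, k = 1: hand enumeration with index tie-break gives
  # edges 1-2 (mutual), 2-3 and 1-4 (enforced): a connected 3-edge path
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  g <- neighbor_graph(sq, k = 1)
  expect_setequal(paste(g$edges$from, g$edges$to), c("1 2", "2 3", "1 4"))
  expect_true(all(g$edges$weight == 1))
  expect_equal(igraph::components(g$graph)$no, 1L)

  set.seed(31)
  X <- matrix(rnorm(80), 40, 2)
  D <- pairwise_distances(X)
  # weights equal ambient distances; no self-loops or duplicates
  for (k in c(2, 5)) {
    g <- neighbor_graph(X, k = k)
    expect_equal(g$edges$weight, D[cbind(g$edges$from, g$edges$to)])
    expect_true(all(g$edges$from != g$edges$to))
    expect_false(any(duplicated(g$edges[c("from", "to")])))
  }

  # monotonicity: natural+enforced edge set at k is a subset of that at k+1
  for (k in c(1, 3, 6)) {
    ek <- neighbor_graph(X, k = k, connect = FALSE)$edges
    ek1 <- neighbor_graph(X, k = k + 1, connect = FALSE)$edges
    expect_true(all(paste(ek$from, ek$to) %in% paste(ek1$from, ek1$to)))
  }

  # complete graph at k = n - 1
  g <- neighbor_graph(X[1:12, ], k = 11)
  expect_equal(nrow(g$edges), choose(12, 2))
})

test_that("circle topology appears at small k, across seeds", {
  # over 20 seeds of 100 uniform circle points: the median smallest k giving
  # one component is <= 6, and the median smallest k also giving a cycle is
  # <= 8 (loose envelopes around single-sample observations at k = 4 and 6)
  k_one <- integer(20); k_cyc <- integer(20)
  for (s in 1:20) {
    ks <- k_scan(sim_circle(100, seed = 100 + s), k = 1:12)
    k_one[s] <- min(ks$k[ks$components == 1])
    k_cyc[s] <- min(ks$k[ks$components == 1 & ks$circuit_rank >= 1])
    expect_true(all(diff(ks$components) <= 0))  # monotone non-increasing
  }
  expect_lte(median(k_one), 6)
  expect_lte(median(k_cyc), 8)
})
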