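# Independent oracles used across the suite. Each one recomputes a quantity
# by a route disjoint from the package implementation (brute force,
# enumeration, dynamic programming, LP feasibility).

# all-pairs shortest paths by Floyd-Warshall dynamic programming
fw_all_pairs <- function(n, edges) {
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- edges$from[r]; j <- edges$to[r]; w <- edges$weight[r]
    D[i, j] <- min(D[i, j], w); D[j, i] <- min(D[j, i], w)
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  D
}

# boolean transitive closure by repeated matrix powering
closure_components <- function(n, edges) {
  A <- diag(TRUE, n)
  for (r in seq_len(nrow(edges))) {
    A[edges$from[r], edges$to[r]] <- TRUE
    A[edges$to[r], edges$from[r]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  match(apply(A, 1, paste, collapse = ""), unique(apply(A, 1, paste, collapse = "")))
}

# LP feasibility of q = V' lambda, lambda >= 0, sum lambda = 1
# (pracma::linprog simplex; independent of the package's NNLS route)
lp_in_hull <- function(V, q) {
  r <- tryCatch(
    pracma::linprog(rep(0, nrow(V)),
                    Aeq = rbind(t(V), rep(1, nrow(V))), beq = c(q, 1),
                    maxiter = 500),
    error = function(e) NULL)
  !is.null(r) && !is.null(r$x) && !any(is.na(r$x))
}

# brute-force vertex set of conv(P): p_i is a vertex iff the LP says it is
# NOT expressible as a convex combination of the other points
lp_hull_vertices <- function(P) {
  which(!vapply(seq_len(nrow(P)),
                function(i) lp_in_hull(P[-i, , drop = FALSE], P[i, ]),
                logical(1)))
}

# direct k-nearest-neighbor vote classifier (ties broken by index)
knn_vote <- function(train_x, train_lab, test_x, k) {
  apply(test_x, 1, function(q) {
    d <- sqrt(colSums((t(train_x) - q)^2))
    mean(train_lab[head(order(d, seq_along(d)), k)])
  })
}

# total weight of the minimum spanning connection, by exhaustive enumeration
# over all subsets of candidate meta-edges that connect all components
brute_min_connection <- function(m, cand) {
  # cand: data.frame(a, b, w) of candidate inter-component edges
  best <- Inf
  nc <- nrow(cand)
  for (mask in seq_len(2^nc) - 1L) {
    sel <- which(bitwAnd(mask, 2^(seq_len(nc) - 1L)) > 0)
    if (length(sel) == 0) next
    lab <- seq_len(m)
    for (r in sel) {
      la <- lab[cand$a[r]]; lb <- lab[cand$b[r]]
      lab[lab == lb] <- la
    }
    if (length(unique(lab)) == 1L) best <- min(best, sum(cand$w[sel]))
  }
  best
}

# midpoint Spearman rank correlation (for trajectory drift checks)
spearman <- function(a, b) cor(rank(a), rank(b))
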