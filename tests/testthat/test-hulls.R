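square_center_ds <- function() {
  datascape(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5)), k = 4)
}

test_that("local hulls have the forced geometry on simple fixtures", {
  # center of a square with the corners as neighbors: square hull, center
  # is interior, 4 facets
  ds <- square_center_ds()
  h <- ds$hulls[[5]]
  expect_setequal(h$vidx, 1:4)
  expect_false(5 %in% h$vidx)
  expect_false(h$degenerate)
  expect_equal(nrow(h$facets$A), 4L)

  # 3 collinear points in 2-d: degenerate segment, endpoints are vertices
  ds <- datascape(cbind(c(0, 1, 2), 0), k = 2)
  h <- ds$hulls[[2]]
  expect_true(h$degenerate)
  expect_setequal(h$vidx, c(1L, 3L))

  # fewer than 2 distinct points: degenerate single-point hull
  ds <- datascape(rbind(c(0, 0), c(0, 0)), k = 1)
  expect_true(ds$hulls[[1]]$degenerate)
  expect_equal(nrow(ds$hulls[[1]]$V), 1L)
})

test_that("hull vertex sets agree with an LP convex-combination oracle", {
  skip_if_not_installed("pracma")
  set.seed(13)
  for (rep in 1:6) {
    P <- matrix(rnorm(30), 10, 3)
    g <- neighbor_graph(P, k = 9)
    h <- datascaper:::build_local_hull(g, 1, tol = 1e-9)
    expect_setequal(h$vidx, lp_hull_vertices(P))
  }
})

test_that("hull vertices reproduce the hull and are minimal", {
  set.seed(17)
  P <- matrix(rnorm(24), 12, 2)
  g <- neighbor_graph(P, k = 11)
  h <- datascaper:::build_local_hull(g, 1, tol = 1e-9)
  # every input point is inside the hull spanned by the vertex set alone
  for (i in seq_len(nrow(P))) expect_true(point_in_hull(h, P[i, ]))
  # minimality: dropping any vertex excludes that vertex from the hull
  for (v in seq_len(nrow(h$V))) {
    hv <- h
    hv$V <- h$V[-v, , drop = FALSE]
    hv$facets <- NULL
    expect_false(point_in_hull(hv, h$V[v, ]))
  }
})

test_that("point_in_hull matches direct geometry and the LP oracle", {
  ds <- square_center_ds()
  h <- ds$hulls[[5]]  # unit-square hull
  expect_true(point_in_hull(h, c(0.5, 0.5)))
  expect_false(point_in_hull(h, c(2, 0)))
  expect_true(point_in_hull(h, c(1, 0)))    # vertex: boundary counts inside
  expect_true(point_in_hull(h, c(0.5, 0)))  # edge midpoint
  expect_error(point_in_hull(h, c(1, 2, 3)), "dimension")

  skip_if_not_installed("pracma")
  set.seed(19)
  checked <- 0
  while (checked < 150) {
    d <- sample(c(2, 3, 5), 1)
    V <- matrix(rnorm((d + 5) * d), d + 5, d)
    g <- neighbor_graph(V, k = d + 4)
    h <- datascaper:::build_local_hull(g, 1, tol = 1e-9)
    q <- if (runif(1) < 0.5) {
      w <- rexp(nrow(V)); as.vector(t(V) %*% (w / sum(w)))
    } else rnorm(d, sd = 2)
    # skip queries inside the tolerance band around the surface
    if (abs(datascaper:::hull_distance(h, q)) < 1e-7 &&
        !lp_in_hull(h$V, q)) next
    expect_equal(point_in_hull(h, q), lp_in_hull(h$V, q))
    checked <- checked + 1
  }
})

test_that("facet and convex-combination membership routes agree in 2-d", {
  set.seed(23)
  P <- matrix(rnorm(30), 15, 2)
  g <- neighbor_graph(P, k = 14)
  h <- datascaper:::build_local_hull(g, 1, tol = 1e-9)
  expect_false(is.null(h$facets))
  for (rep in 1:100) {
    q <- rnorm(2, sd = 1.5)
    facet_route <- all(h$facets$A %*% q - h$facets$b <= h$eps)
    nnls_route <- datascaper:::hull_distance(h, q) <= h$eps
    expect_equal(facet_route, nnls_route)
  }
})

test_that("contains is the union of per-hull membership", {
  ann <- sim_annulus(120, seed = 2)
  ds <- datascape(ann, k = 6)
  set.seed(29)
  Q <- cbind(runif(200, -2, 2), runif(200, -2, 2))
  got <- as.logical(contains(ds, Q))
  ora <- apply(Q, 1, function(q)
    any(vapply(ds$hulls, point_in_hull, logical(1), q = q)))
  expect_equal(got, ora)

  # every dataset point is inside (coverage); far points are outside
  expect_true(all(contains(ds, ds$points)))
  expect_false(as.logical(contains(ds, c(50, 50))))

  # all_hulls enumerates every containing hull
  q <- ds$points[1, ]
  all_ids <- attr(contains(ds, q, all_hulls = TRUE), "hulls")[[1]]
  ora_ids <- ds$ids[vapply(ds$hulls, point_in_hull, logical(1), q = q)]
  expect_setequal(all_ids, ora_ids)
})

test_that("cavities survive the union of local hulls but not a global hull", {
  ann <- sim_annulus(200, seed = 4)
  ds <- datascape(ann, k = 6)
  expect_false(as.logical(contains(ds, c(0, 0))))
  # ... while the single global convex hull swallows the cavity
  g <- neighbor_graph(as.matrix(ann), k = nrow(ann) - 1)
  hull_all <- datascaper:::build_local_hull(g, 1, tol = 1e-9)
  expect_true(point_in_hull(hull_all, c(0, 0)))
})

test_that("extreme points are hull vertices of every containing hull", {
  # 4 corners of a square: all extreme
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_setequal(extreme_points(datascape(sq, k = 3)), c("1", "2", "3", "4"))

  # plus the center: exactly the center is not extreme
  ds <- square_center_ds()
  expect_setequal(extreme_points(ds), c("1", "2", "3", "4"))

  # exact definition restricted to the dataset agrees with the implemented
  # per-hull vertex test on a small random instance (brute force, all hulls)
  set.seed(37)
  X <- matrix(rnorm(60), 30, 2)
  ds <- datascape(X, k = 4)
  brute <- vapply(seq_len(30), function(t) {
    p <- X[t, ]
    for (h in ds$hulls) {
      if (point_in_hull(h, p) && !(t %in% h$vidx)) return(FALSE)
    }
    TRUE
  }, logical(1))
  expect_setequal(extreme_points(ds), ds$ids[brute])
})

test_that("sinusoid extreme set is a strict nonempty subset tracing the surface", {
  ds <- datascape(sim_sinusoid(400, seed = 8), k = 10)
  ne <- length(ds$extreme)
  expect_gt(ne, 0)
  expect_lt(ne, 400)
  # every non-extreme point is strictly inside some hull it is not a vertex of
  for (i in setdiff(seq_len(400), ds$extreme)[1:25]) {
    inside_nonvertex <- any(vapply(seq_along(ds$hulls), function(h)
      !(i %in% ds$hulls[[h]]$vidx) &&
        point_in_hull(ds$hulls[[h]], ds$points[i, ]), logical(1)))
    expect_true(inside_nonvertex)
  }
})
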