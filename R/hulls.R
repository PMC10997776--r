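#' Neighborhood convex hulls
#'
#' Each point's local hull is the convex hull of the point together with its
#' natural and enforced graph neighbors (connecting neighbors are never used:
#' they encode reachability, not similarity, and would fill in cavities the
#' graph deliberately preserves). The union of all local hulls estimates the
#' support of the data; a point is inside the estimated shape iff it is
#' inside at least one local hull.
#'
#' Hulls are stored by their vertex set (the minimal point set whose convex
#' hull reproduces the hull). In two full-dimensional dimensions facet
#' half-spaces are enumerated for fast membership testing; in all other cases
#' — higher dimension, or neighborhoods spanning an affine subspace of lower
#' dimension than the ambient space (flagged `degenerate`) — membership is
#' decided by solving the convex-combination feasibility problem directly,
#' which handles flat hulls with no special casing.
#'
#' @name local_hulls
#' @keywords internal
NULL

# Build the local hull for center index `i` of a neighbor_graph.
# tol is the relative boundary tolerance; the absolute tolerance is
# tol * hull diameter (floored at tol for zero-diameter hulls).
build_local_hull <- function(graph, i, tol = 1e-9) {
  idx <- c(i, graph$neighbors[[i]])
  P <- graph$points[idx, , drop = FALSE]
  d <- ncol(P)

  dup <- duplicated(P)
  Pu <- P[!dup, , drop = FALSE]
  iu <- idx[!dup]

  centroid <- colMeans(Pu)
  diam <- 2 * sqrt(max(rowSums(sweep(Pu, 2, centroid)^2)))
  eps <- tol * max(diam, 1e-12)

  rank <- affine_rank(Pu, eps)
  degenerate <- rank < d || nrow(Pu) <= d

  facets <- NULL
  if (d == 2L && !degenerate) {
    vloc <- grDevices::chull(Pu)
    facets <- facets_2d(Pu[vloc, , drop = FALSE])
  } else if (nrow(Pu) <= 2L) {
    vloc <- seq_len(nrow(Pu))
  } else {
    vloc <- which(hull_vertices_cpp(Pu, eps) == 1L)
  }

  V <- Pu[vloc, , drop = FALSE]
  structure(list(
    center = i, center_id = graph$ids[i],
    input_idx = idx, vidx = iu[vloc], V = V,
    facets = facets, degenerate = degenerate,
    centroid = centroid,
    radius = sqrt(max(rowSums(sweep(V, 2, centroid)^2))),
    eps = eps
  ), class = "local_hull")
}

affine_rank <- function(P, eps) {
  if (nrow(P) == 1L) return(0L)
  Pc <- sweep(P, 2, colMeans(P))
  sv <- svd(Pc, nu = 0, nv = 0)$d
  sum(sv > max(eps, max(sv) * 1e-10))
}

# outward facet half-spaces of a 2-d hull from chull() vertex order:
# inside iff A %*% q <= b (within tolerance) for every facet row
facets_2d <- function(V) {
  m <- nrow(V)
  nxt <- c(seq_len(m)[-1], 1L)
  e <- V[nxt, , drop = FALSE] - V
  A <- cbind(e[, 2], -e[, 1])            # normals to each edge
  b <- rowSums(A * V)
  ctr <- colMeans(V)
  flip <- (A %*% ctr - b) > 0            # orient outward
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]
  nrm <- sqrt(rowSums(A^2))
  list(A = A / nrm, b = b / nrm)
}

#' Test whether a point lies in a local hull
#'
#' Boundary points count as inside: the test accepts any point within the
#' hull's absolute tolerance (`tol` times the hull diameter at build time) of
#' the hull. Full-dimensional 2-d hulls are tested against their facet
#' half-spaces; every other hull is tested by computing the Euclidean
#' distance from the query to the closest convex combination of the hull
#' vertices.
#'
#' @param hull a `"local_hull"` object (element of `ds$hulls`).
#' @param q numeric vector of ambient coordinates.
#' @param eps optional absolute tolerance override.
#' @return logical scalar.
#' @export
point_in_hull <- function(hull, q, eps = NULL) {
  q <- as.numeric(q)
  if (length(q) != ncol(hull$V))
    stop("query has dimension ", length(q), " but hull has dimension ", ncol(hull$V))
  if (is.null(eps)) eps <- hull$eps
  # cheap rejection by the hull's bounding sphere
  if (sqrt(sum((q - hull$centroid)^2)) > hull$radius + eps) return(FALSE)
  if (!is.null(hull$facets)) {
    return(all(hull$facets$A %*% q - hull$facets$b <= eps))
  }
  hull_dist_cpp(hull$V, q)$dist <= eps
}

# distance from q to conv(vertices) regardless of representation
hull_distance <- function(hull, q) hull_dist_cpp(hull$V, as.numeric(q))$dist

#' Membership of points in the estimated shape
#'
#' A query point is inside the datascape iff it lies inside at least one
#' neighborhood convex hull. Hulls are scanned in order of ambient distance
#' from the query to the hull centroids and the scan short-circuits on the
#' first hit, which does not change the answer.
#'
#' @param ds a `"datascape"` object built with hulls.
#' @param q a single point (numeric vector) or a matrix/data frame of query
#'   points, one per row.
#' @param all_hulls if `TRUE`, do not short-circuit: record every containing
#'   hull for each query.
#' @return logical vector, one entry per query, with attribute `"hulls"`: a
#'   list of the center ids of the containing hull(s) found (the first hit,
#'   or all hits when `all_hulls = TRUE`).
#' @examples
#' ds <- datascape(sim_circle(40, seed = 1), k = 4)
#' contains(ds, c(0, 0))   # circle cavity: center is outside
#' contains(ds, ds$points[1, ])  # dataset points are always inside
#' @export
contains <- function(ds, q, all_hulls = FALSE) {
  stopifnot(inherits(ds, "datascape"))
  if (is.null(ds$hulls)) stop("datascape was built without hulls")
  Q <- if (is.null(dim(q))) matrix(as.numeric(q), nrow = 1) else as_points(q)
  if (ncol(Q) != ncol(ds$points))
    stop("query has dimension ", ncol(Q), " but datascape has dimension ",
         ncol(ds$points))
  ctr <- ds$hull_centroids
  rad <- ds$hull_radii
  out <- logical(nrow(Q))
  hit <- vector("list", nrow(Q))
  for (r in seq_len(nrow(Q))) {
    qq <- Q[r, ]
    d2 <- colSums((t(ctr) - qq)^2)
    cand <- which(d2 <= (rad + ds$eps_abs)^2)
    for (h in cand[order(d2[cand])]) {
      if (point_in_hull(ds$hulls[[h]], qq)) {
        out[r] <- TRUE
        hit[[r]] <- c(hit[[r]], ds$hulls[[h]]$center_id)
        if (!all_hulls) break
      }
    }
  }
  structure(out, hulls = hit)
}

#' Extreme (boundary) points of a datascape
#'
#' A dataset point is *extreme* when it is a hull vertex of every local hull
#' that contains it; extreme points trace the boundary surface of the
#' estimated shape. The search is restricted to the dataset points
#' themselves, which is the practical approximation of the continuum
#' definition of the boundary.
#'
#' @param ds a `"datascape"` object.
#' @return character vector of extreme point ids.
#' @export
extreme_points <- function(ds) {
  stopifnot(inherits(ds, "datascape"))
  ds$ids[ds$extreme]
}

# extreme-point computation over all dataset points; returns integer indices
compute_extremes <- function(graph, hulls, eps_abs) {
  n <- nrow(graph$points)
  ctr <- t(vapply(hulls, `[[`, numeric(ncol(graph$points)), "centroid"))
  rad <- vapply(hulls, `[[`, numeric(1), "radius")
  # hulls in which each point participates as an input (center or neighbor)
  member_hulls <- lapply(seq_len(n), function(i) c(i, graph$neighbors[[i]]))
  is_vertex_of <- vector("list", n)
  for (h in seq_len(n)) {
    for (v in hulls[[h]]$vidx) is_vertex_of[[v]] <- c(is_vertex_of[[v]], h)
  }
  extreme <- logical(n)
  for (i in seq_len(n)) {
    p <- graph$points[i, ]
    # input hulls: vertex status is already known
    if (!all(member_hulls[[i]] %in% is_vertex_of[[i]])) next
    # other hulls that could contain p (bounding-sphere prefilter)
    d2 <- colSums((t(ctr) - p)^2)
    cand <- setdiff(which(d2 <= (rad + eps_abs)^2), member_hulls[[i]])
    ok <- TRUE
    for (h in cand) {
      if (point_in_hull(hulls[[h]], p)) {
        # contained in a hull it is not a vertex of (it is not even an input)
        ok <- FALSE
        break
      }
    }
    extreme[i] <- ok
  }
  which(extreme)
}

#' @export
print.local_hull <- function(x, ...) {
  cat(sprintf("Local convex hull of point '%s': %d vertices in %d-d%s\n",
              x$center_id, nrow(x$V), ncol(x$V),
              if (x$degenerate) " (degenerate: lower-dimensional)" else ""))
  invisible(x)
}
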