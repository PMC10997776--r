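#' Geodesic distance and path between two points
#'
#' The geodesic distance is the minimum cumulative edge weight over all graph
#' paths between two vertices; because edge weights are ambient distances
#' between neighbors, the geodesic approximates distance measured *along* the
#' shape of the data rather than through it. If the two points lie in
#' different components and connecting edges are excluded (or absent), the
#' result is an infinite-length sentinel, never an error.
#'
#' @param ds a `"datascape"` or `"neighbor_graph"` object.
#' @param from,to point ids (or integer indices).
#' @param use_connecting may the path use connecting edges? Defaults to
#'   `TRUE`: connecting edges exist precisely so that all geodesics are
#'   finite. Set `FALSE` to respect component structure.
#' @return an object of class `"geodesic"`: list with `path` (ordered vertex
#'   ids, `NULL` if unreachable) and `length`.
#' @examples
#' g <- neighbor_graph(cbind(c(0, 1, 3)), k = 1)
#' geodesic(g, "1", "3")$length  # 3, via the middle point
#' @export
geodesic <- function(ds, from, to, use_connecting = TRUE) {
  from <- resolve_id(ds, from)
  to <- resolve_id(ds, to)
  g <- igraph_view(ds, use_connecting)
  if (from == to) {
    return(structure(list(path = ds$ids[from], length = 0), class = "geodesic"))
  }
  sp <- suppressWarnings(
    igraph::shortest_paths(g, from = from, to = to,
                           weights = igraph::E(g)$weight, output = "both"))
  vp <- sp$vpath[[1]]
  if (length(vp) == 0) {
    return(structure(list(path = NULL, length = Inf), class = "geodesic"))
  }
  structure(list(path = igraph::V(g)$name[as.integer(vp)],
                 length = sum(igraph::E(g)$weight[as.integer(sp$epath[[1]])])),
            class = "geodesic")
}

#' @export
print.geodesic <- function(x, ...) {
  if (is.null(x$path)) {
    cat("Geodesic: unreachable (infinite length)\n")
  } else {
    cat(sprintf("Geodesic: length %.6g over %d vertices\n  %s\n",
                x$length, length(x$path), paste(x$path, collapse = " -> ")))
  }
  invisible(x)
}

#' Geodesic distance matrix
#'
#' All-pairs (or subset) geodesic distances via Dijkstra. Unreachable pairs
#' are `Inf`.
#'
#' @inheritParams geodesic
#' @param from,to optional id vectors; default all points.
#' @return numeric matrix of distances, dimnames = ids.
#' @export
geodesic_distances <- function(ds, from = NULL, to = NULL,
                               use_connecting = TRUE) {
  g <- igraph_view(ds, use_connecting)
  fi <- if (is.null(from)) seq_along(ds$ids) else vapply(from, resolve_id,
                                                         1L, ds = ds)
  ti <- if (is.null(to)) seq_along(ds$ids) else vapply(to, resolve_id,
                                                       1L, ds = ds)
  D <- igraph::distances(g, v = fi, to = ti, weights = igraph::E(g)$weight,
                         algorithm = "dijkstra")
  dimnames(D) <- list(ds$ids[fi], ds$ids[ti])
  D
}

resolve_id <- function(ds, id) {
  if (is.numeric(id) && !as.character(id) %in% ds$ids) {
    i <- as.integer(id)
    if (i < 1 || i > length(ds$ids)) stop("unknown point index: ", id)
    return(i)
  }
  i <- match(as.character(id), ds$ids)
  if (is.na(i)) stop("unknown point id: ", id)
  i
}

#' Insert out-of-sample points into the graph
#'
#' A query point is linked to its `k` nearest dataset points (ambient
#' metric, weights = ambient distances), yielding an augmented graph on
#' which geodesics involving the query can be computed. The original
#' datascape is untouched and its hulls and extreme set are *not* rebuilt —
#' insertion is a query-time operation. When several points are inserted
#' together they may also select each other as neighbors (so duplicate
#' states of a trajectory are joined by zero-weight edges).
#'
#' @inheritParams geodesic
#' @param q a point (vector) or matrix of points to insert, one per row.
#' @param use_connecting include connecting edges in the augmented graph?
#' @return an object of class `"datascape_insertion"`: list with the
#'   augmented igraph (`graph`), the generated query ids (`qids`), and for
#'   each query its neighbor ids and edge weights.
#' @export
insert_point <- function(ds, q, use_connecting = TRUE) {
  Q <- if (is.null(dim(q))) matrix(as.numeric(q), nrow = 1) else as_points(q)
  if (ncol(Q) != ncol(ds$points))
    stop("query has dimension ", ncol(Q), " but datascape has dimension ",
         ncol(ds$points))
  m <- nrow(Q)
  qids <- paste0(".q", seq_len(m))
  g <- igraph::add_vertices(igraph_view(ds, use_connecting), m, name = qids)
  all_pts <- rbind(ds$points, Q)
  all_ids <- c(ds$ids, qids)
  DQ <- cross_distances(Q, all_pts, ds$metric)
  nbrs <- vector("list", m)
  wts <- vector("list", m)
  eform <- character(0); eto <- character(0); ew <- numeric(0)
  for (r in seq_len(m)) {
    self <- nrow(ds$points) + r
    dq <- DQ[r, ]
    ord <- order(dq, seq_along(dq))
    nn <- head(ord[ord != self], min(ds$k, nrow(all_pts) - 1L))
    nbrs[[r]] <- all_ids[nn]
    wts[[r]] <- dq[nn]
    eform <- c(eform, rep(qids[r], length(nn)))
    eto <- c(eto, all_ids[nn]); ew <- c(ew, dq[nn])
  }
  # de-duplicate symmetric query-query edges
  keep <- !duplicated(t(apply(cbind(eform, eto), 1, sort)))
  g <- igraph::add_edges(g, rbind(match(eform[keep], igraph::V(g)$name),
                                  match(eto[keep], igraph::V(g)$name)))
  igraph::E(g)$weight[is.na(igraph::E(g)$weight)] <- ew[keep]
  structure(list(graph = g, qids = qids, neighbors = nbrs, weights = wts,
                 k = ds$k),
            class = "datascape_insertion")
}

#' Geodesic distance from a point to the datascape boundary
#'
#' Distance from a query point to the nearest extreme point, measured along
#' the graph augmented with the query. Computed by a single multi-source
#' shortest-path sweep from the extreme set (a zero-weight super-source).
#'
#' @inheritParams geodesic
#' @param q query point coordinates; if `NULL` the boundary distance of
#'   every dataset point is returned (see [extremeness()]).
#' @return non-negative numeric.
#' @export
boundary_distance <- function(ds, q = NULL, use_connecting = TRUE) {
  stopifnot(inherits(ds, "datascape"))
  if (is.null(ds$extreme)) stop("datascape was built without hulls")
  if (length(ds$extreme) == 0)
    stop("empty extreme set: the datascape is ill-conditioned (every point ",
         "is interior to some hull)")
  if (is.null(q)) return(unname(extremeness(ds, use_connecting)))
  ins <- insert_point(ds, q, use_connecting)
  multi_source_dist(ins$graph, ds$ids[ds$extreme], ins$qids)
}

#' Extremeness score of every dataset point
#'
#' The geodesic distance of each point to the extreme set. Scores are zero
#' exactly on extreme points and grow towards the interior; ranking points
#' by extremeness exposes the interior backbone of the shape.
#'
#' @inheritParams geodesic
#' @return named numeric vector (names = ids).
#' @export
extremeness <- function(ds, use_connecting = TRUE) {
  stopifnot(inherits(ds, "datascape"))
  if (is.null(ds$extreme)) stop("datascape was built without hulls")
  if (length(ds$extreme) == 0)
    stop("empty extreme set: the datascape is ill-conditioned")
  g <- igraph_view(ds, use_connecting)
  d <- multi_source_dist(g, ds$ids[ds$extreme], ds$ids)
  names(d) <- ds$ids
  d
}

# one Dijkstra sweep from a zero-weight super-source attached to `sources`
multi_source_dist <- function(g, sources, targets) {
  g2 <- igraph::add_vertices(g, 1, name = ".boundary.")
  src <- match(".boundary.", igraph::V(g2)$name)
  g2 <- igraph::add_edges(g2, rbind(src, match(sources, igraph::V(g2)$name)))
  igraph::E(g2)$weight[is.na(igraph::E(g2)$weight)] <- 0
  d <- igraph::distances(g2, v = src, to = match(targets, igraph::V(g2)$name),
                         weights = igraph::E(g2)$weight,
                         algorithm = "dijkstra")
  as.numeric(d)
}
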