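#' Symmetrized k-nearest-neighbor graph
#'
#' Builds the weighted neighborhood graph that abstracts the topology of the
#' space the points were sampled from. Construction has four steps:
#'
#' 1. *natural neighbors*: each point is linked to its `k` nearest points
#'    under the ambient metric (ties broken by ascending row index);
#' 2. *symmetrization*: whenever `i` is a natural neighbor of `j` but not the
#'    reverse, `i` gains `j` as an *enforced* neighbor, so neighborhood is a
#'    symmetric relation;
#' 3. *components*: maximal connected components of the resulting graph are
#'    identified;
#' 4. *connecting edges* (optional): for every pair of components the closest
#'    cross pair of points is a candidate edge, and a minimum-spanning-tree
#'    choice among the candidates reconnects the graph with the smallest
#'    possible total added weight. Connecting edges are tagged and can be
#'    excluded from any downstream computation — they exist only to make all
#'    geodesics finite, and are never used when estimating the shape.
#'
#' Every stored edge has weight equal to the ambient distance between its
#' endpoints.
#'
#' @param x numeric matrix or data frame of points (rows = observations).
#' @param k number of natural neighbors; values `>= n` are clamped to
#'   `n - 1` with a warning.
#' @param metric ambient metric, see [ambient_metric()].
#' @param connect logical; add connecting edges between components?
#' @param ids optional character vector of unique point identifiers
#'   (defaults to row names, else `"1".."n"`).
#' @param labels optional binary (0/1) label per point.
#' @return an object of class `"neighbor_graph"`: a list with the points,
#'   ids, labels, per-vertex natural/enforced neighbor index sets, an edge
#'   table (`from`, `to`, `weight`, `provenance`), the igraph representation,
#'   and the pre-connection component labels.
#' @examples
#' g <- neighbor_graph(cbind(c(0, 1, 3)), k = 1)
#' g$edges  # a-b natural, b-c enforced by symmetrization
#' @export
neighbor_graph <- function(x, k, metric = "euclidean", connect = TRUE,
                           ids = NULL, labels = NULL) {
  pts <- as_points(x)
  n <- nrow(pts)
  ids <- check_ids(ids, x, n)
  labels <- check_labels(labels, n)
  met <- ambient_metric(metric)
  if (k < 1) stop("'k' must be >= 1")
  if (k >= n && n > 1) {
    warning("k = ", k, " >= n; clamped to n - 1 = ", n - 1L)
    k <- n - 1L
  }
  k <- as.integer(k)

  D <- pairwise_distances(pts, met)
  natural <- natural_neighbors(D, k)
  enforced <- enforced_neighbors(natural, n)
  neighbors <- lapply(seq_len(n), function(i) sort(c(natural[[i]], enforced[[i]])))

  edges <- edge_table(natural, D)
  comp <- component_labels(n, edges)
  con <- NULL
  if (connect && max(comp) > 1L) {
    con <- connecting_edges(D, comp)
    edges <- rbind(edges, con)
  }

  g <- igraph::graph_from_data_frame(
    data.frame(from = ids[edges$from], to = ids[edges$to],
               weight = edges$weight, provenance = edges$provenance,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))

  structure(list(
    points = pts, ids = ids, labels = labels,
    k = k, metric = met,
    natural = natural, enforced = enforced, neighbors = neighbors,
    edges = edges, graph = g,
    components0 = comp, n_components0 = max(comp),
    connected = connect
  ), class = "neighbor_graph")
}

check_ids <- function(ids, x, n) {
  if (is.null(ids)) {
    ids <- if (is.data.frame(x) || is.matrix(x)) rownames(x) else NULL
    if (is.null(ids)) ids <- as.character(seq_len(n))
  }
  ids <- as.character(ids)
  if (length(ids) != n) stop("'ids' must have one entry per point")
  if (anyDuplicated(ids)) {
    stop("duplicate ids: ", paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  }
  ids
}

check_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  labels <- as.integer(labels)
  if (length(labels) != n) stop("'labels' must have one entry per point")
  if (any(is.na(labels)) || !all(labels %in% c(0L, 1L)))
    stop("'labels' must be binary (0/1) with no missing values")
  labels
}

# k smallest off-diagonal entries per row; ties broken by ascending index
natural_neighbors <- function(D, k) {
  n <- nrow(D)
  lapply(seq_len(n), function(i) {
    ord <- order(D[i, ], seq_len(n))
    head(ord[ord != i], k)
  })
}

# N+(i) = { j : i in N_k(j), j not in N_k(i) }
enforced_neighbors <- function(natural, n) {
  rev_of <- vector("list", n)
  for (j in seq_len(n)) {
    for (i in natural[[j]]) rev_of[[i]] <- c(rev_of[[i]], j)
  }
  lapply(seq_len(n), function(i) {
    as.integer(setdiff(sort(unique(rev_of[[i]])), natural[[i]]))
  })
}

# undirected edge table from the natural relation; an edge is "natural" when
# the relation holds in both directions and "enforced" when symmetrization
# added the missing direction
edge_table <- function(natural, D) {
  n <- length(natural)
  from <- integer(0); to <- integer(0); mutual <- logical(0)
  for (i in seq_len(n)) {
    for (j in natural[[i]]) {
      if (i < j) {
        from <- c(from, i); to <- c(to, j)
        mutual <- c(mutual, i %in% natural[[j]])
      } else if (!(i %in% natural[[j]])) {  # only j<i direction is natural
        from <- c(from, j); to <- c(to, i)
        mutual <- c(mutual, FALSE)
      }
    }
  }
  if (length(from) == 0L) {
    return(data.frame(from = integer(0), to = integer(0), weight = numeric(0),
                      provenance = character(0), stringsAsFactors = FALSE))
  }
  tab <- unique(data.frame(from = from, to = to, mutual = mutual,
                           stringsAsFactors = FALSE))
  data.frame(from = tab$from, to = tab$to,
             weight = D[cbind(tab$from, tab$to)],
             provenance = ifelse(tab$mutual, "natural", "enforced"),
             stringsAsFactors = FALSE)
}

# connected-component labels of the symmetric edge set (depth-first search
# delegated to igraph)
component_labels <- function(n, edges) {
  if (nrow(edges) == 0L) return(seq_len(n))
  g <- igraph::graph_from_edgelist(cbind(edges$from, edges$to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  as.integer(igraph::components(g)$membership)
}

# minimum-weight reconnection: per component pair, the closest cross pair of
# points is the candidate edge; a spanning tree of the component meta-graph
# picks the candidates with minimal total added weight
connecting_edges <- function(D, comp) {
  m <- max(comp)
  idx <- split(seq_along(comp), comp)
  meta_from <- integer(0); meta_to <- integer(0); meta_w <- numeric(0)
  pair_i <- integer(0); pair_j <- integer(0)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      sub <- D[idx[[a]], idx[[b]], drop = FALSE]
      best <- arrayInd(which.min(sub), dim(sub))
      meta_from <- c(meta_from, a); meta_to <- c(meta_to, b)
      meta_w <- c(meta_w, sub[best])
      pair_i <- c(pair_i, idx[[a]][best[1]])
      pair_j <- c(pair_j, idx[[b]][best[2]])
    }
  }
  mg <- igraph::graph_from_edgelist(cbind(meta_from, meta_to), directed = FALSE)
  igraph::E(mg)$weight <- meta_w
  igraph::E(mg)$cand <- seq_along(meta_w)
  keep <- igraph::E(igraph::mst(mg))$cand
  i <- pmin(pair_i[keep], pair_j[keep])
  j <- pmax(pair_i[keep], pair_j[keep])
  data.frame(from = i, to = j, weight = D[cbind(i, j)],
             provenance = "connecting", stringsAsFactors = FALSE)
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("Symmetrized k-nearest-neighbor graph\n")
  cat(sprintf("  points: %d in %d dimension(s); k = %d; metric = %s\n",
              nrow(x$points), ncol(x$points), x$k, x$metric$name))
  tab <- table(factor(x$edges$provenance,
                      levels = c("natural", "enforced", "connecting")))
  cat(sprintf("  edges: %d (%d natural, %d enforced, %d connecting)\n",
              nrow(x$edges), tab[["natural"]], tab[["enforced"]],
              tab[["connecting"]]))
  cat(sprintf("  components before connection: %d\n", x$n_components0))
  invisible(x)
}

#' Extract the edge list of a neighborhood graph
#'
#' @param graph a `"neighbor_graph"` or `"datascape"` object.
#' @param use_connecting keep connecting edges?
#' @return data frame with columns `from`, `to` (ids), `weight`, `provenance`.
#' @export
graph_edges <- function(graph, use_connecting = TRUE) {
  e <- graph$edges
  if (!use_connecting) e <- e[e$provenance != "connecting", , drop = FALSE]
  data.frame(from = graph$ids[e$from], to = graph$ids[e$to],
             weight = e$weight, provenance = e$provenance,
             stringsAsFactors = FALSE)
}

# igraph view with or without connecting edges
igraph_view <- function(graph, use_connecting = TRUE) {
  g <- graph$graph
  if (!use_connecting) {
    g <- igraph::delete_edges(g, which(igraph::E(g)$provenance == "connecting"))
  }
  g
}
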