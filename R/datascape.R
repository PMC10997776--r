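#' Build a datascape
#'
#' The datascape is a shape-aware abstraction of a point cloud: a symmetrized
#' k-nearest-neighbor graph (topology and geodesic metric) combined with the
#' union of per-point neighborhood convex hulls (support estimate, boundary,
#' inside/outside membership). Unlike a single global convex hull, the union
#' of local hulls preserves holes and cavities of the sampled space.
#'
#' `k` controls the scale of the abstraction: it must be large enough for the
#' graph to capture the key topological features of the underlying space
#' (e.g. the single cycle of a circle) and small enough not to short-circuit
#' across cavities. [k_scan()] and [circle_error_curve()] explore this
#' trade-off; the choice is ultimately the analyst's.
#'
#' @param x numeric matrix or data frame of points, rows = observations. A
#'   data frame may carry a `label` column produced by [sim_cohort()]; it is
#'   used as `labels` unless overridden.
#' @param k number of natural nearest neighbors.
#' @param metric ambient metric (name or function), see [ambient_metric()].
#' @param ids,labels optional point identifiers and binary labels.
#' @param connect add connecting edges between graph components?
#' @param hulls build the local hulls and extreme-point set? Setting `FALSE`
#'   yields a graph-only datascape (faster; supports geodesics and label
#'   scores but not membership or boundary queries).
#' @param tol relative geometric tolerance: a point within `tol` times the
#'   hull diameter of a hull's surface counts as inside.
#' @param drop_duplicates remove exactly duplicated rows before building?
#'   Duplicates are permitted (they become mutual nearest neighbors joined by
#'   zero-weight edges) but rarely informative.
#' @return an object of class `c("datascape", "neighbor_graph")`.
#' @examples
#' ds <- datascape(sim_sinusoid(200, seed = 1), k = 10)
#' ds
#' length(extreme_points(ds))
#' @seealso [neighbor_graph()], [contains()], [geodesic()], [risk_scores()]
#' @export
datascape <- function(x, k, metric = "euclidean", ids = NULL, labels = NULL,
                      connect = TRUE, hulls = TRUE, tol = 1e-9,
                      drop_duplicates = FALSE) {
  if (is.data.frame(x) && is.null(labels) && "label" %in% names(x)) {
    labels <- x$label
    x <- x[setdiff(names(x), "label")]
  }
  pts <- as_points(x)
  if (drop_duplicates) {
    keep <- !duplicated(pts)
    pts <- pts[keep, , drop = FALSE]
    if (!is.null(ids)) ids <- ids[keep]
    if (!is.null(labels)) labels <- labels[keep]
    if (is.null(ids) && !is.null(rownames(pts))) ids <- rownames(pts)
  }
  ds <- neighbor_graph(pts, k = k, metric = metric, connect = connect,
                       ids = ids, labels = labels)
  ds$tol <- tol
  if (hulls) {
    ds$hulls <- lapply(seq_len(nrow(ds$points)),
                       function(i) build_local_hull(ds, i, tol))
    ds$hull_centroids <- t(vapply(ds$hulls, `[[`,
                                  numeric(ncol(ds$points)), "centroid"))
    ds$hull_radii <- vapply(ds$hulls, `[[`, numeric(1), "radius")
    ds$eps_abs <- max(vapply(ds$hulls, `[[`, numeric(1), "eps"))
    ds$extreme <- compute_extremes(ds, ds$hulls, ds$eps_abs)
  }
  class(ds) <- c("datascape", "neighbor_graph")
  ds
}

#' @export
print.datascape <- function(x, ...) {
  cat("Datascape\n")
  cat(sprintf("  points: %d in %d dimension(s); k = %d; metric = %s\n",
              nrow(x$points), ncol(x$points), x$k, x$metric$name))
  tab <- table(factor(x$edges$provenance,
                      levels = c("natural", "enforced", "connecting")))
  cat(sprintf("  edges: %d (%d natural, %d enforced, %d connecting)\n",
              nrow(x$edges), tab[["natural"]], tab[["enforced"]],
              tab[["connecting"]]))
  cat(sprintf("  components before connection: %d\n", x$n_components0))
  if (!is.null(x$hulls)) {
    cat(sprintf("  local hulls: %d (%d degenerate); extreme points: %d\n",
                length(x$hulls),
                sum(vapply(x$hulls, `[[`, logical(1), "degenerate")),
                length(x$extreme)))
  } else {
    cat("  hulls: not built\n")
  }
  if (!is.null(x$labels))
    cat(sprintf("  labels: %d positive / %d total\n",
                sum(x$labels), length(x$labels)))
  invisible(x)
}

#' @export
summary.datascape <- function(object, ...) {
  s <- list(
    n = nrow(object$points), d = ncol(object$points), k = object$k,
    metric = object$metric$name,
    edges = table(factor(object$edges$provenance,
                         levels = c("natural", "enforced", "connecting"))),
    components0 = object$n_components0,
    n_extreme = if (is.null(object$extreme)) NA_integer_
                else length(object$extreme),
    degenerate_hulls = if (is.null(object$hulls)) NA_integer_
                       else sum(vapply(object$hulls, `[[`, logical(1),
                                       "degenerate")),
    circuit_rank = nrow(object$edges) - nrow(object$points) +
      igraph::components(object$graph)$no
  )
  class(s) <- "summary.datascape"
  s
}

#' @export
print.summary.datascape <- function(x, ...) {
  cat(sprintf("Datascape: n = %d, d = %d, k = %d, metric = %s\n",
              x$n, x$d, x$k, x$metric))
  cat(sprintf("  edges: %s\n",
              paste(names(x$edges), as.integer(x$edges), collapse = ", ")))
  cat(sprintf("  components (pre-connection): %d; circuit rank: %d\n",
              x$components0, x$circuit_rank))
  if (!is.na(x$n_extreme))
    cat(sprintf("  extreme points: %d; degenerate hulls: %d\n",
                x$n_extreme, x$degenerate_hulls))
  invisible(x)
}

#' Plot a datascape
#'
#' Scatter plot of two coordinates with graph edges; extreme points are
#' highlighted in red and connecting edges drawn dashed.
#'
#' @param x a `"datascape"` object.
#' @param dims the two coordinate columns to draw.
#' @param edges draw graph edges?
#' @param ... passed to [graphics::plot()].
#' @export
plot.datascape <- function(x, dims = c(1, 2), edges = TRUE, ...) {
  P <- x$points[, dims, drop = FALSE]
  graphics::plot(P, xlab = paste0("dim ", dims[1]), ylab = paste0("dim ", dims[2]),
                 type = "n", ...)
  if (edges && nrow(x$edges) > 0) {
    e <- x$edges
    con <- e$provenance == "connecting"
    graphics::segments(P[e$from, 1], P[e$from, 2], P[e$to, 1], P[e$to, 2],
                       col = ifelse(con, "red", "grey70"),
                       lty = ifelse(con, 2, 1))
  }
  graphics::points(P, pch = 16, cex = 0.6, col = "grey30")
  if (!is.null(x$extreme) && length(x$extreme) > 0)
    graphics::points(P[x$extreme, , drop = FALSE], pch = 16, cex = 0.7,
                     col = "red")
  invisible(x)
}
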