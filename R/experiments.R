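#' Circle distance-error curve over k
#'
#' For points sampled uniformly on the unit circle, compares geodesic
#' distances in the neighborhood graph (built *without* connecting edges, so
#' component structure is respected) against the true arc-length distances,
#' for a range of `k`. The per-pair standardized error is
#' `min(1, |d_G - d_arc| / pi)`; disconnected pairs have infinite graph
#' distance and therefore score the maximal error 1. The curve typically
#' drops sharply once the graph becomes one component, is smallest around
#' the `k` at which the circle's cycle appears, and creeps up again as large
#' `k` short-circuits across the disc.
#'
#' @param n number of circle points.
#' @param k integer vector of neighbor counts to scan (default `1:(n-1)`).
#' @param seed RNG seed for the circle sample.
#' @param data optional precomputed [sim_circle()] data frame (overrides
#'   `n`/`seed`).
#' @return an object of class `"error_curve"`: data frame with columns `k`
#'   and `error` (mean standardized error over unordered pairs, in
#'   \[0, 1\]), with attributes `n` and `seed`.
#' @export
circle_error_curve <- function(n = 100, k = NULL, seed = NULL, data = NULL) {
  if (is.null(data)) data <- sim_circle(n, seed)
  angles <- attr(data, "angles")
  if (is.null(angles)) stop("'data' must carry an \"angles\" attribute")
  n <- nrow(data)
  if (is.null(k)) k <- seq_len(n - 1L)
  arc <- circle_arc_distances(angles)
  ut <- upper.tri(arc)
  err <- vapply(k, function(kk) {
    g <- neighbor_graph(data, k = kk, connect = FALSE)
    dg <- geodesic_distances(g, use_connecting = FALSE)
    mean(pmin(1, abs(dg[ut] - arc[ut]) / pi))
  }, numeric(1))
  structure(data.frame(k = as.integer(k), error = err),
            class = c("error_curve", "data.frame"), n = n, seed = seed)
}

#' Topology scan over k
#'
#' Builds the neighborhood graph (without connecting edges) for each `k` and
#' records the number of connected components and the circuit rank
#' (`|E| - |V| + c`, the number of independent cycles). Components proxy
#' 0-dimensional topological features and circuit rank proxies independent
#' loops, giving a cheap guide for choosing `k`: one looks for the smallest
#' `k` at which the expected features of the underlying space (one
#' component, the right number of loops) appear and stabilise.
#'
#' @param x point matrix or data frame.
#' @param k integer vector of neighbor counts.
#' @param metric ambient metric.
#' @return data frame with columns `k`, `components`, `circuit_rank`.
#' @examples
#' k_scan(sim_circle(60, seed = 1), k = 1:10)
#' @export
k_scan <- function(x, k, metric = "euclidean") {
  pts <- as_points(x)
  res <- lapply(k, function(kk) {
    g <- neighbor_graph(pts, k = kk, metric = metric, connect = FALSE)
    comp <- g$n_components0
    data.frame(k = as.integer(kk), components = comp,
               circuit_rank = nrow(g$edges) - nrow(pts) + comp)
  })
  do.call(rbind, res)
}

#' @export
print.error_curve <- function(x, ...) {
  cat(sprintf("Circle distance-error curve: n = %d, %d values of k\n",
              attr(x, "n"), nrow(x)))
  best <- x$k[which.min(x$error)]
  cat(sprintf("  minimum mean standardized error %.4f at k = %d\n",
              min(x$error), best))
  invisible(x)
}

#' @export
plot.error_curve <- function(x, ...) {
  graphics::plot(x$k, x$error, type = "l", xlab = "k",
                 ylab = "mean standardized distance error", ylim = c(0, 1), ...)
  graphics::points(x$k[which.min(x$error)], min(x$error), pch = 16, col = "red")
  invisible(x)
}
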