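#' Ambient metrics
#'
#' The neighborhood graph is built from distances measured in the ambient
#' coordinate space. Built-in metrics are `"euclidean"` (the default, and the
#' metric used throughout the reference experiments) and `"manhattan"`. Any
#' function taking two numeric vectors and returning a single non-negative
#' number is also accepted wherever a metric is expected; it is validated on a
#' few pairs for symmetry, non-negativity and `d(x, x) = 0`.
#'
#' @param metric a metric name or a function of two vectors.
#' @return a list with elements `name` and `fun`, of class `"ambient_metric"`.
#' @examples
#' m <- ambient_metric("euclidean")
#' m$fun(c(0, 0), c(3, 4))  # 5
#' @export
ambient_metric <- function(metric = "euclidean") {
  if (inherits(metric, "ambient_metric")) return(metric)
  if (is.character(metric)) {
    metric <- match.arg(metric, c("euclidean", "manhattan"))
    fun <- switch(metric,
      euclidean = function(a, b) sqrt(sum((a - b)^2)),
      manhattan = function(a, b) sum(abs(a - b)))
    return(structure(list(name = metric, fun = fun), class = "ambient_metric"))
  }
  if (is.function(metric)) {
    return(structure(list(name = "custom", fun = metric),
                     class = "ambient_metric"))
  }
  stop("'metric' must be a metric name or a function of two vectors")
}

#' Pairwise distance matrix
#'
#' Computes the full symmetric matrix of ambient distances between all rows of
#' `x`. Built-in metrics go through [stats::dist()]; custom metric functions
#' are evaluated pairwise.
#'
#' @param x numeric matrix or data frame, rows = points.
#' @param metric metric name or function, see [ambient_metric()].
#' @return an n x n symmetric matrix with zero diagonal.
#' @examples
#' pairwise_distances(rbind(0, 3))  # 1-d points at 0 and 3
#' @export
pairwise_distances <- function(x, metric = "euclidean") {
  x <- as_points(x)
  m <- ambient_metric(metric)
  n <- nrow(x)
  if (m$name %in% c("euclidean", "manhattan")) {
    D <- as.matrix(dist(x, method = m$name))
    dimnames(D) <- NULL
    return(D)
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- m$fun(x[i, ], x[j, ])
    }
  }
  validate_metric_values(D)
  D
}

# coerce to a validated numeric matrix of points
as_points <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  if (!is.numeric(x)) stop("point coordinates must be numeric")
  if (any(!is.finite(x))) {
    bad <- which(!apply(x, 1, function(r) all(is.finite(r))))
    stop("non-finite coordinates in row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  if (nrow(x) < 1L) stop("need at least one point")
  x
}

# distances from each row of Q to each row of P (|Q| x |P|)
cross_distances <- function(Q, P, metric) {
  m <- ambient_metric(metric)
  if (m$name == "euclidean") {
    D2 <- outer(rowSums(Q^2), rowSums(P^2), "+") - 2 * tcrossprod(Q, P)
    return(sqrt(pmax(D2, 0)))
  }
  out <- matrix(0, nrow(Q), nrow(P))
  for (r in seq_len(nrow(Q))) {
    out[r, ] <- if (m$name == "manhattan") colSums(abs(t(P) - Q[r, ]))
                else vapply(seq_len(nrow(P)),
                            function(j) m$fun(Q[r, ], P[j, ]), numeric(1))
  }
  out
}

validate_metric_values <- function(D) {
  if (any(!is.finite(D))) stop("metric returned a non-finite value")
  if (any(D < 0)) stop("metric returned a negative value")
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(D)))
    stop("metric is not symmetric")
  invisible(D)
}
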