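#' Sample points inside a local hull
#'
#' Draws convex combinations of the hull vertices with flat-Dirichlet
#' weights (uniform on the vertex-weight simplex). This is rejection-free
#' and dimension-independent; it is *not* volume-uniform — density is biased
#' towards vertex-dense regions of the hull.
#'
#' @param hull a `"local_hull"` object.
#' @param m number of samples.
#' @param seed optional RNG seed.
#' @return an `m` x `d` matrix; every row lies inside the hull.
#' @export
sample_hull <- function(hull, m, seed = NULL) {
  with_seed(seed, {
    r <- nrow(hull$V)
    W <- matrix(rexp(m * r), m, r)
    W <- W / rowSums(W)
    W %*% hull$V
  })
}

#' Sample points inside the datascape
#'
#' Draws `per_hull` points from every neighborhood convex hull, yielding
#' `n * per_hull` points that all lie inside the estimated shape — the
#' sampled cloud reproduces the shape of the original data at higher
#' density. `simulate()` on a datascape is an alias (with `nsim` the
#' per-hull count).
#'
#' @param ds a `"datascape"` built with hulls.
#' @param per_hull samples per hull.
#' @param seed optional RNG seed.
#' @return data frame of sampled coordinates with a `hull` column naming the
#'   source hull's center id.
#' @examples
#' ds <- datascape(sim_circle(50, seed = 1), k = 5)
#' nrow(sample_datascape(ds, per_hull = 3, seed = 2))  # 150
#' @export
sample_datascape <- function(ds, per_hull, seed = NULL) {
  stopifnot(inherits(ds, "datascape"))
  if (is.null(ds$hulls)) stop("datascape was built without hulls")
  if (per_hull == 0) {
    out <- as.data.frame(ds$points[0, , drop = FALSE])
    out$hull <- character(0)
    return(out)
  }
  with_seed(seed, {
    S <- do.call(rbind, lapply(ds$hulls, sample_hull, m = per_hull))
    out <- as.data.frame(S)
    names(out) <- colnames(ds$points) %||% paste0("V", seq_len(ncol(S)))
    out$hull <- rep(vapply(ds$hulls, `[[`, character(1), "center_id"),
                    each = per_hull)
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sample_datascape
#' @param object,nsim,... standard [stats::simulate()] arguments; `nsim` is
#'   the per-hull sample count.
#' @export
simulate.datascape <- function(object, nsim = 1, seed = NULL, ...) {
  sample_datascape(object, per_hull = nsim, seed = seed)
}

#' Neighborhood label-ratio risk scores
#'
#' For binary-labeled data the datascape acts as an unsupervised classifier:
#' each point's risk score is the fraction of positively-labeled points
#' among its graph neighbors (natural and enforced; the point itself and
#' connecting neighbors are excluded — connecting edges encode reachability,
#' not similarity).
#'
#' @param ds a `"datascape"` or `"neighbor_graph"` with labels (or pass
#'   `labels`).
#' @param labels optional binary labels overriding `ds$labels`.
#' @return data frame with columns `id`, `score` in \[0, 1\], and
#'   `n_neighbors`.
#' @export
risk_scores <- function(ds, labels = NULL) {
  labels <- check_labels(labels %||% ds$labels, nrow(ds$points))
  if (is.null(labels)) stop("no labels available for risk scoring")
  nn <- ds$neighbors
  data.frame(
    id = ds$ids,
    score = vapply(nn, function(v) mean(labels[v]), numeric(1)),
    n_neighbors = lengths(nn),
    stringsAsFactors = FALSE)
}

#' Predict scores and membership for new points
#'
#' @param object a `"datascape"` object.
#' @param newdata matrix or data frame of query points, one per row.
#' @param type `"risk"` — insert each query into the graph and return the
#'   label ratio among its `k` nearest neighbors; `"membership"` — logical
#'   inside/outside the estimated shape; `"boundary"` — geodesic distance to
#'   the nearest extreme point.
#' @param labels optional labels overriding `object$labels` (for `"risk"`).
#' @param ... unused.
#' @return numeric (or logical) vector, one entry per query row.
#' @export
predict.datascape <- function(object, newdata,
                              type = c("risk", "membership", "boundary"),
                              labels = NULL, ...) {
  type <- match.arg(type)
  Q <- if (is.null(dim(newdata))) matrix(as.numeric(newdata), nrow = 1)
       else as_points(newdata)
  switch(type,
    membership = as.logical(contains(object, Q)),
    boundary = vapply(seq_len(nrow(Q)),
                      function(r) boundary_distance(object, Q[r, ]),
                      numeric(1)),
    risk = {
      labels <- check_labels(labels %||% object$labels, nrow(object$points))
      if (is.null(labels)) stop("no labels available for risk scoring")
      DQ <- cross_distances(Q, object$points, object$metric)
      kk <- min(object$k, nrow(object$points))
      vapply(seq_len(nrow(Q)), function(r) {
        nn <- head(order(DQ[r, ], seq_len(ncol(DQ))), kk)
        mean(labels[nn])
      }, numeric(1))
    })
}

# k nearest dataset points of a query (same tie-break as graph construction)
query_knn <- function(ds, q) {
  dq <- cross_distances(matrix(q, nrow = 1), ds$points, ds$metric)[1, ]
  head(order(dq, seq_along(dq)), min(ds$k, nrow(ds$points)))
}

#' Area under the ROC curve
#'
#' Computed through the rank-statistic (Mann-Whitney) identity with midranks
#' for ties.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary 0/1 labels.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC needs at least one positive and one negative label")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Track a trajectory through the datascape
#'
#' Given the time-ordered states of one entity, each state is inserted into
#' the graph and scored by the label ratio of its nearest neighbors; the
#' geodesic between the first and last state (both inserted) summarises the
#' net displacement along the shape of the data.
#'
#' @param ds a labeled `"datascape"`.
#' @param states matrix or data frame of states, one row per time point
#'   (at least two).
#' @param labels optional label override.
#' @return an object of class `"datascape_trajectory"`: list with `states`,
#'   per-state `scores`, and the first-to-last `geodesic`.
#' @export
track_trajectory <- function(ds, states, labels = NULL) {
  S <- as_points(states)
  if (nrow(S) < 2) stop("a trajectory needs at least two states")
  scores <- predict(ds, S, type = "risk", labels = labels)
  ins <- insert_point(ds, S[c(1, nrow(S)), , drop = FALSE])
  dd <- igraph::distances(ins$graph,
                          v = match(ins$qids[1], igraph::V(ins$graph)$name),
                          to = match(ins$qids[2], igraph::V(ins$graph)$name),
                          weights = igraph::E(ins$graph)$weight)
  structure(list(states = S, scores = scores,
                 geodesic_length = as.numeric(dd)),
            class = "datascape_trajectory")
}

#' @export
print.datascape_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory of %d states\n", nrow(x$states)))
  cat("  risk scores:", paste(sprintf("%.3f", x$scores), collapse = " "), "\n")
  cat(sprintf("  geodesic length (first to last state): %.6g\n",
              x$geodesic_length))
  invisible(x)
}

#' Cross-validated risk-score AUC
#'
#' Label-stratified k-fold benchmark of the datascape as an unsupervised
#' classifier: per fold, a graph is built on the training points only and
#' every held-out point is scored by [predict.datascape()] (`type = "risk"`);
#' the AUC over all held-out points of a fold is recorded.
#'
#' @param x point matrix or data frame (a `label` column is honoured).
#' @param labels binary labels (if not carried by `x`).
#' @param k neighbor count for the per-fold graphs.
#' @param folds number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param metric ambient metric.
#' @return numeric vector of per-fold AUCs.
#' @export
cv_risk_auc <- function(x, labels = NULL, k, folds = 4, seed = NULL,
                        metric = "euclidean") {
  if (is.data.frame(x) && is.null(labels) && "label" %in% names(x)) {
    labels <- x$label
    x <- x[setdiff(names(x), "label")]
  }
  pts <- as_points(x)
  labels <- check_labels(labels, nrow(pts))
  if (is.null(labels)) stop("labels are required")
  fold <- with_seed(seed, {
    f <- integer(length(labels))
    for (cl in c(0L, 1L)) {
      i <- which(labels == cl)
      f[i] <- sample(rep_len(seq_len(folds), length(i)))
    }
    f
  })
  vapply(seq_len(folds), function(fo) {
    tr <- fold != fo
    ds <- datascape(pts[tr, , drop = FALSE], k = k, metric = metric,
                    labels = labels[tr], hulls = FALSE)
    sc <- predict(ds, pts[!tr, , drop = FALSE], type = "risk")
    roc_auc(sc, labels[!tr])
  }, numeric(1))
}
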