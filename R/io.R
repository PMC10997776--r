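#' Read a point table from CSV/TSV
#'
#' Reads a delimited file with a header row and validates it into the
#' pieces [datascape()] needs. Feature cells must be numeric; rows with
#' missing or non-numeric features are rejected with their row numbers —
#' imputation is deliberately not performed.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param id_col,label_col optional column names for identifiers and binary
#'   labels.
#' @param feature_cols optional character vector of feature columns
#'   (default: all remaining columns).
#' @param sep optional field separator override.
#' @return list with `points` (numeric matrix), `ids`, `labels` (or `NULL`).
#' @export
read_dataset <- function(path, id_col = NULL, label_col = NULL,
                         feature_cols = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  for (col in c(id_col, label_col)) {
    if (!is.null(col) && !col %in% names(df))
      stop("column not found in ", path, ": ", col)
  }
  ids <- if (!is.null(id_col)) as.character(df[[id_col]]) else NULL
  labels <- if (!is.null(label_col)) df[[label_col]] else NULL
  feats <- feature_cols %||% setdiff(names(df), c(id_col, label_col))
  missing_cols <- setdiff(feats, names(df))
  if (length(missing_cols) > 0)
    stop("feature column(s) not found: ", paste(missing_cols, collapse = ", "))
  fm <- suppressWarnings(
    vapply(df[feats], function(col) as.numeric(as.character(col)),
           numeric(nrow(df))))
  fm <- matrix(fm, nrow = nrow(df),
               dimnames = list(NULL, feats))
  bad <- which(!apply(fm, 1, function(r) all(is.finite(r))))
  if (length(bad) > 0)
    stop("missing or non-numeric feature value(s) in data row(s): ",
         paste(head(bad, 10), collapse = ", "))
  if (!is.null(ids) && anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(head(unique(ids[duplicated(ids)]), 5), collapse = ", "))
  list(points = fm, ids = ids, labels = labels)
}

#' Export the graph edge list
#'
#' @param ds a `"neighbor_graph"` or `"datascape"`.
#' @param path output TSV path (columns: from, to, weight, provenance).
#' @export
write_edges <- function(ds, path) {
  e <- graph_edges(ds)
  e$weight <- sprintf("%.17g", e$weight)
  utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export the graph as GraphML
#'
#' @param ds a `"neighbor_graph"` or `"datascape"`.
#' @param path output `.graphml` path.
#' @export
write_graphml <- function(ds, path) {
  igraph::write_graph(ds$graph, path, format = "graphml")
  invisible(path)
}

CONTAINER_SCHEMA <- "datascaper-container/1"

#' Save and load a datascape container
#'
#' A datascape is serialized as a plain-text directory: a JSON manifest
#' (schema tag, parameters, ids, labels, extreme ids and md5 checksums) plus
#' TSV parts for the point coordinates, the weighted edge list and the
#' per-hull vertex-id lists. Coordinates and weights are written with full
#' double precision, so a reloaded datascape answers membership, geodesic
#' and boundary queries identically. Only built-in metric names can be
#' serialized; a datascape built with a custom metric function cannot be
#' saved.
#'
#' @param ds a `"datascape"` object.
#' @param path directory to create (must not exist or be empty).
#' @return `save_datascape`: the path, invisibly; `load_datascape`: the
#'   reconstructed `"datascape"`.
#' @export
save_datascape <- function(ds, path) {
  stopifnot(inherits(ds, "datascape"))
  if (ds$metric$name == "custom")
    stop("datascapes built with a custom metric function cannot be serialized")
  if (file.exists(path) && length(dir(path)) > 0)
    stop("'path' exists and is not empty: ", path)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)

  pts <- data.frame(id = ds$ids,
                    matrix(sprintf("%.17g", ds$points), nrow(ds$points)),
                    stringsAsFactors = FALSE)
  names(pts) <- c("id", colnames(ds$points) %||%
                    paste0("V", seq_len(ncol(ds$points))))
  utils::write.table(pts, file.path(path, "points.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edges(ds, file.path(path, "edges.tsv"))
  if (!is.null(ds$hulls)) {
    hl <- data.frame(
      center = vapply(ds$hulls, `[[`, character(1), "center_id"),
      degenerate = vapply(ds$hulls, `[[`, logical(1), "degenerate"),
      vertices = vapply(ds$hulls, function(h)
        paste(ds$ids[h$vidx], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
    utils::write.table(hl, file.path(path, "hulls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  parts <- intersect(c("points.tsv", "edges.tsv", "hulls.tsv"), dir(path))
  manifest <- list(
    schema = CONTAINER_SCHEMA,
    k = ds$k, metric = ds$metric$name, tol = ds$tol %||% 1e-9,
    connect = ds$connected,
    n = nrow(ds$points), d = ncol(ds$points),
    labels = ds$labels,
    extreme = if (!is.null(ds$extreme)) ds$ids[ds$extreme],
    checksums = as.list(tools::md5sum(file.path(path, parts)))
  )
  names(manifest$checksums) <- parts
  jsonlite::write_json(manifest, file.path(path, "datascape.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_datascape
#' @export
load_datascape <- function(path) {
  mf <- file.path(path, "datascape.json")
  if (!file.exists(mf)) stop("not a datascape container (no manifest): ", path)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$schema, CONTAINER_SCHEMA))
    stop("unsupported container schema: ", manifest$schema %||% "<none>")
  for (part in names(manifest$checksums)) {
    got <- unname(tools::md5sum(file.path(path, part)))
    if (!identical(got, manifest$checksums[[part]]))
      stop("checksum mismatch for ", part, ": container is corrupted")
  }
  pts <- utils::read.table(file.path(path, "points.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(pts$id)
  P <- as.matrix(pts[setdiff(names(pts), "id")])
  labels <- if (!is.null(manifest$labels) && length(manifest$labels) > 0)
    as.integer(manifest$labels) else NULL

  ds <- datascape(P, k = manifest$k, metric = manifest$metric, ids = ids,
                  labels = labels, connect = isTRUE(manifest$connect),
                  hulls = file.exists(file.path(path, "hulls.tsv")),
                  tol = manifest$tol)

  # verify the rebuild agrees with the stored graph and hulls
  e_stored <- utils::read.table(file.path(path, "edges.tsv"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  e_now <- graph_edges(ds)
  key <- function(e) {
    f <- as.character(e$from); t <- as.character(e$to)
    paste(pmin(f, t), pmax(f, t), e$provenance)
  }
  if (!setequal(key(e_stored), key(e_now)))
    stop("stored edge list does not match the rebuilt graph: ",
         "container is corrupted or was produced by an incompatible version")
  if (!is.null(manifest$extreme) &&
      !setequal(manifest$extreme, extreme_points(ds)))
    stop("stored extreme set does not match the rebuilt datascape")
  ds
}
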