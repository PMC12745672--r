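# Plain-text serialisation: event logs as TSV with a fixed column order,
# adjacency matrices as dense CSV plus a JSON provenance sidecar, partitions
# as CSV or GraphML, snapshots and landscapes as JSON.

#' Write an event log as TSV
#'
#' Fixed column order: time, kind, actor, object, x, y, species, parent,
#' rtype.
#'
#' @param log event data frame.
#' @param path output file.
#' @export
write_eventlog_tsv <- function(log, path) {
  cols <- c("time", "kind", "actor", "object", "x", "y", "species",
            "parent", "rtype")
  write.table(log[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an event log written by [write_eventlog_tsv()]
#' @param path TSV file.
#' @return event data frame.
#' @export
read_eventlog_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write an adjacency matrix (dense CSV + JSON provenance sidecar)
#'
#' @param adj an [adjacency_matrix()].
#' @param path CSV output path; the sidecar is written to `paste0(path,
#'   ".json")`.
#' @param provenance named list merged into the sidecar (seeds, replicate
#'   counts, tolerances, ...).
#' @export
write_adjacency_csv <- function(adj, path, provenance = list()) {
  w <- adj$weights
  utils::write.csv(w, path, row.names = TRUE)
  meta <- c(list(definition = adj$definition, n = nrow(w),
                 symmetric = adj$symmetric, signed = adj$signed),
            provenance)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an adjacency matrix written by [write_adjacency_csv()]
#' @param path CSV file; definition is taken from the sidecar if present,
#'   else from `definition`.
#' @param definition fallback definition tag.
#' @return an [adjacency_matrix()].
#' @export
read_adjacency_csv <- function(path, definition = NULL) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  w <- as.matrix(df)
  colnames(w) <- rownames(w)
  side <- paste0(path, ".json")
  if (is.null(definition)) {
    if (!file.exists(side)) stop("no sidecar and no definition given")
    definition <- jsonlite::read_json(side)$definition
  }
  adjacency_matrix(w, definition)
}

#' Write an adjacency matrix as an edge list TSV (i, j, weight)
#' @param adj an [adjacency_matrix()].
#' @param path output file; zero off-diagonal weights are omitted.
#' @export
write_edgelist_tsv <- function(adj, path) {
  w <- adj$weights
  idx <- which(w != 0 & row(w) != col(w), arr.ind = TRUE)
  if (adj$symmetric) idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
  df <- data.frame(i = rownames(w)[idx[, 1]], j = colnames(w)[idx[, 2]],
                   weight = w[idx])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a partition as CSV (id, community)
#' @param part a [partition()].
#' @param path output file.
#' @export
write_partition_csv <- function(part, path) {
  utils::write.csv(data.frame(id = part$ids, community = part$labels),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a network plus its partition as GraphML
#' @param adj an [adjacency_matrix()]; `part` a matching [partition()].
#' @param path output file (GraphML).
#' @export
write_partition_graphml <- function(adj, part, path) {
  w <- working_weights(adj)
  mode <- if (adj$symmetric) "undirected" else "directed"
  g <- igraph::graph_from_adjacency_matrix(w, mode = mode, weighted = TRUE,
                                           diag = FALSE)
  igraph::V(g)$community <- part$labels[match(adj$ids, part$ids)]
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Serialise a snapshot to JSON
#' @param snap a [snapshot()]; `path` output file.
#' @export
write_snapshot_json <- function(snap, path) {
  jsonlite::write_json(
    list(time = snap$time, individuals = snap$individuals,
         resources = snap$resources, next_id = snap$next_id,
         next_pid = snap$next_pid),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Read a snapshot written by [write_snapshot_json()]
#' @param path JSON file.
#' @return a [snapshot()].
#' @export
read_snapshot_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ind <- as.data.frame(x$individuals)
  ind$host_id <- as.integer(ind$host_id)
  res <- as.data.frame(x$resources)
  if (nrow(res) == 0)
    res <- data.frame(pid = integer(0), prtype = integer(0),
                      px = numeric(0), py = numeric(0),
                      pcreated = numeric(0))
  snapshot(x$time, ind, res, x$next_id, x$next_pid)
}

#' Serialise a landscape description to JSON
#' @param landscape a [make_landscape()] object; `path` output file.
#' @export
write_landscape_json <- function(landscape, path) {
  x <- unclass(landscape)
  if (!is.null(x$weights)) x$weights <- as.data.frame(x$weights)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
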