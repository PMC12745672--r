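# Delineation of local communities by modularity maximisation and
# comparison of delineations via modularity and cross-modularity.

#' Partition container
#' @param ids ordered individual ids; `labels` integer community label per
#'   id; `Q` modularity on the source matrix; `source` definition tag.
#' @return object of class `partition`.
#' @export
partition <- function(ids, labels, Q = NA_real_, source = NA_character_) {
  stopifnot(length(ids) == length(labels), !anyDuplicated(ids))
  structure(list(ids = as.character(ids), labels = canonical_labels(labels),
                 Q = Q, source = source),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat("<partition>", length(unique(x$labels)), "communities over",
      length(x$ids), "individuals | Q =", format(x$Q, digits = 4),
      if (!is.na(x$source)) paste("|", x$source), "\n")
  invisible(x)
}

# relabel communities 1, 2, ... in order of first appearance (canonical
# form; makes tie-breaking and equality checks reproducible)
canonical_labels <- function(labels) {
  as.integer(factor(labels, levels = unique(labels)))
}

#' Newman-Girvan modularity of a weighted partitioned network
#'
#' Q = (1/m) * sum_ij (W_ij - s_out_i * s_in_j / m) * [c_i == c_j], with the
#' diagonal excluded and m the total weight. For symmetric W this reduces to
#' the classical weighted undirected modularity; for asymmetric W it is the
#' directed (out/in strength) generalisation.
#'
#' @param M an [adjacency_matrix()] or a non-negative square matrix
#'   (influence matrices enter via their magnitudes).
#' @param labels community label per row (or a [partition()] whose ids must
#'   match the matrix).
#' @return Q in `[-1, 1]`; 0 for a single community or an empty network.
#' @export
modularity_q <- function(M, labels) {
  W <- if (inherits(M, "adjacency")) working_weights(M) else {
    if (any(M < 0)) stop("modularity needs non-negative weights")
    W0 <- M; diag(W0) <- 0; W0
  }
  if (inherits(labels, "partition")) {
    if (!is.null(rownames(W)) &&
        !identical(as.character(rownames(W)), labels$ids)) {
      idx <- match(rownames(W), labels$ids)
      if (anyNA(idx)) stop("partition does not cover the matrix ids")
      labels <- labels$labels[idx]
    } else labels <- labels$labels
  }
  if (length(labels) != nrow(W)) stop("label / matrix size mismatch")
  m <- sum(W)
  if (m <= 0) return(0)
  s_out <- rowSums(W); s_in <- colSums(W)
  q <- 0
  for (c_ in unique(labels)) {
    sel <- labels == c_
    q <- q + sum(W[sel, sel]) / m -
      sum(s_out[sel]) * sum(s_in[sel]) / m^2
  }
  q
}

#' Delineate local communities by Leiden modularity maximisation
#'
#' Runs the Leiden algorithm (via igraph) on the non-negative working
#' weights; asymmetric (influence) matrices are optimised on the
#' symmetrised magnitudes (W + t(W))/2 while the reported Q uses the
#' directed formula on the magnitudes themselves. Best of `restarts`
#' restarts is kept, ties broken by lower community count then by canonical
#' label order.
#'
#' @param M an [adjacency_matrix()] or non-negative matrix with rownames.
#' @param seed integer; restarts derive sub-seeds from it.
#' @param restarts independent optimiser restarts.
#' @param initial optional [partition()]s to include as candidate starting
#'   memberships (used when re-optimising after a certification failure).
#' @param resolution modularity resolution (1 = classical).
#' @return a [partition()] with the achieved Q attached.
#' @export
leiden_partition <- function(M, seed = 1L, restarts = 10L, initial = NULL,
                             resolution = 1) {
  W <- if (inherits(M, "adjacency")) working_weights(M) else {
    W0 <- abs(M); diag(W0) <- 0; W0
  }
  if (nrow(W) == 0) stop("empty adjacency matrix")
  if (!all(is.finite(W))) stop("non-finite weights")
  ids <- rownames(W)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(W)))
  src <- if (inherits(M, "adjacency")) M$definition else NA_character_
  if (sum(W) == 0) { # no structure at all: all singletons, Q = 0
    return(partition(ids, seq_along(ids), Q = 0, source = src))
  }
  Wsym <- (W + t(W)) / 2
  g <- igraph::graph_from_adjacency_matrix(Wsym, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  cand <- list()
  seeds <- expand_seeds(seed, restarts)
  for (r in seq_len(restarts)) {
    old <- .Random.seed_guard(seeds[r])
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 10)
    old()
    cand[[r]] <- igraph::membership(cl)
  }
  if (!is.null(initial)) {
    if (inherits(initial, "partition")) initial <- list(initial)
    for (p0 in initial) {
      memb <- p0$labels[match(ids, p0$ids)]
      if (anyNA(memb)) next
      cand[[length(cand) + 1L]] <- memb
      old <- .Random.seed_guard(seeds[1])
      cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                   resolution = resolution,
                                   n_iterations = 10,
                                   initial_membership = memb)
      old()
      cand[[length(cand) + 1L]] <- igraph::membership(cl)
    }
  }
  best <- NULL
  for (memb in cand) {
    lab <- canonical_labels(memb)
    q <- modularity_q(if (inherits(M, "adjacency")) M else W, lab)
    key <- list(q = q, k = length(unique(lab)), lab = lab)
    if (is.null(best) || key$q > best$q + 1e-12 ||
        (abs(key$q - best$q) <= 1e-12 &&
         (key$k < best$k ||
          (key$k == best$k &&
           paste(key$lab, collapse = ",") <
             paste(best$lab, collapse = ","))))) best <- key
  }
  partition(ids, best$lab, Q = best$q, source = src)
}

#' Cross-modularity of one definition's matrix under another's partition
#'
#' Q_AB = Q(M_A, P_B) / Q(M_A, P_A): the proportion of definition A's
#' maximal modularity retained when definition B's communities are imposed.
#' Values near 1 mean B's communities explain A's adjacencies almost as
#' well as A's own; the index is not symmetric.
#'
#' @param M_A adjacency matrix of definition A.
#' @param P_A the optimiser's partition for `M_A`; `P_B` any partition
#'   covering the same ids.
#' @return the ratio; errors if Q(M_A, P_A) <= 0 (undefined).
#' @export
cross_modularity <- function(M_A, P_A, P_B) {
  qa <- modularity_q(M_A, P_A)
  if (qa <= 0)
    stop("cross-modularity undefined: Q(M_A, P_A) = ",
         format(qa, digits = 4), " <= 0")
  modularity_q(M_A, P_B) / qa
}

#' Normalised mutual information between two partitions
#'
#' Alternative consistency measure reported alongside cross-modularity.
#'
#' @param P_A,P_B [partition()]s over the same ids.
#' @return NMI in `[0, 1]`.
#' @export
partition_nmi <- function(P_A, P_B) {
  lb <- P_B$labels[match(P_A$ids, P_B$ids)]
  if (anyNA(lb)) stop("partitions cover different ids")
  igraph::compare(P_A$labels, lb, method = "nmi")
}

#' Cross-modularity report over a set of definitions
#'
#' Partitions every matrix (if partitions are not supplied), certifies each
#' partition against the others (re-optimising with the rival partition as
#' an initial membership if it scores higher, so that Q(M_A, P_B) <=
#' Q(M_A, P_A) holds), and assembles the Q_AB matrix together with
#' per-definition modularities and NMI values.
#'
#' @param mats named list of [adjacency_matrix()]s over the same ids.
#' @param partitions optional named list of [partition()]s.
#' @param seed,restarts forwarded to [leiden_partition()].
#' @return list with `Q` (named per-definition modularity), `partitions`,
#'   `Q_AB` (rows = matrix definition A, cols = partition definition B) and
#'   `nmi`.
#' @export
cross_modularity_report <- function(mats, partitions = NULL, seed = 1L,
                                    restarts = 10L) {
  defs <- names(mats)
  stopifnot(!is.null(defs), all(nzchar(defs)))
  if (is.null(partitions)) {
    partitions <- lapply(seq_along(mats), function(k)
      leiden_partition(mats[[k]], seed = expand_seeds(seed, length(mats))[k],
                       restarts = restarts))
    names(partitions) <- defs
  }
  # certification: a rival partition must never beat the own optimum
  for (a in defs) {
    qa <- modularity_q(mats[[a]], partitions[[a]])
    rival <- vapply(defs, function(b) modularity_q(mats[[a]],
                                                   partitions[[b]]),
                    numeric(1))
    if (any(rival > qa + 1e-12)) {
      partitions[[a]] <- leiden_partition(
        mats[[a]], seed = seed, restarts = restarts * 2L,
        initial = partitions[defs[rival > qa + 1e-12]])
    }
  }
  qs <- vapply(defs, function(a) modularity_q(mats[[a]], partitions[[a]]),
               numeric(1))
  Q_AB <- matrix(NA_real_, length(defs), length(defs),
                 dimnames = list(defs, defs))
  nmi <- Q_AB
  for (a in defs) for (b in defs) {
    Q_AB[a, b] <- cross_modularity(mats[[a]], partitions[[a]],
                                   partitions[[b]])
    nmi[a, b] <- partition_nmi(partitions[[a]], partitions[[b]])
  }
  list(Q = qs, partitions = partitions, Q_AB = Q_AB, nmi = nmi)
}
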