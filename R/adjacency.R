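# Estimation of the metacommunity adjacency matrix P = (p_ij) among the
# snapshot individuals, under the three definitions of the local community
# of a focal individual:
#   space       p_ij = Bhattacharyya overlap of gridded utilization
#               distributions (occupancy-time fractions)
#   interaction p_ij = proportion of replicate runs in which i and j
#               interacted
#   influence   p_ij = mean (treatment - control) offspring of j when i is
#               removed, from paired replicates under common random numbers

#' Adjacency matrix container
#'
#' @param weights square numeric matrix, dimnames = individual ids.
#' @param definition `"space"`, `"interaction"` or `"influence"`.
#' @return object of class `adjacency`: carries the (possibly signed)
#'   weights, the definition tag, and symmetry/sign flags. The diagonal is
#'   never used for partitioning.
#' @export
adjacency_matrix <- function(weights,
                             definition = c("space", "interaction",
                                            "influence")) {
  definition <- match.arg(definition)
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights),
            !is.null(rownames(weights)))
  if (definition != "influence") {
    if (any(weights < -1e-12) || any(weights > 1 + 1e-12))
      stop(definition, " weights must lie in [0,1]")
    weights[] <- pmin(pmax(weights, 0), 1)
  }
  structure(list(weights = weights,
                 ids = rownames(weights),
                 definition = definition,
                 symmetric = definition != "influence",
                 signed = definition == "influence"),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat("<adjacency>", x$definition, "|", nrow(x$weights), "individuals |",
      if (x$signed) "signed" else "non-negative",
      if (x$symmetric) "symmetric" else "directed", "\n")
  invisible(x)
}

# non-negative working weights for partitioning (magnitudes for influence)
working_weights <- function(adj) {
  w <- abs(adj$weights)
  diag(w) <- 0
  w
}

## ---------------------------------------------------------------- space use

#' Gridded utilization distributions from replicate event logs
#'
#' Accumulates, for every snapshot individual, the exact sojourn time spent
#' in each cell of a G x G grid (locations are piecewise constant between
#' move events), pooled over replicates, and normalises to occupancy
#' fractions. A parasite shares its host's trajectory while both are alive.
#'
#' @param runs list of [run_replicate()] results (with `log_moves = TRUE`).
#' @param snap the common starting [snapshot()].
#' @param horizon replicate duration.
#' @param G grid cells per side.
#' @return list with `fields` (individuals x G^2 matrix of weights, rows
#'   summing to 1; ids as rownames) and `alive_time` (pooled time observed
#'   per individual).
#' @export
space_use_fields <- function(runs, snap, horizon, G = 32L) {
  ind <- snap$individuals
  n <- nrow(ind)
  ids <- ind$id
  fld <- matrix(0, n, G * G, dimnames = list(ids, NULL))
  alive <- numeric(n)
  t0 <- snap$time; t_end <- t0 + horizon
  host_row <- match(ind$host_id, ids) # parasite -> its host's row
  for (run in runs) {
    log <- run$log
    mv <- log[log$kind == "move", c("time", "actor", "x", "y")]
    dth <- log[log$kind == "death", c("time", "actor")]
    death_at <- dth$time[match(ids, dth$actor)] # NA if survived
    mv_by <- split(seq_len(nrow(mv)), factor(mv$actor, levels = ids))
    for (i in seq_len(n)) {
      src <- if (ind$guild[i] == 1L) host_row[i] else i
      stop_t <- min(death_at[i], death_at[src], t_end, na.rm = TRUE)
      if (stop_t <= t0) next
      rows <- mv_by[[src]]
      tt <- c(t0, mv$time[rows])
      xx <- c(ind$x[src], mv$x[rows])
      yy <- c(ind$y[src], mv$y[rows])
      keep <- tt < stop_t
      tt <- tt[keep]; xx <- xx[keep]; yy <- yy[keep]
      dt <- c(tt[-1], stop_t) - tt
      cells <- grid_cell(xx, yy, G)
      agg <- rowsum(dt, cells)
      fld[i, as.integer(rownames(agg))] <-
        fld[i, as.integer(rownames(agg))] + agg[, 1]
      alive[i] <- alive[i] + (stop_t - t0)
    }
  }
  ok <- alive > 0
  fld[ok, ] <- fld[ok, , drop = FALSE] / alive[ok]
  list(fields = fld, alive_time = alive)
}

#' Space-use field of one individual
#'
#' @inheritParams space_use_fields
#' @param id snapshot individual id.
#' @return numeric weight vector of length `G^2` summing to 1.
#' @export
estimate_space_use <- function(runs, snap, id, horizon, G = 32L) {
  if (!id %in% snap$individuals$id) stop("unknown individual id ", id)
  sf <- space_use_fields(runs, snap, horizon, G)
  if (sf$alive_time[match(id, snap$individuals$id)] <= 0)
    stop("individual ", id, " has zero observed alive time")
  sf$fields[as.character(id), ]
}

#' Bhattacharyya overlap of two discretized utilization distributions
#'
#' @param c_i,c_j non-negative weight vectors on the same grid, each summing
#'   to 1.
#' @return `sum(sqrt(c_i * c_j))`, in `[0, 1]`; 1 for identical
#'   distributions, 0 for disjoint supports.
#' @export
bhattacharyya_overlap <- function(c_i, c_j) {
  if (length(c_i) != length(c_j)) stop("grid mismatch")
  min(1, sum(sqrt(c_i * c_j)))
}

#' Space-use adjacency from utilization fields
#'
#' @param fields matrix as returned by [space_use_fields()]; rows with zero
#'   observed time are dropped.
#' @param alive_time optional vector used to drop unobserved individuals.
#' @return an [adjacency_matrix()] with unit diagonal, entries in `[0,1]`.
#' @export
space_adjacency <- function(fields, alive_time = NULL) {
  if (!is.null(alive_time)) fields <- fields[alive_time > 0, , drop = FALSE]
  s <- sqrt(fields)
  P <- tcrossprod(s)
  P[] <- pmin(pmax(P, 0), 1)
  diag(P) <- 1
  adjacency_matrix(P, "space")
}

## -------------------------------------------------------------- interaction

#' Detect interacting pairs by replaying an event log
#'
#' Applies the interaction rules at event times, using toroidal distances:
#' two consumers interact when one consumes a particle lying within the
#' consumption radius of the other and both species use that resource type;
#' a parasite and a consumer interact when the parasite infects it; two
#' parasites interact when one infects a host the other could have infected
#' (host species in its host range and host within its transmission radius).
#'
#' The simulation engine records the same pairs natively as events fire;
#' this replay is the reference implementation used for scripted logs and
#' as a cross-check of the engine's bookkeeping.
#'
#' @param log event data frame (must include move events).
#' @param snap starting [snapshot()].
#' @param rates the [default_rates()] model (for usage, host range, radii).
#' @return 2-column matrix of unordered interacting id pairs (i < j).
#' @export
detect_interactions <- function(log, snap, rates) {
  Sc <- nrow(rates$usage)
  ids <- snap$individuals$id
  sp <- snap$individuals$species
  gl <- snap$individuals$guild
  px <- snap$individuals$x
  py <- snap$individuals$y
  host <- snap$individuals$host_id
  alive <- rep(TRUE, length(ids))
  add <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    pairs[[key]] <<- c(min(i, j), max(i, j))
  }
  pairs <- list()
  last_infect_host <- NA_integer_
  for (r in seq_len(nrow(log))) {
    kind <- log$kind[r]; a <- log$actor[r]
    ai <- match(a, ids)
    if (kind == "move") {
      px[ai] <- log$x[r]; py[ai] <- log$y[r]
    } else if (kind == "death") {
      alive[ai] <- FALSE
    } else if (kind == "birth") {
      code <- log$species[r]
      ids <- c(ids, a)
      sp <- c(sp, if (code > Sc) code - Sc else code)
      gl <- c(gl, if (code > Sc) 1L else 0L)
      px <- c(px, log$x[r]); py <- c(py, log$y[r])
      host <- c(host, if (code > Sc) last_infect_host else NA_integer_)
      alive <- c(alive, TRUE)
    } else if (kind == "consume") {
      rt <- log$rtype[r]
      cx <- log$x[r]; cy <- log$y[r]
      cand <- which(alive & gl == 0L & ids != a)
      cand <- cand[rates$usage[cbind(sp[cand], rt)] > 0]
      if (length(cand)) {
        cand <- cand[torus_dist(px[cand], py[cand], cx, cy) <
                       rates$r_c[sp[cand]]]
        for (j in cand) add(a, ids[j])
      }
    } else if (kind == "infect") {
      h <- log$object[r]
      last_infect_host <- h
      add(a, h)
      hi <- match(h, ids)
      others <- which(alive & gl == 1L & ids != a)
      if (length(others)) {
        ok <- rates$host_range[cbind(sp[others], sp[hi])] > 0
        others <- others[ok]
        if (length(others)) {
          ox <- px[match(host[others], ids)]
          oy <- py[match(host[others], ids)]
          close <- torus_dist(ox, oy, px[hi], py[hi]) <
            rates$par_rt[sp[others]]
          for (j in others[close]) add(a, ids[j])
        }
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, unname(pairs))
}

# restrict a pair matrix to snapshot individuals
filter_pairs <- function(pairs, ids) {
  if (nrow(pairs) == 0) return(pairs)
  keep <- pairs[, 1] %in% ids & pairs[, 2] %in% ids
  pairs[keep, , drop = FALSE]
}

#' Interaction adjacency from replicate pair sets
#'
#' @param pair_sets list (one element per replicate) of 2-column id-pair
#'   matrices.
#' @param ids snapshot individual ids defining the matrix order.
#' @return an [adjacency_matrix()]: p_ij = proportion of replicates in which
#'   the pair interacted.
#' @export
interaction_adjacency <- function(pair_sets, ids) {
  stopifnot(length(pair_sets) >= 1)
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  for (pp in pair_sets) {
    pp <- filter_pairs(pp, ids)
    if (nrow(pp) == 0) next
    i <- match(pp[, 1], ids); j <- match(pp[, 2], ids)
    P[cbind(i, j)] <- P[cbind(i, j)] + 1
  }
  P <- (P + t(P)) / length(pair_sets)
  adjacency_matrix(P, "interaction")
}

## ---------------------------------------------------------------- influence

#' Influence adjacency from paired removal experiments
#'
#' For each focal snapshot individual i, runs `R` paired replicates
#' (control with i present; treatment with i, and any parasite it carries,
#' removed) sharing seeds (common random numbers), and sets
#' p_ij = mean over replicates of offspring(j | treatment_i) -
#' offspring(j | control), where births by individuals born during a
#' replicate are credited to their snapshot ancestor (see
#' [lineage_offspring()]), so the count is the lineage-level reproductive
#' output of j over the horizon. The matrix is signed and generally
#' asymmetric; controls are shared across focals since they do not depend
#' on i.
#'
#' @param snap a [snapshot()].
#' @param config a [sim_config()].
#' @param horizon replicate duration.
#' @param n_rep paired replicates per focal.
#' @param seed master seed; per-replicate seeds come from [expand_seeds()].
#' @param focal_ids optionally restrict the focal set (defaults to every
#'   snapshot individual, each used once).
#' @param denoise `"none"` (default) returns the raw mean differences:
#'   with per-entity random streams, paired runs differ only inside the
#'   causal cone of the removal, so the raw matrix is already sparse and
#'   spatially localised. `"soft"` additionally shrinks every entry towards
#'   zero by `z` times its own standard error across replicates. The raw
#'   matrix and the standard errors are always kept as attributes.
#' @param z noise-floor multiplier for `denoise = "soft"`.
#' @return an [adjacency_matrix()] of definition `"influence"` with
#'   attributes `raw` (unshrunk mean differences), `se` (their standard
#'   errors) and `controls` (control offspring counts, replicates x
#'   individuals).
#' @export
influence_adjacency <- function(snap, config, horizon, n_rep = 10L,
                                seed = 1L, focal_ids = NULL,
                                denoise = c("none", "soft"), z = 2) {
  denoise <- match.arg(denoise)
  ids <- snap$individuals$id
  if (is.null(focal_ids)) focal_ids <- ids
  stopifnot(all(focal_ids %in% ids), n_rep >= 1)
  seeds <- expand_seeds(seed, n_rep)
  ctrl_off <- matrix(0L, n_rep, length(ids),
                     dimnames = list(NULL, ids))
  for (r in seq_len(n_rep)) {
    ctrl <- run_replicate(snap, config, horizon, seeds[r],
                          log_moves = FALSE, record_interactions = FALSE)
    ctrl_off[r, ] <- lineage_offspring(ctrl, ids, snap$time)
  }
  n <- length(ids)
  P <- matrix(0, n, n, dimnames = list(ids, ids))
  SE <- matrix(0, n, n, dimnames = list(ids, ids))
  for (f in focal_ids) {
    reduced <- remove_individual(snap, f)
    dsum <- numeric(n); dsq <- numeric(n)
    for (r in seq_len(n_rep)) {
      trt <- run_replicate(reduced, config, horizon, seeds[r],
                           log_moves = FALSE, record_interactions = FALSE)
      dd <- lineage_offspring(trt, ids, snap$time) - ctrl_off[r, ]
      dsum <- dsum + dd
      dsq <- dsq + dd^2
    }
    mu <- dsum / n_rep
    P[as.character(f), ] <- mu
    if (n_rep > 1)
      SE[as.character(f), ] <-
        sqrt(pmax(0, (dsq - n_rep * mu^2) / (n_rep - 1)) / n_rep)
  }
  fd <- cbind(match(focal_ids, ids), match(focal_ids, ids))
  P[fd] <- 0
  raw <- P
  if (denoise == "soft" && n_rep > 1)
    P <- sign(P) * pmax(0, abs(P) - z * SE)
  adj <- adjacency_matrix(P, "influence")
  attr(adj, "raw") <- raw
  attr(adj, "se") <- SE
  attr(adj, "controls") <- ctrl_off
  adj
}

## -------------------------------------------------------------- convergence

#' Grow an adjacency estimate until it converges
#'
#' Adds batches of replicates and stops when the relative Frobenius change
#' between successive cumulative estimates falls below `tol`:
#' ||P_k - P_{k-1}||_F / max(||P_k||_F, eps) < tol.
#'
#' @param step_fn function(state, seeds) -> list(state = ..., P = matrix).
#'   `state` carries the estimator's accumulator (NULL at the first call);
#'   `P` is the cumulative estimate after consuming the batch seeds.
#' @param seed master seed feeding [expand_seeds()].
#' @param batch replicates per batch; `tol` relative tolerance;
#'   `max_replicates` hard cap.
#' @return list with `P` (final estimate), `replicates`, `deltas` (relative
#'   changes after each batch beyond the first), `converged` flag. A run
#'   hitting the cap returns `converged = FALSE` rather than failing
#'   silently.
#' @export
run_until_converged <- function(step_fn, seed = 1L, batch = 50L,
                                tol = 0.05, max_replicates = 1000L) {
  stopifnot(batch >= 1, tol > 0)
  state <- NULL
  P_prev <- NULL
  deltas <- numeric(0)
  used <- 0L
  repeat {
    seeds <- expand_seeds(seed, batch, offset = used)
    res <- step_fn(state, seeds)
    state <- res$state
    P <- res$P
    used <- used + batch
    if (!is.null(P_prev)) {
      delta <- norm(P - P_prev, "F") / max(norm(P, "F"), 1e-12)
      deltas <- c(deltas, delta)
      if (delta < tol)
        return(list(P = P, replicates = used, deltas = deltas,
                    converged = TRUE))
    }
    P_prev <- P
    if (used >= max_replicates)
      return(list(P = P, replicates = used, deltas = deltas,
                  converged = FALSE))
  }
}
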