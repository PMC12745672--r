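# Deterministic small-scale fixtures: planted-partition adjacency matrices
# spanning the three block-structure regimes (isolated blocks, blocks with
# spillover, no block structure) and hand-scripted event logs, so every
# estimator is testable without running the stochastic engine.

#' Planted-partition adjacency matrix with ground truth
#'
#' Block matrix: entries `within` inside diagonal blocks, `between`
#' elsewhere, plus uniform noise of amplitude `noise`; symmetric, zero
#' diagonal. `between = noise = 0` gives fully isolated communities;
#' `0 < between < within` the classical interconnected-communities regime;
#' `within = between` a structureless matrix.
#'
#' @param block_sizes integer vector of community sizes.
#' @param within,between,noise weights with `within >= between >= 0`;
#'   `within + noise` must not exceed 1.
#' @param seed integer.
#' @return list with `adjacency` (an [adjacency_matrix()], definition
#'   `"interaction"`) and `truth` (the planted [partition()]).
#' @export
make_planted_adjacency <- function(block_sizes, within = 0.8, between = 0.05,
                                   noise = 0.02, seed = 1L) {
  stopifnot(within >= between, between >= 0, within + noise <= 1)
  n <- sum(block_sizes)
  labels <- rep(seq_along(block_sizes), block_sizes)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  same <- outer(labels, labels, "==")
  W <- matrix(ifelse(same, within, between), n, n)
  if (noise > 0) {
    eps <- matrix(runif(n * n, 0, noise), n, n)
    eps <- (eps + t(eps)) / 2
    W <- W + eps
  }
  diag(W) <- 0
  ids <- paste0("i", seq_len(n))
  dimnames(W) <- list(ids, ids)
  list(adjacency = adjacency_matrix(W, "interaction"),
       truth = partition(ids, labels, source = "planted"))
}

#' Build an event log (and matching snapshot) from a hand-written script
#'
#' @param script data frame with columns `time`, `kind` (birth / death /
#'   move / consume / infect), `actor`, and optionally `object`, `x`, `y`,
#'   `species`, `parent`, `rtype` (missing columns are filled with NA).
#'   Times must be non-decreasing.
#' @param individuals data frame for the starting [snapshot()] (columns
#'   `id`, `species`, `guild`, `x`, `y`, `host_id`, `born_at`; defaults
#'   filled for the latter three).
#' @param time snapshot clock (default 0).
#' @return list with `log` and `snapshot`.
#' @export
make_toy_eventlog <- function(script, individuals, time = 0) {
  stopifnot(all(c("time", "kind", "actor") %in% names(script)))
  if (is.unsorted(script$time)) stop("script times must be non-decreasing")
  bad <- setdiff(unique(script$kind), KIND_LEVELS)
  if (length(bad)) stop("unknown event kind: ", paste(bad, collapse = ", "))
  for (col in c("object", "species", "parent", "rtype"))
    if (is.null(script[[col]])) script[col] <- rep(NA_integer_, nrow(script))
  for (col in c("x", "y"))
    if (is.null(script[[col]])) script[col] <- rep(NA_real_, nrow(script))
  log <- script[, c("time", "kind", "actor", "object", "x", "y", "species",
                    "parent", "rtype")]
  for (col in c("host_id")) if (is.null(individuals[[col]]))
    individuals[[col]] <- NA_integer_
  if (is.null(individuals$guild)) individuals$guild <- 0L
  if (is.null(individuals$born_at)) individuals$born_at <- time
  known <- c(individuals$id, log$actor[log$kind == "birth"])
  ref <- log$actor[log$kind != "birth"]
  if (!all(ref %in% known))
    stop("script references individuals never introduced")
  snap <- snapshot(time, individuals,
                   data.frame(pid = integer(0), prtype = integer(0),
                              px = numeric(0), py = numeric(0),
                              pcreated = numeric(0)),
                   next_id = max(known) + 1L, next_pid = 1L)
  list(log = log, snapshot = snap)
}
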