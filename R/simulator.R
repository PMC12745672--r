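# R front end for the Gillespie engine: initial states, burn-in to
# stationarity, replicates from a fixed snapshot, and paired removal
# (treatment/control) experiments under common random numbers.

KIND_LEVELS <- c("birth", "death", "move", "consume", "infect")

empty_log <- function() {
  data.frame(time = numeric(0), kind = character(0), actor = integer(0),
             object = integer(0), x = numeric(0), y = numeric(0),
             species = integer(0), parent = integer(0), rtype = integer(0))
}

as_log_df <- function(lg) {
  data.frame(time = lg$time, kind = KIND_LEVELS[lg$kind], actor = lg$actor,
             object = lg$object, x = lg$x, y = lg$y, species = lg$species,
             parent = lg$parent, rtype = lg$rtype)
}

#' Snapshot constructor
#'
#' A snapshot is a frozen metacommunity state: the clock, the live
#' individuals and the unconsumed resource particles. It carries no RNG
#' state, so replicate runs from the same snapshot differ only via their
#' seeds.
#'
#' @param time clock value.
#' @param individuals data frame with columns `id`, `species` (within-guild
#'   index), `guild` (0 consumer / 1 parasite), `x`, `y`, `host_id`,
#'   `born_at`.
#' @param resources data frame with columns `pid`, `prtype`, `px`, `py`,
#'   `pcreated`.
#' @param next_id,next_pid id counters for individuals and particles.
#' @return object of class `snapshot`.
#' @export
snapshot <- function(time, individuals, resources, next_id, next_pid) {
  stopifnot(all(c("id", "species", "guild", "x", "y", "host_id", "born_at")
                %in% names(individuals)),
            !anyDuplicated(individuals$id))
  structure(list(time = time, individuals = individuals,
                 resources = resources,
                 next_id = as.integer(next_id),
                 next_pid = as.integer(next_pid)),
            class = "snapshot")
}

#' @export
print.snapshot <- function(x, ...) {
  nc <- sum(x$individuals$guild == 0)
  np <- sum(x$individuals$guild == 1)
  cat("<snapshot> t =", format(x$time, digits = 4), "|", nc, "consumers,",
      np, "parasites,", nrow(x$resources), "resource particles\n")
  invisible(x)
}

state_for_engine <- function(snap) {
  i <- snap$individuals
  list(time = snap$time,
       id = as.integer(i$id), species = as.integer(i$species),
       guild = as.integer(i$guild),
       host_id = as.integer(i$host_id),
       x = as.numeric(i$x), y = as.numeric(i$y),
       born_at = as.numeric(i$born_at),
       next_id = snap$next_id,
       pid = as.integer(snap$resources$pid),
       prtype = as.integer(snap$resources$prtype),
       px = as.numeric(snap$resources$px),
       py = as.numeric(snap$resources$py),
       pcreated = as.numeric(snap$resources$pcreated),
       next_pid = snap$next_pid)
}

result_to_snapshot <- function(res) {
  ind <- as.data.frame(res$individuals)
  live <- ind[is.na(ind$died_at), c("id", "species", "guild", "x", "y",
                                    "host_id", "born_at")]
  rownames(live) <- NULL
  snapshot(res$time, live, as.data.frame(res$particles),
           res$next_id, res$next_pid)
}

#' Seed an initial metacommunity state
#'
#' Consumers are placed uniformly at random (inside patches for patchy
#' landscapes, where the matrix is unhabitable); an initial crop of resource
#' particles is drawn from the landscape's stationary stock; optionally a
#' fraction of hosts start infected.
#'
#' @param config a [sim_config()].
#' @param n_per_species initial consumer individuals per species.
#' @param infected_frac initial fraction of hosts carrying a parasite
#'   (rate-model with parasites only).
#' @param seed integer.
#' @return a [snapshot()] at time 0.
#' @export
init_state <- function(config, n_per_species = 20L, infected_frac = 0.3,
                       seed = 1L) {
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  rates <- config$rates; ls <- config$landscape
  S <- nrow(rates$usage)
  n <- S * n_per_species
  if (ls$kind == "patchy") {
    p <- ls$patches
    pick <- sample.int(nrow(p), n, replace = TRUE)
    r <- p$radius[pick] * sqrt(runif(n)); th <- 2 * pi * runif(n)
    x <- wrap01(p$cx[pick] + r * cos(th))
    y <- wrap01(p$cy[pick] + r * sin(th))
  } else {
    x <- runif(n); y <- runif(n)
  }
  ind <- data.frame(id = seq_len(n),
                    species = rep(seq_len(S), each = n_per_species),
                    guild = 0L, x = x, y = y, host_id = NA_integer_,
                    born_at = 0)
  next_id <- n + 1L
  if (rates$parasites && infected_frac > 0) {
    Sp <- nrow(rates$host_range)
    hosts <- which(runif(n) < infected_frac)
    newp <- list()
    for (h in hosts) {
      ok <- which(rates$host_range[, ind$species[h]] > 0)
      if (length(ok) == 0) next
      psp <- ok[sample.int(length(ok), 1L)]
      newp[[length(newp) + 1L]] <- data.frame(
        id = next_id, species = psp, guild = 1L,
        x = ind$x[h], y = ind$y[h], host_id = ind$id[h], born_at = 0)
      next_id <- next_id + 1L
    }
    if (length(newp)) ind <- rbind(ind, do.call(rbind, newp))
  }
  # initial particle crop ~ stationary stock of the production/expiry balance
  part <- sample_resource_events(config$landscape, config$rates$tau_R,
                                 seed = expand_seeds(seed, 1L))
  resources <- data.frame(pid = part$id, prtype = part$rtype,
                          px = part$x, py = part$y, pcreated = 0)
  snapshot(0, ind, resources, next_id, nrow(part) + 1L)
}

#' Run the stochastic simulation engine
#'
#' Exact continuous-time simulation of the metacommunity from a snapshot.
#'
#' @param snap starting [snapshot()].
#' @param config a [sim_config()].
#' @param horizon duration (> 0, or 0 for a no-op).
#' @param seed integer seed; identical seeds give identical runs.
#' @param log_moves record move events (needed for space-use estimation and
#'   log replay; off for speed when only births matter).
#' @param record_interactions collect the set of interacting pairs as events
#'   happen (consumption witnessed in-range by a same-resource user;
#'   infection; infection witnessed in-range by a same-host-range parasite).
#' @param max_events guard against runaway rates.
#' @return list with `snapshot` (final state), `log` (event data frame with
#'   columns time, kind, actor, object, x, y, species, parent, rtype),
#'   `pairs` (2-column matrix of interacting ids), `extinct` flag,
#'   `individuals` (full table including the dead, with `parent_id` and
#'   `died_at`).
#' @export
sim_run <- function(snap, config, horizon, seed = 1L, log_moves = TRUE,
                    record_interactions = TRUE, max_events = 5e6) {
  stopifnot(inherits(snap, "snapshot"), inherits(config, "sim_config"),
            horizon >= 0)
  if (horizon == 0) {
    return(list(snapshot = snap, log = empty_log(),
                pairs = matrix(integer(0), 0, 2), extinct = FALSE,
                individuals = snap$individuals))
  }
  res <- engine_run_cpp(state_for_engine(snap), unclass(config$rates),
                        config$comps, horizon, as.numeric(seed), log_moves,
                        record_interactions, max_events)
  lg <- as_log_df(res$log)
  lg <- lg[order(lg$time, method = "radix"), , drop = FALSE]
  rownames(lg) <- NULL
  list(snapshot = result_to_snapshot(res), log = lg, pairs = res$pairs,
       extinct = res$extinct,
       individuals = as.data.frame(res$individuals))
}

#' Abundance trajectory implied by an event log
#' @param log event data frame from [sim_run()].
#' @param n0 abundance at the start of the log.
#' @param t0 log start time.
#' @return data frame (`time`, `abundance`) with one row per birth/death.
#' @export
abundance_series <- function(log, n0, t0 = 0) {
  bd <- log[log$kind %in% c("birth", "death"), , drop = FALSE]
  step <- ifelse(bd$kind == "birth", 1L, -1L)
  data.frame(time = c(t0, bd$time), abundance = n0 + c(0L, cumsum(step)))
}

#' Burn a configuration in to (statistical) stationarity
#'
#' Runs the model from a fresh initial state and accepts the end state as a
#' stationary snapshot when an OLS slope test on the total-abundance series
#' over the last half of the burn-in is non-significant (|t| < 2). If the
#' test fails the burn-in is extended, up to `t_max`.
#'
#' @param config a [sim_config()].
#' @param seed integer.
#' @param t_burn initial burn-in duration; `t_max` the cap.
#' @param n_per_species,infected_frac forwarded to [init_state()].
#' @param min_species snapshot must retain at least this many consumer
#'   species, else an error is thrown.
#' @return a [snapshot()] with attributes `slope_t` (final t-statistic) and
#'   `burn_time`.
#' @export
run_to_stationarity <- function(config, seed = 1L, t_burn = 10, t_max = 40,
                                n_per_species = 25L, infected_frac = 0.3,
                                min_species = 2L) {
  snap <- init_state(config, n_per_species, infected_frac, seed)
  n <- nrow(snap$individuals)
  t_done <- 0
  seeds <- expand_seeds(seed, 64L, offset = 1000L)
  chunk <- 0L
  series <- data.frame(time = 0, abundance = n)
  repeat {
    chunk <- chunk + 1L
    step <- if (t_done == 0) t_burn else t_burn / 2
    run <- sim_run(snap, config, step, seed = seeds[chunk],
                   log_moves = FALSE, record_interactions = FALSE)
    if (run$extinct) stop("metacommunity went extinct during burn-in")
    ab <- abundance_series(run$log, n, t0 = t_done)
    series <- rbind(series, ab[-1, ])
    snap <- run$snapshot
    n <- nrow(snap$individuals)
    t_done <- t_done + step
    # evaluate the (piecewise-constant) abundance at a coarse grid of times:
    # testing every event would pseudo-replicate an autocorrelated series
    grid_t <- seq(t_done / 2, t_done, length.out = 24L)
    ab_t <- series$abundance[findInterval(grid_t, series$time)]
    tstat <- if (length(unique(ab_t)) < 3) Inf else {
      fit <- summary(lm(ab_t ~ grid_t))
      fit$coefficients["grid_t", "t value"]
    }
    if (is.finite(tstat) && abs(tstat) < 2) break
    if (t_done >= t_max)
      stop("no stationarity by t = ", t_max, " (slope t = ",
           format(tstat, digits = 3), ")")
  }
  live_sp <- unique(snap$individuals$species[snap$individuals$guild == 0])
  if (length(live_sp) < min_species)
    stop("snapshot retains only ", length(live_sp), " consumer species")
  attr(snap, "slope_t") <- tstat
  attr(snap, "burn_time") <- t_done
  snap
}

#' Run one replicate from a fixed snapshot
#'
#' @inheritParams sim_run
#' @return as [sim_run()]; snapshot individual ids are retained in the log
#'   so per-individual statistics can be pooled across replicates.
#' @export
run_replicate <- function(snap, config, horizon, seed,
                          log_moves = TRUE, record_interactions = TRUE) {
  sim_run(snap, config, horizon, seed, log_moves, record_interactions)
}

#' Remove an individual from a snapshot
#'
#' If the focal is a consumer carrying a parasite, the parasite is removed
#' with it (parasites are not free-living). Removing a parasite leaves its
#' host susceptible again.
#'
#' @param snap a [snapshot()].
#' @param focal individual id present in the snapshot.
#' @return the reduced snapshot.
#' @export
remove_individual <- function(snap, focal) {
  i <- snap$individuals
  if (!focal %in% i$id) stop("focal id ", focal, " not in snapshot")
  drop <- i$id == focal
  # parasite riding the focal host goes too
  drop <- drop | (i$guild == 1L & !is.na(i$host_id) & i$host_id == focal)
  snap$individuals <- i[!drop, , drop = FALSE]
  rownames(snap$individuals) <- NULL
  snap
}

#' Paired removal experiment (control vs treatment)
#'
#' Control: a replicate from the intact snapshot. Treatment: the identical
#' run with the focal individual removed before time zero. Both runs use the
#' same seed (common random numbers), so with a hazard-free focal the two
#' logs are identical.
#'
#' @param snap a [snapshot()]; `focal` id in it.
#' @param config a [sim_config()]; `horizon`, `seed` as in [sim_run()].
#' @param log_moves forwarded (off by default: only births are needed for
#'   offspring counting).
#' @return list with `control` and `treatment` run results.
#' @export
removal_replicate <- function(snap, config, focal, horizon, seed,
                              log_moves = FALSE) {
  ctrl <- run_replicate(snap, config, horizon, seed, log_moves = log_moves,
                        record_interactions = FALSE)
  trt <- run_replicate(remove_individual(snap, focal), config, horizon,
                       seed, log_moves = log_moves,
                       record_interactions = FALSE)
  list(control = ctrl, treatment = trt)
}

#' Count offspring of an individual in an event log
#'
#' @param log event data frame.
#' @param id parent individual id.
#' @param window optional `c(t_min, t_max)` restriction.
#' @return number of birth events parented by `id`.
#' @export
offspring_count <- function(log, id, window = NULL) {
  k <- log$kind == "birth" & !is.na(log$parent) & log$parent == id
  if (!is.null(window)) k <- k & log$time >= window[1] & log$time <= window[2]
  sum(k)
}

# offspring counts for many parents at once (fast path)
offspring_table <- function(log, ids) {
  b <- log[log$kind == "birth" & !is.na(log$parent), "parent"]
  cnt <- table(factor(b, levels = ids))
  as.integer(cnt)
}

#' Map every individual of a run to its snapshot ancestor
#'
#' Individuals born during a replicate are credited to the snapshot
#' individual their lineage descends from; snapshot individuals map to
#' themselves.
#'
#' @param individuals full individual table from [sim_run()] (`id`,
#'   `parent_id`, ...).
#' @param snapshot_ids ids present in the starting snapshot.
#' @return named integer vector: ancestor id for every id in `individuals`.
#' @export
snapshot_ancestor <- function(individuals, snapshot_ids) {
  ord <- order(individuals$id)
  id <- individuals$id[ord]
  par <- individuals$parent_id[ord]
  pidx <- match(par, id) # parents are born before children: pidx < k
  anc <- integer(length(id))
  root <- id %in% snapshot_ids
  for (k in seq_along(id)) {
    anc[k] <- if (root[k]) id[k]
      else if (is.na(pidx[k])) NA_integer_
      else anc[pidx[k]]
  }
  names(anc) <- id
  anc
}

#' Offspring produced by each snapshot lineage during a run
#'
#' Births are credited to the snapshot ancestor of the parent, so the count
#' for id j is the total number of births in j's lineage over the run.
#'
#' @param run a [sim_run()] result.
#' @param snapshot_ids snapshot individual ids to tally for.
#' @param t0 run start time (births at or before it are ignored).
#' @return integer vector of lineage birth counts, one per `snapshot_ids`.
#' @export
lineage_offspring <- function(run, snapshot_ids, t0) {
  ind <- run$individuals
  anc <- snapshot_ancestor(ind, snapshot_ids)
  ids_sorted <- as.integer(names(anc))
  born <- ind$born_at > t0 & !is.na(ind$parent_id)
  credit <- anc[match(ind$parent_id[born], ids_sorted)]
  tabulate(match(credit, snapshot_ids), nbins = length(snapshot_ids))
}

# map an interacting-pair matrix to snapshot-ancestor pairs (set semantics;
# self-pairs after mapping are dropped)
pairs_to_ancestors <- function(pairs, individuals, snapshot_ids) {
  if (nrow(pairs) == 0) return(pairs)
  anc <- snapshot_ancestor(individuals, snapshot_ids)
  ids_sorted <- as.integer(names(anc))
  a <- anc[match(pairs[, 1], ids_sorted)]
  b <- anc[match(pairs[, 2], ids_sorted)]
  keep <- !is.na(a) & !is.na(b) & a != b
  m <- cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  unique(m)
}
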