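# End-to-end orchestration: a scenario = landscape kind x dispersal regime
# (x optional parasites). For each scenario the pipeline burns in to a
# stationary snapshot, estimates the three adjacency matrices from
# replicates of that snapshot, delineates local communities by Leiden, and
# derives modularity, cross-modularity and distance-decay summaries.

#' Run one metacommunity scenario end to end
#'
#' @param kind landscape kind (`"homogeneous"`, `"heterogeneous"`,
#'   `"patchy"`).
#' @param dispersal `"short"`, `"long"` or `"mixed"`.
#' @param parasites include the host-parasite layer?
#' @param seed master seed; every stage derives sub-seeds from it.
#' @param n_rep_shared replicates used for the space-use and interaction
#'   estimates (both are read off the same runs).
#' @param n_rep_influence paired replicates per focal for the influence
#'   estimate.
#' @param horizon replicate duration (time units).
#' @param G space-use grid cells per side.
#' @param n_per_species initial consumers per species for the burn-in.
#' @param t_burn,t_max burn-in length and cap forwarded to
#'   [run_to_stationarity()].
#' @param restarts Leiden restarts.
#' @param rates_args extra arguments forwarded to [default_rates()].
#' @param landscape_args extra arguments forwarded to [make_landscape()].
#' @param decay_bins distance bins for [distance_decay()].
#' @param influence_denoise `"none"` or `"soft"`, forwarded to
#'   [influence_adjacency()]. With the engine's per-entity random streams,
#'   paired runs only differ inside the causal cone of the removal, so the
#'   raw mean differences are already spatially localised; `"none"` is the
#'   default.
#' @return list with the snapshot, the three [adjacency_matrix()]s, the
#'   [cross_modularity_report()], and per-definition distance-decay curves.
#' @export
run_scenario <- function(kind, dispersal, parasites = FALSE, seed = 1L,
                         n_rep_shared = 60L, n_rep_influence = 20L,
                         horizon = 3, G = 32L, n_per_species = 25L,
                         t_burn = 10, t_max = 40,
                         restarts = 10L, rates_args = list(),
                         landscape_args = list(), decay_bins = 20L,
                         influence_denoise = c("none", "soft")) {
  influence_denoise <- match.arg(influence_denoise)
  landscape <- do.call(make_landscape,
                       c(list(kind = kind, seed = seed), landscape_args))
  rates <- do.call(default_rates,
                   c(list(dispersal = dispersal, parasites = parasites),
                     rates_args))
  config <- sim_config(landscape, rates)
  snap <- run_to_stationarity(config, seed = seed, t_burn = t_burn,
                              t_max = t_max,
                              n_per_species = n_per_species)
  ids <- snap$individuals$id
  # shared replicates: space use + interactions from the same runs
  seeds <- expand_seeds(seed, n_rep_shared, offset = 5000L)
  runs <- vector("list", n_rep_shared)
  pair_sets <- vector("list", n_rep_shared)
  for (r in seq_len(n_rep_shared)) {
    run <- run_replicate(snap, config, horizon, seeds[r],
                         log_moves = TRUE, record_interactions = TRUE)
    pair_sets[[r]] <- pairs_to_ancestors(run$pairs, run$individuals, ids)
    runs[[r]] <- list(log = run$log)
  }
  sf <- space_use_fields(runs, snap, horizon, G)
  seen <- sf$alive_time > 0
  P_space <- space_adjacency(sf$fields, sf$alive_time)
  P_int <- interaction_adjacency(pair_sets, ids[seen])
  P_inf <- influence_adjacency(snap, config, horizon, n_rep_influence,
                               seed = expand_seeds(seed, 1L,
                                                   offset = 9000L),
                               denoise = influence_denoise)
  if (!all(seen)) {
    w <- P_inf$weights[seen, seen, drop = FALSE]
    P_inf <- adjacency_matrix(w, "influence")
  }
  mats <- list(space = P_space, interaction = P_int, influence = P_inf)
  report <- cross_modularity_report(mats, seed = seed, restarts = restarts)
  decay <- lapply(report$partitions, function(p)
    distance_decay(p, snap, rates$niche, n_bins = decay_bins))
  list(kind = kind, dispersal = dispersal, parasites = parasites,
       seed = seed, landscape = landscape, rates = rates, config = config,
       snapshot = snap, fields = sf, mats = mats, report = report,
       decay = decay)
}

#' Distance decay of local-community co-membership
#'
#' For consumer pairs, the proportion sharing a community label, by
#' toroidal snapshot distance bin and niche-overlap class.
#'
#' @param part a [partition()] covering the snapshot consumers.
#' @param snap the [snapshot()] (pair distances use snapshot locations).
#' @param niche binary usage matrix for the overlap classes.
#' @param n_bins equal-width bins from 0 to half the domain diagonal.
#' @return data frame (`bin_lo`, `bin_hi`, `bin_mid`, `class`, `prop`,
#'   `n_pairs`); combinations with no pairs carry `NA`, not 0.
#' @export
distance_decay <- function(part, snap, niche, n_bins = 20L) {
  cons <- snap$individuals[snap$individuals$guild == 0L, ]
  lab <- part$labels[match(as.character(cons$id), part$ids)]
  keep <- !is.na(lab)
  cons <- cons[keep, ]; lab <- lab[keep]
  n <- nrow(cons)
  if (n < 2) stop("no consumer pairs to bin")
  S <- nrow(niche)
  cls_sp <- matrix("", S, S)
  for (i in seq_len(S)) for (j in seq_len(S))
    cls_sp[i, j] <- niche_overlap_class(i, j, niche)
  D <- torus_dist_matrix(cons$x, cons$y)
  iu <- which(upper.tri(D), arr.ind = TRUE)
  d <- D[iu]
  same <- lab[iu[, 1]] == lab[iu[, 2]]
  cls <- cls_sp[cbind(cons$species[iu[, 1]], cons$species[iu[, 2]])]
  max_d <- sqrt(2) / 2
  edges <- seq(0, max_d, length.out = n_bins + 1)
  bin <- pmin(findInterval(d, edges, rightmost.closed = TRUE), n_bins)
  out <- expand.grid(bin = seq_len(n_bins),
                     class = c("none", "partial", "complete"),
                     stringsAsFactors = FALSE)
  out$bin_lo <- edges[out$bin]
  out$bin_hi <- edges[out$bin + 1]
  out$bin_mid <- (out$bin_lo + out$bin_hi) / 2
  out$prop <- NA_real_
  out$n_pairs <- 0L
  for (r in seq_len(nrow(out))) {
    sel <- bin == out$bin[r] & cls == out$class[r]
    out$n_pairs[r] <- sum(sel)
    if (out$n_pairs[r] > 0) out$prop[r] <- mean(same[sel])
  }
  if (all(out$n_pairs == 0)) stop("no pairs in any distance bin")
  out[, c("bin_lo", "bin_hi", "bin_mid", "class", "prop", "n_pairs")]
}

#' Case study 1: consumer-resource scenario grid
#'
#' Runs the 3 landscapes x 3 dispersal regimes grid (optionally restricted)
#' and tabulates per scenario x definition the modularity, community count
#' and cross-modularity matrix, plus means and standard errors across
#' scenarios. A scenario failing stationarity is recorded as missing and
#' the grid continues.
#'
#' @param seed master seed (each scenario derives its own).
#' @param kinds,dispersals scenario axes.
#' @param ... forwarded to [run_scenario()].
#' @return list with `table` (long data frame), `cross` (named list of
#'   Q_AB matrices), `decay` (long data frame over scenarios), `summary`
#'   (mean and SE of Q per definition across scenarios), `failed`.
#' @export
run_case_study_1 <- function(seed = 1L,
                             kinds = c("homogeneous", "heterogeneous",
                                       "patchy"),
                             dispersals = c("short", "long", "mixed"),
                             ...) {
  rows <- list(); cross <- list(); decay <- list(); failed <- character(0)
  k <- 0L
  for (kind in kinds) for (disp in dispersals) {
    k <- k + 1L
    name <- paste(kind, disp, sep = "_")
    sc <- tryCatch(
      run_scenario(kind, disp, parasites = FALSE,
                   seed = expand_seeds(seed, 1L, offset = 100L * k), ...),
      error = function(e) e)
    if (inherits(sc, "error")) {
      failed <- c(failed, paste0(name, ": ", conditionMessage(sc)))
      next
    }
    for (def in names(sc$report$Q)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = name, kind = kind, dispersal = disp, definition = def,
        Q = unname(sc$report$Q[def]),
        n_communities =
          length(unique(sc$report$partitions[[def]]$labels)))
      dd <- sc$decay[[def]]
      dd$scenario <- name; dd$definition <- def
      decay[[length(decay) + 1L]] <- dd
    }
    cross[[name]] <- sc$report$Q_AB
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(tab, tab$definition), function(d)
    data.frame(definition = d$definition[1], mean_Q = mean(d$Q),
               se_Q = sd(d$Q) / sqrt(nrow(d)), n = nrow(d))))
  rownames(summ) <- NULL
  list(table = tab, cross = cross, decay = do.call(rbind, decay),
       summary = summ, failed = failed)
}

#' Project a partition onto additional individuals
#'
#' Individuals already labelled keep their label; an unlabelled parasite
#' inherits its host's label; an unlabelled host inherits its parasite's
#' label; anything else takes the label of the nearest labelled individual
#' (toroidal snapshot distance).
#'
#' @param part a [partition()] over a subset of the snapshot.
#' @param snap the [snapshot()].
#' @param target_ids ids the returned partition must cover.
#' @return a [partition()] over `target_ids` (Q not carried over).
#' @export
project_partition <- function(part, snap, target_ids) {
  ind <- snap$individuals
  lab <- part$labels[match(as.character(target_ids), part$ids)]
  rows <- match(target_ids, ind$id)
  # parasite -> host label / host -> own parasite's label
  for (w in which(is.na(lab))) {
    r <- rows[w]
    if (ind$guild[r] == 1L) {
      lab[w] <- part$labels[match(as.character(ind$host_id[r]), part$ids)]
    } else {
      para <- ind$id[ind$guild == 1L & !is.na(ind$host_id) &
                       ind$host_id == ind$id[r]]
      if (length(para))
        lab[w] <- part$labels[match(as.character(para[1]), part$ids)]
    }
  }
  if (anyNA(lab)) {
    src_rows <- match(as.numeric(part$ids), ind$id)
    for (w in which(is.na(lab))) {
      r <- rows[w]
      dd <- torus_dist(ind$x[r], ind$y[r], ind$x[src_rows],
                       ind$y[src_rows])
      lab[w] <- part$labels[which.min(dd)]
    }
  }
  partition(target_ids, lab, source = part$source)
}

subset_adjacency <- function(adj, ids) {
  keep <- adj$ids %in% as.character(ids)
  adjacency_matrix(adj$weights[keep, keep, drop = FALSE], adj$definition)
}

#' Delineations from taxon subsets of one host-parasite scenario
#'
#' Given a parasite-enabled [run_scenario()] result, delineates local
#' communities from three data subsets (hosts only, parasites only, both)
#' for every definition, and computes the cross-modularities between
#' subsets, projecting partitions across subsets via host-parasite links
#' (see [project_partition()]).
#'
#' @param sc a [run_scenario()] result with `parasites = TRUE`.
#' @param seed seed for the subset partitioning.
#' @return list with `subset_Q` (subset x definition table), `partitions`
#'   and `mats` (nested by definition then subset), and `cross_subsets`
#'   (per definition, Q_AB over subsets: rows = matrix subset A, cols =
#'   partition subset B).
#' @export
taxon_subset_report <- function(sc, seed = 1L) {
  snap <- sc$snapshot
  ind <- snap$individuals
  subsets <- list(hosts = ind$id[ind$guild == 0L],
                  parasites = ind$id[ind$guild == 1L],
                  both = ind$id)
  defs <- names(sc$mats)
  subset_Q <- list(); parts <- list(); mats <- list()
  for (def in defs) {
    for (ss in names(subsets)) {
      idset <- intersect(as.numeric(sc$mats[[def]]$ids), subsets[[ss]])
      M <- subset_adjacency(sc$mats[[def]], idset)
      p <- leiden_partition(M, seed = expand_seeds(seed, 1L, offset = 7L))
      mats[[def]][[ss]] <- M
      parts[[def]][[ss]] <- p
      subset_Q[[length(subset_Q) + 1L]] <- data.frame(
        definition = def, subset = ss, Q = p$Q,
        n_communities = length(unique(p$labels)))
    }
  }
  cross_subsets <- list()
  for (def in defs) {
    cm <- matrix(NA_real_, 3, 3,
                 dimnames = list(names(subsets), names(subsets)))
    for (a in names(subsets)) for (b in names(subsets)) {
      pb <- project_partition(parts[[def]][[b]], snap,
                              as.numeric(mats[[def]][[a]]$ids))
      cm[a, b] <- cross_modularity(mats[[def]][[a]], parts[[def]][[a]], pb)
    }
    cross_subsets[[def]] <- cm
  }
  list(subset_Q = do.call(rbind, subset_Q), partitions = parts,
       mats = mats, cross_subsets = cross_subsets)
}

#' Case study 2: host-parasite model and taxon subsets
#'
#' Runs the intermediate scenario (continuous heterogeneous landscape,
#' mixed dispersal) with and without parasites, then analyses the parasite
#' run by taxon subset via [taxon_subset_report()].
#'
#' @param seed master seed.
#' @param ... forwarded to [run_scenario()].
#' @return list with `baseline_Q` (consumer modularity without parasites),
#'   `hosts_Q` (consumer-data modularity with parasites in the system),
#'   `subset_Q` (subset x definition modularity table), `cross_subsets`
#'   (per definition, Q_AB over subsets A, B), `scenario` objects.
#' @export
run_case_study_2 <- function(seed = 1L, ...) {
  base <- run_scenario("heterogeneous", "mixed", parasites = FALSE,
                       seed = seed, ...)
  para <- run_scenario("heterogeneous", "mixed", parasites = TRUE,
                       seed = seed, ...)
  rep_ <- taxon_subset_report(para, seed = seed)
  defs <- names(para$mats)
  list(baseline_Q = base$report$Q,
       hosts_Q = vapply(defs, function(d) rep_$partitions[[d]]$hosts$Q,
                        numeric(1)),
       subset_Q = rep_$subset_Q,
       cross_subsets = rep_$cross_subsets,
       baseline = base, parasite = para,
       subset_partitions = rep_$partitions, subset_mats = rep_$mats)
}
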