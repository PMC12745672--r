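test_that("space-use sojourn accumulation matches hand computation", {
  # one individual, horizon 3: sits at cell A for 2 units, moves to B for 1
  ind <- data.frame(id = 1L, species = 1L, guild = 0L, x = 0.1, y = 0.1,
                    host_id = NA_integer_, born_at = 0)
  script <- data.frame(time = 2, kind = "move", actor = 1L,
                       x = 0.9, y = 0.9, species = 1L)
  toy <- make_toy_eventlog(script, ind)
  f <- estimate_space_use(list(list(log = toy$log)), toy$snapshot,
                          id = 1L, horizon = 3, G = 4L)
  cellA <- localcomm:::grid_cell(0.1, 0.1, 4L)
  cellB <- localcomm:::grid_cell(0.9, 0.9, 4L)
  expect_equal(f[cellA], 2 / 3)
  expect_equal(f[cellB], 1 / 3)
  expect_equal(sum(f), 1)

  # an individual that never moves concentrates all weight in its cell
  quiet <- make_toy_eventlog(script[0, ], ind)
  f0 <- estimate_space_use(list(list(log = quiet$log)), quiet$snapshot,
                           id = 1L, horizon = 3, G = 4L)
  expect_equal(unname(f0[cellA]), 1)
  expect_error(estimate_space_use(list(list(log = quiet$log)),
                                  quiet$snapshot, id = 99L, horizon = 3),
               "unknown")
})

test_that("space-use fields from engine runs are proper distributions", {
  cfg <- sim_config(make_landscape("homogeneous", seed = 1),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 10L, seed = 2)
  runs <- lapply(1:3, function(s)
    list(log = run_replicate(snap, cfg, 2, seed = s)$log))
  sf <- space_use_fields(runs, snap, horizon = 2, G = 16L)
  seen <- sf$alive_time > 0
  expect_true(any(seen))
  sums <- rowSums(sf$fields[seen, , drop = FALSE])
  expect_equal(unname(sums), rep(1, sum(seen)), tolerance = 1e-9)
  expect_true(all(sf$fields >= 0))
})

test_that("Bhattacharyya overlap reproduces the worked values", {
  u <- c(0.25, 0.25, 0.25, 0.25)
  expect_equal(bhattacharyya_overlap(u, u), 1)
  expect_equal(bhattacharyya_overlap(c(1, 0), c(0, 1)), 0)
  expect_equal(bhattacharyya_overlap(c(0.5, 0.5), c(1, 0)), sqrt(0.5),
               tolerance = 1e-12)
  expect_error(bhattacharyya_overlap(c(1, 0), c(1, 0, 0)), "mismatch")
})

test_that("space adjacency equals pairwise Bhattacharyya coefficients", {
  set.seed(3)
  f <- matrix(runif(5 * 9), 5, 9)
  f <- f / rowSums(f)
  rownames(f) <- paste(1:5)
  adj <- space_adjacency(f)
  for (i in 1:5) for (j in 1:5) {
    want <- if (i == j) 1 else bhattacharyya_overlap(f[i, ], f[j, ])
    expect_equal(adj$weights[i, j], want, tolerance = 1e-10)
  }
  expect_true(all(adj$weights >= 0 & adj$weights <= 1))
  expect_identical(adj$weights, t(adj$weights))
})

test_that("interaction detection applies the event-time rules", {
  u <- tiny_niche() # sp1, sp2 share type 1; sp3 uses type 2 only
  rt <- default_rates(niche = u, dispersal = "short", r_c = 0.05)
  # consumers at known positions; one consume event of a type-1 particle
  # within r_c of individual 2 (same usable type) but far from 3
  ind <- data.frame(id = 1:3, species = 1:3, guild = 0L,
                    x = c(0.50, 0.52, 0.90), y = c(0.50, 0.50, 0.90),
                    host_id = NA_integer_, born_at = 0)
  script <- data.frame(time = 1, kind = "consume", actor = 1L, object = 11L,
                       x = 0.51, y = 0.50, species = 1L, rtype = 1L)
  toy <- make_toy_eventlog(script, ind)
  pairs <- detect_interactions(toy$log, toy$snapshot, rt)
  expect_equal(nrow(pairs), 1)
  expect_equal(sort(pairs[1, ]), c(1, 2))
  # no other usable-type individual in range: no pair
  script$x <- 0.7 # particle out of everyone else's radius
  toy2 <- make_toy_eventlog(script, ind)
  expect_equal(nrow(detect_interactions(toy2$log, toy2$snapshot, rt)), 0)
  # an empty script yields no interactions at all
  toy3 <- make_toy_eventlog(script[0, ], ind)
  expect_equal(nrow(detect_interactions(toy3$log, toy3$snapshot, rt)), 0)
})

test_that("log replay reproduces the engine's native interaction pairs", {
  cfg <- sim_config(make_landscape("homogeneous", seed = 4),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 15L, seed = 3)
  run <- sim_run(snap, cfg, horizon = 2, seed = 9, log_moves = TRUE,
                 record_interactions = TRUE)
  replay <- detect_interactions(run$log, snap, cfg$rates)
  canon <- function(m) {
    if (nrow(m) == 0) return(character(0))
    sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  expect_gt(nrow(run$pairs), 10)
  expect_identical(canon(replay), canon(run$pairs))
})

test_that("interaction adjacency is the proportion of replicates", {
  ids <- c(101L, 102L, 103L)
  sets <- c(replicate(3, cbind(101L, 102L), simplify = FALSE),
            replicate(7, matrix(integer(0), 0, 2), simplify = FALSE))
  adj <- interaction_adjacency(sets, ids)
  expect_equal(adj$weights["101", "102"], 0.3)
  expect_equal(adj$weights["102", "101"], 0.3)
  expect_equal(sum(adj$weights), 0.6)
  expect_true(all(adj$weights >= 0 & adj$weights <= 1))
})

test_that("removing an uncoupled focal leaves influence at exactly zero", {
  rt <- default_rates(niche = tiny_niche(), dispersal = "short")
  rt$m[1] <- 0; rt$d[1] <- 0; rt$r_c[1] <- 0 # species 1: no hazards at all
  cfg <- sim_config(make_landscape("homogeneous", n_types = 2L,
                                   total_rate = 150, seed = 3), rt)
  snap <- toy_snapshot(x = c(0.2, 0.5, 0.62, 0.85),
                       y = c(0.2, 0.5, 0.55, 0.85),
                       species = c(1L, 2L, 2L, 3L))
  adj <- influence_adjacency(snap, cfg, horizon = 3, n_rep = 5L, seed = 2,
                             focal_ids = 1L, denoise = "none")
  expect_identical(unname(adj$weights["1", ]), rep(0, 4))
})

test_that("competitive release yields positive influence at 3 SE", {
  # two strict competitors crowded onto one scarce resource
  u <- matrix(1L, 1, 1, dimnames = list("sp1", "rt1"))
  rt <- default_rates(niche = u, dispersal = "short", sigma_short = 0.02,
                      m = 1, d = 0.4, r_c = 0.2, b = 1, contact = 200,
                      tau_R = 2)
  cfg <- sim_config(make_landscape("homogeneous", n_types = 1L,
                                   total_rate = 4, seed = 2), rt)
  snap <- toy_snapshot(x = c(0.5, 0.52), y = c(0.5, 0.5))
  n_rep <- 220L
  diffs <- vapply(seq_len(n_rep), function(r) {
    pr <- removal_replicate(snap, cfg, focal = 1L, horizon = 4,
                            seed = expand_seeds(77L, n_rep)[r])
    off <- function(run) lineage_offspring(run, snap$individuals$id, 0)[2]
    off(pr$treatment) - off(pr$control)
  }, numeric(1))
  se <- sd(diffs) / sqrt(n_rep)
  expect_gt(mean(diffs), 3 * se)
  # the estimator reports the same quantity
  adj <- influence_adjacency(snap, cfg, horizon = 4, n_rep = 50L,
                             seed = 77L, focal_ids = 1L, denoise = "none")
  expect_gt(adj$weights["1", "2"], 0)
})

test_that("a one-individual community has an empty influence field", {
  cfg <- sim_config(make_landscape("homogeneous", n_types = 1L,
                                   total_rate = 5, seed = 1),
                    default_rates(niche = matrix(1L, 1, 1)))
  snap <- toy_snapshot(x = 0.5, y = 0.5)
  adj <- influence_adjacency(snap, cfg, horizon = 1, n_rep = 2L, seed = 1)
  expect_equal(dim(adj$weights), c(1L, 1L))
  expect_equal(unname(adj$weights[1, 1]), 0)
})

test_that("the convergence controller stops and reports honestly", {
  # zero-variance estimator: converges right after the second batch
  const_step <- function(state, seeds) {
    list(state = NULL, P = matrix(1, 3, 3))
  }
  res <- run_until_converged(const_step, seed = 1, batch = 10L, tol = 0.05)
  expect_true(res$converged)
  expect_equal(res$replicates, 20L)
  expect_lt(res$deltas[length(res$deltas)], 0.05)

  # never-converging estimator hits the cap with a flag, not silence
  k <- 0
  wild_step <- function(state, seeds) {
    k <<- k + 1
    list(state = NULL, P = matrix(k %% 2, 2, 2) + diag(2))
  }
  res2 <- run_until_converged(wild_step, seed = 1, batch = 10L, tol = 0.01,
                              max_replicates = 50L)
  expect_false(res2$converged)
  expect_equal(res2$replicates, 50L)

  # halving the tolerance never uses fewer replicates (fixed scenario)
  cfg <- sim_config(make_landscape("homogeneous", seed = 1),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 5L, seed = 2)
  ids <- snap$individuals$id
  int_step <- function(state, seeds) {
    sets <- if (is.null(state)) list() else state$sets
    for (s in seeds) {
      run <- run_replicate(snap, cfg, 1, s, log_moves = FALSE)
      sets[[length(sets) + 1L]] <-
        localcomm:::filter_pairs(run$pairs, ids)
    }
    list(state = list(sets = sets),
         P = interaction_adjacency(sets, ids)$weights)
  }
  loose <- run_until_converged(int_step, seed = 3, batch = 5L, tol = 0.2,
                               max_replicates = 200L)
  tight <- run_until_converged(int_step, seed = 3, batch = 5L, tol = 0.1,
                               max_replicates = 200L)
  expect_gte(tight$replicates, loose$replicates)
})

test_that("interacting pairs overlap in space use at matched resolution", {
  cfg <- sim_config(make_landscape("heterogeneous", seed = 6),
                    default_rates(dispersal = "mixed"))
  snap <- init_state(cfg, n_per_species = 10L, seed = 2)
  ids <- snap$individuals$id
  runs <- list(); sets <- list()
  for (s in 1:10) {
    run <- run_replicate(snap, cfg, 2, seed = 100 + s, log_moves = TRUE)
    runs[[s]] <- list(log = run$log)
    sets[[s]] <- localcomm:::filter_pairs(run$pairs, ids)
  }
  sf <- space_use_fields(runs, snap, horizon = 2, G = 8L)
  adj_int <- interaction_adjacency(sets, ids)
  adj_sp <- space_adjacency(sf$fields, sf$alive_time)
  common <- intersect(adj_int$ids, adj_sp$ids)
  wi <- adj_int$weights[common, common]
  ws <- adj_sp$weights[common, common]
  expect_gt(sum(wi > 0), 0)
  expect_true(all(ws[wi > 0] > 0))
})
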