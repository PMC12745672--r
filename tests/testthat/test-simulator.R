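test_that("a system with all rates zero does nothing", {
  cfg <- sim_config(dead_landscape(), inert_rates())
  snap <- toy_snapshot(x = c(0.2, 0.7), y = c(0.3, 0.8), species = c(1, 2))
  run <- sim_run(snap, cfg, horizon = 5, seed = 1)
  expect_equal(nrow(run$log), 0)
  expect_equal(run$snapshot$individuals, snap$individuals)
  expect_false(run$extinct)
  # zero horizon is a no-op as well
  run0 <- sim_run(snap, cfg, horizon = 0, seed = 1)
  expect_equal(nrow(run0$log), 0)
})

test_that("runs are deterministic in the seed and differ across seeds", {
  cfg <- sim_config(make_landscape("homogeneous", seed = 2),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 10L, seed = 4)
  a <- sim_run(snap, cfg, horizon = 2, seed = 42)
  b <- sim_run(snap, cfg, horizon = 2, seed = 42)
  c_ <- sim_run(snap, cfg, horizon = 2, seed = 43)
  expect_identical(a$log, b$log)
  expect_identical(a$snapshot$individuals, b$snapshot$individuals)
  expect_false(identical(a$log, c_$log))
  # event times are non-decreasing and the abundance path moves by +-1
  expect_false(is.unsorted(a$log$time))
  ab <- abundance_series(a$log, nrow(snap$individuals))
  expect_true(all(abs(diff(ab$abundance)) == 1))
})

test_that("a lone mover's wrapped displacement kernel is symmetric", {
  cfg <- sim_config(dead_landscape(),
                    inert_rates(m = 4, sigma_short = 0.05))
  snap <- toy_snapshot(x = 0.5, y = 0.5)
  run <- sim_run(snap, cfg, horizon = 3000, seed = 8)
  mv <- run$log[run$log$kind == "move", ]
  expect_gt(nrow(mv), 1e4)
  pos_x <- c(0.5, mv$x); pos_y <- c(0.5, mv$y)
  wrap_step <- function(p) {
    s <- diff(p)
    s - round(s) # minimal displacement on the torus
  }
  for (s in list(wrap_step(pos_x), wrap_step(pos_y))) {
    expect_lt(abs(mean(s)), 3 * sd(s) / sqrt(length(s)))
    expect_lt(abs(sd(s) - 0.05), 0.005) # kernel scale recovered
  }
})

test_that("a lone mortal consumer lives Exp(d) on average", {
  d <- 0.7
  cfg <- sim_config(dead_landscape(), inert_rates(d = d))
  snap <- toy_snapshot(x = 0.5, y = 0.5)
  lifes <- vapply(1:400, function(s) {
    run <- sim_run(snap, cfg, horizon = 50, seed = s)
    run$log$time[run$log$kind == "death"][1]
  }, numeric(1))
  expect_false(anyNA(lifes))
  expect_lt(abs(mean(lifes) - 1 / d), 3 * (1 / d) / sqrt(400))
})

test_that("consumers only consume usable types and particles die once", {
  cfg <- sim_config(make_landscape("homogeneous", seed = 1),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 15L, seed = 2)
  run <- sim_run(snap, cfg, horizon = 3, seed = 3)
  cons <- run$log[run$log$kind == "consume", ]
  expect_gt(nrow(cons), 50)
  expect_false(anyDuplicated(cons$object) > 0)
  usage <- default_niche()
  expect_true(all(usage[cbind(cons$species, cons$rtype)] == 1))
})

test_that("offspring counting is exact on logs and conserved on runs", {
  lg <- data.frame(time = c(0.5, 1, 1.5, 2), kind = "birth",
                   actor = 5:8, object = NA, x = 0, y = 0, species = 1,
                   parent = c(1L, 1L, 2L, 1L), rtype = NA)
  expect_equal(offspring_count(lg, 1), 3)
  expect_equal(offspring_count(lg, 2), 1)
  expect_equal(offspring_count(lg, 3), 0)
  expect_equal(offspring_count(lg, 1, window = c(0, 1)), 2)
  expect_equal(offspring_count(data.frame(lg[0, ]), 1), 0)

  cfg <- sim_config(make_landscape("homogeneous", seed = 1),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 15L, seed = 2)
  run <- sim_run(snap, cfg, horizon = 3, seed = 3)
  births <- run$log[run$log$kind == "birth", ]
  per_parent <- vapply(unique(births$parent), function(id)
    offspring_count(run$log, id), numeric(1))
  expect_equal(sum(per_parent), nrow(births))
})

test_that("lineage crediting maps every newborn to a snapshot ancestor", {
  cfg <- sim_config(make_landscape("homogeneous", seed = 1),
                    default_rates())
  snap <- init_state(cfg, n_per_species = 12L, seed = 5)
  run <- sim_run(snap, cfg, horizon = 4, seed = 6)
  anc <- snapshot_ancestor(run$individuals, snap$individuals$id)
  expect_false(anyNA(anc))
  expect_true(all(anc %in% snap$individuals$id))
  # ancestors are fixed points; direct children map to their parent
  kids <- run$individuals[!is.na(run$individuals$parent_id) &
                            run$individuals$parent_id %in%
                              snap$individuals$id, ]
  expect_true(all(anc[as.character(kids$id)] == kids$parent_id))
  # lineage totals match the birth count
  lo <- lineage_offspring(run, snap$individuals$id, t0 = 0)
  expect_equal(sum(lo), sum(run$log$kind == "birth"))
})

test_that("removal experiments share randomness outside the focal's reach", {
  # focal of a species with zero hazards: control and treatment identical
  rt <- default_rates(niche = tiny_niche(), dispersal = "short")
  rt$m[1] <- 0; rt$d[1] <- 0; rt$r_c[1] <- 0
  cfg <- sim_config(make_landscape("homogeneous", n_types = 2L,
                                   total_rate = 100, seed = 3), rt)
  snap <- toy_snapshot(x = c(0.1, 0.5, 0.6, 0.9), y = c(0.1, 0.5, 0.6, 0.9),
                       species = c(1L, 2L, 2L, 3L))
  pr <- removal_replicate(snap, cfg, focal = 1, horizon = 4, seed = 7,
                          log_moves = TRUE)
  expect_identical(pr$control$log, pr$treatment$log)
  # removing an infected host removes its parasite too
  rtp <- default_rates(parasites = TRUE)
  cfgp <- sim_config(make_landscape("homogeneous", seed = 1), rtp)
  snp <- init_state(cfgp, n_per_species = 10L, infected_frac = 0.5,
                    seed = 1)
  inf_host <- snp$individuals$host_id[snp$individuals$guild == 1][1]
  red <- remove_individual(snp, inf_host)
  expect_equal(nrow(red$individuals), nrow(snp$individuals) - 2L)
  expect_error(remove_individual(snp, 999999L), "not in snapshot")
})

test_that("infection shortens host lives by the mortality increment", {
  # many hosts, half infected, no transmission: lifetimes Exp(d) vs
  # Exp(d + delta)
  rtp <- default_rates(parasites = TRUE, beta = 0, delta = 1.5,
                       par_d = 1e-9, m = 0, r_c = 0, b = 0, contact = 0)
  cfgp <- sim_config(dead_landscape(), rtp)
  n <- 120
  set.seed(1)
  ind <- data.frame(id = 1:n, species = rep(1:8, length.out = n),
                    guild = 0L, x = runif(n), y = runif(n),
                    host_id = NA_integer_, born_at = 0)
  # attach a parasite to every second host (species chosen from its range)
  paras <- lapply(seq(1, n, by = 2), function(h) {
    ok <- which(rtp$host_range[, ind$species[h]] > 0)
    data.frame(id = n + h, species = ok[1], guild = 1L,
               x = ind$x[h], y = ind$y[h], host_id = h, born_at = 0)
  })
  snap <- snapshot(0, rbind(ind, do.call(rbind, paras)),
                   data.frame(pid = integer(0), prtype = integer(0),
                              px = numeric(0), py = numeric(0),
                              pcreated = numeric(0)),
                   next_id = 3 * n, next_pid = 1L)
  run <- sim_run(snap, cfgp, horizon = 60, seed = 9)
  deaths <- run$log[run$log$kind == "death" & run$log$species <= 8, ]
  infected <- deaths$actor %in% seq(1, n, by = 2)
  t_inf <- deaths$time[infected]; t_un <- deaths$time[!infected]
  se <- sqrt(var(t_inf) / length(t_inf) + var(t_un) / length(t_un))
  expect_lt(mean(t_inf) + 3 * se, mean(t_un))
})

test_that("burn-in reaches a stationary, reproducible snapshot", {
  cfg <- sim_config(make_landscape("heterogeneous", seed = 5),
                    default_rates(dispersal = "mixed"))
  s1 <- run_to_stationarity(cfg, seed = 5)
  s2 <- run_to_stationarity(cfg, seed = 5)
  expect_identical(s1$individuals, s2$individuals)
  expect_lt(abs(attr(s1, "slope_t")), 2)
  expect_gte(length(unique(s1$individuals$species[
    s1$individuals$guild == 0])), 2)
  expect_gt(nrow(s1$individuals), 1)
})
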