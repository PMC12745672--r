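# memoized scenario batches shared by the heavier integration tests, so
# each configuration is simulated once per test session

.scenario_cache <- new.env(parent = emptyenv())

batch_settings <- list() # scenario defaults ARE the study conditions

# baseline consumer-resource runs of the reference scenario
# (heterogeneous landscape, mixed dispersal), one per seed
get_baseline_batch <- function(seeds = 41:50) {
  key <- paste0("base_", paste(range(seeds), collapse = "_"))
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- lapply(seeds, function(sd)
      do.call(run_scenario,
              c(list(kind = "heterogeneous", dispersal = "mixed",
                     seed = sd), batch_settings)))
  }
  .scenario_cache[[key]]
}

# matching host-parasite runs (same seeds, same settings)
get_parasite_batch <- function(seeds = 41:43) {
  key <- paste0("para_", paste(range(seeds), collapse = "_"))
  if (is.null(.scenario_cache[[key]])) {
    .scenario_cache[[key]] <- lapply(seeds, function(sd)
      do.call(run_scenario,
              c(list(kind = "heterogeneous", dispersal = "mixed",
                     parasites = TRUE, seed = sd), batch_settings)))
  }
  .scenario_cache[[key]]
}

# consumer-only modularity of a scenario's matrices (host submatrix)
consumer_subset_q <- function(sc, seed = 3L) {
  hosts <- sc$snapshot$individuals$id[sc$snapshot$individuals$guild == 0]
  vapply(names(sc$mats), function(d) {
    keep <- sc$mats[[d]]$ids %in% as.character(hosts)
    M <- adjacency_matrix(sc$mats[[d]]$weights[keep, keep, drop = FALSE],
                          sc$mats[[d]]$definition)
    leiden_partition(M, seed = seed)$Q
  }, numeric(1))
}
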