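two_cliques <- function(k = 4) {
  W <- matrix(0, 2 * k, 2 * k)
  W[1:k, 1:k] <- 1
  W[(k + 1):(2 * k), (k + 1):(2 * k)] <- 1
  diag(W) <- 0
  dimnames(W) <- list(paste(1:(2 * k)), paste(1:(2 * k)))
  W
}

test_that("modularity reproduces the closed-form worked values", {
  W <- two_cliques(4)
  expect_equal(modularity_q(W, rep(1, 8)), 0)
  expect_equal(modularity_q(W, rep(1:2, each = 4)), 0.5)
  # agrees with the direct double-loop evaluation on random matrices,
  # symmetric and asymmetric
  set.seed(7)
  for (rep in 1:5) {
    n <- sample(5:9, 1)
    A <- matrix(runif(n * n), n, n)
    if (rep %% 2) A <- (A + t(A)) / 2
    lab <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_q(A, lab), modularity_direct(A, lab),
                 tolerance = 1e-12)
  }
  # and with igraph's implementation on an undirected weighted graph
  set.seed(8)
  A <- matrix(runif(64), 8, 8); A <- (A + t(A)) / 2; diag(A) <- 0
  lab <- rep(1:2, each = 4)
  g <- igraph::graph_from_adjacency_matrix(A, "undirected",
                                           weighted = TRUE)
  expect_equal(modularity_q(A, lab),
               igraph::modularity(g, lab, weights = igraph::E(g)$weight),
               tolerance = 1e-12)
  expect_error(modularity_q(A, c(1, 2)), "mismatch")
  expect_error(modularity_q(-A, lab), "non-negative")
})

test_that("random relabellings of a planted matrix have mean Q near zero", {
  pl <- make_planted_adjacency(c(10, 10, 10), within = 0.8, between = 0.05,
                               noise = 0, seed = 2)
  set.seed(11)
  qs <- replicate(300, modularity_q(pl$adjacency,
                                    sample(pl$truth$labels)))
  # shuffled labels carry no structure: |mean Q| is a rounding error next
  # to the planted value (an O(1/n) negative bias is expected from the
  # squared-strength null term)
  expect_lt(abs(mean(qs)), 0.05)
  expect_gt(modularity_q(pl$adjacency, pl$truth), 10 * abs(mean(qs)))
})

test_that("Leiden recovers planted structure and attains the exhaustive
           optimum on small graphs", {
  # isolated blocks: exact recovery
  pl <- make_planted_adjacency(c(4, 4, 4), within = 0.9, between = 0,
                               noise = 0, seed = 1)
  part <- leiden_partition(pl$adjacency, seed = 5)
  expect_identical(part$labels, pl$truth$labels)
  expect_equal(length(unique(part$labels)), 3)
  # >= 2 disconnected components: Q at least that of one community
  expect_gte(part$Q, 0)
  # determinism
  expect_identical(part, leiden_partition(pl$adjacency, seed = 5))
  # exhaustive maximum over all set partitions on <= 10 nodes
  set.seed(13)
  for (rep in 1:3) {
    n <- c(7, 8, 10)[rep]
    A <- matrix(runif(n * n) * rbinom(n * n, 1, 0.5), n, n)
    A <- (A + t(A)) / 2; diag(A) <- 0
    rownames(A) <- colnames(A) <- paste(1:n)
    got <- leiden_partition(A, seed = rep, restarts = 60L)$Q
    expect_equal(got, exhaustive_best_q(A), tolerance = 1e-9)
  }
  expect_error(leiden_partition(matrix(0, 0, 0)), "empty")
})

test_that("cross-modularity is a ratio with the certified inequality", {
  pl <- make_planted_adjacency(c(4, 4, 4), within = 0.8, between = 0.1,
                               noise = 0.02, seed = 3)
  part <- leiden_partition(pl$adjacency, seed = 1)
  expect_equal(cross_modularity(pl$adjacency, part, part), 1)
  # merging two blocks: ratio matches direct formula evaluation
  merged <- partition(part$ids, ifelse(part$labels == 3, 2, part$labels))
  want <- modularity_q(pl$adjacency, merged) /
    modularity_q(pl$adjacency, part)
  expect_equal(cross_modularity(pl$adjacency, part, merged), want,
               tolerance = 1e-12)
  expect_lte(want, 1)
  # undefined denominator raises with a diagnostic
  flat <- matrix(0.5, 6, 6, dimnames = list(paste(1:6), paste(1:6)))
  one <- partition(paste(1:6), rep(1, 6))
  expect_error(cross_modularity(adjacency_matrix(flat, "interaction"),
                                one, one), "undefined")
})

test_that("nested delineations produce the expected asymmetry", {
  # fine communities (B) nested inside coarse ones (A): imposing A's
  # partition on B's matrix costs little, the reverse costs much
  n <- 16
  sub <- rep(1:4, each = 4)
  super <- rep(1:2, each = 8)
  M_B <- matrix(0.02, n, n); M_B[outer(sub, sub, "==")] <- 1
  M_A <- matrix(0.02, n, n); M_A[outer(super, super, "==")] <- 1
  diag(M_A) <- diag(M_B) <- 0
  dimnames(M_A) <- dimnames(M_B) <- list(paste(1:n), paste(1:n))
  P_A <- partition(paste(1:n), super)
  P_B <- partition(paste(1:n), sub)
  A <- adjacency_matrix(M_A, "space")
  B <- adjacency_matrix(M_B, "interaction")
  q_ab <- cross_modularity(A, P_A, P_B)
  q_ba <- cross_modularity(B, P_B, P_A)
  expect_lt(q_ab, 1)
  expect_gt(q_ba, q_ab)
  # the ratios match direct evaluation
  expect_equal(q_ab, modularity_q(A, P_B) / modularity_q(A, P_A),
               tolerance = 1e-12)
})

test_that("the cross-modularity report certifies partitions and Q_AA = 1", {
  pl1 <- make_planted_adjacency(c(5, 5), within = 0.9, between = 0.05,
                                noise = 0.01, seed = 4)
  pl2 <- make_planted_adjacency(c(3, 3, 4), within = 0.7, between = 0.1,
                                noise = 0.05, seed = 5)
  mats <- list(space = pl1$adjacency, interaction = pl2$adjacency)
  rep_ <- cross_modularity_report(mats, seed = 2)
  expect_equal(unname(diag(rep_$Q_AB)), c(1, 1))
  for (a in names(mats)) for (b in names(mats))
    expect_lte(rep_$Q_AB[a, b], 1 + 1e-9)
  expect_equal(unname(diag(rep_$nmi)), c(1, 1))
  expect_true(all(rep_$nmi >= 0 & rep_$nmi <= 1 + 1e-9))
})

test_that("directed influence matrices are partitioned on magnitudes", {
  set.seed(21)
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- -0.8  # strong negative (competitive) block
  W[4:6, 4:6] <- 0.7
  W[1, 4] <- 0.05
  diag(W) <- 0
  dimnames(W) <- list(paste(1:6), paste(1:6))
  adj <- adjacency_matrix(W, "influence")
  expect_true(adj$signed)
  expect_false(adj$symmetric)
  part <- leiden_partition(adj, seed = 1)
  expect_identical(part$labels, rep(1:2, each = 3))
  expect_gt(part$Q, 0.3)
})
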