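test_that("importance graphs map features onto symmetric edges", {
  imp <- c(0.2, 0.3, 0.5)
  pm <- rbind(c(1, 2), c(1, 3), c(2, 3))
  g <- importance_graph(imp, pm)
  expect_equal(g$weights, rbind(c(0, 0.2, 0.3), c(0.2, 0, 0.5), c(0.3, 0.5, 0)))
  ## zero-importance feature gives a zero edge
  g0 <- importance_graph(c(0.7, 0, 0.3), pm)
  expect_equal(g0$weights[1, 3], 0)
  ## round trip graph -> edge list -> graph
  e <- graph_edges(g)
  g2 <- importance_graph(e$weight, cbind(e$i, e$j))
  expect_equal(g2$weights, g$weights)
  expect_error(importance_graph(c(1, 2), pm), "lengths differ")
})

test_that("the intra-community objective counts each inside edge once", {
  E <- matrix(0, 4, 4)
  E[1, 3] <- E[3, 1] <- 5
  E[2, 4] <- E[4, 2] <- 5
  E[1, 2] <- E[2, 1] <- 0.1
  E[3, 4] <- E[4, 3] <- 0.1
  expect_equal(partition_objective(1:4, E), 0)          # singletons
  expect_equal(partition_objective(rep(1, 4), E), 10.2) # one community
  expect_equal(partition_objective(c(1, 1, 2, 2), E), 0.2)
  expect_error(partition_objective(c(1, 1, NA, 2), E), "assigned")
})

test_that("edge sums split the weighted degree into internal and external", {
  E <- matrix(0, 5, 5)
  E[1, 2] <- E[2, 1] <- 0.1
  E[1, 3] <- E[3, 1] <- 0.2
  E[1, 4] <- E[4, 1] <- 0.4
  a <- c(1, 1, 1, 2, 2)
  s <- edge_sums(1, a, E)
  expect_equal(s$In, 0.3)
  expect_equal(unname(s$Ex["2"]), 0.4)
  ## isolated node
  s5 <- edge_sums(5, a, E)
  expect_equal(s5$In, 0)
  expect_equal(unname(s5$Ex), 0)
  ## conservation: In + sum(Ex) = weighted degree, random graphs
  for (s in 1:5) {
    E <- random_graph(7, seed = s)
    a <- sample(1:3, 7, replace = TRUE)
    for (i in 1:7) {
      es <- edge_sums(i, a, E)
      expect_equal(es$In + sum(es$Ex), sum(E[i, ]), tolerance = 1e-12)
    }
  }
})

test_that("move benefits follow the insertion and swap formulas", {
  ## insertion: dT = Ex_{i,Ck} - In_i
  E <- matrix(0, 5, 5)
  E[1, 2] <- E[2, 1] <- 0.1
  E[1, 3] <- E[3, 1] <- 0.2
  E[1, 4] <- E[4, 1] <- 0.4
  a <- c(1, 1, 1, 2, 2)
  mb <- move_benefit(list(type = "insert", node = 1, target = 2), a, E)
  expect_equal(mb$dT, 0.4 - 0.3, tolerance = 1e-12)
  expect_equal(mb$benefit, -mb$dT)
  ## isolated node: dT = 0
  mb5 <- move_benefit(list(type = "insert", node = 5, target = 1), a, E)
  expect_equal(mb5$dT, 0)
  ## swap arithmetic: dT = (Ex_i + Ex_j) - (In_i + In_j) - 2 E_ij
  E2 <- matrix(0, 4, 4)
  a2 <- c(1, 1, 2, 2)
  E2[1, 3] <- E2[3, 1] <- 0.05   # the swapped pair's own edge
  E2[1, 4] <- E2[4, 2] <- E2[2, 4] <- E2[4, 1] <- 0  # placeholder
  ## build Ex_i_Ck = 0.5, Ex_j_Cm = 0.2, In_i = 0.1, In_j = 0.1
  E2[1, 4] <- E2[4, 1] <- 0.45   # i = 1 to community 2 (plus 0.05 to node 3)
  E2[1, 2] <- E2[2, 1] <- 0.1    # In_1
  E2[3, 2] <- E2[2, 3] <- 0.15   # j = 3 to community 1 (plus 0.05 to node 1)
  E2[3, 4] <- E2[4, 3] <- 0.1    # In_3
  mb2 <- move_benefit(list(type = "swap", i = 1, j = 3), a2, E2)
  expect_equal(mb2$dT, (0.5 + 0.2) - (0.1 + 0.1) - 2 * 0.05, tolerance = 1e-12)
  expect_error(move_benefit(list(type = "insert", node = 1, target = 1), a, E),
               "target")
  expect_error(move_benefit(list(type = "swap", i = 1, j = 2), a, E), "share")
})

test_that("every move's incremental dT matches a full objective recomputation", {
  for (s in 1:10) {
    E <- random_graph(6, seed = s)
    a <- sample(1:3, 6, replace = TRUE)
    base <- partition_objective(a, E)
    for (i in 1:6) for (k in setdiff(1:3, a[i])) {
      mb <- move_benefit(list(type = "insert", node = i, target = k), a, E)
      a2 <- a; a2[i] <- k
      expect_equal(mb$dT, partition_objective(a2, E) - base, tolerance = 1e-12)
    }
    for (i in 1:5) for (j in (i + 1):6) {
      if (a[i] == a[j]) next
      mb <- move_benefit(list(type = "swap", i = i, j = j), a, E)
      a2 <- a; a2[i] <- a[j]; a2[j] <- a[i]
      expect_equal(mb$dT, partition_objective(a2, E) - base, tolerance = 1e-12)
    }
  }
})

test_that("the search finds hand-checkable optima and terminates cleanly", {
  E <- matrix(0, 4, 4)
  E[1, 3] <- E[3, 1] <- 5
  E[2, 4] <- E[4, 2] <- 5
  E[1, 2] <- E[2, 1] <- 0.1
  E[3, 4] <- E[4, 3] <- 0.1
  p <- kl_search(E, 2, restarts = 10, seed = 1)
  ## optimum groups each heavy edge across communities AND pushes the two
  ## light edges across as well: {1,4}, {2,3} with no internal weight
  expect_equal(p$objective, 0, tolerance = 1e-12)
  expect_equal(p$assignment[1], p$assignment[4])
  expect_equal(p$assignment[2], p$assignment[3])
  expect_true(p$assignment[1] != p$assignment[2])
  ## matches brute force over all 2-partitions
  expect_equal(p$objective, oracle_best_partition(E, 2)$objective,
               tolerance = 1e-12)
  ## all-zero graph: T = 0, immediate termination
  z <- kl_search(matrix(0, 5, 5), 2, restarts = 3, seed = 1)
  expect_equal(z$objective, 0)
  expect_length(z$objective_trace, 1L)
  ## accepted-move trace strictly decreases
  E2 <- random_graph(8, seed = 3)
  p2 <- kl_search(E2, 3, restarts = 20, seed = 2)
  expect_true(all(diff(p2$objective_trace) < 0))
  ## incremental bookkeeping agrees with a from-scratch evaluation
  expect_equal(p2$objective, partition_objective(p2$assignment, E2),
               tolerance = 1e-12)
  expect_error(kl_search(E, 9, restarts = 1, seed = 1), "1..nodes")
})

test_that("multi-restart search matches the exhaustive partition oracle", {
  hits <- 0L
  for (s in 1:20) {
    m <- sample(6:9, 1)
    n <- sample(2:3, 1)
    E <- random_graph(m, seed = 100 + s)
    p <- kl_search(E, n, restarts = 100, seed = s)
    o <- oracle_best_partition(E, n)
    expect_gte(p$objective, o$objective - 1e-12)  # never below the optimum
    if (abs(p$objective - o$objective) < 1e-10) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("planted community structure is recovered exactly", {
  set.seed(4)
  for (ngroup in 2:5) {
    nodes <- 40
    groups <- sort(rep_len(seq_len(ngroup), nodes))
    E <- planted_graph(groups, between = 1, within = 0.01, seed = ngroup)
    p <- kl_search(E, ngroup, restarts = 100, seed = 7)
    expect_equal(match(p$assignment, unique(p$assignment)),
                 match(groups, unique(groups)))
  }
})

test_that("the elbow scan reports complementary percentages and finds breaks", {
  groups <- rep(1:3, each = 4)
  E <- planted_graph(groups, between = 1, within = 1e-3, seed = 2)
  sc <- scan_elbow(E, 2:6, restarts = 50, seed = 1)
  expect_equal(sc$within_pct + sc$among_pct, rep(100, nrow(sc)),
               tolerance = 1e-10)
  expect_equal(attr(sc, "selected"), 3)
  ## n = node count: all singletons, among = 100%
  sc_full <- scan_elbow(E, nrow(E), restarts = 5, seed = 1)
  expect_equal(sc_full$within, 0)
  expect_equal(sc_full$among_pct, 100)
  ## best objective is non-increasing in n (exhaustive oracle, small graph)
  E2 <- random_graph(8, seed = 11)
  objs <- vapply(1:5, function(n) oracle_best_partition(E2, n)$objective,
                 numeric(1))
  expect_true(all(diff(objs) <= 1e-12))
  sc2 <- scan_elbow(E2, 1:5, restarts = 150, seed = 3)
  expect_true(all(diff(sc2$within) <= 1e-10))
  expect_error(scan_elbow(E2, integer(0)), "empty")
})

test_that("community accumulation tables sum importance by community pair", {
  ## 4 residues in communities {1,2} and {3,4}; 6 pair features
  pm <- t(combn(4, 2))
  overall <- c(0.05, 0.2, 0.25, 0.3, 0.1, 0.1)
  ## features: (1,2) within X, (1,3) (1,4) (2,3) (2,4) across, (3,4) within Y
  per_pair <- cbind(overall, rev(overall))
  per_pair <- sweep(per_pair, 2, colSums(per_pair), "/")
  tab <- importance_table(per_pair, rbind(c(1, 2), c(1, 3)), paste0("f", 1:6))
  g <- importance_graph(tab$overall, pm)
  part <- kl_search(g, 2, restarts = 20, seed = 1)
  ## force the reference partition for the hand check
  part$assignment <- c(1, 1, 2, 2)
  part$letters <- allostate:::community_letters(part, g$weights)
  ct <- community_tables(part, tab, pm)
  m <- ct$overall_matrix
  expect_equal(sum(m), 100, tolerance = 1e-10)
  within_XY <- (tab$overall[1] + tab$overall[6]) * 100
  expect_equal(sum(diag(m)), within_XY, tolerance = 1e-10)
  expect_equal(m[upper.tri(m)][1],
               100 * sum(tab$overall[2:5]), tolerance = 1e-10)
  ## planted state-pair mass on one community pair shows up at ~100%
  v <- numeric(6); v[2] <- 1  # feature (1,3): spans the two communities
  tab2 <- importance_table(cbind(v, rep(1 / 6, 6)), rbind(c(1, 2), c(1, 3)),
                           paste0("f", 1:6))
  ct2 <- community_tables(part, tab2, pm,
                          groups = list(AB = list("A", "B")))
  expect_equal(ct2$state_pairs[1, "AB"], 100, tolerance = 1e-10)
  expect_error(community_tables(part, tab, rbind(c(1, 9))), "missing")
})
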