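test_that("transition counting follows the sliding window within trajectories", {
  ct <- count_and_trim(c(1, 1, 2, 2), lag = 1)
  expect_equal(ct$counts, rbind(c(1, 1), c(0, 1)))
  ct2 <- count_and_trim(c(1, 2, 1, 2, 1), lag = 2)
  expect_equal(ct2$counts, rbind(c(2, 0), c(0, 1)))
  ## no transitions across trajectory boundaries: joining 1-block and
  ## 2-block trajectories must not create a 1 -> 2 count
  ct3 <- count_and_trim(list(c(1, 1, 1), c(2, 2, 2)), lag = 1)
  expect_equal(ct3$counts, rbind(c(2, 0), c(0, 2)))
  expect_error(count_and_trim(list(c(1, 2)), lag = 5), "shorter than the lag")
})

test_that("ergodic trimming keeps the dominant strongly connected component", {
  ## states 1, 2 interconvert; state 3 visited once with no return
  labels <- c(1, 2, 1, 2, 1, 3, 3)
  ct <- count_and_trim(labels, lag = 1)
  expect_equal(ct$active_set, c(1, 2))
  ## brute-force reachability oracle across random chains
  for (s in 1:20) {
    set.seed(s)
    lab <- sample.int(5, 60, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.07, 0.03))
    ct <- count_and_trim(lab, lag = 1, k = 5)
    expect_equal(ct$active_set, oracle_scc_largest(ct$counts))
  }
})

test_that("symmetric counts give the row-normalized matrix with exact balance", {
  C <- rbind(c(6, 2, 0), c(2, 8, 3), c(0, 3, 4))
  lab <- NULL # construct the model directly from counts via the fixed point
  est <- allostate:::reversible_mle(C)
  expect_equal(est$T, C / rowSums(C), tolerance = 1e-9)
  pi <- stationary_distribution(est$T)
  expect_equal(pi * est$T, t(pi * est$T), tolerance = 1e-8)
})

test_that("reversible MLE matches a direct likelihood-optimization oracle", {
  C <- rbind(c(8, 2), c(1, 9))
  est <- allostate:::reversible_mle(C)
  expect_equal(est$T, oracle_reversible_T(C), tolerance = 1e-6)
  ## a larger asymmetric case
  set.seed(2)
  C2 <- matrix(rpois(16, 20), 4, 4)
  est2 <- allostate:::reversible_mle(C2)
  expect_equal(est2$T, oracle_reversible_T(C2), tolerance = 1e-5)
})

test_that("fitted models are stochastic, stationary and detailed-balanced", {
  set.seed(9)
  for (s in 1:5) {
    lab <- sample_chain(condition_generator(4), 2000, seed = s)
    m <- msm(lab, lag = 1)
    expect_equal(rowSums(m$T), rep(1, nrow(m$T)), tolerance = 1e-10)
    expect_equal(as.vector(m$pi %*% m$T), m$pi, tolerance = 1e-10)
    expect_equal(m$pi * m$T, t(m$pi * m$T), tolerance = 1e-8)
    ev <- allostate:::msm_eigenvalues(m)
    expect_true(all(is.finite(ev)))  # reversible spectra are real
  }
})

test_that("implied timescales follow the eigenvalue formula", {
  ## T = [[0.9, 0.1], [0.1, 0.9]] at lag 30 ns: t2 = -30 / ln 0.8
  lab <- sample_chain(rbind(c(0.9, 0.1), c(0.1, 0.9)), 50000, seed = 4)
  m <- msm(lab, lag = 1)
  ev <- allostate:::msm_eigenvalues(m)
  tau_ns <- 30
  t2 <- -tau_ns / log(ev[2])
  expect_equal(-tau_ns / log(0.8), 134.4, tolerance = 0.01)
  expect_equal(t2, -tau_ns / log(0.8), tolerance = 0.15) # estimator error
  ## table form with undefined timescales reported as NA
  its <- implied_timescales(lab, lags = c(1, 2), n_timescales = 3)
  expect_equal(nrow(its), 6)
  expect_true(all(is.na(its$timescale_frames[its$process >= 2])))
  ## a chain simulated from a fixed T has constant t2 across lags
  its2 <- implied_timescales(lab, lags = c(1, 2, 4, 8), n_timescales = 1)
  ts <- its2$timescale_frames
  expect_lt(max(abs(ts - mean(ts))) / mean(ts), 0.25)
})

test_that("identity-like chains yield undefined timescales", {
  lab <- list(rep(1L, 50), rep(2L, 50))
  ## two isolated self-looping states: active set is a single state
  ct <- count_and_trim(lab, lag = 1)
  expect_equal(length(ct$active_set), 1L)
  m <- msm(lab, lag = 1)
  its <- implied_timescales(lab, lags = 1, n_timescales = 2)
  expect_true(all(is.na(its$timescale_frames)))
})

test_that("PCCA recovers planted block structure and the identity lumping", {
  ## identity lumping when n_macro equals the state count
  lab <- sample_chain(condition_generator(3), 3000, seed = 1)
  m <- msm(lab, lag = 1)
  p <- pcca(m, nrow(m$T))
  expect_equal(p$membership, seq_len(nrow(m$T)))

  ## two nearly uncoupled blocks
  block_T <- function(sizes, eps, seed = 3) {
    set.seed(seed)
    k <- sum(sizes)
    g <- rep(seq_along(sizes), sizes)
    W <- matrix(eps * runif(k * k), k, k)
    same <- outer(g, g, "==")
    W[same] <- 1 + runif(sum(same))
    W <- (W + t(W)) / 2
    list(T = W / rowSums(W), groups = g)
  }
  bt <- block_T(c(4, 5), eps = 1e-4)
  fake <- structure(list(T = bt$T, pi = stationary_distribution(bt$T),
                         reversible = TRUE, active_set = seq_len(9)),
                    class = "msm")
  p2 <- pcca(fake, 2)
  expect_equal(p2$membership, match(bt$groups, unique(bt$groups)))

  ## 8 planted basins over 120 microstates
  bt8 <- block_T(rep(15, 8), eps = 1e-5, seed = 8)
  fake8 <- structure(list(T = bt8$T, pi = stationary_distribution(bt8$T),
                          reversible = TRUE, active_set = seq_len(120)),
                     class = "msm")
  p8 <- pcca(fake8, 8)
  expect_equal(p8$membership, match(bt8$groups, unique(bt8$groups)))
})

test_that("condition-split macrostate matrices recover their generators", {
  T_b <- condition_generator(4, "bonded")
  T_n <- condition_generator(4, "non_bonded")
  labs <- list(sample_chain(T_n, 50000, seed = 1),
               sample_chain(T_b, 50000, seed = 2))
  est_n <- condition_macro_T(labs, lag = 1, n_macro = 4, select = 1)
  est_b <- condition_macro_T(labs, lag = 1, n_macro = 4, select = 2)
  expect_equal(rowSums(est_n$T), rep(1, 4), tolerance = 1e-10)
  for (est in list(list(e = est_n, g = T_n), list(e = est_b, g = T_b))) {
    Ni <- rowSums(est$e$counts)
    z <- abs(est$e$T - est$g) / sqrt(est$g * (1 - est$g) / Ni)
    ## CLT bound, family-aware over the 16 entries
    expect_true(all(z <= 4))
    expect_lte(sum(z > 3), 1)
  }
  ## hand count on a short trajectory
  est1 <- condition_macro_T(list(c(1, 1, 2, 1)), lag = 1, n_macro = 2)
  expect_equal(est1$counts, rbind(c(1, 1), c(1, 0)))
  expect_equal(est1$T, rbind(c(0.5, 0.5), c(1, 0)))
  expect_error(condition_macro_T(labs, 1, select = integer(0)), "empty")
})

test_that("Chapman-Kolmogorov test validates Markov chains and flags cycles", {
  ## k = 1: predicted equals estimated identically
  lab <- sample_chain(condition_generator(3), 5000, seed = 6)
  ck <- ck_test(lab, lag = 2, kmax = 4)
  k1 <- ck[ck$k == 1, ]
  expect_equal(k1$predicted, k1$estimated, tolerance = 1e-12)
  ## a genuinely Markovian chain stays within error bars at k = 2..4
  viol <- ck[ck$k > 1, ]
  expect_lt(mean(viol$violation), 0.15)
  ## deterministic 3-cycle lumped to 2 states: gross violation
  cyc <- rep(c(1, 2, 2), 400)  # lump states 2 and 3 of the cycle together
  ck_bad <- ck_test(cyc, lag = 1, kmax = 3)
  expect_true(any(ck_bad$violation[ck_bad$k > 1]))
  expect_error(ck_test(list(c(1, 2, 1)), lag = 2, kmax = 5), "too short")
})

test_that("microstate dispersion measures within-state spread and flags 2 A", {
  base <- helix_backbone(10)
  arr <- array(rep(base, each = 6), c(6, 10, 3))
  ens <- trajectory_ensemble(list(arr))
  d0 <- microstate_dispersion(ens, rep(1L, 6))
  expect_equal(d0$dispersion, 0, tolerance = 1e-10)
  expect_false(d0$flagged)

  ## two alternating conformers A/B differing by a +/- 0.5 A shift of a
  ## residue group: the aligned mean is the midpoint, so each frame sits at
  ## half the pairwise superposed RMSD of the two conformers
  arr2 <- array(rep(base, each = 4), c(4, 10, 3))
  arr2[c(1, 3), 1:3, 1] <- arr2[c(1, 3), 1:3, 1] + 0.5
  arr2[c(2, 4), 1:3, 1] <- arr2[c(2, 4), 1:3, 1] - 0.5
  d2 <- microstate_dispersion(trajectory_ensemble(list(arr2)), rep(1L, 4))
  expect_equal(d2$dispersion, oracle_rmsd(arr2[1, , ], arr2[2, , ]) / 2,
               tolerance = 0.01)

  ## dispersion above the 2.0 A threshold is flagged
  arr4 <- array(rep(base, each = 4), c(4, 10, 3))
  arr4[c(1, 3), 1:5, 1] <- arr4[c(1, 3), 1:5, 1] + 20
  d4 <- microstate_dispersion(trajectory_ensemble(list(arr4)), rep(1L, 4))
  expect_true(d4$dispersion > 2)
  expect_true(d4$flagged)
  ## the same spread passes a looser threshold
  expect_false(microstate_dispersion(trajectory_ensemble(list(arr4)),
                                     rep(1L, 4), threshold = 10)$flagged)
})

test_that("microstate clustering is deterministic and exhaustive at k", {
  set.seed(1)
  cvs <- rbind(matrix(rnorm(200, 0), 100, 2), matrix(rnorm(200, 8), 100, 2))
  mic <- cluster_microstates(cvs, 2, seed = 5)
  expect_equal(mic$k, 2)
  ## two well-separated clouds split exactly
  expect_equal(length(unique(mic$labels[1:100])), 1L)
  expect_equal(length(unique(mic$labels[101:200])), 1L)
  ## nearest-centroid consistency (brute force)
  d1 <- colSums((t(cvs) - mic$centers[1, ])^2)
  d2 <- colSums((t(cvs) - mic$centers[2, ])^2)
  expect_equal(mic$labels, ifelse(d1 < d2, 1L, 2L))
  ## k = 1: centroid center
  mic1 <- cluster_microstates(cvs, 1, seed = 5)
  expect_equal(as.vector(mic1$centers), colMeans(cvs), tolerance = 1e-10)
  mic_same <- cluster_microstates(cvs, 2, seed = 5)
  expect_identical(mic$labels, mic_same$labels)
  expect_error(cluster_microstates(cvs[1:3, ], 10), "distinct")
})

test_that("model objects round trip through their JSON files", {
  lab <- sample_chain(condition_generator(3), 3000, seed = 2)
  m <- msm(lab, lag = 1)
  p <- pcca(m, 2)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_model_json(m, f1)
  write_model_json(p, f2)
  m2 <- read_model_json(f1)
  p2 <- read_model_json(f2)
  expect_equal(m2$T, m$T, tolerance = 1e-12)
  expect_equal(m2$pi, m$pi, tolerance = 1e-12)
  expect_identical(as.integer(m2$active_set), as.integer(m$active_set))
  expect_identical(p2$membership, p$membership)
  expect_s3_class(m2, "msm")
  unlink(c(f1, f2))
})
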