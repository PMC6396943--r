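## Independent oracles and fixture builders. Everything here is computed by
## a route separate from the package implementation it checks.

## random rigid motion applied to an N x 3 coordinate matrix
random_rigid <- function(coords, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])), c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0), c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0), c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  sweep(coords %*% (Rx %*% Ry %*% Rz), 2, stats::runif(3, -10, 10), "+")
}

## RMSD oracle: superpose with bio3d (independent implementation), then
## measure the residual deviation directly (bio3d::rmsd itself rounds)
oracle_rmsd <- function(a, b) {
  fitted <- suppressWarnings(bio3d::fit.xyz(as.vector(t(b)), as.vector(t(a))))
  d <- matrix(fitted - as.vector(t(b)), ncol = 3, byrow = TRUE)
  sqrt(mean(rowSums(d^2)))
}

## brute-force strongly connected components via boolean reachability closure
oracle_scc_largest <- function(counts) {
  k <- nrow(counts)
  R <- (counts > 0) | diag(k) > 0
  for (m in seq_len(k)) R <- R | (R %*% R) > 0
  comp <- integer(k)
  cid <- 0L
  for (i in seq_len(k)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    comp[R[i, ] & R[, i]] <- cid
  }
  stats_by <- lapply(seq_len(cid), function(cc) {
    v <- which(comp == cc)
    list(v = v, total = sum(counts[v, v, drop = FALSE]), size = length(v))
  })
  present <- which(vapply(stats_by, function(s)
    s$total > 0 || any(counts[s$v, ] > 0) || any(counts[, s$v] > 0), logical(1)))
  if (length(present) == 0L) return(integer(0))
  stats_by <- stats_by[present]
  totals <- vapply(stats_by, `[[`, numeric(1), "total")
  sizes <- vapply(stats_by, `[[`, numeric(1), "size")
  firsts <- vapply(stats_by, function(s) min(s$v), numeric(1))
  sort(stats_by[[order(-totals, -sizes, firsts)[1]]]$v)
}

## reversible-MLE oracle: direct numerical maximization of the likelihood
## over the symmetric unnormalized flow matrix (log parameterization)
oracle_reversible_T <- function(C) {
  k <- nrow(C)
  ut <- which(upper.tri(C, diag = TRUE))
  negll <- function(theta) {
    X <- matrix(0, k, k)
    X[ut] <- exp(theta)
    X <- X + t(X) - diag(diag(X))
    P <- X / rowSums(X)
    -sum(C[C > 0] * log(P[C > 0]))
  }
  init <- log((C + t(C))[ut] / sum(C) + 1e-8)
  fit <- stats::optim(init, negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  X <- matrix(0, k, k)
  X[ut] <- exp(fit$par)
  X <- X + t(X) - diag(diag(X))
  X / rowSums(X)
}

## exhaustive partition oracle: minimum of the intra-community objective
## over every assignment of m nodes into at most n labels (vectorized)
oracle_best_partition <- function(E, n) {
  m <- nrow(E)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), m)))
  obj <- numeric(nrow(grid))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    if (E[i, j] != 0) obj <- obj + E[i, j] * (grid[, i] == grid[, j])
  }
  list(objective = min(obj), assignment = grid[which.min(obj), ])
}

## random symmetric nonnegative weight graph
random_graph <- function(m, seed, density = 1) {
  set.seed(seed)
  E <- matrix(0, m, m)
  ut <- upper.tri(E)
  w <- stats::runif(sum(ut))
  if (density < 1) w[stats::runif(length(w)) > density] <- 0
  E[ut] <- w
  E + t(E)
}

## planted community graph: heavy edges between groups, light within
planted_graph <- function(groups, between = 1, within = 0.01, seed = 1) {
  set.seed(seed)
  m <- length(groups)
  E <- matrix(0, m, m)
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    w <- if (groups[i] == groups[j]) within * stats::runif(1, 0.5, 1)
         else between * stats::runif(1, 0.5, 1)
    E[i, j] <- E[j, i] <- w
  }
  E
}

## small labeled feature set: `classes` macrostates, one planted
## discriminative feature per class pair is not needed -- a single feature
## taking distinct means per class separates everything.
separable_features <- function(n_per_class = 30L, classes = 2L,
                               n_features = 10L, effect = 5, sigma = 1,
                               seed = 1L) {
  set.seed(seed)
  y <- rep(seq_len(classes), each = n_per_class)
  x <- matrix(stats::rnorm(length(y) * n_features, sd = sigma),
              length(y), n_features)
  x[, 1] <- x[, 1] + effect * y
  list(x = x, y = y)
}

## committor oracle by Monte-Carlo first passage
oracle_committor_mc <- function(T, A, B, i, nrep = 20000L, seed = 1L) {
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(nrep)) {
    s <- i
    repeat {
      s <- sample.int(nrow(T), 1L, prob = T[s, ])
      if (s %in% B) { hits <- hits + 1L; break }
      if (s %in% A) break
    }
  }
  hits / nrep
}
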