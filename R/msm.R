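#' Cluster collective variables into microstates
#'
#' k-means discretization of the 2D-RMSD space into microstates. The
#' clustering uses 10 restarts and is deterministic given `seed`.
#'
#' @param cv a `cv_matrix` from [rmsd2d()] (or a plain frames x d matrix).
#' @param k number of microstates; must not exceed the number of distinct
#'   CV points.
#' @param seed integer seed.
#' @param nstart k-means restarts (default 10).
#' @return An object of class `microstates`: list with `centers` (k x d),
#'   `labels` (per frame, 1..k), `k`, and `frame_index` if available.
#' @export
cluster_microstates <- function(cv, k, seed = 1L, nstart = 10L) {
  vals <- if (inherits(cv, "cv_matrix")) cv$values else as.matrix(cv)
  ndistinct <- nrow(unique(vals))
  if (k > ndistinct)
    stop("k (", k, ") exceeds the number of distinct CV points (", ndistinct, ")")
  set.seed(seed)
  km <- stats::kmeans(vals, centers = k, nstart = nstart, iter.max = 100L)
  out <- list(centers = km$centers, labels = as.integer(km$cluster), k = k,
              frame_index = if (inherits(cv, "cv_matrix")) cv$frame_index else NULL)
  class(out) <- "microstates"
  out
}

#' @export
print.microstates <- function(x, ...) {
  cat("Microstate model:", x$k, "microstates over", length(x$labels), "frames\n")
  invisible(x)
}

## split a flat label vector into per-trajectory pieces using a frame_index
split_labels <- function(micro) {
  if (is.null(micro$frame_index)) return(list(micro$labels))
  split(micro$labels, micro$frame_index$trajectory)
}

#' Count lagged transitions and trim to the ergodic core
#'
#' Transitions are counted with a sliding window of stride 1 within each
#' trajectory (never across trajectory boundaries). The active set is the
#' vertex set of the largest strongly connected component of the
#' positive-count digraph, "largest" meaning greatest total internal
#' transition count, ties broken by vertex count then by lowest vertex index.
#'
#' @param labels list of per-trajectory integer label vectors (1-based), or
#'   a single vector.
#' @param lag lag time in frames (>= 1).
#' @param k number of states; defaults to the maximum label.
#' @return List with `counts` (k x k), `active_set` (sorted state indices)
#'   and `lag`.
#' @export
count_and_trim <- function(labels, lag, k = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be >= 1")
  if (is.null(k)) k <- max(unlist(labels))
  if (all(vapply(labels, length, 1L) <= lag))
    stop("all trajectories are shorter than the lag")
  counts <- matrix(0, k, k)
  for (s in labels) {
    L <- length(s)
    if (L <= lag) next
    from <- s[seq_len(L - lag)]
    to <- s[seq_len(L - lag) + lag]
    tab <- table(factor(from, levels = 1:k), factor(to, levels = 1:k))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  list(counts = counts, active_set = largest_scc(counts), lag = lag)
}

## Largest strongly connected component of the positive-count digraph.
largest_scc <- function(counts) {
  k <- nrow(counts)
  pos <- which(counts > 0, arr.ind = TRUE)
  present <- sort(unique(c(pos[, 1], pos[, 2])))
  if (length(present) == 0L) return(integer(0))
  g <- igraph::graph_from_adjacency_matrix((counts > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  ms <- comp$membership
  stats_by <- lapply(seq_len(comp$no), function(cc) {
    v <- which(ms == cc)
    list(v = v, total = sum(counts[v, v, drop = FALSE]), size = length(v))
  })
  totals <- vapply(stats_by, `[[`, numeric(1), "total")
  sizes <- vapply(stats_by, `[[`, numeric(1), "size")
  firsts <- vapply(stats_by, function(s) min(s$v), numeric(1))
  best <- order(-totals, -sizes, firsts)[1]
  sort(stats_by[[best]]$v)
}

#' Fit a Markov state model from microstate labels
#'
#' The central model-fitting routine: counts lagged transitions
#' ([count_and_trim()]), restricts to the ergodic core, and estimates a
#' transition matrix. With `reversible = TRUE` (default) the estimate is the
#' maximum-likelihood reversible transition matrix obtained by the standard
#' self-consistent fixed-point iteration, so detailed balance
#' `pi_i T_ij = pi_j T_ji` holds at the optimum. The stationary distribution
#' is the left eigenvector of eigenvalue 1, renormalized to sum to one.
#'
#' @param labels list of per-trajectory label vectors, a single vector, or a
#'   `microstates` object.
#' @param lag lag time in frames.
#' @param reversible enforce detailed balance via reversible MLE.
#' @param save_interval_ps physical time per frame, for reporting lags in ns.
#' @param tol,max_iter fixed-point convergence tolerance on the
#'   log-likelihood (default 1e-10) and iteration cap (default 10000).
#' @return An object of class `msm`: list with `T` (row-stochastic, over the
#'   active set), `pi`, `counts` (full), `active_set`, `lag`, `lag_ps`,
#'   `reversible`, `loglik`.
#' @export
msm <- function(labels, lag = 1L, reversible = TRUE, save_interval_ps = NULL,
                tol = 1e-10, max_iter = 10000L) {
  if (inherits(labels, "microstates")) {
    if (is.null(save_interval_ps)) save_interval_ps <- NA_real_
    labels <- split_labels(labels)
  }
  ct <- count_and_trim(labels, lag)
  act <- ct$active_set
  if (length(act) < 1L) stop("no ergodic core: no observed transitions")
  C <- ct$counts[act, act, drop = FALSE]
  if (any(rowSums(C) == 0)) stop("zero count row after trimming")
  est <- if (reversible) reversible_mle(C, tol = tol, max_iter = max_iter)
         else list(T = C / rowSums(C), loglik = NA_real_, converged = TRUE)
  P <- est$T
  pi <- stationary_distribution(P)
  out <- list(T = P, pi = pi, counts = ct$counts, active_set = act,
              lag = ct$lag,
              lag_ps = if (is.null(save_interval_ps)) NA_real_
                       else ct$lag * save_interval_ps,
              reversible = reversible, loglik = est$loglik,
              converged = est$converged)
  class(out) <- "msm"
  out
}

## Reversible MLE by the self-consistent fixed-point iteration on the
## unnormalized symmetric flow matrix x_ij (Prinz-style update):
##   x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j)
reversible_mle <- function(C, tol = 1e-10, max_iter = 10000L) {
  Csym <- C + t(C)
  ci <- rowSums(C)
  x <- Csym / sum(Csym)
  ll_old <- -Inf
  P_old <- x / rowSums(x)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xi <- rowSums(x)
    denom <- outer(ci / xi, ci / xi, "+")
    x <- Csym / denom
    x[Csym == 0] <- 0
    P <- x / rowSums(x)
    ll <- sum(C[C > 0] * log(P[C > 0]))
    ## require both the likelihood and the matrix itself to settle: the
    ## likelihood is flat near the optimum, so it alone under-resolves T
    if (is.finite(ll_old) && abs(ll - ll_old) < tol &&
        max(abs(P - P_old)) < 1e-11) { converged <- TRUE; break }
    ll_old <- ll
    P_old <- P
  }
  if (!converged) warning("reversible MLE did not converge within ", max_iter,
                          " iterations")
  list(T = x / rowSums(x), loglik = ll, converged = converged)
}

#' Stationary distribution of a transition matrix
#'
#' The left eigenvector associated with eigenvalue 1.0, renormalized to sum
#' to one.
#'
#' @param P row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' @export
print.msm <- function(x, ...) {
  cat("Markov state model:", nrow(x$T), "active states",
      sprintf("(of %d), lag %d frames", nrow(x$counts), x$lag))
  if (is.finite(x$lag_ps)) cat(sprintf(" (%.3g ns)", x$lag_ps / 1000))
  cat(",", if (x$reversible) "reversible MLE" else "non-reversible", "\n")
  invisible(x)
}

#' @export
summary.msm <- function(object, ...) {
  ev <- msm_eigenvalues(object)
  out <- list(n_states = nrow(object$T), lag = object$lag,
              pi = object$pi, eigenvalues = ev,
              timescales_frames = -object$lag / log(pmax(ev[-1], 0)))
  class(out) <- "summary.msm"
  out
}

#' @export
print.summary.msm <- function(x, ...) {
  cat("MSM with", x$n_states, "states at lag", x$lag, "frames\n")
  cat("stationary distribution:\n")
  print(round(x$pi, 4))
  cat("leading eigenvalues:\n")
  print(round(utils::head(x$eigenvalues, 6), 6))
  invisible(x)
}

## Eigenvalues, using the pi-symmetrized form for reversible models so they
## are exactly real; sorted descending.
msm_eigenvalues <- function(model) {
  P <- model$T
  if (model$reversible) {
    s <- sqrt(model$pi)
    A <- (s %o% (1 / s)) * P
    ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  } else {
    ev <- eigen(P, only.values = TRUE)$values
    ev <- ifelse(abs(Im(ev)) > 1e-12, NA_real_, Re(ev))
    ev <- sort(ev, decreasing = TRUE, na.last = TRUE)
  }
  ev
}

#' Simulate a state sequence from a fitted MSM
#'
#' @param object an `msm` fit.
#' @param nsim sequence length.
#' @param seed integer seed.
#' @param init initial state (index into the active set); sampled from the
#'   stationary distribution if `NULL`.
#' @param ... unused.
#' @return Integer vector of state labels (original state indices).
#' @export
simulate.msm <- function(object, nsim = 1000L, seed = NULL, init = NULL, ...) {
  s <- sample_chain(object$T, nsim, seed = seed, init = init)
  object$active_set[s]
}

#' Implied relaxation timescales across a lag grid
#'
#' For each lag, fits an MSM and reports `t_i(tau) = -tau / ln lambda_i(tau)`
#' for the eigenvalues sorted descending (the stationary eigenvalue 1 is
#' excluded). Nonpositive or complex eigenvalues yield `NA` timescales,
#' never silently dropped rows.
#'
#' @param labels list of per-trajectory label vectors or a `microstates`
#'   object.
#' @param lags integer vector of lags in frames.
#' @param n_timescales how many timescales to report (default 5).
#' @param reversible passed to [msm()].
#' @param save_interval_ps physical time per frame; when given, timescales
#'   are also reported in ns.
#' @return data.frame of class `implied_timescales` with one row per lag.
#' @export
implied_timescales <- function(labels, lags, n_timescales = 5L,
                               reversible = TRUE, save_interval_ps = NULL) {
  if (inherits(labels, "microstates")) labels <- split_labels(labels)
  rows <- lapply(lags, function(tau) {
    m <- msm(labels, lag = tau, reversible = reversible,
             save_interval_ps = save_interval_ps)
    ev <- msm_eigenvalues(m)[-1]
    ts <- rep(NA_real_, length(ev))
    ok <- !is.na(ev) & ev > 0 & ev < 1
    ts[ok] <- -tau / log(ev[ok])
    ts <- c(ts, rep(NA_real_, n_timescales))[seq_len(n_timescales)]
    data.frame(lag = tau, process = seq_len(n_timescales),
               timescale_frames = ts,
               timescale_ns = if (is.null(save_interval_ps)) NA_real_
                              else ts * save_interval_ps / 1000)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("implied_timescales", "data.frame")
  out
}

#' @export
plot.implied_timescales <- function(x, ...) {
  y <- x$timescale_frames
  graphics::plot(NA, xlim = range(x$lag), ylim = range(y, na.rm = TRUE),
                 xlab = "lag (frames)", ylab = "implied timescale (frames)",
                 log = "y", ...)
  for (p in unique(x$process)) {
    sub <- x[x$process == p, ]
    graphics::lines(sub$lag, sub$timescale_frames, type = "b", pch = 16,
                    col = p)
  }
  invisible(x)
}

#' Perron-cluster lumping of microstates into macrostates
#'
#' Crisp assignment of microstates to metastable macrostates from the
#' eigenfunction structure of the transition matrix: k-means (seeded, 10
#' restarts) on the rows of the leading `n_macro` right-eigenvector matrix.
#' Macrostates are relabeled in order of first appearance along the
#' microstate index so the result is deterministic given the seed.
#'
#' @param model an `msm` fit (reversible recommended, so eigenvectors are real).
#' @param n_macro number of macrostates, between 2 and the state count
#'   (`n_macro = k` gives the identity lumping).
#' @param seed integer seed for the k-means step.
#' @return An object of class `macrostates`: list with `membership` (length
#'   k over the active set, values 1..n_macro), `n_macro`, and the parent
#'   model's `active_set`.
#' @export
pcca <- function(model, n_macro, seed = 1L) {
  k <- nrow(model$T)
  if (n_macro < 1L || n_macro > k) stop("n_macro must be in 1..k")
  if (n_macro == k) {
    membership <- seq_len(k)
  } else {
    s <- sqrt(model$pi)
    A <- (s %o% (1 / s)) * model$T
    e <- eigen((A + t(A)) / 2, symmetric = TRUE)
    ## right eigenvectors of T from the symmetrized problem
    psi <- (1 / s) * e$vectors[, seq_len(n_macro), drop = FALSE]
    set.seed(seed)
    km <- stats::kmeans(psi, centers = n_macro, nstart = 100L, iter.max = 100L)
    membership <- as.integer(km$cluster)
  }
  ## contiguous labels in order of first appearance
  membership <- match(membership, unique(membership))
  out <- list(membership = membership, n_macro = n_macro,
              active_set = model$active_set)
  class(out) <- "macrostates"
  out
}

#' @export
print.macrostates <- function(x, ...) {
  cat("Macrostate lumping:", length(x$membership), "microstates ->",
      x$n_macro, "macrostates\n")
  print(table(macrostate = x$membership))
  invisible(x)
}

#' Map per-frame microstate labels to macrostate labels
#'
#' Frames in microstates outside the model's active set get `NA`.
#'
#' @param labels list of per-trajectory microstate label vectors, a single
#'   vector, or a `microstates` object.
#' @param macro a `macrostates` object from [pcca()].
#' @return List of per-trajectory macrostate label vectors.
#' @export
macro_labels <- function(labels, macro) {
  if (inherits(labels, "microstates")) labels <- split_labels(labels)
  if (!is.list(labels)) labels <- list(labels)
  lut <- rep(NA_integer_, max(unlist(labels), max(macro$active_set)))
  lut[macro$active_set] <- macro$membership
  lapply(labels, function(s) lut[s])
}

#' Condition-split macrostate transition matrix
#'
#' Sliding-window macrostate transition counts over a selected subset of
#' trajectories (e.g. only the covalently bonded ones), row-normalized.
#' Rows for macrostates never visited in the selection are `NA` and flagged.
#'
#' @param labels list of per-trajectory macrostate label vectors (see
#'   [macro_labels()]).
#' @param lag lag in frames.
#' @param n_macro number of macrostates; defaults to the maximum label.
#' @param select logical or integer index of trajectories to use (default all).
#' @return List with `T` (row-stochastic with possible `NA` rows), `counts`,
#'   `undefined_rows`.
#' @export
condition_macro_T <- function(labels, lag, n_macro = NULL, select = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (!is.null(select)) labels <- labels[select]
  if (length(labels) == 0L) stop("empty trajectory selection")
  if (is.null(n_macro)) n_macro <- max(unlist(labels), na.rm = TRUE)
  counts <- matrix(0, n_macro, n_macro)
  for (s in labels) {
    L <- length(s)
    if (L <= lag) next
    from <- s[seq_len(L - lag)]
    to <- s[seq_len(L - lag) + lag]
    ok <- !is.na(from) & !is.na(to)
    tab <- table(factor(from[ok], levels = 1:n_macro),
                 factor(to[ok], levels = 1:n_macro))
    counts <- counts + unclass(tab)
  }
  dimnames(counts) <- NULL
  rs <- rowSums(counts)
  P <- counts / ifelse(rs > 0, rs, NA_real_)
  list(T = P, counts = counts, undefined_rows = which(rs == 0))
}

#' Chapman-Kolmogorov self-consistency test
#'
#' Compares the k-step prediction of the lag-`tau` macrostate transition
#' matrix, `[T(tau)^k]_{ii}`, against the directly estimated self-transition
#' probability at lag `k*tau`, for each macrostate. Both estimates use plain
#' row-normalized sliding-window counts so the k = 1 comparison is exact by
#' construction. Two error bars accompany the direct estimate: the standard
#' multinomial form `sqrt(p(1-p)/N_i)` with `N_i` the transition count out of
#' state i, and a modified form in which the denominator is replaced by the
#' ratio of the total transition count to `N_i` (reducing the error bar's
#' dependence on the frame-save frequency).
#'
#' @param labels list of per-trajectory macrostate label vectors.
#' @param lag base lag in frames.
#' @param kmax test multiples 1..kmax.
#' @param n_macro number of macrostates.
#' @return data.frame of class `ck_test` with columns `state`, `k`,
#'   `predicted`, `estimated`, `se_standard`, `se_modified`, `violation`
#'   (outside predicted +/- 3 standard errors).
#' @export
ck_test <- function(labels, lag, kmax = 5L, n_macro = NULL) {
  if (!is.list(labels)) labels <- list(labels)
  if (is.null(n_macro)) n_macro <- max(unlist(labels), na.rm = TRUE)
  if (all(vapply(labels, length, 1L) <= kmax * lag))
    stop("trajectories too short for kmax * lag")
  base <- condition_macro_T(labels, lag, n_macro)
  rows <- list()
  Pk <- diag(n_macro)
  for (k in seq_len(kmax)) {
    Pk <- Pk %*% base$T
    direct <- condition_macro_T(labels, k * lag, n_macro)
    Ni <- rowSums(direct$counts)
    Ntot <- sum(direct$counts)
    for (i in seq_len(n_macro)) {
      p <- direct$T[i, i]
      se_std <- if (Ni[i] > 0) sqrt(p * (1 - p) / Ni[i]) else NA_real_
      se_mod <- if (Ni[i] > 0) sqrt(p * (1 - p) / (Ntot / Ni[i])) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        state = i, k = k, predicted = Pk[i, i], estimated = p,
        se_standard = se_std, se_modified = se_mod,
        violation = is.finite(p) && is.finite(se_std) &&
          abs(p - Pk[i, i]) > 3 * pmax(se_std, 1e-12))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ck_test", "data.frame")
  out
}

#' Mean structural dispersion within each microstate
#'
#' Average RMSD of a microstate's member frames to the microstate mean
#' structure (frames aligned to an iteratively refined mean). Microstates
#' with dispersion above the threshold are flagged: kinetic similarity within
#' a microstate is conventionally assumed when the average is below 2.0
#' Angstrom.
#'
#' @param traj a [trajectory_ensemble].
#' @param labels per-frame microstate labels (flat, pooled across
#'   trajectories in order) or a `microstates` object.
#' @param threshold flag threshold in Angstrom (default 2.0).
#' @return data.frame with `microstate`, `n_frames`, `dispersion`, `flagged`.
#' @export
microstate_dispersion <- function(traj, labels, threshold = 2.0) {
  if (inherits(labels, "microstates")) labels <- labels$labels
  arr <- do.call(abind3, traj$trajectories)
  stopifnot(length(labels) == dim(arr)[1])
  states <- sort(unique(labels))
  rows <- lapply(states, function(s) {
    idx <- which(labels == s)
    sub <- arr[idx, , , drop = FALSE]
    if (length(idx) == 1L) {
      d <- 0
    } else {
      ref <- sub[1, , ]
      for (it in 1:10) {
        sub <- align_frames(sub, ref)
        m <- apply(sub, c(2, 3), mean)
        shift <- sqrt(mean(rowSums((m - sweep(ref, 2, colMeans(ref)))^2)))
        ref <- m
        if (shift < 1e-6) break
      }
      m <- apply(sub, c(2, 3), mean)
      d <- mean(vapply(seq_len(dim(sub)[1]),
                       function(f) rmsd(sub[f, , ], m), numeric(1)))
    }
    data.frame(microstate = s, n_frames = length(idx), dispersion = d,
               flagged = d > threshold)
  })
  do.call(rbind, rows)
}

#' Write a model object as JSON
#'
#' Serializes a `microstates`, `msm`, or `macrostates` object to a JSON
#' model file that [read_model_json()] restores.
#'
#' @param x the model object.
#' @param path output path.
#' @export
write_model_json <- function(x, path) {
  kind <- class(x)[1]
  if (!kind %in% c("microstates", "msm", "macrostates"))
    stop("unsupported model class: ", kind)
  payload <- unclass(x)
  if (kind == "msm") {
    payload$T <- unname(as.matrix(payload$T))
    payload$counts <- unname(as.matrix(payload$counts))
  }
  if (kind == "microstates") payload$centers <- unname(as.matrix(payload$centers))
  jsonlite::write_json(list(kind = kind, model = payload), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model object written by [write_model_json()]
#'
#' @param path JSON model file.
#' @return The restored object with its original class.
#' @export
read_model_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  x <- raw$model
  if (raw$kind == "msm") {
    x$T <- as.matrix(x$T)
    x$counts <- as.matrix(x$counts)
    dimnames(x$T) <- dimnames(x$counts) <- NULL
  }
  if (raw$kind == "microstates") {
    x$centers <- as.matrix(x$centers)
    dimnames(x$centers) <- NULL
    x$labels <- as.integer(x$labels)
  }
  if (raw$kind == "macrostates") {
    x$membership <- as.integer(x$membership)
    x$active_set <- as.integer(x$active_set)
  }
  class(x) <- raw$kind
  x
}
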