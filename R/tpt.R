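#' Forward and backward committors
#'
#' The forward committor `q_plus[i]` is the probability that a chain started
#' in state i reaches the target set B before the source set A. It is 0 on
#' A, 1 on B, and on the intermediate states solves the linear system
#' `-q_i + sum_{k in I} T_ik q_k = -sum_{k in B} T_ik`. The backward
#' committor is taken as `q_minus = 1 - q_plus`, the convention valid for
#' reversible chains (which the reversible MLE guarantees).
#'
#' @param T row-stochastic transition matrix.
#' @param A,B disjoint, non-empty source and target state index sets.
#' @return List with `q_plus` and `q_minus`.
#' @export
committors <- function(T, A, B) {
  k <- nrow(T)
  A <- as.integer(A); B <- as.integer(B)
  if (length(A) == 0L || length(B) == 0L) stop("A and B must be non-empty")
  if (length(intersect(A, B)) > 0L) stop("A and B must be disjoint")
  I <- setdiff(seq_len(k), c(A, B))
  q <- numeric(k)
  q[B] <- 1
  if (length(I) > 0L) {
    M <- diag(length(I)) - T[I, I, drop = FALSE]
    b <- rowSums(T[I, B, drop = FALSE])
    sol <- tryCatch(solve(M, b), error = function(e)
      stop("singular committor system: an intermediate state cannot reach A or B"))
    q[I] <- sol
  }
  list(q_plus = q, q_minus = 1 - q)
}

#' Effective and net reactive fluxes
#'
#' The effective flux along each edge is
#' `f_ij = pi_i q_minus_i T_ij q_plus_j` (diagonal zeroed); the net flux is
#' its positive part, `f_plus_ij = max(0, f_ij - f_ji)`.
#'
#' @param T row-stochastic transition matrix.
#' @param pi stationary distribution.
#' @param q committor list from [committors()].
#' @return List with `f` and `f_plus` matrices (flux per lag time).
#' @export
fluxes <- function(T, pi, q) {
  f <- (pi * q$q_minus) * T * rep(q$q_plus, each = nrow(T))
  diag(f) <- 0
  f_plus <- pmax(f - t(f), 0)  # matrix first so dims survive pmax
  list(f = f, f_plus = f_plus)
}

#' Total reactive flux out of the source set
#'
#' `F = sum_{i in A} sum_{j not in A} pi_i T_ij q_plus_j`, the A-to-B
#' transition flux per lag time.
#'
#' @param T,pi transition matrix and stationary distribution.
#' @param q committor list.
#' @param A source set.
#' @return Scalar flux per lag time.
#' @export
total_flux <- function(T, pi, q, A) {
  k <- nrow(T)
  notA <- setdiff(seq_len(k), A)
  sum(outer(pi[A], q$q_plus[notA]) * T[A, notA, drop = FALSE])
}

## Widest (maximum-bottleneck) simple path from any node of A to any node of
## B on the positive-flux graph; ties between equal bottlenecks resolved by
## the lexicographically smallest state sequence. Returns list(path,
## bottleneck) or NULL. Bellman-Ford-style relaxation with simple-path
## guard; graphs here are small macrostate networks.
widest_path <- function(f, A, B) {
  k <- nrow(f)
  best_b <- rep(-Inf, k)
  best_p <- vector("list", k)
  for (a in sort(A)) { best_b[a] <- Inf; best_p[[a]] <- a }
  better <- function(b1, p1, b2, p2) {
    if (b1 > b2) return(TRUE)
    if (b1 < b2) return(FALSE)
    ## equal bottleneck: lexicographically smaller sequence wins
    lex_less(p1, p2)
  }
  for (round in seq_len(k)) {
    changed <- FALSE
    for (i in seq_len(k)) {
      if (!is.finite(best_b[i]) && best_b[i] < 0) next
      for (j in which(f[i, ] > 0)) {
        if (j %in% best_p[[i]]) next   # keep paths simple
        nb <- min(best_b[i], f[i, j])
        np <- c(best_p[[i]], j)
        if (is.null(best_p[[j]]) || better(nb, np, best_b[j], best_p[[j]])) {
          best_b[j] <- nb
          best_p[[j]] <- np
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  ends <- B[is.finite(best_b[B]) & best_b[B] > 0]
  if (length(ends) == 0L) return(NULL)
  bb <- best_b[ends]
  cand <- ends[bb == max(bb)]
  pick <- cand[1]
  for (cc in cand[-1]) if (lex_less(best_p[[cc]], best_p[[pick]])) pick <- cc
  list(path = best_p[[pick]], bottleneck = best_b[pick])
}

lex_less <- function(p1, p2) {
  n <- min(length(p1), length(p2))
  for (t in seq_len(n)) {
    if (p1[t] < p2[t]) return(TRUE)
    if (p1[t] > p2[t]) return(FALSE)
  }
  length(p1) < length(p2)
}

#' Decompose the net flux into pathways and channels
#'
#' Repeatedly extracts the widest (maximum-bottleneck) A-to-B path from the
#' net flux matrix, assigns it its bottleneck flux, subtracts that flux from
#' every edge on the path, and continues until the residual flux drops below
#' `tol * F` or `max_paths` paths have been extracted. Identical state
#' sequences are aggregated into channels whose probabilities are each
#' channel's flux over the total decomposed flux.
#'
#' @param f_plus net flux matrix from [fluxes()].
#' @param A,B source and target sets.
#' @param total total flux `F` used for the residual criterion (defaults to
#'   the decomposable flux found).
#' @param tol residual tolerance as a fraction of `total` (default 1e-8).
#' @param max_paths pathway cap (default 10000).
#' @return List with `pathways` (data.frame: sequence, flux), `channels`
#'   (data.frame: sequence, flux, probability, sorted by probability),
#'   `residual`, `n_paths`.
#' @export
decompose_pathways <- function(f_plus, A, B, total = NULL, tol = 1e-8,
                               max_paths = 10000L) {
  f <- f_plus
  if (is.null(total)) total <- sum(f[A, , drop = FALSE])
  if (total <= 0) stop("no positive flux out of A")
  seqs <- character(0)
  flux <- numeric(0)
  extracted <- 0
  repeat {
    if (length(seqs) >= max_paths) break
    if (total - extracted < tol * total) break
    wp <- widest_path(f, A, B)
    if (is.null(wp) || wp$bottleneck <= 0) break
    p <- wp$path
    b <- wp$bottleneck
    for (t in seq_len(length(p) - 1L)) f[p[t], p[t + 1L]] <- f[p[t], p[t + 1L]] - b
    seqs <- c(seqs, paste(p, collapse = "-"))
    flux <- c(flux, b)
    extracted <- extracted + b
  }
  if (length(seqs) == 0L) stop("no A to B path with positive flux")
  pathways <- data.frame(sequence = seqs, flux = flux)
  agg <- stats::aggregate(flux ~ sequence, pathways, sum)
  agg$probability <- agg$flux / sum(agg$flux)
  agg <- agg[order(-agg$probability, agg$sequence), ]
  rownames(agg) <- NULL
  list(pathways = pathways, channels = agg,
       residual = total - extracted, n_paths = length(seqs))
}

#' Transition path theory analysis of a macrostate model
#'
#' Full TPT treatment of an A-to-B transition on a macrostate transition
#' matrix: committors, effective and net fluxes, total flux, and the
#' pathway/channel decomposition.
#'
#' @param T row-stochastic macrostate transition matrix.
#' @param A,B source and target macrostate sets (disjoint, non-empty); all
#'   other states are intermediates.
#' @param pi stationary distribution; computed from `T` if `NULL`.
#' @param tol,max_paths decomposition controls, see [decompose_pathways()].
#' @return An object of class `tpt_flux` with fields `q_plus`, `q_minus`,
#'   `f`, `f_plus`, `total_flux`, `pathways`, `channels`, `residual`, `A`,
#'   `B`.
#' @export
tpt <- function(T, A, B, pi = NULL, tol = 1e-8, max_paths = 10000L) {
  if (is.null(pi)) pi <- stationary_distribution(T)
  q <- committors(T, A, B)
  fl <- fluxes(T, pi, q)
  Ftot <- total_flux(T, pi, q, A)
  dec <- decompose_pathways(fl$f_plus, A, B, total = Ftot, tol = tol,
                            max_paths = max_paths)
  out <- list(q_plus = q$q_plus, q_minus = q$q_minus, f = fl$f,
              f_plus = fl$f_plus, total_flux = Ftot,
              pathways = dec$pathways, channels = dec$channels,
              residual = dec$residual, n_paths = dec$n_paths, A = A, B = B,
              pi = pi)
  class(out) <- "tpt_flux"
  out
}

#' @export
print.tpt_flux <- function(x, n = 10L, ...) {
  cat("Transition path analysis:",
      sprintf("A = {%s} -> B = {%s}\n", paste(x$A, collapse = ","),
              paste(x$B, collapse = ",")))
  cat(sprintf("total flux %.4g per lag time; %d pathways in %d channels\n",
              x$total_flux, x$n_paths, nrow(x$channels)))
  top <- utils::head(x$channels, n)
  cat("top channels:\n")
  print(data.frame(channel = paste("State", gsub("-", "–", top$sequence)),
                   probability = sprintf("%.3f%%", 100 * top$probability)))
  invisible(x)
}

#' @export
summary.tpt_flux <- function(object, ...) {
  cat("committors (q_plus):\n")
  print(round(object$q_plus, 4))
  cat(sprintf("total flux: %.6g; residual after decomposition: %.3g\n",
              object$total_flux, object$residual))
  invisible(object)
}

#' Write channel probabilities as TSV
#'
#' Columns (sequence, flux per lag, probability), sorted by probability
#' descending.
#'
#' @param x a `tpt_flux` object.
#' @param path output path.
#' @export
write_channels_tsv <- function(x, path) {
  utils::write.table(x$channels[, c("sequence", "flux", "probability")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
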