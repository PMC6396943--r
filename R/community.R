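#' Build a residue importance graph
#'
#' Models the protein as an undirected graph: nodes are residues, edge
#' weights are the feature importance of the corresponding Calpha pair
#' (overall importance by default, or any single state pair's vector).
#' Self-weights are zero and absent pairs get weight zero.
#'
#' @param importance numeric vector over features (or an `importance_table`,
#'   whose overall vector is used).
#' @param pair_map P x 2 matrix mapping feature index to residue indices
#'   (i < j); taken from the table-compatible `feature_matrix` layout.
#' @param n_nodes residue count; defaults to the maximum index in `pair_map`.
#' @param node_labels optional residue labels.
#' @return An object of class `importance_graph`: list with `weights`
#'   (symmetric n x n matrix, zero diagonal) and `node_labels`.
#' @export
importance_graph <- function(importance, pair_map = NULL, n_nodes = NULL,
                             node_labels = NULL) {
  if (inherits(importance, "importance_table")) importance <- importance$overall
  if (is.null(pair_map)) stop("pair_map is required")
  pair_map <- as.matrix(pair_map)
  if (nrow(pair_map) != length(importance))
    stop("pair_map and importance vector lengths differ")
  if (any(importance < 0) || any(!is.finite(importance)))
    stop("weights must be finite and nonnegative")
  if (is.null(n_nodes)) n_nodes <- max(pair_map)
  E <- matrix(0, n_nodes, n_nodes)
  E[pair_map] <- importance
  E[pair_map[, 2:1, drop = FALSE]] <- importance
  diag(E) <- 0
  if (is.null(node_labels)) node_labels <- paste0("R", seq_len(n_nodes))
  out <- list(weights = E, node_labels = node_labels)
  class(out) <- "importance_graph"
  out
}

#' @export
print.importance_graph <- function(x, ...) {
  cat("Importance graph:", nrow(x$weights), "residues, total edge weight",
      format(sum(x$weights) / 2, digits = 6), "\n")
  invisible(x)
}

#' Graph/edge-list round trip
#'
#' @param g an `importance_graph`.
#' @return data.frame with `i`, `j`, `weight` for i < j.
#' @export
graph_edges <- function(g) {
  n <- nrow(g$weights)
  pm <- t(utils::combn(n, 2L))
  data.frame(i = pm[, 1], j = pm[, 2], weight = g$weights[pm])
}

weights_of <- function(g) if (inherits(g, "importance_graph")) g$weights else as.matrix(g)

#' Intra-community importance objective
#'
#' The total feature importance retained inside communities:
#' `T = sum_l sum_{i<j in C_l} E_ij`, each unordered edge counted once.
#' Minimizing T pushes the state-discriminating signal onto inter-community
#' residue pairs.
#'
#' @param assignment integer community label per node (or an
#'   `ml_communities` object).
#' @param g an `importance_graph` or symmetric weight matrix.
#' @return Scalar objective value.
#' @export
partition_objective <- function(assignment, g) {
  E <- weights_of(g)
  if (inherits(assignment, "ml_communities")) assignment <- assignment$assignment
  if (length(assignment) != nrow(E) || anyNA(assignment))
    stop("every node must be assigned")
  same <- outer(assignment, assignment, "==")
  sum(E[same & upper.tri(E)])
}

#' Internal and external edge sums for a node
#'
#' `In_i` is the total edge weight from node i to its own community;
#' `Ex_{i,Cq}` is the total edge weight from node i into each other
#' community.
#'
#' @param node node index.
#' @param assignment integer community label per node.
#' @param g graph or weight matrix.
#' @return List with `In` (scalar) and `Ex` (named vector over the other
#'   community labels).
#' @export
edge_sums <- function(node, assignment, g) {
  E <- weights_of(g)
  own <- assignment[node]
  comms <- sort(unique(assignment))
  sums <- vapply(comms, function(cc) sum(E[node, assignment == cc]), numeric(1))
  names(sums) <- comms
  list(In = unname(sums[as.character(own)]),
       Ex = sums[setdiff(as.character(comms), as.character(own))])
}

#' Objective change of an insertion or swap move
#'
#' For inserting node i into community Ck the objective changes by
#' `Ex_{i,Ck} - In_i`; for swapping nodes i (in Cm) and j (in Ck) it changes
#' by `(Ex_{i,Ck} + Ex_{j,Cm}) - (In_i + In_j) - 2 E_ij`. The benefit is the
#' objective reduction, `-dT`; a move is worth taking only when the benefit
#' is positive (T strictly decreases).
#'
#' @param move list: either `list(type = "insert", node =, target =)` or
#'   `list(type = "swap", i =, j =)`.
#' @param assignment integer community label per node.
#' @param g graph or weight matrix.
#' @return List with `dT` and `benefit = -dT`.
#' @export
move_benefit <- function(move, assignment, g) {
  E <- weights_of(g)
  if (move$type == "insert") {
    i <- move$node; k <- move$target
    if (k == assignment[i]) stop("insertion target equals the node's community")
    s <- edge_sums(i, assignment, g)
    dT <- sum(E[i, assignment == k]) - s$In
  } else if (move$type == "swap") {
    i <- move$i; j <- move$j
    if (assignment[i] == assignment[j]) stop("swap nodes share a community")
    Ex_i_Ck <- sum(E[i, assignment == assignment[j]])
    Ex_j_Cm <- sum(E[j, assignment == assignment[i]])
    In_i <- sum(E[i, assignment == assignment[i]])
    In_j <- sum(E[j, assignment == assignment[j]])
    dT <- (Ex_i_Ck + Ex_j_Cm) - (In_i + In_j) - 2 * E[i, j]
  } else stop("unknown move type")
  list(dT = dT, benefit = -dT)
}

## One greedy descent from a given assignment. Returns list(assignment,
## objective, trace). Best-improvement: evaluates every insertion and every
## cross-community swap, applies the single move with the largest objective
## reduction; ties prefer insertion over swap, then the lowest node index
## (then lowest target / partner). Stops when no move strictly decreases T.
kl_descent <- function(E, assignment, n) {
  m <- nrow(E)
  obj <- {
    same <- outer(assignment, assignment, "==")
    sum(E[same & upper.tri(E)])
  }
  trace <- obj
  repeat {
    M <- matrix(0, m, n)
    M[cbind(seq_len(m), assignment)] <- 1
    S <- E %*% M                       # S[i, q] = weight from i into community q
    In <- S[cbind(seq_len(m), assignment)]
    D <- S - In                        # D[i, q] = dT of inserting i into q
    D[cbind(seq_len(m), assignment)] <- Inf
    ## best insertion
    ins_best <- which(D == min(D), arr.ind = TRUE)
    ins_best <- ins_best[order(ins_best[, 1], ins_best[, 2]), , drop = FALSE][1, ]
    ins_dT <- D[ins_best[1], ins_best[2]]
    ## best swap: dT = D[i, a_j] + D[j, a_i] - 2 E_ij for a_i != a_j
    G <- D[, assignment, drop = FALSE]  # G[i, j] = D[i, a_j]
    Sw <- G + t(G) - 2 * E
    Sw[outer(assignment, assignment, "==")] <- Inf
    Sw[lower.tri(Sw, diag = TRUE)] <- Inf
    sw_dT <- min(Sw)
    if (is.finite(sw_dT)) {
      sw_best <- which(Sw == sw_dT, arr.ind = TRUE)
      sw_best <- sw_best[order(sw_best[, 1], sw_best[, 2]), , drop = FALSE][1, ]
    }
    best_dT <- min(ins_dT, sw_dT)
    if (!is.finite(best_dT) || best_dT >= -1e-13) break
    if (ins_dT <= sw_dT) {             # insertion wins ties
      assignment[ins_best[1]] <- ins_best[2]
    } else {
      ai <- assignment[sw_best[1]]
      assignment[sw_best[1]] <- assignment[sw_best[2]]
      assignment[sw_best[2]] <- ai
    }
    obj <- obj + best_dT
    trace <- c(trace, obj)
  }
  list(assignment = assignment, objective = obj, trace = trace)
}

#' Multi-restart Kernighan-Lin community search
#'
#' Partitions residues into `n` communities minimizing the intra-community
#' importance objective. Each restart starts from a random
#' partition (every community seeded non-empty), greedily applies the single
#' best insertion or cross-community swap until no move strictly reduces the
#' objective, and the lowest-objective partition across restarts is
#' returned. Deterministic given the seed.
#'
#' @param g an `importance_graph` or symmetric weight matrix.
#' @param n number of communities (1..nodes).
#' @param restarts random restarts (10000 reproduces the reference
#'   configuration; tests use far fewer).
#' @param seed integer seed.
#' @return An object of class `ml_communities`: list with `assignment`
#'   (contiguous labels 1..n_found), `n` (requested), `objective`,
#'   `objective_trace` (best restart), `restarts`, `seed`, `letters`
#'   (community letters ordered by descending external importance).
#' @export
kl_search <- function(g, n, restarts = 100L, seed = 1L) {
  E <- weights_of(g)
  m <- nrow(E)
  if (n < 1L || n > m) stop("n must be in 1..nodes")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    a <- integer(m)
    a[sample.int(m, n)] <- sample.int(n)     # every community starts non-empty
    a[a == 0L] <- sample.int(n, sum(a == 0L), replace = TRUE)
    res <- kl_descent(E, a, n)
    if (is.null(best) || res$objective < best$objective - 1e-15) best <- res
  }
  a <- match(best$assignment, unique(best$assignment))
  out <- list(assignment = a, n = n, objective = best$objective,
              objective_trace = best$trace, restarts = restarts, seed = seed,
              node_labels = if (inherits(g, "importance_graph")) g$node_labels
                            else paste0("R", seq_len(m)))
  out$letters <- community_letters(out, E)
  class(out) <- "ml_communities"
  out
}

## Letter communities A, B, C, ... by descending external (inter-community)
## importance, mirroring the reporting convention.
community_letters <- function(p, E) {
  a <- p$assignment
  ext <- vapply(sort(unique(a)), function(cc) {
    sum(E[a == cc, a != cc])
  }, numeric(1))
  LETTERS[order(order(-ext, sort(unique(a))))]
}

#' @export
print.ml_communities <- function(x, ...) {
  cat("ML communities:", length(unique(x$assignment)), "communities over",
      length(x$assignment), "residues\n")
  cat("intra-community importance:", format(x$objective, digits = 6),
      sprintf("(%d restarts, seed %d)\n", x$restarts, x$seed))
  lab <- x$letters[x$assignment]
  for (L in sort(unique(lab)))
    cat(sprintf("  Commu. %s: %s\n", L,
                paste(x$node_labels[lab == L], collapse = " ")))
  invisible(x)
}

#' Scan community counts and pick an elbow
#'
#' Runs [kl_search()] over a range of community counts, reporting the best
#' intra-community ("within") objective and the complementary inter-community
#' ("among") fraction of total importance for each n (within% + among% =
#' 100%). The automatic selection takes the n with the maximum discrete
#' second difference of the within-objective curve; pass `select` to
#' override manually.
#'
#' @param g graph or weight matrix.
#' @param n_range integer vector of community counts.
#' @param restarts,seed passed to [kl_search()].
#' @param select manual override for the selected n.
#' @return An object of class `community_scan`: data.frame with `n`,
#'   `within`, `within_pct`, `among_pct`; attributes `selected` and `fits`.
#' @export
scan_elbow <- function(g, n_range, restarts = 100L, seed = 1L, select = NULL) {
  if (length(n_range) == 0L) stop("empty n range")
  E <- weights_of(g)
  total <- sum(E) / 2
  fits <- lapply(seq_along(n_range), function(i) {
    kl_search(g, n_range[i], restarts = restarts, seed = seed + i - 1L)
  })
  within <- vapply(fits, `[[`, numeric(1), "objective")
  df <- data.frame(n = n_range, within = within,
                   within_pct = 100 * within / total,
                   among_pct = 100 * (1 - within / total))
  if (is.null(select)) {
    if (length(within) >= 3L) {
      d2 <- within[-c(1, length(within))] * -2 +
        within[-c(length(within) - 1, length(within))] +
        within[-(1:2)]
      select <- n_range[which.max(d2) + 1L]
    } else select <- n_range[which.min(within)]
  }
  attr(df, "selected") <- select
  attr(df, "fits") <- fits
  class(df) <- c("community_scan", "data.frame")
  df
}

#' @export
plot.community_scan <- function(x, ...) {
  graphics::plot(x$n, x$among_pct, type = "b", pch = 16,
                 xlab = "number of communities",
                 ylab = "importance among communities (%)", ...)
  graphics::abline(v = attr(x, "selected"), lty = 2)
  invisible(x)
}

#' Community-pair importance accumulation tables
#'
#' (i) The overall matrix: entry (X, Y) is the summed overall importance of
#' features whose two residues fall in communities X and Y (diagonal =
#' within-community). Entries sum to 100% of total importance. (ii) For each
#' macrostate pair, the fraction of that pair's importance carried by
#' designated community-group pairs (by default each of the two most
#' externally connected communities against the union of the rest).
#'
#' @param partition an `ml_communities` object.
#' @param table an `importance_table` whose features map onto residue pairs
#'   via `pair_map`.
#' @param pair_map P x 2 residue-index matrix for the table's features.
#' @param groups optional named list of community-letter groups for the
#'   state-pair report, e.g.
#'   `list("A with C and D" = list("A", c("C","D")))`.
#' @return List with `overall_matrix` (percent) and `state_pairs`
#'   (data.frame, one row per macrostate pair, one column per group pair,
#'   percent of that pair's importance).
#' @export
community_tables <- function(partition, table, pair_map, groups = NULL) {
  a <- partition$assignment
  if (max(pair_map) > length(a)) stop("residue missing from partition")
  lab <- partition$letters[a]
  ncomm <- length(unique(a))
  lets <- sort(unique(lab))
  li <- lab[pair_map[, 1]]
  lj <- lab[pair_map[, 2]]
  ov <- matrix(0, ncomm, ncomm, dimnames = list(lets, lets))
  for (f in seq_len(nrow(pair_map))) {
    x <- sort(c(li[f], lj[f]))
    ov[x[1], x[2]] <- ov[x[1], x[2]] + table$overall[f]
  }
  ov <- 100 * ov / sum(table$overall)
  if (is.null(groups)) {
    rest <- setdiff(lets, lets[1:2])
    if (length(rest) >= 1L && length(lets) >= 3L) {
      groups <- list()
      groups[[paste(lets[1], "with", paste(rest, collapse = "/"))]] <-
        list(lets[1], rest)
      groups[[paste(lets[2], "with", paste(rest, collapse = "/"))]] <-
        list(lets[2], rest)
    } else groups <- list()
  }
  sp <- NULL
  if (length(groups) > 0L && !is.null(table$per_pair)) {
    rows <- lapply(seq_len(ncol(table$per_pair)), function(cp) {
      v <- table$per_pair[, cp]
      vals <- vapply(groups, function(gr) {
        sel <- (li %in% gr[[1]] & lj %in% gr[[2]]) |
               (lj %in% gr[[1]] & li %in% gr[[2]])
        100 * sum(v[sel]) / sum(v)
      }, numeric(1))
      df <- data.frame(state_pair = sprintf("S%d-S%d",
                                            table$state_pairs[cp, 1],
                                            table$state_pairs[cp, 2]))
      for (nm in names(vals)) df[[nm]] <- vals[[nm]]
      df
    })
    sp <- do.call(rbind, rows)
  }
  list(overall_matrix = ov, state_pairs = sp)
}

#' Write a community partition as TSV
#'
#' @param partition an `ml_communities` object.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(residue = partition$node_labels,
                   community = partition$letters[partition$assignment])
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
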