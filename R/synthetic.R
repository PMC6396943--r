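#' Sample a Markov chain
#'
#' @param T row-stochastic transition matrix.
#' @param length_out chain length.
#' @param seed integer seed (optional).
#' @param init initial state; sampled from the stationary distribution if
#'   `NULL`.
#' @return Integer state sequence (1-based).
#' @export
sample_chain <- function(T, length_out, seed = NULL, init = NULL) {
  T <- as.matrix(T)
  if (any(abs(rowSums(T) - 1) > 1e-8) || any(T < 0))
    stop("T must be row-stochastic")
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(T)
  s <- integer(length_out)
  s[1] <- if (is.null(init)) sample.int(k, 1, prob = stationary_distribution(T))
          else as.integer(init)
  ## cumulative rows + one uniform draw per step
  cum <- t(apply(T, 1, cumsum))
  u <- stats::runif(length_out - 1L)
  for (t in seq_len(length_out - 1L)) {
    s[t + 1L] <- sum(u[t] > cum[s[t], ]) + 1L
  }
  s
}

#' Condition-dependent macrostate generator matrix
#'
#' A banded, ergodic transition matrix over `n` metastable states with high
#' self-transition probability, nearest-neighbor exchange, and a small
#' uniform mixing floor. The bonded condition biases the nearest-neighbor
#' drift toward higher state indices (mimicking a perturbation that shifts
#' the population balance); the non-bonded condition biases it the other
#' way.
#'
#' @param n number of macrostates.
#' @param condition `"bonded"` or `"non_bonded"`.
#' @param self self-transition weight (default 0.7).
#' @param drift asymmetry between up and down neighbor rates (default 0.08).
#' @param floor uniform mixing probability mass (default 0.02).
#' @return n x n row-stochastic matrix.
#' @export
condition_generator <- function(n, condition = c("non_bonded", "bonded"),
                                self = 0.7, drift = 0.08, floor = 0.02) {
  condition <- match.arg(condition)
  up <- if (condition == "bonded") 0.1 + drift else 0.1 - drift
  down <- if (condition == "bonded") 0.1 - drift else 0.1 + drift
  T <- matrix(floor / n, n, n)
  for (i in seq_len(n)) {
    T[i, i] <- T[i, i] + self
    T[i, min(i + 1, n)] <- T[i, min(i + 1, n)] + up
    T[i, max(i - 1, 1)] <- T[i, max(i - 1, 1)] + down
  }
  T / rowSums(T)
}

#' Specification for a synthetic ground-truthed dataset
#'
#' Describes a synthetic ensemble emulating the experimental design the
#' package targets: several trajectories per bond condition, a hidden Markov
#' chain over metastable macrostates with condition-dependent transition
#' matrices, per-macrostate rigid displacements of planted residue
#' communities on an ideal helical backbone, and isotropic Gaussian
#' positional noise. Defaults mirror the reference sampling plan: 148
#' residues, 8 macrostates, 6 trajectories per condition, 1 microsecond per
#' trajectory saved every 100 ps (10,000 frames per microsecond; 120,000
#' frames in total).
#'
#' @param n_residues residue count (default 148).
#' @param n_macrostates metastable state count (default 8).
#' @param n_traj_per_condition trajectories per condition (default 6).
#' @param duration_us trajectory length in microseconds (default 1).
#' @param save_interval_ps frame-save interval in picoseconds (default 100).
#' @param communities planted residue-to-community assignment; default
#'   splits the chain into 4 contiguous blocks.
#' @param displacement rigid displacement scale per macrostate step, Angstrom
#'   (default 3).
#' @param sigma isotropic positional noise per coordinate, Angstrom
#'   (default 0.5).
#' @param T_bonded,T_non_bonded generator matrices; defaults from
#'   [condition_generator()].
#' @param seed root seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 148L, n_macrostates = 8L,
                           n_traj_per_condition = 6L, duration_us = 1,
                           save_interval_ps = 100,
                           communities = NULL, displacement = 3,
                           sigma = 0.5,
                           T_bonded = NULL, T_non_bonded = NULL,
                           seed = 1L) {
  if (is.null(communities)) {
    communities <- sort(rep_len(1:4, n_residues))
  }
  if (length(communities) != n_residues)
    stop("communities must assign every residue")
  if (is.null(T_bonded)) T_bonded <- condition_generator(n_macrostates, "bonded")
  if (is.null(T_non_bonded))
    T_non_bonded <- condition_generator(n_macrostates, "non_bonded")
  for (T in list(T_bonded, T_non_bonded))
    if (any(abs(rowSums(T) - 1) > 1e-8)) stop("generator must be row-stochastic")
  if (sigma < 0) stop("sigma must be >= 0")
  frames <- round(duration_us * 1e6 / save_interval_ps)
  out <- list(n_residues = as.integer(n_residues),
              n_macrostates = as.integer(n_macrostates),
              n_traj_per_condition = as.integer(n_traj_per_condition),
              duration_us = duration_us,
              save_interval_ps = save_interval_ps,
              frames_per_traj = as.integer(frames),
              communities = as.integer(communities),
              displacement = displacement, sigma = sigma,
              T_bonded = T_bonded, T_non_bonded = T_non_bonded,
              seed = as.integer(seed))
  class(out) <- "synthetic_spec"
  out
}

#' Test-scale synthetic specification
#'
#' The small configuration used by the test suite and worked examples: 20
#' residues in 3 planted communities, 4 macrostates, 2 trajectories per
#' condition of 2,000 frames each.
#'
#' @param ... overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
test_spec <- function(...) {
  defaults <- list(n_residues = 20L, n_macrostates = 4L,
                   n_traj_per_condition = 2L, duration_us = 0.2,
                   save_interval_ps = 100,
                   communities = rep(1:3, c(6, 7, 7)))
  args <- utils::modifyList(defaults, list(...))
  do.call(synthetic_spec, args)
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("Synthetic spec:", x$n_residues, "residues,", x$n_macrostates,
      "macrostates,", 2 * x$n_traj_per_condition, "trajectories x",
      x$frames_per_traj, "frames\n")
  cat("  communities:", paste(table(x$communities), collapse = "/"),
      "| displacement", x$displacement, "A | sigma", x$sigma, "A\n")
  invisible(x)
}

#' Ideal helical Calpha backbone
#'
#' An alpha-helical Calpha trace (radius 2.3 Angstrom, rise 1.5 Angstrom and
#' 100 degrees of turn per residue): nondegenerate, trivially constructed,
#' and superposition-friendly.
#'
#' @param n residue count.
#' @return n x 3 coordinate matrix.
#' @export
helix_backbone <- function(n) {
  i <- seq_len(n) - 1
  ang <- i * 100 * pi / 180
  cbind(2.3 * cos(ang), 2.3 * sin(ang), 1.5 * i)
}

## fixed displacement directions per community; community 1 is anchored.
community_directions <- function(ncomm) {
  dirs <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0) / sqrt(2), c(1, 0, 1) / sqrt(2),
                c(0, 1, 1) / sqrt(2), c(1, 1, 1) / sqrt(3))
  if (ncomm > nrow(dirs)) stop("at most ", nrow(dirs), " planted communities")
  dirs[seq_len(ncomm), , drop = FALSE]
}

#' Emit coordinate trajectories from macrostate label sequences
#'
#' Every frame starts from the ideal helical backbone; macrostate s
#' translates each planted community c rigidly by
#' `(s - 1) * displacement * u_c` (distinct unit directions per community,
#' community 1 anchored), then adds isotropic Gaussian noise of standard
#' deviation `sigma` per coordinate. With `sigma = 0` each inter-community
#' pair distance therefore takes exactly `n_macrostates` distinct values
#' while intra-community distances are constant — the planted
#' discriminative signal.
#'
#' @param labels list of per-trajectory macrostate label sequences.
#' @param spec a [synthetic_spec()].
#' @param conditions condition tag per trajectory.
#' @param seed seed for the noise stream (defaults to `spec$seed + 1`).
#' @return List with `ensemble` (a [trajectory_ensemble]) and `truth`
#'   (macrostate labels per frame, generator matrices, planted partition,
#'   planted discriminative pairs as a P-length logical over the lexicographic
#'   pair enumeration).
#' @export
emit_trajectories <- function(labels, spec, conditions = NULL, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed + 1L
  n <- spec$n_residues
  comm <- spec$communities
  base <- helix_backbone(n)
  dirs <- community_directions(max(comm))
  if (is.null(conditions))
    conditions <- rep("non_bonded", length(labels))
  set.seed(seed)
  trajs <- lapply(labels, function(s) {
    arr <- array(0, c(length(s), n, 3))
    for (f in seq_along(s)) {
      shift <- (s[f] - 1) * spec$displacement * dirs[comm, , drop = FALSE]
      arr[f, , ] <- base + shift +
        matrix(stats::rnorm(3 * n, sd = spec$sigma), n, 3)
    }
    arr
  })
  ref <- structure3d(base)
  ens <- trajectory_ensemble(trajs, condition = conditions, reference = ref,
                             save_interval_ps = spec$save_interval_ps)
  pm <- t(utils::combn(n, 2L))
  planted <- comm[pm[, 1]] != comm[pm[, 2]]
  truth <- list(labels = labels, conditions = conditions,
                T_bonded = spec$T_bonded, T_non_bonded = spec$T_non_bonded,
                communities = comm, planted_pairs = planted)
  list(ensemble = ens, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Samples one macrostate chain per trajectory from the condition's
#' generator matrix, optionally emits coordinates, and (optionally) writes
#' per-condition trajectories as multi-model PDB, ground truth and a
#' manifest as JSON. All randomness flows from `spec$seed`; the dataset is
#' reproducible byte-for-byte from (spec, seed).
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir output directory; `NULL` keeps everything in memory.
#' @param emit_coords generate coordinates (set `FALSE` for a labels +
#'   manifest-only plan, e.g. when only the sampling-plan bookkeeping is
#'   needed).
#' @return List with `ensemble` (or `NULL`), `truth`, `manifest`.
#' @export
make_dataset <- function(spec, out_dir = NULL, emit_coords = TRUE) {
  nt <- spec$n_traj_per_condition
  conditions <- rep(c("non_bonded", "bonded"), each = nt)
  labels <- lapply(seq_along(conditions), function(i) {
    T <- if (conditions[i] == "bonded") spec$T_bonded else spec$T_non_bonded
    sample_chain(T, spec$frames_per_traj, seed = spec$seed + 100L + i)
  })
  res <- if (emit_coords) emit_trajectories(labels, spec, conditions)
         else list(ensemble = NULL,
                   truth = list(labels = labels, conditions = conditions,
                                T_bonded = spec$T_bonded,
                                T_non_bonded = spec$T_non_bonded,
                                communities = spec$communities,
                                planted_pairs = NULL))
  manifest <- list(
    n_residues = spec$n_residues,
    n_macrostates = spec$n_macrostates,
    n_trajectories = length(conditions),
    conditions = conditions,
    frames_per_trajectory = spec$frames_per_traj,
    frames_per_us = round(1e6 / spec$save_interval_ps),
    total_data_points = length(conditions) * spec$frames_per_traj,
    n_pair_features = spec$n_residues * (spec$n_residues - 1) / 2,
    save_interval_ps = spec$save_interval_ps,
    duration_us = spec$duration_us,
    seed = spec$seed
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (emit_coords) {
      for (i in seq_along(res$ensemble$trajectories)) {
        write_trajectory_pdb(res$ensemble$trajectories[[i]],
                             file.path(out_dir, sprintf("traj_%02d_%s.pdb", i,
                                                        conditions[i])))
      }
    }
    utils::write.csv(
      data.frame(trajectory = rep(seq_along(labels),
                                  each = spec$frames_per_traj),
                 condition = rep(conditions, each = spec$frames_per_traj),
                 frame = rep(seq_len(spec$frames_per_traj), length(labels)),
                 macrostate = unlist(labels)),
      file.path(out_dir, "ground_truth_labels.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(manifest = manifest,
           communities = spec$communities,
           T_bonded = spec$T_bonded, T_non_bonded = spec$T_non_bonded),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  list(ensemble = res$ensemble, truth = res$truth, manifest = manifest)
}
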