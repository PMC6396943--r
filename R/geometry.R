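#' Construct a Calpha structure
#'
#' A `structure3d` is the minimal representation of a protein conformation
#' used throughout the package: one Calpha coordinate per residue, plus
#' residue labels carrying the author-assigned numbering (VVD constructs
#' conventionally start at residue 37, which is the default offset).
#'
#' @param coords numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param residue_names optional character vector of residue names
#'   (one-letter or three-letter codes); defaults to `"X"`.
#' @param first_resno author numbering of the first residue (default 37).
#' @return An object of class `structure3d` with fields `coords`,
#'   `residue_labels` (e.g. `"X37"`) and `resno`.
#' @export
structure3d <- function(coords, residue_names = NULL, first_resno = 37L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("need at least one residue")
  if (!all(is.finite(coords))) stop("coords must be finite")
  if (is.null(residue_names)) residue_names <- rep("X", n)
  resno <- seq.int(first_resno, length.out = n)
  out <- list(
    coords = unname(coords),
    resno = resno,
    residue_labels = paste0(residue_names, resno)
  )
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat("Calpha structure:", nrow(x$coords), "residues, numbered",
      x$resno[1], "-", x$resno[length(x$resno)], "\n")
  invisible(x)
}

#' Bundle trajectories into an ensemble
#'
#' A `trajectory_ensemble` holds one or more coordinate trajectories over a
#' shared residue set, each tagged with an experimental condition (for the
#' photoreceptor application: whether the cofactor-cysteine covalent bond is
#' present), plus the frame-save interval in picoseconds.
#'
#' @param trajectories list of numeric arrays, each `frames x N x 3` (Angstrom).
#' @param condition character vector, one of `"bonded"`/`"non_bonded"` per
#'   trajectory (recycled if length 1).
#' @param reference a [structure3d] supplying residue labels; if `NULL` a
#'   default labeling starting at residue 37 is created.
#' @param save_interval_ps frame-save interval in picoseconds (default 100).
#' @return An object of class `trajectory_ensemble`.
#' @export
trajectory_ensemble <- function(trajectories, condition = "non_bonded",
                                reference = NULL, save_interval_ps = 100) {
  if (!is.list(trajectories) || length(trajectories) == 0L)
    stop("trajectories must be a non-empty list")
  dims <- vapply(trajectories, function(a) dim(a)[2], numeric(1))
  if (length(unique(dims)) != 1L)
    stop("all trajectories must share the residue count")
  if (save_interval_ps <= 0) stop("save_interval_ps must be positive")
  n <- dims[1]
  if (is.null(reference)) reference <- structure3d(matrix(0, n, 3))
  if (nrow(reference$coords) != n)
    stop("reference residue count does not match trajectories")
  condition <- rep_len(match.arg(condition, c("bonded", "non_bonded"),
                                 several.ok = TRUE), length(trajectories))
  out <- list(
    trajectories = trajectories,
    condition = condition,
    residue_labels = reference$residue_labels,
    resno = reference$resno,
    save_interval_ps = save_interval_ps
  )
  class(out) <- "trajectory_ensemble"
  out
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, function(a) dim(a)[1], numeric(1))
  cat("Trajectory ensemble:", length(x$trajectories), "trajectories,",
      length(x$residue_labels), "residues,", sum(nf), "frames total\n")
  cat("  conditions:", paste(sprintf("%s(%d)", names(table(x$condition)),
                                     table(x$condition)), collapse = ", "), "\n")
  cat("  save interval:", x$save_interval_ps, "ps\n")
  invisible(x)
}

n_frames <- function(traj) {
  sum(vapply(traj$trajectories, function(a) dim(a)[1], numeric(1)))
}

## Kabsch rotation: the 3x3 rotation aligning centred P onto centred Q,
## reflections excluded via the determinant correction.
kabsch_rotation <- function(P, Q) {
  s <- svd(crossprod(P, Q))
  d <- sign(det(s$u) * det(s$v))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

coords_of <- function(x) {
  if (inherits(x, "structure3d")) x$coords else as.matrix(x)
}

#' Minimum RMSD after optimal superposition
#'
#' Root-mean-square deviation between two conformations after removing the
#' optimal rigid rotation and translation (Kabsch superposition via SVD with
#' determinant correction, so reflections are excluded).
#'
#' @param mobile,reference [structure3d] objects or N x 3 matrices with equal
#'   residue counts; N >= 3 is required for a determined superposition
#'   (use `superpose = FALSE` for smaller or degenerate inputs).
#' @param superpose superimpose before measuring (default `TRUE`).
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(mobile, reference, superpose = TRUE) {
  P <- coords_of(mobile); Q <- coords_of(reference)
  if (nrow(P) != nrow(Q)) stop("atom counts differ")
  if (superpose) {
    if (nrow(P) < 3L)
      stop("need >= 3 atoms for a determined superposition; ",
           "use superpose = FALSE for a translation-free RMSD")
    P <- sweep(P, 2, colMeans(P))
    Q <- sweep(Q, 2, colMeans(Q))
    P <- P %*% kabsch_rotation(P, Q)
  }
  sqrt(mean(rowSums((P - Q)^2)))
}

## Align every frame of a frames x N x 3 array onto a reference (centred
## internally); returns the aligned array.
align_frames <- function(arr, ref) {
  refc <- sweep(ref, 2, colMeans(ref))
  out <- arr
  for (f in seq_len(dim(arr)[1])) {
    P <- arr[f, , ]
    P <- sweep(P, 2, colMeans(P))
    out[f, , ] <- P %*% kabsch_rotation(P, refc)
  }
  out
}

#' Per-residue root-mean-square fluctuation
#'
#' Fluctuation of each Calpha about its trajectory-averaged position,
#' `RMSF_i = sqrt(mean_t |v_it - mean(v_i)|^2)`. Because the averaged
#' structure depends on how frames are superposed, two modes are provided:
#' with `superpose = TRUE` (default) frames are iteratively aligned to the
#' running mean structure (at most `max_iter` rounds, stopping when the mean
#' shifts by less than `tol` Angstrom); with `superpose = FALSE` raw
#' coordinates are used as stored.
#'
#' @param traj a [trajectory_ensemble]; frames from all trajectories are pooled.
#' @param superpose align frames to the iteratively refined mean first.
#' @param max_iter,tol iteration cap and mean-shift convergence tolerance.
#' @return Named numeric vector of per-residue RMSF in Angstrom.
#' @export
rmsf <- function(traj, superpose = TRUE, max_iter = 10L, tol = 1e-6) {
  arr <- do.call(abind3, traj$trajectories)
  if (dim(arr)[1] < 2L) stop("RMSF needs at least two frames")
  if (superpose) {
    ref <- arr[1, , ]
    for (it in seq_len(max_iter)) {
      arr <- align_frames(arr, ref)
      m <- apply(arr, c(2, 3), mean)
      shift <- sqrt(mean(rowSums((m - sweep(ref, 2, colMeans(ref)))^2)))
      ref <- m
      if (shift < tol) break
    }
  }
  m <- apply(arr, c(2, 3), mean)
  dev2 <- sweep(arr, c(2, 3), m)^2
  out <- sqrt(apply(dev2, 2, mean) * 3)  # mean over frames and xyz, times 3 dims
  ## equivalent to sqrt(mean_t sum_xyz dev^2): mean over (frames, xyz) * 3
  names(out) <- traj$residue_labels
  out
}

## bind frames x N x 3 arrays along the frame axis
abind3 <- function(...) {
  arrs <- list(...)
  nf <- vapply(arrs, function(a) dim(a)[1], numeric(1))
  out <- array(0, c(sum(nf), dim(arrs[[1]])[2], 3))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Pairwise Calpha distance featurization
#'
#' Converts an ensemble into the frames x P matrix of all unordered pairwise
#' Calpha distances, P = N(N-1)/2. Distances are invariant under rigid motion
#' of each frame, which is what makes them suitable machine-learning features
#' for conformational states. Features are enumerated lexicographically over
#' residue index pairs (i, j), i < j.
#'
#' @param traj a [trajectory_ensemble] with at least two residues.
#' @return An object of class `feature_matrix`: list with `values`
#'   (frames x P, Angstrom), `pair_map` (P x 2 integer matrix of residue
#'   indices), `pair_labels` (e.g. `"T38-G105"`), and `frame_index`
#'   (data.frame with trajectory id, frame number, condition).
#' @export
pairwise_distances <- function(traj) {
  n <- length(traj$residue_labels)
  if (n < 2L) stop("need at least two residues")
  pm <- t(utils::combn(n, 2L))
  vals <- lapply(traj$trajectories, function(a) {
    t(vapply(seq_len(dim(a)[1]),
             function(f) as.vector(stats::dist(a[f, , ])),
             numeric(nrow(pm))))
  })
  fi <- do.call(rbind, lapply(seq_along(vals), function(i) {
    data.frame(trajectory = i, frame = seq_len(nrow(vals[[i]])),
               condition = traj$condition[i])
  }))
  out <- list(
    values = do.call(rbind, vals),
    pair_map = pm,
    pair_labels = paste0(traj$residue_labels[pm[, 1]], "-",
                         traj$residue_labels[pm[, 2]]),
    frame_index = fi
  )
  class(out) <- "feature_matrix"
  out
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$values), "frames x", ncol(x$values),
      "Calpha pair distances\n")
  invisible(x)
}

#' Two-dimensional RMSD collective variables
#'
#' Projects every frame onto the plane (RMSD to the dark-state reference,
#' RMSD to the light-state reference). This two-coordinate description is the
#' collective-variable space on which microstates are clustered.
#'
#' @param traj a [trajectory_ensemble].
#' @param dark,light reference [structure3d] objects sharing the ensemble's
#'   residue set.
#' @return An object of class `cv_matrix`: list with `values` (frames x 2,
#'   Angstrom, columns `rmsd_dark`, `rmsd_light`), `frame_index`, and the two
#'   references.
#' @export
rmsd2d <- function(traj, dark, light) {
  n <- length(traj$residue_labels)
  if (nrow(dark$coords) != n || nrow(light$coords) != n)
    stop("reference residue set does not match the trajectory")
  vals <- lapply(traj$trajectories, function(a) {
    t(vapply(seq_len(dim(a)[1]), function(f) {
      c(rmsd(a[f, , ], dark), rmsd(a[f, , ], light))
    }, numeric(2)))
  })
  fi <- do.call(rbind, lapply(seq_along(vals), function(i) {
    data.frame(trajectory = i, frame = seq_len(nrow(vals[[i]])),
               condition = traj$condition[i])
  }))
  v <- do.call(rbind, vals)
  colnames(v) <- c("rmsd_dark", "rmsd_light")
  out <- list(values = v, frame_index = fi, dark = dark, light = light)
  class(out) <- "cv_matrix"
  out
}

#' @export
print.cv_matrix <- function(x, ...) {
  cat("2D-RMSD collective variables:", nrow(x$values), "frames\n")
  invisible(x)
}

#' Read a Calpha structure from a PDB file
#'
#' Reads the first model of a PDB file and keeps only Calpha atoms; all
#' other atoms are ignored (a notice reports how many were dropped).
#'
#' @param path PDB file path.
#' @return A [structure3d] with the file's residue names and numbering.
#' @export
read_structure_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  dropped <- nrow(pdb$atom) - length(ca$atom)
  if (dropped > 0)
    message("read_structure_pdb: ignoring ", dropped, " non-Calpha atoms")
  at <- pdb$atom[ca$atom, ]
  structure3d(cbind(at$x, at$y, at$z), residue_names = at$resid,
              first_resno = at$resno[1])
}

#' Read a multi-model PDB trajectory
#'
#' Reads every model of a multi-model PDB as one trajectory of Calpha
#' coordinates.
#'
#' @param path multi-model PDB file path.
#' @param condition condition tag for the trajectory.
#' @param save_interval_ps frame-save interval in picoseconds.
#' @return A [trajectory_ensemble] with a single trajectory.
#' @export
read_trajectory_pdb <- function(path, condition = "non_bonded",
                                save_interval_ps = 100) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca <- bio3d::atom.select(pdb, "calpha", verbose = FALSE)
  xyz <- pdb$xyz[, ca$xyz, drop = FALSE]
  n <- length(ca$atom)
  arr <- array(0, c(nrow(xyz), n, 3))
  for (f in seq_len(nrow(xyz))) arr[f, , ] <- matrix(xyz[f, ], n, 3, byrow = TRUE)
  at <- pdb$atom[ca$atom, ]
  ref <- structure3d(arr[1, , ], residue_names = at$resid,
                     first_resno = at$resno[1])
  trajectory_ensemble(list(arr), condition = condition, reference = ref,
                      save_interval_ps = save_interval_ps)
}

#' Write a trajectory as a multi-model PDB
#'
#' Writes each frame as one `MODEL`/`ENDMDL` block of Calpha ATOM records
#' (single-frame blocks produced by bio3d).
#'
#' @param arr frames x N x 3 coordinate array.
#' @param path output file.
#' @param resno residue numbering (default starts at 37).
#' @export
write_trajectory_pdb <- function(arr, path, resno = NULL) {
  n <- dim(arr)[2]
  if (is.null(resno)) resno <- seq.int(37L, length.out = n)
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (f in seq_len(dim(arr)[1])) {
    writeLines(sprintf("MODEL     %4d", f), con)
    bio3d::write.pdb(file = tmp, xyz = as.vector(t(arr[f, , ])),
                     resno = resno, resid = rep("ALA", n),
                     elety = rep("CA", n))
    lines <- readLines(tmp)
    writeLines(grep("^ATOM", lines, value = TRUE), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a feature or CV matrix as CSV with a JSON metadata sidecar
#'
#' @param x a `feature_matrix` or `cv_matrix`.
#' @param path output CSV path; metadata goes to `<path>.json`.
#' @export
write_features_csv <- function(x, path) {
  if (inherits(x, "feature_matrix")) {
    df <- as.data.frame(x$values)
    names(df) <- x$pair_labels
    meta <- list(kind = "feature_matrix", n_features = ncol(x$values),
                 pair_map = x$pair_map)
  } else if (inherits(x, "cv_matrix")) {
    df <- as.data.frame(x$values)
    meta <- list(kind = "cv_matrix")
  } else stop("unsupported object")
  df <- cbind(x$frame_index, df)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
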