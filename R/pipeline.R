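#' Pipeline run configuration
#'
#' Declarative configuration for the end-to-end analysis
#' (featurize -> MSM -> importance -> communities -> TPT). All randomness
#' flows from the single `seed` via fixed per-stage offsets, so identical
#' configurations give identical numeric outputs.
#'
#' @param spec a [synthetic_spec()] describing the input ensemble (an
#'   external ensemble can be passed directly to [run_pipeline()]).
#' @param k_micro number of microstates (the reference configuration uses
#'   300; the test-scale default is 50).
#' @param lag_frames MSM lag in frames.
#' @param n_macro number of macrostates.
#' @param classifier a [classifier_spec()].
#' @param n_communities community count for the partition stage.
#' @param restarts community-search restarts.
#' @param tpt_source,tpt_target macrostate source/target sets for TPT.
#' @param ck_kmax Chapman-Kolmogorov multiples to test.
#' @param seed root seed.
#' @return A list of class `run_config`.
#' @export
run_config <- function(spec = test_spec(), k_micro = 50L, lag_frames = 5L,
                       n_macro = spec$n_macrostates,
                       classifier = classifier_spec(),
                       n_communities = max(spec$communities),
                       restarts = 100L,
                       tpt_source = 1L, tpt_target = n_macro,
                       ck_kmax = 3L, seed = 1L) {
  if (lag_frames >= spec$frames_per_traj)
    stop("lag must be shorter than the shortest trajectory")
  out <- list(spec = spec, k_micro = k_micro, lag_frames = lag_frames,
              n_macro = n_macro, classifier = classifier,
              n_communities = n_communities, restarts = restarts,
              tpt_source = tpt_source, tpt_target = tpt_target,
              ck_kmax = ck_kmax, seed = as.integer(seed))
  class(out) <- "run_config"
  out
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order on a synthetic (or supplied) ensemble:
#' 2D-RMSD collective variables against the generator's extreme-state
#' references, k-means microstates, reversible MSM with implied timescales,
#' PCCA macrostate lumping, condition-split macrostate kinetics,
#' Chapman-Kolmogorov and microstate-dispersion diagnostics, pairwise
#' Calpha featurization, one-vs-one random-forest importance, ML community
#' partition with elbow scan, and transition path analysis. Intermediate
#' artifacts and summary tables are written under `out_dir` when given.
#'
#' @param config a [run_config()].
#' @param ensemble optional [trajectory_ensemble] to analyze instead of
#'   generating one from `config$spec`.
#' @param out_dir optional output directory for CSV/TSV/JSON artifacts.
#' @param verbose print stage progress.
#' @return An object of class `allostate_run` bundling every stage's result.
#' @export
run_pipeline <- function(config, ensemble = NULL, out_dir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[allostate] ", ...)
  spec <- config$spec
  stage_seed <- function(off) config$seed + off

  truth <- NULL
  if (is.null(ensemble)) {
    say("generating synthetic ensemble")
    spec$seed <- stage_seed(0L)
    ds <- make_dataset(spec)
    ensemble <- ds$ensemble
    truth <- ds$truth
  }
  n_res <- length(ensemble$residue_labels)

  say("2D-RMSD collective variables")
  dark <- structure3d(helix_backbone(n_res))
  light_arr <- emit_trajectories(
    list(rep(spec$n_macrostates, 1L)),
    utils::modifyList(spec, list(sigma = 0)), seed = 1L)$ensemble
  light <- structure3d(light_arr$trajectories[[1]][1, , ])
  cv <- rmsd2d(ensemble, dark, light)

  say("k-means microstates (k = ", config$k_micro, ")")
  micro <- cluster_microstates(cv, config$k_micro, seed = stage_seed(1L))

  say("reversible MSM at lag ", config$lag_frames, " frames")
  model <- msm(micro, lag = config$lag_frames,
               save_interval_ps = ensemble$save_interval_ps)
  lags <- unique(pmax(1L, round(config$lag_frames * c(0.5, 1, 2, 4))))
  its <- implied_timescales(micro, lags,
                            save_interval_ps = ensemble$save_interval_ps)

  say("PCCA lumping into ", config$n_macro, " macrostates")
  macro <- pcca(model, config$n_macro, seed = stage_seed(2L))
  mlab <- macro_labels(micro, macro)

  say("condition-split macrostate kinetics")
  by_cond <- lapply(c("non_bonded", "bonded"), function(cc) {
    sel <- which(ensemble$condition == cc)
    if (length(sel) == 0L) return(NULL)
    est <- condition_macro_T(mlab, config$lag_frames, config$n_macro,
                             select = sel)
    est$pi <- tryCatch(stationary_distribution(
      ifelse(is.na(est$T), 0, est$T)), error = function(e) NULL)
    est
  })
  names(by_cond) <- c("non_bonded", "bonded")

  say("validation: Chapman-Kolmogorov + microstate dispersion")
  ck <- ck_test(mlab, config$lag_frames, kmax = config$ck_kmax,
                n_macro = config$n_macro)
  disp <- microstate_dispersion(ensemble, micro)

  say("pairwise Calpha featurization")
  feats <- pairwise_distances(ensemble)
  frame_macro <- unlist(mlab)

  say("one-vs-one random forest importance")
  keep <- !is.na(frame_macro)
  cls <- config$classifier
  cls$seed <- stage_seed(3L)
  sub <- feats
  sub$values <- feats$values[keep, , drop = FALSE]
  ovo <- train_ovo(sub, frame_macro[keep], cls)

  say("ML community partition (n = ", config$n_communities, ", ",
      config$restarts, " restarts)")
  graph <- importance_graph(ovo$importance, feats$pair_map, n_res,
                            node_labels = ensemble$residue_labels)
  scan <- scan_elbow(graph, 2:min(8L, n_res - 1L),
                     restarts = config$restarts, seed = stage_seed(4L))
  part <- kl_search(graph, config$n_communities,
                    restarts = config$restarts, seed = stage_seed(5L))
  tables <- community_tables(part, ovo$importance, feats$pair_map)

  say("transition path theory")
  pooled <- condition_macro_T(mlab, config$lag_frames, config$n_macro)
  Tm <- ifelse(is.na(pooled$T), 0, pooled$T)
  zero_rows <- which(rowSums(Tm) == 0)
  for (i in zero_rows) Tm[i, i] <- 1   # unreached macrostates become absorbing
  flux <- tryCatch(tpt(Tm, config$tpt_source, config$tpt_target),
                   error = function(e) {
                     say("TPT skipped: ", conditionMessage(e)); NULL
                   })

  run <- list(config = config, truth = truth, cv = cv, micro = micro,
              model = model, timescales = its, macro = macro,
              macro_labels = mlab, by_condition = by_cond, ck = ck,
              dispersion = disp, features = feats, ovo = ovo, graph = graph,
              scan = scan, partition = part, tables = tables, tpt = flux,
              n_data_points = n_frames(ensemble),
              config_hash = config_hash(config))
  class(run) <- "allostate_run"
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

#' @export
print.allostate_run <- function(x, ...) {
  cat("allostate pipeline run (seed ", x$config$seed, ", config ",
      x$config_hash, ")\n", sep = "")
  cat("  data points:", x$n_data_points, "| microstates:", x$micro$k,
      "| macrostates:", x$macro$n_macro, "\n")
  cat("  stationary distribution (pooled):\n")
  pooled <- condition_macro_T(x$macro_labels, x$config$lag_frames,
                              x$config$n_macro)
  print(round(stationary_distribution(ifelse(is.na(pooled$T), 0, pooled$T)), 4))
  cat("  intra-community importance: ",
      sprintf("%.3f%%", 100 * x$partition$objective /
                (sum(x$graph$weights) / 2)),
      " of total\n", sep = "")
  if (!is.null(x$tpt))
    cat("  total A->B flux:", format(x$tpt$total_flux, digits = 4),
        "per lag;", nrow(x$tpt$channels), "channels\n")
  invisible(x)
}

#' Write the report bundle of a pipeline run
#'
#' @param run an `allostate_run`.
#' @param out_dir output directory.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_features_csv(run$cv, p("cv.csv"))
  utils::write.csv(run$timescales, p("implied_timescales.csv"), row.names = FALSE)
  utils::write.csv(run$ck, p("ck_test.csv"), row.names = FALSE)
  utils::write.csv(run$dispersion, p("microstate_dispersion.csv"),
                   row.names = FALSE)
  write_importance_tsv(run$ovo$importance, p("importance.tsv"))
  utils::write.csv(ranked_importance(run$ovo$importance, 5L),
                   p("top_features.csv"), row.names = FALSE)
  write_partition_tsv(run$partition, p("communities.tsv"))
  utils::write.table(run$tables$overall_matrix, p("community_matrix.tsv"),
                     sep = "\t", quote = FALSE)
  if (!is.null(run$tables$state_pairs))
    utils::write.table(run$tables$state_pairs, p("community_state_pairs.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(run$tpt)) write_channels_tsv(run$tpt, p("channels.tsv"))
  for (cc in names(run$by_condition)) {
    bc <- run$by_condition[[cc]]
    if (is.null(bc)) next
    utils::write.csv(bc$T, p(sprintf("macro_T_%s.csv", cc)), row.names = FALSE)
  }
  jsonlite::write_json(
    list(seed = run$config$seed, config_hash = run$config_hash,
         n_data_points = run$n_data_points,
         k_micro = run$micro$k, n_macro = run$macro$n_macro,
         lag_frames = run$config$lag_frames,
         community_objective = run$partition$objective,
         flagged_microstates = sum(run$dispersion$flagged),
         total_flux = if (is.null(run$tpt)) NA else run$tpt$total_flux),
    p("run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
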