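#' End-to-end analysis pipeline on a synthetic cohort
#'
#' Orchestrates generate -> filter -> behavioural summaries and model ->
#' DDM comparison -> mixture clustering into one reproducible run with a
#' manifest.  Physiological stages are optional (they dominate run time)
#' and are enabled with \code{physio = TRUE}, which synthesizes ECG per
#' participant, extracts stimulus-locked iHR epochs and runs the
#' time-resolved condition-effect analysis.
#'
#' @param cfg a \code{\link{study_config}}.
#' @param seed master seed; every stage consumes a logged substream.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @param behavior_mcmc list of MCMC settings for the behavioural model
#'   (NULL skips the Bayesian fit).
#' @param ddm_designs designs to compare (default mod1 and mod2 for a
#'   fast run; pass \code{ddm_design_grid()} for the full grid).
#' @param mixture_K candidate component counts.
#' @param physio run the ECG/cluster stage.
#' @param n_perm permutations for the cluster test.
#' @return list of stage results plus a manifest.
#' @export
run_pipeline <- function(cfg = study_config(n_participants = 12),
                         seed = 1, out_dir = NULL,
                         behavior_mcmc = NULL,
                         ddm_designs = ddm_design_grid()[c("mod1", "mod2")],
                         mixture_K = 1:3,
                         physio = FALSE, n_perm = 1000) {
  stage_seeds <- seed + c(generate = 0, behavior = 1, ddm = 2,
                          mixture = 3, physio = 4)
  manifest <- list(seed = seed, stage_seeds = as.list(stage_seeds),
                   cfg = unclass(cfg), timings = list())
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  set.seed(stage_seeds[["generate"]])
  cohort <- simulate_cohort(cfg)
  manifest$timings$generate <- tic() - t0

  threat <- cohort$trials[cohort$trials$trial_type == "threat", ]
  filt <- filter_anticipations(threat)
  summ <- avoidance_summary(filt$kept)

  t0 <- tic()
  set.seed(stage_seeds[["behavior"]])
  beh_fit <- NULL
  if (!is.null(behavior_mcmc)) {
    beh_fit <- do.call(fit_hierarchical_logistic,
                       c(list(trials = filt$kept), behavior_mcmc))
  }
  manifest$timings$behavior <- tic() - t0

  t0 <- tic()
  set.seed(stage_seeds[["ddm"]])
  ddm_tab <- ddm_compare_designs(filt$kept, designs = ddm_designs, mode = "ml")
  manifest$timings$ddm <- tic() - t0

  t0 <- tic()
  set.seed(stage_seeds[["mixture"]])
  mix <- mixture_select_K(filt$kept, K_range = mixture_K, n_restarts = 5)
  manifest$timings$mixture <- tic() - t0

  physio_res <- NULL
  if (physio) {
    t0 <- tic()
    set.seed(stage_seeds[["physio"]])
    epochs <- list(); designs <- list()
    for (i in seq_along(cohort$profiles)) {
      pr <- cohort$profiles[[i]]
      tr <- cohort$trials[cohort$trials$participant_id == pr$participant_id, ]
      ecg <- synthesize_ecg(pr, tr, cfg)
      filtered <- bandpass_zero_phase(ecg$samples, ecg$fs, 1, 100)
      beats <- detect_r_peaks(filtered, ecg$fs)
      ibi <- correct_ibis(compute_ibis(beats))
      ep <- epoch_ihr(ibi, ecg$event_markers)
      epochs[[pr$participant_id]] <- zscore_within_participant(ep)
      designs[[pr$participant_id]] <- spm_design(tr)
    }
    bs <- fit_trialwise_glm(epochs, designs, formula_id = 1)
    cl <- find_clusters(bs, "condition", min_duration_s = 0.1)
    cl <- cluster_permutation_test(bs, "condition", cl, n_perm = n_perm)
    physio_res <- list(beta_series = bs, condition_clusters = cl)
    manifest$timings$physio <- tic() - t0
  }

  res <- list(cohort = cohort, filter = filt, avoidance = summ,
              behavior_fit = beh_fit, ddm_comparison = ddm_tab,
              mixture = mix, physio = physio_res, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_trials_csv(cohort$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(summ, file.path(out_dir, "avoidance_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(ddm_tab),
                     file.path(out_dir, "ddm_comparison.csv"), row.names = FALSE)
    utils::write.csv(mix$table, file.path(out_dir, "mixture_bic.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Defective RT densities
#'
#' Kernel density of RTs for each response type, weighted by the relative
#' frequency of that response among responded trials, so the avoid and
#' approach curves jointly integrate to one.
#'
#' @param trials responded threat trials.
#' @param bw kernel bandwidth passed to \code{density}.
#' @return list with components \code{avoid} and \code{approach}, each a
#'   list(x, y, weight); a response type with no trials gets weight 0 and
#'   a zero curve.
#' @export
defective_rt_density <- function(trials, bw = "nrd0") {
  tr <- trials[!is.na(trials$rt) & !is.na(trials$response), ]
  n <- nrow(tr)
  out <- list()
  for (resp in c("avoid", "approach")) {
    rt <- tr$rt[tr$response == resp]
    w <- length(rt) / n
    if (length(rt) >= 2) {
      d <- density(rt, bw = bw)
      out[[resp]] <- list(x = d$x, y = d$y * w, weight = w)
    } else {
      out[[resp]] <- list(x = numeric(0), y = numeric(0), weight = w)
    }
  }
  out
}

#' Summary report of a pipeline run
#'
#' @param run output of \code{\link{run_pipeline}}.
#' @return invisibly, a list of the printed tables.
#' @export
pipeline_report <- function(run) {
  cat("== Cohort ==\n")
  cls <- table(vapply(run$cohort$profiles, function(p) p$latent_class, ""))
  cat(sprintf("  %d participants (%s)\n", length(run$cohort$profiles),
              paste(names(cls), cls, sep = "=", collapse = ", ")))
  cat(sprintf("  anticipations removed: %d (%.2f%%), non-responses: %d\n",
              run$filter$n_removed, run$filter$pct_removed,
              run$filter$n_nonresponse))
  cat("\n== Avoidance by condition ==\n")
  ag <- aggregate(p_avoid ~ condition, run$avoidance, mean)
  print(ag)
  cat("\n== DDM design comparison ==\n")
  print(as.data.frame(run$ddm_comparison)[, c("design", "criterion", "delta", "best")])
  cat("\n== Mixture BIC ==\n")
  print(run$mixture$table)
  cat(sprintf("  best K = %d\n", run$mixture$best_K))
  if (!is.null(run$physio)) {
    cat("\n== iHR condition clusters ==\n")
    print(run$physio$condition_clusters)
  }
  invisible(list(avoidance = ag, ddm = run$ddm_comparison,
                 mixture = run$mixture$table))
}
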