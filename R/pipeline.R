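#' Build a pipeline run configuration
#'
#' A run pairs one reach session with one grasp session sharing a neuron
#' roster (one simulated "recording day") and fixes every analysis option,
#' so a config plus its seeds reproduces a run exactly.
#'
#' @param out_dir output directory for reports and figures.
#' @param seed master integer seed; session and decoder seeds derive from it.
#' @param ensemble neuron spec data frame, or `NULL` to build one from
#'   `counts`/`effect` via [default_ensemble()].
#' @param counts category counts `c(reach_only, grasp_only, both, untuned)`
#'   used when `ensemble` is `NULL`.
#' @param effect preset passed to [default_ensemble()].
#' @param reach_dir,grasp_dir optional directories of pre-existing sessions
#'   (read with [read_session()]); when given, simulation is skipped.
#' @param pre_s,post_s analysis window (seconds around Light ON).
#' @param trials_reach,trials_grasp trials per action when simulating.
#' @param alpha ANOVA significance level.
#' @param mi_fraction cumulative-MI threshold fraction.
#' @param mi_scope indicator-sample scope, `"full_window"` or
#'   `"movement_only"`.
#' @param hyper_grid SVM grid (default [default_svm_grid()]).
#' @param eval_scheme decoder evaluation scheme, `"cv"` or `"held_out"`.
#' @param run_decoding set `FALSE` to skip the (slower) SVM experiments.
#' @param make_plots set `FALSE` to skip figure files.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, ensemble = NULL,
                       counts = c(7L, 5L, 9L, 10L),
                       effect = "strong", reach_dir = NULL, grasp_dir = NULL,
                       pre_s = 0.5, post_s = 1.7,
                       trials_reach = 25L, trials_grasp = 50L,
                       alpha = 0.05, mi_fraction = 0.9,
                       mi_scope = "full_window",
                       hyper_grid = default_svm_grid(), eval_scheme = "cv",
                       run_decoding = TRUE, make_plots = TRUE) {
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 ensemble = ensemble, counts = as.integer(counts),
                 effect = effect, reach_dir = reach_dir,
                 grasp_dir = grasp_dir, pre_s = pre_s, post_s = post_s,
                 trials_reach = as.integer(trials_reach),
                 trials_grasp = as.integer(trials_grasp), alpha = alpha,
                 mi_fraction = mi_fraction, mi_scope = mi_scope,
                 hyper_grid = hyper_grid, eval_scheme = eval_scheme,
                 run_decoding = isTRUE(run_decoding),
                 make_plots = isTRUE(make_plots)),
            class = "run_config")
}

decoding_result_row <- function(res, task) {
  data.frame(task = task, subset = res$subset_name,
             n_neurons = length(res$neuron_ids), accuracy = res$accuracy,
             C = res$C, gamma = res$gamma, eval_scheme = res$eval_scheme,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a paired reach + grasp session, then runs alignment
#' and binning, the ANOVA report, the MI profile with cumulative-information
#' thresholds and tuning categories, the contribution table, and the two SVM
#' decoding experiments. Writes `stats-report-<task>.tsv`, `mi-profile.tsv`,
#' `contributions.tsv`, `decoding-results.tsv`, `summary.json`, and PSTH /
#' MI / accuracy figures into `config$out_dir`. Deterministic given the
#' config (including seeds); the summary contains no timestamps.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with all intermediate objects and the summary.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$reach_dir) || !is.null(config$grasp_dir)) {
    if (is.null(config$reach_dir) || is.null(config$grasp_dir))
      stop("both reach_dir and grasp_dir are required when reading sessions; ",
           "missing: ", if (is.null(config$reach_dir)) "reach_dir" else "grasp_dir")
    reach <- read_session(config$reach_dir)
    grasp <- read_session(config$grasp_dir)
  } else {
    ens <- config$ensemble
    if (is.null(ens))
      ens <- default_ensemble(config$counts[1], config$counts[2],
                              config$counts[3], config$counts[4],
                              config$effect, seed = config$seed)
    reach <- simulate_session(session_config(
      "reach", ens, config$trials_reach, config$pre_s, config$post_s,
      seed = config$seed + 1L))
    grasp <- simulate_session(session_config(
      "grasp", ens, config$trials_grasp, config$pre_s, config$post_s,
      seed = config$seed + 2L))
  }
  if (!identical(names(reach$spikes), names(grasp$spikes)))
    stop("reach and grasp sessions must share the neuron roster")

  al_r <- align_and_window(reach, config$pre_s, config$post_s)
  al_g <- align_and_window(grasp, config$pre_s, config$post_s)
  bin_r <- bin_rates(al_r)
  bin_g <- bin_rates(al_g)
  ind_r <- indicator_samples(al_r, scope = config$mi_scope)
  ind_g <- indicator_samples(al_g, scope = config$mi_scope)

  stats_r <- anova_report(bin_r, config$alpha)
  stats_g <- anova_report(bin_g, config$alpha)
  profile <- mi_profile(ind_r, ind_g, config$mi_fraction)
  contrib <- contribution_table(profile)

  write.table(stats_r, file.path(config$out_dir, "stats-report-reach.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(stats_g, file.path(config$out_dir, "stats-report-grasp.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prof_out <- profile
  prof_out$thr_reach <- attr(profile, "thr_reach")
  prof_out$thr_grasp <- attr(profile, "thr_grasp")
  write.table(prof_out, file.path(config$out_dir, "mi-profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(contrib, file.path(config$out_dir, "contributions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  ensembles <- addition <- NULL
  dec_rows <- list()
  if (config$run_decoding) {
    ens_r <- experiment_ensembles(bin_r, profile,
                                  hyper_grid = config$hyper_grid,
                                  seed = config$seed + 11L,
                                  eval_scheme = config$eval_scheme)
    ens_g <- experiment_ensembles(bin_g, profile,
                                  hyper_grid = config$hyper_grid,
                                  seed = config$seed + 12L,
                                  eval_scheme = config$eval_scheme)
    addition <- experiment_addition(bin_r, bin_g, profile,
                                    hyper_grid = config$hyper_grid,
                                    seed = config$seed + 13L,
                                    eval_scheme = config$eval_scheme)
    ensembles <- list(reach = ens_r, grasp = ens_g)
    for (task in c("reach", "grasp")) {
      for (res in ensembles[[task]])
        if (!is.null(res)) dec_rows[[length(dec_rows) + 1L]] <-
            decoding_result_row(res, task)
      add <- addition[[task]]
      if (!is.null(add)) {
        dec_rows[[length(dec_rows) + 1L]] <- decoding_result_row(add$base, task)
        dec_rows[[length(dec_rows) + 1L]] <-
          decoding_result_row(add$combined, task)
      }
    }
    dec_tab <- do.call(rbind, dec_rows)
    write.table(dec_tab, file.path(config$out_dir, "decoding-results.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (config$make_plots) {
    plot_psth(bin_r, file.path(config$out_dir, "psth-reach.png"))
    plot_psth(bin_g, file.path(config$out_dir, "psth-grasp.png"))
    plot_mi_profile(profile, file.path(config$out_dir, "mi-profile.png"))
    if (config$run_decoding)
      plot_decoding(do.call(rbind, dec_rows),
                    file.path(config$out_dir, "decoding.png"))
  }

  summary <- list(
    seed = config$seed,
    options = list(pre_s = config$pre_s, post_s = config$post_s,
                   alpha = config$alpha, mi_fraction = config$mi_fraction,
                   mi_scope = config$mi_scope,
                   eval_scheme = config$eval_scheme,
                   trials_reach = config$trials_reach,
                   trials_grasp = config$trials_grasp),
    n_neurons = length(reach$spikes),
    thresholds = list(reach = attr(profile, "thr_reach"),
                      grasp = attr(profile, "thr_grasp")),
    categories = as.list(table(profile$category)),
    task_related = list(reach = sum(stats_r$is_task_related),
                        grasp = sum(stats_g$is_task_related)),
    decoding = if (length(dec_rows)) do.call(rbind, dec_rows) else NULL
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12, dataframe = "rows")

  invisible(list(reach = reach, grasp = grasp, binned_reach = bin_r,
                 binned_grasp = bin_g, stats_reach = stats_r,
                 stats_grasp = stats_g, profile = profile,
                 contributions = contrib, ensembles = ensembles,
                 addition = addition, summary = summary))
}

# Trial-averaged firing-rate (PSTH) panels, one per neuron (first 12), one
# curve per action, aligned to Light ON.
plot_psth <- function(binned, path) {
  ids <- binned$neuron_ids[seq_len(min(12L, length(binned$neuron_ids)))]
  t_mid <- binned$bin_starts_s + binned$bin_width_s / 2
  grDevices::png(path, width = 1200, height = 900, res = 120)
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(3, 4), mar = c(3, 3, 2, 1), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(old), add = TRUE)
  for (id in ids) {
    j <- match(id, binned$neuron_ids)
    curves <- sapply(1:4, function(a)
      colMeans(binned$values[binned$labels == a, j, , drop = FALSE][, 1, ]))
    graphics::matplot(t_mid, curves, type = "l", lty = 1, lwd = 1.5,
                      col = c("red", "green3", "blue", "skyblue"),
                      xlab = "time from Light ON (s)", ylab = "rate (Hz)",
                      main = id)
    graphics::abline(v = 0, col = "grey40", lty = 2)
  }
}

# Per-neuron MI bar chart, reach and grasp side by side, with thresholds.
plot_mi_profile <- function(profile, path) {
  grDevices::png(path, width = 1200, height = 500, res = 120)
  on.exit(grDevices::dev.off())
  m <- rbind(profile$mi_reach, profile$mi_grasp)
  graphics::barplot(m, beside = TRUE, names.arg = profile$neuron,
                    col = c("blue", "red"), las = 2, cex.names = 0.6,
                    ylab = "MI (bits)", legend.text = c("reach", "grasp"))
  graphics::abline(h = attr(profile, "thr_reach"), col = "blue", lty = 2)
  graphics::abline(h = attr(profile, "thr_grasp"), col = "red", lty = 2)
}

# Decoding accuracies by subset, grouped by task.
plot_decoding <- function(dec_tab, path) {
  grDevices::png(path, width = 900, height = 500, res = 120)
  on.exit(grDevices::dev.off())
  subsets <- unique(dec_tab$subset)
  acc <- sapply(c("reach", "grasp"), function(task)
    vapply(subsets, function(s) {
      v <- dec_tab$accuracy[dec_tab$task == task & dec_tab$subset == s]
      if (length(v)) v[1] else NA_real_
    }, numeric(1)))
  graphics::barplot(t(acc), beside = TRUE, names.arg = subsets, las = 2,
                    col = c("steelblue", "tomato"), ylim = c(0, 1),
                    ylab = "decoding accuracy",
                    legend.text = c("reach", "grasp"))
  graphics::abline(h = 0.25, lty = 2, col = "grey40")
}
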