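#' Align spikes to Light ON and cut the analysis window
#'
#' Re-expresses every spike time relative to its trial's Light ON (t = 0) and
#' keeps spikes in the half-open window `[-pre_s, +post_s)`. Spikes exactly at
#' the upper bound are excluded; spikes exactly at Light ON belong to the
#' first post-cue bin downstream.
#'
#' @param session a `pmd_session`.
#' @param pre_s,post_s window bounds in seconds; default to the values stored
#'   on the session (0.5 s before to 1.7 s after Light ON).
#' @return list of class `aligned_spikes`: `spikes[[neuron]][[trial]]` are
#'   aligned spike times, plus `labels`, `neuron_ids`, `task`, and the window.
#' @export
align_and_window <- function(session, pre_s = session$pre_s,
                             post_s = session$post_s) {
  if (!inherits(session, "pmd_session")) stop("not a pmd_session")
  if (pre_s <= 0 || post_s <= 0) stop("pre_s and post_s must be > 0")
  ev <- session$events
  bad <- which(ev$light_on_s - pre_s < 0 |
                 ev$light_on_s + post_s > session$duration_s)
  if (length(bad))
    stop("analysis window falls outside the recording for trials: ",
         paste(bad, collapse = ", "))
  n_trials <- nrow(ev)
  aligned <- lapply(session$spikes, function(st) {
    lapply(seq_len(n_trials), function(i) {
      rel <- st[st >= ev$light_on_s[i] - pre_s &
                  st < ev$light_on_s[i] + post_s] - ev$light_on_s[i]
      rel
    })
  })
  structure(list(spikes = aligned, labels = ev$action,
                 neuron_ids = names(session$spikes), task = session$task,
                 pre_s = pre_s, post_s = post_s, n_trials = n_trials),
            class = "aligned_spikes")
}

#' Bin aligned spikes into firing rates
#'
#' Counts spikes in consecutive half-open 100-ms bins across the analysis
#' window and converts counts to rates in Hz. A bin is tagged `REST` if it
#' ends at or before Light ON, `MOVE` otherwise; the default (-0.5, +1.7) s
#' window gives 22 bins, the first 5 tagged `REST`.
#'
#' @param aligned output of [align_and_window()].
#' @param bin_width_s bin width in seconds (default 0.1).
#' @return list of class `binned_rates`: `values` is a trials x neurons x
#'   bins array of rates (Hz); also `bin_epochs` (`"REST"`/`"MOVE"`),
#'   `bin_starts_s`, `labels`, `task`, `bin_width_s`.
#' @export
bin_rates <- function(aligned, bin_width_s = 0.1) {
  if (!inherits(aligned, "aligned_spikes")) stop("not aligned_spikes")
  if (bin_width_s <= 0) stop("bin_width_s must be > 0")
  total <- aligned$pre_s + aligned$post_s
  n_bins <- as.integer(floor(total / bin_width_s + 1e-9))
  if (n_bins < 1L) stop("window shorter than one bin")
  starts <- -aligned$pre_s + (seq_len(n_bins) - 1L) * bin_width_s
  epochs <- ifelse(starts + bin_width_s <= 1e-9, "REST", "MOVE")
  n_neurons <- length(aligned$neuron_ids)
  vals <- array(0, dim = c(aligned$n_trials, n_neurons, n_bins),
                dimnames = list(NULL, aligned$neuron_ids, NULL))
  for (j in seq_len(n_neurons)) {
    for (i in seq_len(aligned$n_trials)) {
      ts <- aligned$spikes[[j]][[i]]
      if (!length(ts)) next
      idx <- floor((ts + aligned$pre_s) / bin_width_s) + 1
      idx <- idx[idx >= 1 & idx <= n_bins]  # spikes past the last full bin drop
      if (length(idx))
        vals[i, j, ] <- tabulate(idx, nbins = n_bins) / bin_width_s
    }
  }
  structure(list(values = vals, bin_epochs = epochs, bin_starts_s = starts,
                 bin_width_s = bin_width_s, labels = aligned$labels,
                 task = aligned$task, neuron_ids = aligned$neuron_ids),
            class = "binned_rates")
}

#' Extract 10-ms spike-indicator samples
#'
#' For every 10-ms step of the chosen scope, in every trial, the indicator is
#' 1 if the neuron fired at least one spike in that step and 0 otherwise.
#' Each sample carries its trial's action label; samples are pooled across
#' trials, giving `trials * floor(window / step_s)` samples per neuron.
#'
#' @param aligned output of [align_and_window()].
#' @param step_s indicator resolution in seconds (default 0.01).
#' @param scope `"full_window"` (default) pools rest and movement steps;
#'   `"movement_only"` keeps steps starting at or after Light ON.
#' @return list of class `indicator_samples`: `spk` is a samples x neurons
#'   0/1 integer matrix, `labels` the per-sample action labels.
#' @export
indicator_samples <- function(aligned, step_s = 0.01,
                              scope = c("full_window", "movement_only")) {
  if (!inherits(aligned, "aligned_spikes")) stop("not aligned_spikes")
  scope <- match.arg(scope)
  if (step_s <= 0) stop("step_s must be > 0")
  total <- aligned$pre_s + aligned$post_s
  n_steps <- as.integer(floor(total / step_s + 1e-9))
  starts <- -aligned$pre_s + (seq_len(n_steps) - 1L) * step_s
  keep <- if (scope == "movement_only") starts >= -1e-9 else rep(TRUE, n_steps)
  n_keep <- sum(keep)
  n_neurons <- length(aligned$neuron_ids)
  n_samples <- aligned$n_trials * n_keep
  spk <- matrix(0L, nrow = n_samples, ncol = n_neurons,
                dimnames = list(NULL, aligned$neuron_ids))
  for (j in seq_len(n_neurons)) {
    for (i in seq_len(aligned$n_trials)) {
      ts <- aligned$spikes[[j]][[i]]
      if (!length(ts)) next
      idx <- floor((ts + aligned$pre_s) / step_s) + 1
      idx <- idx[idx >= 1 & idx <= n_steps]
      ind <- tabulate(idx, nbins = n_steps)[keep] > 0L
      spk[(i - 1L) * n_keep + seq_len(n_keep), j] <- as.integer(ind)
    }
  }
  structure(list(spk = spk, labels = rep(aligned$labels, each = n_keep),
                 step_s = step_s, scope = scope, task = aligned$task,
                 neuron_ids = aligned$neuron_ids,
                 steps_per_trial = n_keep, n_trials = aligned$n_trials),
            class = "indicator_samples")
}
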