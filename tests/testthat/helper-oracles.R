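# Independent oracles and small fixture builders shared across test files.

# Brute-force plug-in MI over the 2 x 4 (spk, y) contingency table, written
# as the literal double sum so it stays independent of the package's
# vectorized implementation. `n1` = spike-step counts per action, `ny` =
# sample counts per action.
brute_force_mi <- function(n1, ny, py = rep(0.25, 4)) {
  stopifnot(length(n1) == 4, length(ny) == 4, all(n1 <= ny))
  p_spk_given_y <- rbind(1 - n1 / ny, n1 / ny)  # rows: spk = 0, 1
  p_spk <- as.numeric(p_spk_given_y %*% py)
  mi <- 0
  for (y in 1:4) {
    for (spk in 1:2) {
      pc <- p_spk_given_y[spk, y]
      if (pc > 0) mi <- mi + py[y] * pc * log2(pc / p_spk[spk])
    }
  }
  mi
}

# Closed-form MI for known per-action indicator probabilities.
closed_form_mi <- function(p1y, py = rep(0.25, 4)) {
  n <- 1e6L
  brute_force_mi(round(p1y * n), rep(n, 4), py)
}

# Expand per-action counts into (spk, labels) sample vectors.
samples_from_counts <- function(n1, ny) {
  spk <- unlist(lapply(1:4, function(y) rep(c(1L, 0L), c(n1[y], ny[y] - n1[y]))))
  labels <- rep(1:4, ny)
  list(spk = spk, labels = labels)
}

# Hand-built session with exactly known spikes and events.
manual_session <- function(spikes, events, task = "reach",
                           duration_s = max(events$light_off_s) + 5) {
  structure(list(task = task, spikes = spikes, events = events,
                 duration_s = duration_s, ground_truth = NULL,
                 pre_s = 0.5, post_s = 1.7),
            class = c("pmd_session"))
}

# Small simulated recording day (reach + grasp sharing a roster).
simulated_day <- function(ens, seed, trials_reach = 25L, trials_grasp = 50L,
                          post_s = 1.7) {
  reach <- simulate_session(session_config("reach", ens, trials_reach,
                                           post_s = post_s, seed = seed + 1L))
  grasp <- simulate_session(session_config("grasp", ens, trials_grasp,
                                           post_s = post_s, seed = seed + 2L))
  list(reach = reach, grasp = grasp)
}

# Coarse SVM grid used where the test exercises behaviour, not grid search.
small_grid <- function() list(C = 2^c(-1, 3, 7), gamma = 2^c(-7, -3, 1))
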