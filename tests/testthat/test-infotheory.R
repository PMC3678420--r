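test_that("spike_action_mi equals the brute-force plug-in on random tables", {
  set.seed(202)
  for (rep in 1:200) {
    ny <- rep(sample(20:60, 1), 4)
    n1 <- vapply(ny, function(n) rbinom(1, n, runif(1)), numeric(1))
    sm <- samples_from_counts(n1, ny)
    expect_equal(spike_action_mi(sm$spk, sm$labels),
                 brute_force_mi(n1, ny), tolerance = 1e-12)
  }
})

test_that("closed-form MI cases", {
  # action-independent spiking carries no information
  sm <- samples_from_counts(c(12, 12, 12, 12), rep(40, 4))
  expect_equal(spike_action_mi(sm$spk, sm$labels), 0, tolerance = 1e-12)
  # deterministic spk <=> y1 gives the binary entropy of 1/4
  sm <- samples_from_counts(c(40, 0, 0, 0), rep(40, 4))
  hb <- -(1 / 4) * log2(1 / 4) - (3 / 4) * log2(3 / 4)
  expect_equal(spike_action_mi(sm$spk, sm$labels), hb, tolerance = 1e-12)
  expect_equal(hb, 0.8112781245, tolerance = 1e-9)
  # worked example: 30/100 spikes on y1, 10/100 elsewhere
  sm <- samples_from_counts(c(30, 10, 10, 10), rep(100, 4))
  expect_equal(spike_action_mi(sm$spk, sm$labels),
               brute_force_mi(c(30, 10, 10, 10), rep(100, 4)),
               tolerance = 1e-12)
  expect_gt(spike_action_mi(sm$spk, sm$labels), 0)
})

test_that("MI input contracts are enforced", {
  sm <- samples_from_counts(c(5, 5, 5, 0), c(20, 20, 20, 20))
  sm$labels[sm$labels == 4L] <- 3L  # action 4 absent
  expect_error(spike_action_mi(sm$spk, sm$labels), "absent")
  sm2 <- samples_from_counts(c(5, 5, 5, 5), c(20, 20, 20, 30))
  expect_error(spike_action_mi(sm2$spk, sm2$labels), "unbalanced")
  expect_gte(spike_action_mi(sm2$spk, sm2$labels, p_y = "empirical"), 0)
  expect_error(spike_action_mi(integer(0), integer(0)), "no samples")
  expect_error(spike_action_mi(c(0L, 2L), c(1L, 2L)), "binary")
})

test_that("MI is bounded by 0 and min(H(spk), 2) bits", {
  set.seed(203)
  for (rep in 1:50) {
    ny <- rep(30, 4)
    n1 <- vapply(ny, function(n) rbinom(1, n, runif(1)), numeric(1))
    sm <- samples_from_counts(n1, ny)
    mi <- spike_action_mi(sm$spk, sm$labels)
    p1 <- sum(n1) / sum(ny)
    h_spk <- if (p1 %in% c(0, 1)) 0 else -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
    expect_gte(mi, 0)
    expect_lte(mi, min(h_spk, 2) + 1e-12)
  }
})

test_that("mi_threshold implements the cumulative-90% rule", {
  expect_equal(mi_threshold(c(0.4, 0.3, 0.2, 0.1)), 0.2)
  expect_equal(mi_threshold(c(0.1, 0.2, 0.4, 0.3)), 0.2)  # order-free
  expect_equal(mi_threshold(0.37), 0.37)
  expect_equal(mi_threshold(rep(0.25, 4)), 0.25)  # reaches 90% at the 4th
  expect_equal(mi_threshold(c(0, 0, 0)), 0)
  expect_equal(mi_threshold(c(1, 0, 0), fraction = 0.5), 1)
  expect_error(mi_threshold(numeric(0)), "empty")
  expect_error(mi_threshold(c(0.1, -0.2)), ">= 0")
})

test_that("threshold coverage invariant on random MI lists", {
  set.seed(204)
  for (rep in 1:30) {
    mi <- runif(sample(3:40, 1))
    thr <- mi_threshold(mi)
    tuned <- mi[mi >= thr]
    expect_gte(sum(tuned), 0.9 * sum(mi) - 1e-12)
    expect_lt(sum(tuned) - thr, 0.9 * sum(mi))
  }
})

test_that("categorize_neurons applies inclusive thresholding", {
  expect_equal(categorize_neurons(0.5, 0.5, 0.2, 0.2), "BOTH")
  expect_equal(categorize_neurons(0.5, 0.1, 0.2, 0.2), "REACH_ONLY")
  expect_equal(categorize_neurons(0.1, 0.5, 0.2, 0.2), "GRASP_ONLY")
  expect_equal(categorize_neurons(0, 0, 0.2, 0.2), "UNTUNED")
  # the threshold neuron itself counts as tuned (>=)
  expect_equal(categorize_neurons(0.2, 0.19, 0.2, 0.2), "REACH_ONLY")
  expect_equal(
    categorize_neurons(c(0.5, 0.1), c(0.5, 0.1), 0.2, 0.2),
    c("BOTH", "UNTUNED"))
})

test_that("mi_profile ties MI, thresholds and categories together", {
  ens <- default_ensemble(2, 2, 2, 2, "strong", seed = 18)
  day <- simulated_day(ens, seed = 300, trials_reach = 10L, trials_grasp = 10L)
  ir <- indicator_samples(align_and_window(day$reach))
  ig <- indicator_samples(align_and_window(day$grasp))
  prof <- mi_profile(ir, ig)
  expect_s3_class(prof, "mi_profile")
  expect_equal(prof$neuron, ens$neuron_id)
  expect_equal(attr(prof, "thr_reach"), mi_threshold(prof$mi_reach))
  expect_equal(prof$category,
               categorize_neurons(prof$mi_reach, prof$mi_grasp,
                                  attr(prof, "thr_reach"),
                                  attr(prof, "thr_grasp")))
  # roster mismatch is refused
  ig_bad <- ig
  ig_bad$neuron_ids <- rev(ig$neuron_ids)
  expect_error(mi_profile(ir, ig_bad), "roster")
})

test_that("contribution_table computes and averages information shares", {
  prof <- structure(
    data.frame(neuron = c("a", "b"), mi_reach = c(0.3, 0.6),
               mi_grasp = c(0, 0.5),
               category = c("REACH_ONLY", "BOTH"),
               stringsAsFactors = FALSE),
    thr_reach = 0.3, thr_grasp = 0.5,
    class = c("mi_profile", "data.frame"))
  ct <- contribution_table(prof)
  reach <- ct[ct$task == "reach", ]
  expect_equal(reach$share_pct[reach$category == "REACH_ONLY"], 100 / 3,
               tolerance = 1e-9)
  expect_equal(reach$share_pct[reach$category == "BOTH"], 200 / 3,
               tolerance = 1e-9)
  expect_equal(sum(reach$share_pct), 100)
  grasp <- ct[ct$task == "grasp", ]
  expect_equal(grasp$share_pct[grasp$category == "BOTH"], 100)
  # zero-information task reports NA shares
  prof0 <- prof
  prof0$mi_grasp <- c(0, 0)
  ct0 <- contribution_table(prof0)
  expect_true(all(is.na(ct0$share_pct[ct0$task == "grasp"])))
  # averaging across two sessions is the arithmetic mean of shares
  prof2 <- prof
  prof2$mi_reach <- c(0.6, 0.6)
  ct_avg <- contribution_table(list(prof, prof2))
  r_avg <- ct_avg[ct_avg$task == "reach" & ct_avg$category == "BOTH", ]
  expect_equal(r_avg$share_pct, mean(c(200 / 3, 50)), tolerance = 1e-9)
})
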