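test_that("event table matches the balanced paradigm", {
  ens <- default_ensemble(1, 1, 1, 1, "strong", seed = 3)
  reach <- simulate_session(session_config("reach", ens, seed = 11))
  expect_equal(nrow(reach$events), 100L)
  expect_equal(as.integer(table(reach$events$action)), rep(25L, 4))
  grasp <- simulate_session(session_config("grasp", ens, seed = 11))
  expect_equal(nrow(grasp$events), 200L)
  expect_equal(as.integer(table(grasp$events$action)), rep(50L, 4))
  # trial clock invariants: ordered, non-overlapping, 1.6-2.6 s cue period
  ev <- reach$events
  expect_true(all(diff(ev$light_on_s) > 0))
  expect_true(all(ev$light_off_s - ev$light_on_s >= 1.6 - 1e-9))
  expect_true(all(ev$light_off_s - ev$light_on_s <= 2.6 + 1e-9))
  expect_true(all(ev$light_on_s[-1] - ev$light_off_s[-nrow(ev)] >= 1 - 1e-9))
})

test_that("zero-rate neurons never fire and spike times are sorted", {
  ens <- rbind(
    neuron_spec("mute", "UNTUNED", baseline_rate = 0),
    neuron_spec("live", "BOTH", 5, 2, 1, 2, 0.5)
  )
  s <- simulate_session(session_config("reach", ens, 5L, seed = 7))
  expect_length(s$spikes$mute, 0)
  expect_gt(length(s$spikes$live), 0)
  expect_false(is.unsorted(s$spikes$live))
})

test_that("movement-epoch spike counts match the Poisson expectation", {
  # baseline 5 Hz, gain 3, depth 0: 15 Hz during movement, so the summed
  # count over 100 one-second windows is Poisson(1500); check the 99% band.
  ens <- neuron_spec("n1", "BOTH", 5, 3, 1, 1, tuning_depth = 0)
  s <- simulate_session(session_config("reach", ens, 25L, seed = 21))
  counts <- vapply(seq_len(100), function(i) {
    on <- s$events$light_on_s[i]
    sum(s$spikes$n1 >= on & s$spikes$n1 < on + 1)
  }, numeric(1))
  band <- qpois(c(0.005, 0.995), 1500)
  expect_gte(sum(counts), band[1])
  expect_lte(sum(counts), band[2])
})

test_that("rate fidelity holds over 200 trials in rest and movement", {
  ens <- neuron_spec("n1", "REACH_ONLY", 4, 2, 2, NA, 0.5)
  s <- simulate_session(session_config("grasp", ens, 50L, seed = 33))
  # grasp task: no grasp preference, so movement rate is 4 * 2 = 8 Hz on
  # every trial; rest rate 4 Hz in the 0.5 s before Light ON.
  mv <- sum(vapply(seq_len(200), function(i) {
    on <- s$events$light_on_s[i]
    sum(s$spikes$n1 >= on & s$spikes$n1 < on + 1.6)
  }, numeric(1)))
  rest <- sum(vapply(seq_len(200), function(i) {
    on <- s$events$light_on_s[i]
    sum(s$spikes$n1 >= on - 0.5 & s$spikes$n1 < on)
  }, numeric(1)))
  mv_band <- qpois(c(5e-4, 1 - 5e-4), 8 * 1.6 * 200)
  rest_band <- qpois(c(5e-4, 1 - 5e-4), 4 * 0.5 * 200)
  expect_true(mv >= mv_band[1] && mv <= mv_band[2])
  expect_true(rest >= rest_band[1] && rest <= rest_band[2])
})

test_that("simulation and ensemble generation are deterministic in the seed", {
  ens1 <- default_ensemble(2, 2, 2, 2, "strong", seed = 5)
  ens2 <- default_ensemble(2, 2, 2, 2, "strong", seed = 5)
  expect_identical(ens1, ens2)
  cfg <- session_config("grasp", ens1, 10L, seed = 9)
  expect_identical(simulate_session(cfg), simulate_session(cfg))
  expect_false(identical(
    simulate_session(cfg),
    simulate_session(session_config("grasp", ens1, 10L, seed = 10))))
})

test_that("default_ensemble plants the requested categories", {
  ens <- default_ensemble(7, 5, 9, 10, "strong", seed = 2)
  cats <- c("REACH_ONLY", "GRASP_ONLY", "BOTH", "UNTUNED")
  expect_equal(as.integer(table(factor(ens$category, cats))),
               c(7L, 5L, 9L, 10L))
  one <- default_ensemble(0, 0, 0, 1, "strong", seed = 2)
  expect_equal(one$category, "UNTUNED")
  expect_true(is.na(one$preferred_action_reach))
  expect_true(is.na(one$preferred_action_grasp))
  expect_error(default_ensemble(-1, 0, 0, 1, seed = 1), "counts")
  expect_error(default_ensemble(0, 0, 0, 0, seed = 1), "at least one")
})

test_that("configuration errors are caught", {
  ens <- default_ensemble(1, 1, 1, 1, seed = 1)
  expect_error(session_config("walk", ens), "task")
  expect_error(session_config("reach", ens, trials_per_action = 0), "positive")
  expect_error(session_config("reach", ens[0, ]), "at least one neuron")
  bad <- neuron_spec("x", "UNTUNED", 3)
  bad$tuning_depth <- 2
  expect_error(validate_ensemble(bad), "tuning_depth")
  bad2 <- neuron_spec("x", "UNTUNED", 3)
  bad2$preferred_action_reach <- 2L
  expect_error(validate_ensemble(bad2), "UNTUNED")
})

test_that("session round-trips through the plain-text format", {
  ens <- rbind(default_ensemble(1, 1, 2, 1, "strong", seed = 4),
               neuron_spec("mute", "UNTUNED", 0))
  s <- simulate_session(session_config("reach", ens, 10L, seed = 13))
  dir <- withr::local_tempdir()
  write_session(s, dir)
  expect_equal(nrow(read.delim(file.path(dir, "events.tsv"))), 40L)
  s2 <- read_session(dir)
  expect_equal(s2$task, s$task)
  expect_equal(names(s2$spikes), names(s$spikes))
  expect_length(s2$spikes$mute, 0)  # silent neuron kept in the roster
  for (id in names(s$spikes))
    expect_equal(s2$spikes[[id]], s$spikes[[id]], tolerance = 1e-6)
  expect_equal(s2$events$action, s$events$action)
  expect_equal(s2$ground_truth$category, s$ground_truth$category)
  # identical MI downstream
  mi1 <- with(indicator_samples(align_and_window(s)),
              vapply(seq_len(ncol(spk)), function(j)
                spike_action_mi(spk[, j], labels), numeric(1)))
  mi2 <- with(indicator_samples(align_and_window(s2)),
              vapply(seq_len(ncol(spk)), function(j)
                spike_action_mi(spk[, j], labels), numeric(1)))
  expect_equal(mi1, mi2, tolerance = 1e-12)
})

test_that("malformed session files raise parse errors naming the line", {
  ens <- default_ensemble(1, 0, 0, 1, seed = 6)
  s <- simulate_session(session_config("reach", ens, 3L, seed = 6))
  dir <- withr::local_tempdir()
  write_session(s, dir)
  ev <- readLines(file.path(dir, "events.tsv"))
  ev[3] <- sub("\t[1-4]$", "\t9", ev[3])
  writeLines(ev, file.path(dir, "events.tsv"))
  expect_error(read_session(dir), "line 3")

  write_session(s, dir)
  spk <- read.delim(file.path(dir, "spikes.tsv"))
  spk <- spk[rev(seq_len(nrow(spk))), ]
  write.table(spk, file.path(dir, "spikes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  expect_error(read_session(dir), "not sorted")

  write_session(s, dir)
  writeLines("neuron_id", file.path(dir, "spikes.tsv"))
  expect_error(read_session(dir), "missing required columns")
  expect_error(read_session(withr::local_tempdir()), "missing session file")
})
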