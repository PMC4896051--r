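test_that("spike detection: flat traces, constructed spikes, threshold", {
  flat <- make_spike_fixture(numeric(0), total = 100)
  expect_length(detect_spikes(flat)$peak_times, 0)
  tri <- make_spike_fixture(c(20, 50, 80), peak = 20, total = 100)
  st <- detect_spikes(tri)
  expect_length(st$peak_times, 3)
  expect_equal(st$peak_times, c(20, 50, 80), tolerance = 0.026)
  # threshold above the global maximum -> nothing detected
  expect_length(detect_spikes(tri, threshold = 30)$peak_times, 0)
})

test_that("features on a regular constructed train", {
  # 5 spikes every 10 ms starting at stim_start + 10
  tr <- make_spike_fixture(c(30, 40, 50, 60, 70), stim_start = 20,
                           stim_end = 90, total = 120)
  expect_equal(compute_feature(tr, "Spikecount"), 5)
  expect_equal(compute_feature(tr, "time_to_first_spike"), 10,
               tolerance = 1e-6)
  expect_equal(compute_feature(tr, "mean_frequency"), 1000 * 5 / 50,
               tolerance = 1e-3)
  expect_equal(compute_feature(tr, "doublet_ISI"), 10, tolerance = 1e-6)
  expect_equal(compute_feature(tr, "ISI_CV"), 0, tolerance = 1e-9)
  expect_equal(compute_feature(tr, "adaptation_index2"), 0, tolerance = 1e-9)
  expect_equal(compute_feature(tr, "AP_height"), 20, tolerance = 1e-6)
  # voltage base is -65, peaks at +20
  expect_equal(compute_feature(tr, "AP_amplitude_from_voltagebase"), 85,
               tolerance = 1e-6)
  expect_equal(compute_feature(tr, "AHP_depth_abs"), -65, tolerance = 1e-6)
  expect_error(compute_feature(tr, "no_such_feature"), "supported")
})

test_that("every feature is finite on a 10-spike fixture, missing when silent", {
  tr <- make_spike_fixture(seq(30, 120, by = 10), stim_start = 20,
                           stim_end = 150, total = 200)
  for (nm in efeature_names()) {
    expect_true(is.finite(compute_feature(tr, nm)), label = nm)
  }
  silent <- make_spike_fixture(numeric(0), stim_start = 20, stim_end = 150,
                               total = 200)
  expect_equal(compute_feature(silent, "Spikecount"), 0)
  for (nm in setdiff(efeature_names(), "Spikecount")) {
    expect_true(is.na(compute_feature(silent, nm)), label = nm)
  }
})

test_that("scores are invariant to a uniform time shift", {
  spikes <- c(30, 42, 56, 72, 90)
  tr1 <- make_spike_fixture(spikes, stim_start = 20, stim_end = 100,
                            total = 150)
  tr2 <- make_spike_fixture(spikes + 25, stim_start = 45, stim_end = 125,
                            total = 175)
  for (nm in efeature_names()) {
    expect_equal(compute_feature(tr1, nm), compute_feature(tr2, nm),
                 tolerance = 1e-9, label = nm)
  }
})

test_that("objective score identities", {
  tg <- feature_target("step1", "Spikecount", mean = 1, std = 0.05)
  expect_equal(feature_score(1, tg), 0)
  expect_equal(feature_score(1 + 2 * 0.05, tg), 2)
  expect_equal(feature_score(1 - 3 * 0.05, tg), 3)
  expect_equal(feature_score(NA_real_, tg, penalty = 250), 250)
  expect_equal(feature_score(2, tg), 20)  # |1 - 2| / 0.05
  expect_error(feature_target("p", "Spikecount", 1, 0), "std")
  expect_error(feature_target("p", "bogus", 1, 1), "unknown feature")
})

test_that("calculate_objectives: alignment, zero at target, missing recording", {
  tr <- make_spike_fixture(c(110, 120, 130, 140, 145), stim_start = 100,
                           stim_end = 150, total = 200)
  targets <- list(
    feature_target("step1", "Spikecount", mean = 5, std = 0.25),
    feature_target("step1", "doublet_ISI", mean = 10, std = 1),
    feature_target("step1", "AP_height", mean = 25, std = 2))
  scores <- calculate_objectives(list(step1.soma.v = tr), targets)
  expect_length(scores, 3)
  expect_equal(scores[1:2], c(0, 0), tolerance = 1e-6)
  expect_equal(scores[3], abs(25 - 20) / 2, tolerance = 1e-6)
  expect_error(calculate_objectives(list(other.soma.v = tr), targets),
               "step1.soma.v")
})

test_that("feature table covers the registry", {
  tr <- make_spike_fixture(seq(30, 80, by = 10), stim_start = 20,
                           stim_end = 100, total = 120)
  tab <- feature_table(tr)
  expect_identical(tab$feature, efeature_names())
  expect_equal(tab$value[tab$feature == "Spikecount"], 6)
})
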