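test_that("low-pass preserves the passband and attenuates beyond cutoff", {
  fs <- 4000
  # 10 Hz tone survives decimation to 1 kHz with amplitude intact
  es10 <- lowpass_and_resample(sine_epochs(10, fs, 5))
  expect_equal(es10$fs, 1000)
  expect_equal(n_samples(es10), 5000)
  ref <- sin(2 * pi * 10 * (0:4999) / 1000)
  expect_lt(abs(rms(es10$data[1, 1, 250:4750]) / rms(ref[250:4750]) - 1),
            0.01)
  # 2x cutoff: >= 40 dB down (filter-only path, no decimation)
  es500 <- lowpass_and_resample(sine_epochs(500, fs, 5), target_fs = fs)
  expect_equal(n_samples(es500), 20000)
  att500 <- 20 * log10(rms(es500$data[1, 1, 1000:19000]) / (1 / sqrt(2)))
  expect_lt(att500, -40)
  # 400 Hz: strong but not 40 dB attenuation at this filter order
  es400 <- lowpass_and_resample(sine_epochs(400, fs, 5))
  att400 <- 20 * log10(rms(es400$data[1, 1, 250:4750]) / (1 / sqrt(2)))
  expect_lt(att400, -30)
  expect_error(lowpass_and_resample(sine_epochs(10, fs, 1), cutoff = 600),
               "Nyquist")
})

test_that("notch removes line frequency and harmonics but spares neighbors", {
  fs <- 1000
  gain_db <- function(f) {
    es <- notch_line(sine_epochs(f, fs, 5))
    20 * log10(rms(es$data[1, 1, 500:4500]) / (1 / sqrt(2)))
  }
  expect_lt(gain_db(60), -20)   # residual RMS well under 10%
  expect_lt(gain_db(120), -20)  # first harmonic too
  expect_gt(gain_db(55), -3)
  expect_gt(gain_db(65), -3)
  expect_gt(gain_db(20), 20 * log10(0.95))  # passband change < 5%
  expect_error(notch_line(sine_epochs(10, 100, 2), base = 60), "Nyquist")
})

test_that("filters are zero-phase: a symmetric pulse stays symmetric", {
  n <- 2000
  pulse <- exp(-((0:(n - 1)) - (n - 1) / 2)^2 / 200)
  es <- vector_epochs(pulse, fs = 1000)
  for (out in list(notch_line(es), lowpass_and_resample(es, target_fs = 1000))) {
    y <- out$data[1, 1, ]
    expect_lt(max(abs(y - rev(y))) / max(abs(y)), 1e-6)
  }
})

test_that("re-running conditioning is a near-identity on passband content", {
  es <- sine_epochs(20, 1000, 5)
  once <- notch_line(lowpass_and_resample(es, target_fs = 1000))
  twice <- notch_line(lowpass_and_resample(once, target_fs = 1000))
  mid <- 500:4500
  expect_lt(abs(rms(twice$data[1, 1, mid]) / rms(once$data[1, 1, mid]) - 1),
            0.05)
})

test_that("segment parsing yields the documented covert/overt windows", {
  set.seed(2)
  dat <- array(rnorm(2 * 2 * 5000), c(2, 2, 5000))
  es <- epoch_set(dat, fs = 1000, t0 = -0.5, channel_ids = c("a", "b"),
                  trials = toy_trials(2))
  cov <- parse_segment(es, "covert")
  expect_equal(n_samples(cov), 1000)
  expect_equal(cov$t0, 1)
  expect_identical(cov$data[1, 1, 1], es$data[1, 1, 1501])
  ove <- parse_segment(es, "overt")
  expect_equal(n_samples(ove), 2500)
  expect_equal(ove$t0, 2)
  full <- parse_segment(es, segment_spec("full", -0.5, 4.5))
  expect_identical(full$data, es$data)
  expect_error(parse_segment(es, segment_spec("bad", 4, 5)), "outside")
})

test_that("channel exclusion preserves order and validates labels", {
  set.seed(3)
  ids <- sprintf("MEG%03d", 1:204)
  es <- epoch_set(array(rnorm(1 * 204 * 10), c(1, 204, 10)), 100, 0, ids,
                  toy_trials(1))
  bad <- ids[c(7, 33, 80, 81, 120, 150, 199, 204)]
  es2 <- exclude_channels(es, bad)
  expect_equal(n_channels(es2), 196)
  expect_identical(es2$channel_ids, setdiff(ids, bad))
  expect_identical(exclude_channels(es, character(0)), es)
  expect_warning(es3 <- exclude_channels(es, c(bad, bad[1])), "duplicate")
  expect_equal(n_channels(es3), 196)
  expect_error(exclude_channels(es, "NOPE"), "NOPE")
})

test_that("amplitude rejection drops spikes and the cap keeps early trials", {
  set.seed(4)
  n <- 70
  dat <- array(rnorm(n * 1 * 20), c(n, 1, 20))
  es <- epoch_set(dat, 100, 0, "c1", toy_trials(n))
  capped <- reject_and_cap_trials(es, amp_thresh = Inf, cap = 60)
  expect_equal(n_trials(capped), 60)
  expect_equal(capped$trials$trial_index, 1:60)

  spiked <- es
  spiked$data[5, 1, 3] <- 10 * max(abs(es$data))
  kept <- reject_and_cap_trials(spiked, cap = 60)
  expect_false(5 %in% kept$trials$trial_index)
  expect_equal(n_trials(kept), 60)  # 69 survivors, capped at 60

  allbad <- es
  allbad$data <- allbad$data * 0
  allbad$data[, 1, 1] <- 1e6
  expect_error(reject_and_cap_trials(allbad, amp_thresh = 1), "H1")
})

test_that("the external trial mask hook subsets trials", {
  es <- random_cohort_epochs()
  keep <- rep(c(TRUE, FALSE), length.out = n_trials(es))
  es2 <- apply_trial_mask(es, keep)
  expect_equal(n_trials(es2), sum(keep))
  expect_error(apply_trial_mask(es, keep[-1]), "one entry per trial")
})
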