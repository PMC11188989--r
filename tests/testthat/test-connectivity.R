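test_that("trial correlations match hand-computed Pearson values", {
  x <- c(1, 2, 3); y <- c(1, 3, 2)
  es <- signal_epochs(rbind(x, y, -x, x), fs = 10)
  ca <- trial_correlation(es)
  m <- ca[1, , ]
  expect_equal(m[1, 2], 0.5)          # hand: cov 0.5, sds 1
  expect_equal(m[1, 3], -1)           # negated copy
  expect_equal(m[1, 4], 1)            # duplicated channel
  expect_true(isSymmetric(m))
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
})

test_that("zero-variance channels yield NA pairs with a message", {
  es <- signal_epochs(rbind(c(1, 2, 3), c(5, 5, 5)), fs = 10)
  expect_message(ca <- trial_correlation(es), "zero-variance")
  expect_true(is.na(ca[1, 1, 2]))
  expect_error(trial_correlation(signal_epochs(matrix(1:2, 2, 1), 10)),
               "2 samples")
})

test_that("density and strong-pair summaries follow their definitions", {
  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- -0.5
  m[2, 3] <- m[3, 2] <- 0.2
  expect_equal(correlation_density(m), 0.4)          # (0.5+0.5+0.2)/3
  expect_equal(correlation_density(diag(3)), 0)
  ones <- matrix(1, 3, 3)
  expect_equal(correlation_density(ones), 1)
  expect_equal(strong_pair_count(m, 0.5), 0)         # strict inequality
  expect_equal(strong_pair_count(m, 0.4), 2)
  expect_equal(strong_pair_count(diag(3)), 0)
  expect_equal(strong_sensor_count(m, 0.4), 3)
  expect_equal(strong_sensor_count(m, 0.5), 0)
  expect_equal(connectivity_density(matrix(0.2, 3, 3)), 0.2)
  m2 <- diag(3)
  m2[upper.tri(m2)] <- c(0.1, 0.3, 0.5)
  m2[lower.tri(m2)] <- t(m2)[lower.tri(m2)]
  expect_equal(connectivity_density(m2), 0.3)
  expect_error(correlation_density(matrix(1, 1, 1)), "2 channels")
})

test_that("bootstrap coverage interval matches analytic uniform quantiles", {
  set.seed(7)
  v <- runif(1e5, -0.5, 0.5)
  r <- correlation_range(v, coverage = 0.95, n_boot = 100, seed = 3)
  expect_equal(unname(r[1]), -0.475, tolerance = 0.011)
  expect_equal(unname(r[2]), 0.475, tolerance = 0.011)
  expect_equal(unname(correlation_range(rep(0.3, 20), seed = 1)),
               c(0.3, 0.3))
  expect_error(correlation_range(v, coverage = 1), "inside")
  expect_error(correlation_range(1:5), "10 values")
})

test_that("AEC matches a naive per-pair reference implementation", {
  fs <- 200
  band <- band_spec("mid", 10, 20)
  set.seed(42)
  dat <- array(rnorm(3 * 4 * 200), c(3, 4, 200))
  es <- epoch_set(dat, fs, 0, paste0("c", 1:4), toy_trials(3))
  m <- aec(es, band, mode = "single-trial-averaged")
  ref <- naive_aec(dat, 10, 20, fs)
  expect_lt(max(abs(unclass(m) - ref)), 1e-8)
})

test_that("AEC is 1 for duplicated channels and 0 for independent ones", {
  fs <- 200
  band <- band_spec("mid", 10, 20)
  set.seed(8)
  x <- rnorm(400)
  es <- signal_epochs(rbind(x, x), fs = fs)
  m <- aec(es, band)
  expect_equal(m[1, 2], 1, tolerance = 1e-10)

  vals <- replicate(60, {
    es2 <- signal_epochs(matrix(rnorm(2 * 400), 2), fs = fs)
    aec(es2, band)[1, 2]
  })
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(60))
})

test_that("AEC rises with shared-source coupling for every seed", {
  fs <- 500
  band <- canonical_bands()$beta
  pair_aec <- function(rho, seed, ntr = 20) {
    set.seed(seed)
    trials <- lapply(seq_len(ntr), function(i) {
      sh <- megspeech:::colored_noise(
        megspeech:::spectral_shape_band(band, 1000, fs), 3)
      rbind(sh[, 1] + rho * sh[, 3], sh[, 2] + rho * sh[, 3])
    })
    aec(signal_epochs(trials, fs = fs), band)[1, 2]
  }
  for (seed in 1:20) {
    expect_lt(pair_aec(0.3, seed), pair_aec(0.6, seed))
  }
})

test_that("connectivity is invariant to per-channel rescaling", {
  fs <- 200
  band <- band_spec("mid", 10, 20)
  set.seed(9)
  X <- matrix(rnorm(2 * 400), 2)
  es1 <- signal_epochs(X, fs = fs)
  es2 <- signal_epochs(X * c(3, 0.2), fs = fs)
  expect_lt(max(abs(trial_correlation(es1)[1, , ] -
                    trial_correlation(es2)[1, , ])), 1e-10)
  expect_lt(max(abs(unclass(aec(es1, band)) - unclass(aec(es2, band)))),
            1e-10)
})

test_that("envelope edge trimming changes AEC only marginally", {
  fs <- 1000
  band <- canonical_bands()$beta
  set.seed(10)
  trials <- lapply(1:10, function(i) {
    sh <- megspeech:::colored_noise(
      megspeech:::spectral_shape_band(band, 2500, fs), 3)
    rbind(sh[, 1] + 0.5 * sh[, 3], sh[, 2] + 0.5 * sh[, 3])
  })
  es <- signal_epochs(trials, fs = fs)
  a_trim <- aec(es, band, edge_trim_s = 0.1)[1, 2]
  a_keep <- aec(es, band, edge_trim_s = 0)[1, 2]
  expect_lt(abs(a_trim - a_keep), 0.02)
})

test_that("concatenated and trial-averaged AEC modes both run", {
  es <- random_cohort_epochs(n_participants = 1, n_phrases = 1,
                             trials_per_phrase = 4, n_channels = 3,
                             n_samples = 400, fs = 200)
  band <- band_spec("mid", 10, 20)
  m1 <- aec(es, band, mode = "single-trial-averaged")
  m2 <- aec(es, band, mode = "concatenated")
  expect_equal(attr(m1, "aggregation"), "single-trial-averaged")
  expect_equal(attr(m2, "aggregation"), "concatenated")
  expect_true(isSymmetric(unclass(m2), tol = 1e-12))
  expect_error(aec(es, band_spec("slow", 0.5, 2)), "2 periods")
})
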