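test_that("band-limited sources concentrate power in their band", {
  beta <- canonical_bands()$beta
  s <- bandlimited_source(beta, 5000, 1000, seed = 2)
  p <- psd(s, 1000)
  dens <- matrix(p$density, ncol = 1)
  inband <- megspeech:::band_integral(p$freq, dens, beta$lo, beta$hi)
  total <- megspeech:::band_integral(p$freq, dens, 0, 500)
  expect_gt(inband / total, 0.9)
  # unit amplitude gives unit variance, up to band-limited sampling error
  expect_lt(abs(var(s) - 1), 0.2)
})

test_that("sources are seed-deterministic and amplitude scales variance", {
  beta <- canonical_bands()$beta
  s1 <- bandlimited_source(beta, 2000, 500, seed = 7)
  s2 <- bandlimited_source(beta, 2000, 500, seed = 7)
  expect_identical(s1, s2)
  s4 <- bandlimited_source(beta, 2000, 500, seed = 7, sigma = 2)
  expect_equal(var(s4) / var(s1), 4, tolerance = 1e-10)
  expect_identical(pink_noise(512, 100, seed = 3),
                   pink_noise(512, 100, seed = 3))
  expect_error(bandlimited_source(band_spec("hi", 100, 300), 100, 500,
                                  seed = 1), "Nyquist")
})

test_that("pink noise has a 1/f spectrum over 1-100 Hz", {
  x <- pink_noise(2^16, 1000, seed = 3)
  expect_lt(abs(mean(x)), 0.05)
  p <- psd(x, 1000, window_s = 4)
  sel <- p$freq >= 1 & p$freq <= 100
  slope <- unname(coef(lm(log10(p$density[sel]) ~ log10(p$freq[sel])))[2])
  expect_gt(slope, -1.2)
  expect_lt(slope, -0.8)
  expect_error(pink_noise(0, 100, seed = 1), "positive")
})

test_that("generated cohorts have the configured shape and metadata", {
  p <- synth_params("null", n_channels = 4, trials_per_phrase = 2,
                    t_end = 0.5, seed = 11)
  es <- generate_cohorts(p)
  expect_equal(dim(es$data), c(2 * 3 * 5 * 2, 4, 1000))
  expect_equal(sort(unique(es$trials$participant_id)),
               c("A1", "A2", "A3", "H1", "H2", "H3"))
  expect_equal(unique(es$trials$phrase_id), 1:5)
  expect_true(all(table(es$trials$participant_id, es$trials$phrase_id) == 2))
  es2 <- generate_cohorts(p)
  expect_identical(es$data, es2$data)
  # defaults encode the full design: 3+3 participants x 5 phrases
  full <- synth_params("null", scale = "full")
  expect_equal(full$n_channels, 196L)
  expect_equal(full$trials_per_phrase, 60L)
  expect_equal(2 * full$participants_per_cohort * full$n_phrases *
                 full$trials_per_phrase, 1800)
})

test_that("null configuration gives no cohort beta-power difference", {
  p <- synth_params("null", n_channels = 4, trials_per_phrase = 20,
                    participants_per_cohort = 1, t_end = 1.5, seed = 1)
  es <- generate_cohorts(p)
  bp <- band_power(es)
  beta <- apply(bp$values[, , "beta"], 1, mean)
  h <- beta[bp$trials$cohort == "healthy"]
  a <- beta[bp$trials$cohort == "patient"]
  se <- sqrt(var(h) / length(h) + var(a) / length(a))
  expect_lt(abs(mean(a) - mean(h)) / se, 2)
})

test_that("stronger coupling raises mean absolute pairwise correlation", {
  mac <- function(rho, seed) {
    p <- synth_params("null", n_channels = 8, trials_per_phrase = 2,
                      n_phrases = 2, participants_per_cohort = 1,
                      t_end = 1.5, rho_healthy = rho, rho_patient = rho,
                      line_amp = 0, seed = seed)
    ca <- trial_correlation(generate_cohorts(p))
    mean(apply(ca, 1, function(m) mean(abs(m[upper.tri(m)]))))
  }
  for (seed in 1:3) {
    expect_lt(mac(0.1, seed), mac(0.4, seed))
    expect_lt(mac(0.4, seed), mac(0.7, seed))
  }
})

test_that("beta gain raises beta power and leaves delta/theta unchanged", {
  mk <- function(g) {
    p <- synth_params("null", n_channels = 4, trials_per_phrase = 5,
                      n_phrases = 1, participants_per_cohort = 1,
                      g_beta = g, t_end = 1.5, seed = 6)
    bp <- band_power(generate_cohorts(p))
    pat <- bp$trials$cohort == "patient"
    apply(bp$values[pat, , , drop = FALSE], 3, mean)
  }
  p1 <- mk(1); p2 <- mk(2)
  expect_gt(p2[["beta"]] / p1[["beta"]], 2)
  # same seed, same non-beta spectrum: only window leakage differs
  expect_lt(abs(p2[["delta"]] / p1[["delta"]] - 1), 0.01)
  expect_lt(abs(p2[["theta"]] / p1[["theta"]] - 1), 0.01)
})

test_that("beta-effect preset raises patient coupling on every phrase", {
  p <- synth_params("beta-effect", n_channels = 8, trials_per_phrase = 4,
                    t_end = 1.5, seed = 2)
  es <- generate_cohorts(p)
  ca <- trial_correlation(es)
  dens <- apply(ca, 1, function(m) mean(abs(m[upper.tri(m)])))
  for (ph in 1:5) {
    sel <- es$trials$phrase_id == ph
    coh <- es$trials$cohort[sel]
    expect_gt(mean(dens[sel][coh == "patient"]),
              mean(dens[sel][coh == "healthy"]))
  }
})
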