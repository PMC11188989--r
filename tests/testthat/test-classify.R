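# Random but structured feature matrix with full cohort metadata.
make_fm <- function(n_participants = 3, n_phrases = 5,
                    trials_per_phrase = 60, p = 4, sep = 0, seed = 1) {
  set.seed(seed)
  meta <- list()
  for (cohort in c("healthy", "patient")) {
    for (i in seq_len(n_participants)) {
      meta[[length(meta) + 1L]] <- data.frame(
        participant_id = paste0(if (cohort == "healthy") "H" else "A", i),
        cohort = cohort,
        phrase_id = rep(seq_len(n_phrases), each = trials_per_phrase),
        trial_index = rep(seq_len(trials_per_phrase), n_phrases),
        valid = TRUE, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, meta)
  X <- matrix(rnorm(nrow(trials) * p), ncol = p)
  X[trials$cohort == "patient", 1] <-
    X[trials$cohort == "patient", 1] + sep
  structure(list(X = X, y = trials$cohort, trials = trials),
            class = "feature_matrix")
}

test_that("feature extraction has one column per channel and band", {
  es <- random_cohort_epochs(n_participants = 1, n_phrases = 1,
                             trials_per_phrase = 3, n_channels = 5,
                             n_samples = 60)
  bp <- band_power(es, bands = list(band_spec("lo", 5, 15),
                                    band_spec("hi", 20, 45)))
  fm <- extract_features(bp, "lo")
  expect_equal(dim(fm$X), c(6, 5))
  both <- extract_features(bp, c("lo", "hi"))
  expect_equal(ncol(both$X), 10)
  expect_error(extract_features(bp, "beta"), "not present")

  bp$values[] <- 1
  logfm <- extract_features(bp, "lo", log10_transform = TRUE)
  expect_true(all(logfm$X == 0))
})

test_that("regularized LDA separates well-separated Gaussians", {
  set.seed(19)
  X <- rbind(matrix(rnorm(200 * 2), ncol = 2),
             matrix(rnorm(200 * 2, mean = 5), ncol = 2))
  y <- rep(c("healthy", "patient"), each = 200)
  fit <- fit_rlda(X, y, gamma = 0.1)
  expect_gte(mean(predict(fit, X) == y), 0.99)
})

test_that("gamma = 1 reproduces the diagonal-LDA closed form", {
  set.seed(20)
  X <- matrix(rnorm(100 * 3), ncol = 3)
  y <- rep(c("a", "b"), 50)
  fit <- fit_rlda(X, y, gamma = 1, standardize = FALSE)
  mu0 <- colMeans(X[y == "a", ]); mu1 <- colMeans(X[y == "b", ])
  c0 <- sweep(X[y == "a", ], 2, mu0); c1 <- sweep(X[y == "b", ], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (nrow(X) - 2)
  expect_equal(fit$w, (mu1 - mu0) / diag(S), tolerance = 1e-10)
})

test_that("coefficient thresholding zeroes weights and falls back to priors", {
  set.seed(21)
  X <- matrix(rnorm(60 * 2), ncol = 2)
  y <- rep(c("healthy", "patient"), c(20, 40))
  fit <- fit_rlda(X, y, gamma = 0.5, delta = 1e6)
  expect_true(all(fit$w == 0))
  expect_true(all(predict(fit, X) == "patient"))  # majority class
})

test_that("singular covariance at gamma 0 is reported with advice", {
  set.seed(22)
  X <- matrix(rnorm(10 * 50), nrow = 10)  # p > n
  y <- rep(c("a", "b"), 5)
  expect_error(fit_rlda(X, y, gamma = 0), "gamma > 0")
  expect_silent(fit_rlda(X, y, gamma = 0.5))
})

test_that("prediction is scale-invariant for unregularized LDA", {
  set.seed(23)
  X <- matrix(rnorm(80 * 3), ncol = 3)
  y <- rep(c("a", "b"), 40)
  Xnew <- matrix(rnorm(20 * 3), ncol = 3)
  sc <- c(10, 0.1, 3)
  f1 <- fit_rlda(X, y, gamma = 0, standardize = FALSE)
  f2 <- fit_rlda(sweep(X, 2, sc, "*"), y, gamma = 0, standardize = FALSE)
  expect_identical(predict(f1, Xnew),
                   predict(f2, sweep(Xnew, 2, sc, "*")))
})

test_that("grid tuning respects failures and the regularization tie-break", {
  set.seed(24)
  # separable data: every feasible point is perfect, tie-break picks the
  # most regularized corner
  X <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 6), ncol = 2))
  y <- rep(c("a", "b"), each = 30)
  tn <- tune_hyperparams(X, y, gamma_grid = c(0.1, 0.5),
                         delta_grid = c(0, 1e-4), k = 5, seed = 1)
  expect_equal(tn$gamma, 0.5)
  expect_equal(tn$delta, 1e-4)

  single <- tune_hyperparams(X, y, gamma_grid = 0.3, delta_grid = 1e-3,
                             k = 5, seed = 1)
  expect_equal(single$gamma, 0.3)
  expect_equal(single$delta, 1e-3)

  # p > n folds make gamma = 0 infeasible; it must never be selected
  set.seed(25)
  Xw <- matrix(rnorm(24 * 60), nrow = 24)
  yw <- rep(c("a", "b"), 12)
  tw <- tune_hyperparams(Xw, yw, gamma_grid = c(0, 0.5),
                         delta_grid = 0, k = 4, seed = 2)
  expect_true(is.na(tw$table$accuracy[tw$table$gamma == 0]))
  expect_equal(tw$gamma, 0.5)

  expect_error(tune_hyperparams(X, y, numeric(0), 0), "empty grid")
})

test_that("leave-one-pair-out folds hold out exactly one pair", {
  fm <- make_fm(sep = 3)
  r <- lopo_cv(fm, tune = FALSE, gamma = 0.5)
  expect_equal(nrow(r$folds), 9)
  expect_true(all(r$folds$n_train == 1200))
  expect_true(all(r$folds$n_test == 600))
  expect_equal(sort(unique(r$folds$healthy)), c("H1", "H2", "H3"))
  expect_equal(sort(unique(r$folds$patient)), c("A1", "A2", "A3"))
  # separated features classify held-out participants correctly
  expect_gt(r$median_accuracy, 0.9)

  bad <- fm
  bad$trials$cohort[bad$trials$participant_id == "H1"] <-
    rep(c("healthy", "patient"), length.out = 300)
  bad$y <- bad$trials$cohort
  expect_error(lopo_cv(bad), "both cohorts")
})

test_that("held-out trials cannot influence the fold model", {
  fm <- make_fm(n_participants = 2, trials_per_phrase = 10, sep = 1)
  te <- fm$trials$participant_id %in% c("H1", "A1")
  fit_full <- fit_rlda(fm$X[!te, ], fm$y[!te], gamma = 0.3, delta = 1e-3)
  # deleting the held-out pair entirely changes nothing
  fm2 <- list(X = fm$X[!te, ], y = fm$y[!te], trials = fm$trials[!te, ])
  fit_rm <- fit_rlda(fm2$X, fm2$y, gamma = 0.3, delta = 1e-3)
  expect_identical(fit_full$w, fit_rm$w)
  expect_identical(fit_full$b, fit_rm$b)
})

test_that("featureless null data classifies at chance level", {
  meds <- vapply(1:4, function(seed) {
    fm <- make_fm(n_participants = 2, trials_per_phrase = 15, sep = 0,
                  seed = seed)
    lopo_cv(fm, tune = FALSE, gamma = 0.5, seed = seed)$median_accuracy
  }, 0)
  expect_lt(abs(mean(meds) - 0.5), 3 * sd(meds) / sqrt(length(meds)))
})
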