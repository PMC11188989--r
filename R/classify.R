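# Single-trial cohort classification: regularized LDA (covariance
# shrinkage toward its diagonal, "Gamma"; coefficient threshold,
# "Delta") with hyperparameters tuned by seeded exhaustive grid search
# under stratified k-fold cross-validation, evaluated with a
# leave-one-participant-pair-out scheme.

#' Build a classification feature matrix from band powers
#'
#' One row per trial, one column per channel; features are the band
#' power of the requested band (or the concatenation of several bands).
#'
#' @param bpt a `band_power_table` from [band_power()].
#' @param band band name, or a vector of names to concatenate.
#' @param log10_transform take log10 of the powers.
#' @return A `feature_matrix`: list with `X`, cohort labels `y`, and the
#'   trial metadata.
#' @export
extract_features <- function(bpt, band = "beta", log10_transform = FALSE) {
  stopifnot(inherits(bpt, "band_power_table"))
  have <- dimnames(bpt$values)[[3]]
  miss <- setdiff(band, have)
  if (length(miss))
    stop("band(s) not present in table: ", paste(miss, collapse = ", "))
  X <- do.call(cbind, lapply(band, function(b) {
    m <- bpt$values[, , b, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, nrow = dim(bpt$values)[1])
    colnames(m) <- paste(b, dimnames(bpt$values)[[2]], sep = ".")
    m
  }))
  if (log10_transform) X <- log10(X)
  if (anyNA(X) || any(!is.finite(X))) stop("undefined feature values")
  structure(list(X = X, y = as.character(bpt$trials$cohort),
                 trials = bpt$trials),
            class = "feature_matrix")
}

#' Fit a regularized linear discriminant model
#'
#' Two-class LDA with the pooled within-class covariance shrunk toward
#' its diagonal, `S_gamma = (1 - gamma) S + gamma diag(S)`, weights
#' `w = S_gamma^-1 (mu_1 - mu_0)` soft-thresholded to exact zero where
#' `|w_j| <= delta`, and the usual linear decision rule with empirical
#' class priors.  Features are standardized with training statistics
#' (stored in the model) so delta thresholds are comparable across
#' feature sets.
#'
#' @param X trial x feature matrix.
#' @param y two-level class labels.
#' @param gamma shrinkage weight in `[0, 1]`.
#' @param delta coefficient threshold (>= 0).
#' @param standardize standardize columns with training mean/sd.
#' @param priors optional named prior probabilities (default: empirical
#'   class frequencies).
#' @return An `rlda_model`.
#' @export
fit_rlda <- function(X, y, gamma = 0.5, delta = 0, standardize = TRUE,
                     priors = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  if (length(y) != nrow(X)) stop("labels and feature rows do not align")
  lev <- sort(unique(y))
  if (length(lev) != 2) stop("need exactly 2 classes")
  if (min(table(y)) < 2) stop("need >= 2 trials per class")
  if (gamma < 0 || gamma > 1) stop("gamma must lie in [0, 1]")
  if (delta < 0) stop("delta must be >= 0")
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl == 0] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  } else {
    ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  }
  i0 <- y == lev[1]; i1 <- y == lev[2]
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  n0 <- sum(i0); n1 <- sum(i1); n <- n0 + n1
  c0 <- sweep(X[i0, , drop = FALSE], 2, mu0)
  c1 <- sweep(X[i1, , drop = FALSE], 2, mu1)
  S <- (crossprod(c0) + crossprod(c1)) / (n - 2)
  Sg <- (1 - gamma) * S + gamma * diag(diag(S), ncol(X))
  w <- tryCatch(solve(Sg, mu1 - mu0), error = function(e) {
    stop("regularized covariance is singular (gamma = ", gamma,
         "); use gamma > 0", call. = FALSE)
  })
  w[abs(w) <= delta] <- 0
  if (is.null(priors)) priors <- setNames(c(n0, n1) / n, lev)
  b <- -sum(w * (mu0 + mu1) / 2) + log(priors[lev[2]] / priors[lev[1]])
  structure(list(levels = lev, w = w, b = unname(b), gamma = gamma,
                 delta = delta, center = ctr, scale = scl,
                 priors = priors, means = rbind(mu0, mu1)),
            class = "rlda_model")
}

#' Predict cohort labels with a regularized LDA model
#'
#' @param object an `rlda_model`.
#' @param newdata trial x feature matrix.
#' @param ... unused.
#' @return Character vector of predicted class labels.  Trials with a
#'   zero score (including the all-weights-thresholded case) fall back
#'   to the larger-prior class.
#' @export
predict.rlda_model <- function(object, newdata, ...) {
  X <- sweep(sweep(as.matrix(newdata), 2, object$center), 2,
             object$scale, "/")
  score <- drop(X %*% object$w) + object$b
  out <- ifelse(score > 0, object$levels[2], object$levels[1])
  if (all(object$w == 0)) {
    out[] <- object$levels[which.max(object$priors[object$levels])]
  }
  out
}

#' Grid search for regularized-LDA hyperparameters
#'
#' Scores every (gamma, delta) grid point by mean accuracy under
#' seeded, stratified k-fold cross-validation on the training data, and
#' returns the argmax.  Grid points whose fit fails (e.g., gamma = 0
#' with a singular covariance) are scored as failures and never
#' selected.  Ties break toward larger gamma, then larger delta (more
#' regularization).
#'
#' @param X,y training features and labels.
#' @param gamma_grid,delta_grid candidate values.
#' @param k number of folds (clipped to the smaller class count).
#' @param seed integer RNG seed for the fold assignment.
#' @return List: `gamma`, `delta`, and the full score `table`.
#' @export
tune_hyperparams <- function(X, y, gamma_grid = c(0, 0.01, 0.1, 0.3, 0.5, 1),
                             delta_grid = c(0, 1e-4, 1e-3, 1e-2),
                             k = 10, seed = 1) {
  if (!length(gamma_grid) || !length(delta_grid)) stop("empty grid")
  y <- as.character(y)
  lev <- sort(unique(y))
  k <- min(k, min(table(y)))
  if (k < 2) stop("need at least 2 folds")
  set.seed(seed)
  fold <- integer(length(y))
  for (cl in lev) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  grid <- expand.grid(gamma = gamma_grid, delta = delta_grid)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- rep(NA_real_, k)
    for (f in seq_len(k)) {
      te <- fold == f
      fit <- tryCatch(
        fit_rlda(X[!te, , drop = FALSE], y[!te],
                 gamma = grid$gamma[g], delta = grid$delta[g]),
        error = function(e) NULL)
      if (is.null(fit)) { accs <- NA_real_; break }
      accs[f] <- mean(predict(fit, X[te, , drop = FALSE]) == y[te])
    }
    grid$accuracy[g] <- if (anyNA(accs)) NA_real_ else mean(accs)
  }
  if (all(is.na(grid$accuracy))) stop("every grid point failed to fit")
  ok <- which(!is.na(grid$accuracy))
  ord <- ok[order(grid$accuracy[ok], grid$gamma[ok], grid$delta[ok],
                  decreasing = TRUE)]
  best <- ord[1]
  list(gamma = grid$gamma[best], delta = grid$delta[best], table = grid)
}

#' Leave-one-participant-pair-out cross-validation
#'
#' One fold per (healthy, patient) participant pair: the fold's model is
#' trained on all trials of the remaining participants (hyperparameters
#' tuned by [tune_hyperparams()] inside the fold, on training data only)
#' and tested on every trial of the held-out pair, irrespective of
#' phrase.  With 3 + 3 participants this yields 9 folds; at the full
#' study scale each fold trains on 1200 trials and tests on 600.  The
#' summary statistic is the median fold accuracy.
#'
#' @param fm a `feature_matrix` from [extract_features()].
#' @param gamma_grid,delta_grid hyperparameter grids.
#' @param k inner tuning folds.
#' @param tune tune hyperparameters per fold; if `FALSE`, use `gamma`
#'   and `delta` as given.
#' @param gamma,delta fixed hyperparameters when `tune = FALSE`.
#' @param seed integer RNG seed (fans out per fold).
#' @return A `cv_report`: list with `folds` (one row per pair: test
#'   pair, sizes, chosen hyperparameters, accuracy), `predictions`,
#'   `median_accuracy`.
#' @export
lopo_cv <- function(fm, gamma_grid = c(0, 0.01, 0.1, 0.3, 0.5, 1),
                    delta_grid = c(0, 1e-4, 1e-3, 1e-2), k = 10,
                    tune = TRUE, gamma = 0.5, delta = 0, seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"))
  tr <- fm$trials
  part <- unique(data.frame(participant_id = tr$participant_id,
                            cohort = as.character(tr$cohort),
                            stringsAsFactors = FALSE))
  if (anyDuplicated(part$participant_id))
    stop("participant appears in both cohorts")
  hp <- part$participant_id[part$cohort == "healthy"]
  pp <- part$participant_id[part$cohort == "patient"]
  if (length(hp) < 2 || length(pp) < 2)
    stop("need at least 2 participants per cohort")
  pairs <- expand.grid(healthy = hp, patient = pp,
                       stringsAsFactors = FALSE)
  folds <- vector("list", nrow(pairs))
  preds <- vector("list", nrow(pairs))
  for (f in seq_len(nrow(pairs))) {
    te <- tr$participant_id %in% c(pairs$healthy[f], pairs$patient[f])
    Xtr <- fm$X[!te, , drop = FALSE]; ytr <- fm$y[!te]
    Xte <- fm$X[te, , drop = FALSE];  yte <- fm$y[te]
    if (tune) {
      tn <- tune_hyperparams(Xtr, ytr, gamma_grid, delta_grid, k = k,
                             seed = seed + f)
      g <- tn$gamma; d <- tn$delta
    } else {
      g <- gamma; d <- delta
    }
    fit <- fit_rlda(Xtr, ytr, gamma = g, delta = d)
    ph <- predict(fit, Xte)
    folds[[f]] <- data.frame(
      healthy = pairs$healthy[f], patient = pairs$patient[f],
      n_train = sum(!te), n_test = sum(te), gamma = g, delta = d,
      accuracy = mean(ph == yte), stringsAsFactors = FALSE)
    preds[[f]] <- data.frame(trial = which(te), truth = yte,
                             predicted = ph, stringsAsFactors = FALSE)
  }
  folds <- do.call(rbind, folds)
  structure(list(folds = folds, predictions = preds,
                 median_accuracy = median(folds$accuracy)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, median accuracy %.3f\n",
              nrow(x$folds), x$median_accuracy))
  invisible(x)
}
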