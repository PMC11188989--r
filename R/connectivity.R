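# Pairwise sensor statistics: broadband Pearson correlation summaries and
# amplitude-envelope-correlation (AEC) functional connectivity.

#' Single-trial pairwise sensor correlation
#'
#' Pearson correlation between every pair of channel signals, computed
#' per trial.  Channels with zero variance yield `NA` entries for their
#' pairs (with a message).  Averaging across trials is arithmetic on r.
#'
#' @param es an `epoch_set`.
#' @return Array trial x channel x channel of correlation matrices.
#' @export
trial_correlation <- function(es) {
  validate_epoch_set(es)
  if (n_samples(es) < 2) stop("need at least 2 samples per trial")
  nt <- n_trials(es)
  nc <- n_channels(es)
  out <- array(NA_real_, c(nt, nc, nc),
               dimnames = list(NULL, es$channel_ids, es$channel_ids))
  warned <- FALSE
  for (i in seq_len(nt)) {
    X <- trial_matrix(es, i)
    v <- apply(X, 2, var)
    if (any(v == 0) && !warned) {
      message("zero-variance channel(s); their pairs are set to NA")
      warned <- TRUE
    }
    out[i, , ] <- suppressWarnings(cor(X))
    if (any(v == 0)) {
      out[i, v == 0, ] <- NA_real_
      out[i, , v == 0] <- NA_real_
      diag(out[i, , ]) <- ifelse(v == 0, NA_real_, 1)
    }
  }
  out
}

#' Average correlation matrices by participant and phrase
#'
#' Arithmetic mean of per-trial correlation matrices within each
#' (participant, phrase) cell (Fisher-z averaging available as an
#' option).
#'
#' @param ca trial x channel x channel array from [trial_correlation()].
#' @param trials trial metadata aligned with `ca`.
#' @param fisher_z average on the Fisher z scale instead of r directly.
#' @return List with `cells` (data frame: participant, cohort, phrase)
#'   and `matrices` (list of mean channel x channel matrices).
#' @export
average_correlation <- function(ca, trials, fisher_z = FALSE) {
  key <- interaction(trials$participant_id, trials$phrase_id, drop = TRUE)
  cells <- unique(data.frame(participant_id = trials$participant_id,
                             cohort = as.character(trials$cohort),
                             phrase_id = trials$phrase_id,
                             key = as.character(key),
                             stringsAsFactors = FALSE))
  mats <- lapply(cells$key, function(k) {
    idx <- which(as.character(key) == k)
    m <- apply(ca[idx, , , drop = FALSE], c(2, 3), function(r) {
      if (fisher_z) tanh(mean(atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))))
      else mean(r)
    })
    if (fisher_z) diag(m) <- 1
    m
  })
  list(cells = cells[, c("participant_id", "cohort", "phrase_id")],
       matrices = mats)
}

upper_tri_values <- function(m) m[upper.tri(m)]

#' Correlation density
#'
#' Mean absolute off-diagonal correlation: the sum of absolute
#' correlation values over the number of channel pairs.  Lies in
#' `[0, 1]`.
#'
#' @param m channel x channel correlation matrix.
#' @return Scalar density.
#' @export
correlation_density <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 channels")
  mean(abs(upper_tri_values(m)))
}

#' Signed connectivity density
#'
#' Mean (signed) off-diagonal value of a connectivity matrix: the sum of
#' AEC values over the number of sensor pairs.
#'
#' @param m channel x channel connectivity matrix.
#' @return Scalar density.
#' @export
connectivity_density <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 channels")
  vals <- upper_tri_values(m)
  if (anyNA(vals)) stop("connectivity matrix contains undefined values")
  mean(vals)
}

#' Count strongly correlated channel pairs
#'
#' Number of unordered channel pairs with `|r|` strictly above the
#' threshold.
#'
#' @param m channel x channel correlation matrix.
#' @param thresh absolute correlation threshold (default 0.5).
#' @return Integer pair count.
#' @export
strong_pair_count <- function(m, thresh = 0.5) {
  sum(abs(upper_tri_values(m)) > thresh, na.rm = TRUE)
}

#' Count sensors participating in strong pairs
#'
#' Number of channels involved in at least one pair with `|r|` above the
#' threshold (the per-sensor reading of the strong-correlation count).
#'
#' @inheritParams strong_pair_count
#' @return Integer sensor count.
#' @export
strong_sensor_count <- function(m, thresh = 0.5) {
  a <- abs(m)
  diag(a) <- 0
  sum(apply(a > thresh, 1, any, na.rm = TRUE))
}

#' Central coverage interval of pooled correlation values
#'
#' Seeded bootstrap percentile estimate of the central interval
#' containing a given fraction of the pooled pair-correlation
#' distribution.
#'
#' @param values numeric vector of correlation values (>= 10).
#' @param coverage central mass to cover, in (0, 1).
#' @param n_boot bootstrap replicates.
#' @param seed integer RNG seed.
#' @return Numeric `c(lo, hi)`.
#' @export
correlation_range <- function(values, coverage = 0.95, n_boot = 200,
                              seed = 1) {
  if (length(values) < 10) stop("need at least 10 values")
  if (!(coverage > 0 && coverage < 1))
    stop("coverage must lie strictly inside (0, 1)")
  set.seed(seed)
  probs <- c((1 - coverage) / 2, 1 - (1 - coverage) / 2)
  qs <- vapply(seq_len(n_boot), function(i) {
    quantile(sample(values, replace = TRUE), probs, names = FALSE)
  }, numeric(2))
  c(lo = mean(qs[1, ]), hi = mean(qs[2, ]))
}

# Envelope of the analytic signal of each column (FFT-based Hilbert,
# circular).  Callers are expected to pad and crop around this; see
# aec_trial_matrices().
envelope_mat <- function(X) {
  n <- nrow(X)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1] <- 1; h[n %/% 2L + 1L] <- 1; h[2:(n %/% 2L)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1L) %/% 2L)] <- 2
  }
  F <- mvfft(X) * h
  Mod(mvfft(F, inverse = TRUE) / n)
}

# Odd-reflection extension of each column by `ext` samples at each end.
reflect_pad <- function(X, ext) {
  if (ext <= 0) return(X)
  n <- nrow(X)
  rbind(2 * X[rep(1L, ext), , drop = FALSE] - X[(ext + 1L):2L, , drop = FALSE],
        X,
        2 * X[rep(n, ext), , drop = FALSE] - X[(n - 1L):(n - ext), , drop = FALSE])
}

#' Amplitude envelope correlation connectivity
#'
#' Band-passes every channel with a zero-phase 4th-order Butterworth
#' filter, extracts amplitude envelopes with the Hilbert transform, and
#' correlates envelopes across channel pairs.  In
#' `"single-trial-averaged"` mode the per-trial correlation matrices are
#' averaged arithmetically; in `"concatenated"` mode the band-passed
#' trials are joined end to end before envelope extraction and a single
#' correlation matrix is computed.  Envelope edges (default 100 ms) are
#' trimmed before correlating to bound filter-transient leakage.
#'
#' @param es an `epoch_set`.
#' @param band a [band_spec()].
#' @param mode `"single-trial-averaged"` or `"concatenated"`.
#' @param order Butterworth order.
#' @param edge_trim_s envelope trim at each end, seconds.
#' @return Channel x channel AEC matrix with attributes `measure`,
#'   `band`, `aggregation`.
#' @export
aec <- function(es, band, mode = c("single-trial-averaged", "concatenated"),
                order = 4, edge_trim_s = 0.1) {
  mode <- match.arg(mode)
  if (mode == "single-trial-averaged") {
    mats <- aec_trial_matrices(es, band, order, edge_trim_s)
    m <- apply(mats, c(2, 3), mean)
  } else {
    aec_check(es, band)
    co <- butter_bandpass(order, band$lo, band$hi, es$fs)
    nt <- n_trials(es); nc <- n_channels(es); ns <- n_samples(es)
    ext <- min(ns - 1L, round(0.25 * es$fs))
    X <- aperm(es$data, c(3, 2, 1))
    dim(X) <- c(ns, nc * nt)
    Xf <- filtfilt_mat(co$b, co$a, reflect_pad(X, ext))
    Xf <- Xf[(ext + 1L):(ext + ns), , drop = FALSE]
    # concatenate band-passed trials end to end per channel
    dim(Xf) <- c(ns, nc, nt)
    Xall <- aperm(Xf, c(1, 3, 2))
    dim(Xall) <- c(ns * nt, nc)
    m <- cor(aec_trim(envelope_mat(Xall), round(edge_trim_s * es$fs)))
  }
  dimnames(m) <- list(es$channel_ids, es$channel_ids)
  structure(m, measure = "aec", band = band$name, aggregation = mode)
}

aec_check <- function(es, band) {
  validate_epoch_set(es)
  if (band$hi >= es$fs / 2) stop("band exceeds Nyquist")
  if (n_samples(es) / es$fs < 2 / band$lo)
    stop(sprintf("trials shorter than 2 periods of the band low edge (%g Hz)",
                 band$lo))
}

aec_trim <- function(E, ntrim) {
  if (ntrim > 0 && nrow(E) > 2 * ntrim + 2)
    E[(ntrim + 1L):(nrow(E) - ntrim), , drop = FALSE]
  else E
}

#' Per-trial amplitude envelope correlation matrices
#'
#' The single-trial building block of [aec()]: one envelope-correlation
#' matrix per trial, computed with all trials band-passed and
#' Hilbert-transformed in a single batched pass.  Each trial is
#' odd-reflection extended by 250 ms before filtering so the circular
#' Hilbert transform's junction artifacts fall outside the analyzed
#' window, then cropped back and edge-trimmed before correlating.
#'
#' @inheritParams aec
#' @return Array trial x channel x channel.
#' @export
aec_trial_matrices <- function(es, band, order = 4, edge_trim_s = 0.1) {
  aec_check(es, band)
  co <- butter_bandpass(order, band$lo, band$hi, es$fs)
  nt <- n_trials(es); nc <- n_channels(es); ns <- n_samples(es)
  ntrim <- round(edge_trim_s * es$fs)
  ext <- min(ns - 1L, round(0.25 * es$fs))
  X <- aperm(es$data, c(3, 2, 1))
  dim(X) <- c(ns, nc * nt)
  E <- envelope_mat(filtfilt_mat(co$b, co$a, reflect_pad(X, ext)))
  E <- E[(ext + 1L):(ext + ns), , drop = FALSE]
  out <- array(NA_real_, c(nt, nc, nc),
               dimnames = list(NULL, es$channel_ids, es$channel_ids))
  for (i in seq_len(nt)) {
    out[i, , ] <- cor(aec_trim(E[, ((i - 1L) * nc + 1L):(i * nc),
                                 drop = FALSE], ntrim))
  }
  out
}
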