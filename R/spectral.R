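# Band power estimation: Welch-averaged periodograms (1 s Hann windows,
# 50% overlap) integrated over each band with the trapezoidal rule.
# Power is reported in linear signal units squared.

# Welch PSD of every column of X (samples x signals).
psd_mat <- function(X, fs, window_s = 1, overlap = 0.5) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  n <- nrow(X)
  if (n < 8) stop("signal too short for spectral estimation (minimum 8 samples)")
  nw <- min(round(window_s * fs), n)
  if (nw < 8) nw <- n
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(nw) - 1L) / nw))
  U <- mean(w^2)
  step <- max(1L, round(nw * (1 - overlap)))
  starts <- seq(1L, n - nw + 1L, by = step)
  acc <- matrix(0, nw, ncol(X))
  for (s in starts) {
    seg <- X[s:(s + nw - 1L), , drop = FALSE]
    seg <- sweep(seg, 2L, colMeans(seg))
    acc <- acc + Mod(mvfft(seg * w))^2
  }
  acc <- acc / (length(starts) * fs * nw * U)
  nf <- nw %/% 2L + 1L
  dens <- acc[seq_len(nf), , drop = FALSE]
  if (nw %% 2L == 0L) {
    if (nf > 2) dens[2:(nf - 1L), ] <- 2 * dens[2:(nf - 1L), , drop = FALSE]
  } else if (nf > 1) {
    dens[2:nf, ] <- 2 * dens[2:nf, , drop = FALSE]
  }
  list(freq = (seq_len(nf) - 1L) * fs / nw, density = dens)
}

#' Welch power spectral density
#'
#' One-sided power spectral density by Welch's method: Hann-tapered,
#' mean-removed windows (default 1 s, 50% overlap), averaged
#' periodograms.  The density is normalized so that its integral over
#' frequency approximates the signal variance (Parseval consistency).
#'
#' @param x numeric signal vector.
#' @param fs sampling rate in Hz.
#' @param window_s Welch window length in seconds (clipped to the signal
#'   length).
#' @param overlap fractional window overlap.
#' @return A list with `freq` (Hz) and `density` (signal-units^2 / Hz).
#' @examples
#' s <- sin(2 * pi * 20 * seq(0, 5, by = 1e-3))
#' p <- psd(s, fs = 1000)
#' @export
psd <- function(x, fs, window_s = 1, overlap = 0.5) {
  out <- psd_mat(matrix(x, ncol = 1L), fs, window_s, overlap)
  list(freq = out$freq, density = drop(out$density))
}

# Trapezoidal integral of each density column over [lo, hi], with linear
# interpolation at off-grid band edges.
band_integral <- function(freq, dens, lo, hi) {
  interp_at <- function(f) {
    if (f <= freq[1]) return(dens[1, ])
    j <- findInterval(f, freq)
    if (j >= length(freq)) return(dens[length(freq), ])
    if (freq[j] == f) return(dens[j, ])
    dens[j, ] + (dens[j + 1L, ] - dens[j, ]) * (f - freq[j]) /
      (freq[j + 1L] - freq[j])
  }
  fl <- max(lo, freq[1])
  fh <- min(hi, freq[length(freq)])
  if (fh <= fl) return(numeric(ncol(dens)))
  inner <- which(freq > fl & freq < fh)
  xs <- c(fl, freq[inner], fh)
  D <- rbind(interp_at(fl), dens[inner, , drop = FALSE], interp_at(fh))
  dx <- diff(xs)
  colSums((D[-1L, , drop = FALSE] + D[-nrow(D), , drop = FALSE]) / 2 * dx)
}

#' Per-trial, per-channel band power
#'
#' Mean power of each trial/channel signal in each requested band,
#' computed as the integral of the Welch power spectral density over the
#' band.  Band powers over disjoint bands are additive and scale with
#' the square of the signal amplitude.
#'
#' @param es an `epoch_set`.
#' @param bands list of [band_spec()] objects (default: the six
#'   canonical bands).
#' @param window_s Welch window length in seconds.
#' @return A `band_power_table`: list with `values` (trial x channel x
#'   band array), `bands`, the trial metadata, and provenance fields.
#' @export
band_power <- function(es, bands = canonical_bands(), window_s = 1) {
  validate_epoch_set(es)
  bands <- as_band_list(bands, fs = es$fs)
  dur <- n_samples(es) / es$fs
  for (b in bands) {
    if (dur < 1 / b$lo)
      stop(sprintf(
        "segment too short for band '%s': %.3g s < one period of %g Hz",
        b$name, dur, b$lo))
  }
  nt <- n_trials(es)
  vals <- array(NA_real_, c(nt, n_channels(es), length(bands)),
                dimnames = list(NULL, es$channel_ids, names(bands)))
  for (i in seq_len(nt)) {
    p <- psd_mat(trial_matrix(es, i), es$fs, window_s)
    for (k in seq_along(bands)) {
      vals[i, , k] <- band_integral(p$freq, p$density,
                                    bands[[k]]$lo, bands[[k]]$hi)
    }
  }
  structure(list(values = vals, bands = bands, trials = es$trials,
                 fs = es$fs, t0 = es$t0),
            class = "band_power_table")
}

#' Cohort x phrase mean band power
#'
#' Averages band power across all trials of all participants within each
#' (cohort, phrase) cell.
#'
#' @param bpt a `band_power_table` from [band_power()].
#' @return Array cohort x phrase x channel x band (with dimnames).
#' @export
group_mean_band_power <- function(bpt) {
  stopifnot(inherits(bpt, "band_power_table"))
  tr <- bpt$trials
  cohorts <- c("healthy", "patient")
  phrases <- sort(unique(tr$phrase_id))
  d <- dim(bpt$values)
  out <- array(NA_real_, c(2L, length(phrases), d[2], d[3]),
               dimnames = list(cohorts, as.character(phrases),
                               dimnames(bpt$values)[[2]],
                               dimnames(bpt$values)[[3]]))
  for (ci in seq_along(cohorts)) {
    for (pi in seq_along(phrases)) {
      idx <- tr$cohort == cohorts[ci] & tr$phrase_id == phrases[pi]
      if (!any(idx))
        stop(sprintf("empty group cell: cohort=%s, phrase=%s",
                     cohorts[ci], phrases[pi]))
      out[ci, pi, , ] <- apply(bpt$values[idx, , , drop = FALSE],
                               c(2, 3), mean)
    }
  }
  out
}
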