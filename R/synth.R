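# Synthetic two-cohort oscillatory MEG-like data.
#
# Signals are sums of band-limited Gaussian sources over a 1/f (pink)
# background plus common-mode power-line contamination.  Band-limited
# sources have the spectrum of zero-phase 4th-order Butterworth
# band-passed white noise; they are synthesized in the frequency domain
# (Hermitian-symmetric Gaussian spectrum shaped by the filter magnitude
# response), which is distributionally equivalent to time-domain
# filtering of white noise and much faster at scale.  Inter-channel
# coupling is induced by one shared source per band added to every
# channel with weight rho, so the expected pairwise correlation has a
# closed form usable as a test oracle.

# Amplitude shaping vector over the n two-sided FFT bins for a
# zero-phase Butterworth band pass; normalized to unit output variance.
spectral_shape_band <- function(band, n, fs, order = 4) {
  if (band$hi >= fs / 2)
    stop(sprintf("band '%s' exceeds Nyquist for fs = %g", band$name, fs))
  co <- butter_bandpass(order, band$lo, band$hi, fs)
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)  # two-sided grid folded to [0, fs/2]
  M <- filter_mag2(co$b, co$a, f, fs)  # |H|^2: zero-phase magnitude
  M[1] <- 0
  M / sqrt(mean(M^2))
}

# 1/f amplitude shaping (PSD proportional to 1/f above f_floor).
spectral_shape_pink <- function(n, fs, f_floor = 1) {
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  M <- 1 / sqrt(pmax(f, f_floor))
  M[1] <- 0
  M / sqrt(mean(M^2))
}

# m columns of length-n real noise whose amplitude spectrum follows M:
# pre-drawn standard normals shaped into a Hermitian spectrum (compiled
# kernel) and inverse-transformed.  Consumes R random numbers in a
# fixed order, so output is deterministic given the RNG state.
colored_noise <- function(M, m) {
  n <- length(M)
  if (n < 2) stop("shape vector too short")
  half <- if (n %% 2L == 0L) n %/% 2L - 1L else (n - 1L) %/% 2L
  dc <- rnorm(m)
  nyq <- if (n %% 2L == 0L) rnorm(m) else numeric(0)
  re <- rnorm(half * m)
  im <- rnorm(half * m)
  X <- .hermitian_spectrum(as.numeric(M), as.integer(m), dc, nyq, re, im)
  Re(mvfft(X, inverse = TRUE)) / n
}

#' Band-limited Gaussian source signal
#'
#' Zero-mean noise whose power is concentrated in the requested band
#' (the spectrum of zero-phase 4th-order Butterworth band-passed white
#' noise), with standard deviation approximately `sigma`.
#'
#' @param band a [band_spec()].
#' @param n_samples signal length.
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed (same seed, same signal).
#' @param sigma amplitude (standard deviation scale).
#' @return Numeric vector of length `n_samples`.
#' @export
bandlimited_source <- function(band, n_samples, fs, seed, sigma = 1) {
  if (n_samples <= 0) stop("n_samples must be positive")
  set.seed(seed)
  M <- spectral_shape_band(band, n_samples, fs)
  drop(colored_noise(sigma * M, 1L))
}

#' Pink (1/f) background noise
#'
#' Zero-mean noise with spectral density proportional to 1/f above
#' `f_floor` (flat below), unit variance.
#'
#' @param n_samples signal length (> 0).
#' @param fs sampling rate in Hz.
#' @param seed integer RNG seed.
#' @param f_floor low-frequency flattening corner in Hz.
#' @return Numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, fs, seed, f_floor = 1) {
  if (n_samples <= 0) stop("n_samples must be positive")
  set.seed(seed)
  M <- spectral_shape_pink(n_samples, fs, f_floor)
  drop(colored_noise(M, 1L))
}

#' Parameters of the synthetic cohort generator
#'
#' Defines the generative model for a two-cohort (healthy vs patient)
#' speech-task recording: per-band source amplitudes over a pink
#' background, a per-cohort shared-source coupling weight `rho`, a
#' patient beta-band amplitude gain `g_beta`, common-mode 60 Hz line
#' contamination, and a broadband amplitude boost of the overt-speech
#' window.  The `"null"` preset makes both cohorts generatively
#' identical; the `"beta-effect"` preset raises patient beta amplitude
#' (`g_beta = 1.5`) and patient coupling (`rho = 0.6` vs `0.3`).
#'
#' The default `"reduced"` scale (32 channels, 20 trials per phrase)
#' keeps simulation tractable on one CPU; `scale = "full"` reproduces
#' the full recording layout (196 channels, 60 trials per phrase).
#'
#' @param preset `"null"` or `"beta-effect"`.
#' @param scale `"reduced"` or `"full"`.
#' @param n_channels,trials_per_phrase override the scale defaults.
#' @param fs sampling rate in Hz.
#' @param t0,t_end epoch window in seconds relative to stimulus onset.
#' @param participants_per_cohort participants per cohort.
#' @param n_phrases number of phrase stimuli.
#' @param band_amp named per-band source amplitudes (sd units).
#' @param rho_healthy,rho_patient shared-source coupling in `[0, 1)`.
#' @param g_beta patient beta amplitude gain (>= 1).
#' @param pink_amp pink-background amplitude.
#' @param line_amp,line_freq common-mode line-noise amplitude and frequency.
#' @param overt_gain broadband amplitude factor of the overt window.
#' @param overt_window overt window in seconds.
#' @param participant_jitter_sd log-normal sd of an optional
#'   per-participant global amplitude factor (default 0: participants
#'   within a cohort are exchangeable, as the channel model specifies).
#' @param seed integer RNG seed.
#' @return A `synth_params` list.
#' @export
synth_params <- function(preset = c("null", "beta-effect"),
                         scale = c("reduced", "full"),
                         n_channels = NULL, trials_per_phrase = NULL,
                         fs = 1000, t0 = -0.5, t_end = 4.5,
                         participants_per_cohort = 3, n_phrases = 5,
                         band_amp = c(delta = 1, theta = 0.8, alpha = 0.7,
                                      beta = 0.6, gamma = 0.4,
                                      highgamma = 0.3),
                         rho_healthy = 0.3, rho_patient = NULL,
                         g_beta = NULL, pink_amp = 1,
                         line_amp = 0.2, line_freq = 60,
                         overt_gain = 1.3, overt_window = c(2, 4.5),
                         participant_jitter_sd = 0, seed = 1) {
  preset <- match.arg(preset)
  scale <- match.arg(scale)
  if (is.null(n_channels))
    n_channels <- if (scale == "full") 196L else 32L
  if (is.null(trials_per_phrase))
    trials_per_phrase <- if (scale == "full") 60L else 20L
  if (is.null(g_beta)) g_beta <- if (preset == "beta-effect") 1.5 else 1
  if (is.null(rho_patient))
    rho_patient <- if (preset == "beta-effect") 0.6 else rho_healthy
  if (any(band_amp < 0)) stop("band amplitudes must be >= 0")
  if (rho_healthy < 0 || rho_healthy >= 1 || rho_patient < 0 ||
      rho_patient >= 1) stop("rho must lie in [0, 1)")
  if (g_beta < 1) stop("g_beta must be >= 1")
  if (fs <= 0 || t_end <= t0) stop("invalid sampling rate or epoch window")
  structure(list(
    preset = preset, scale = scale, n_channels = as.integer(n_channels),
    trials_per_phrase = as.integer(trials_per_phrase), fs = fs, t0 = t0,
    t_end = t_end,
    participants_per_cohort = as.integer(participants_per_cohort),
    n_phrases = as.integer(n_phrases), band_amp = band_amp,
    rho_healthy = rho_healthy, rho_patient = rho_patient, g_beta = g_beta,
    pink_amp = pink_amp, line_amp = line_amp, line_freq = line_freq,
    overt_gain = overt_gain, overt_window = overt_window,
    participant_jitter_sd = participant_jitter_sd, seed = as.integer(seed)
  ), class = "synth_params")
}

#' Generate a synthetic two-cohort epoched recording
#'
#' Each channel of each trial is a sum of independent band-limited
#' sources (one per canonical band), a per-band source shared across all
#' channels of the participant with weight `rho` (inducing inter-channel
#' coupling), pink background noise, and a common-mode line-noise
#' sinusoid.  Patient-cohort beta amplitude is multiplied by `g_beta`
#' and patient coupling uses `rho_patient`.  The overt window receives a
#' broadband amplitude factor, emulating the stronger signal during
#' articulation.  Output is deterministic given the parameter seed.
#'
#' @param p a [synth_params()] object.
#' @return An [epoch_set()] with fully populated trial metadata.
#' @examples
#' p <- synth_params(n_channels = 4, trials_per_phrase = 2, t_end = 0.5)
#' es <- generate_cohorts(p)
#' n_trials(es)
#' @export
generate_cohorts <- function(p) {
  stopifnot(inherits(p, "synth_params"))
  bands <- canonical_bands()
  if (!all(names(p$band_amp) %in% names(bands)))
    stop("band_amp names must be canonical band names")
  n_samp <- round((p$t_end - p$t0) * p$fs)
  n_ch <- p$n_channels
  n_per_part <- p$n_phrases * p$trials_per_phrase
  n_total <- 2L * p$participants_per_cohort * n_per_part
  tvec <- p$t0 + (seq_len(n_samp) - 1L) / p$fs
  overt_rows <- tvec >= p$overt_window[1] & tvec < p$overt_window[2]
  gvec <- ifelse(overt_rows, p$overt_gain, 1)

  shapes <- lapply(bands[names(p$band_amp)], spectral_shape_band,
                   n = n_samp, fs = p$fs)
  pink_sh <- spectral_shape_pink(n_samp, p$fs)

  # sample x channel x trial working layout (contiguous writes);
  # permuted to the trial x channel x sample container at the end
  data <- array(0, c(n_samp, n_ch, n_total))
  channel_ids <- sprintf("MEG%03d", seq_len(n_ch))
  meta <- vector("list", 2L * p$participants_per_cohort)

  set.seed(p$seed)
  trial0 <- 0L
  pi_meta <- 0L
  for (cohort in c("healthy", "patient")) {
    rho <- if (cohort == "healthy") p$rho_healthy else p$rho_patient
    for (part in seq_len(p$participants_per_cohort)) {
      pid <- sprintf("%s%d", if (cohort == "healthy") "H" else "A", part)
      jit <- if (p$participant_jitter_sd > 0)
        exp(rnorm(1, 0, p$participant_jitter_sd)) else 1
      amp <- p$band_amp * jit
      if (cohort == "patient" && "beta" %in% names(amp))
        amp["beta"] <- amp["beta"] * p$g_beta
      M_ind <- sqrt(
        Reduce(`+`, Map(function(a, s) (a * s)^2, amp, shapes)) +
          (p$pink_amp * jit * pink_sh)^2)
      M_sh <- sqrt(
        Reduce(`+`, Map(function(a, s) (rho * a * s)^2, amp, shapes)))

      phases <- runif(n_per_part, 0, 2 * pi)
      chunk <- max(1L, 4000L %/% n_ch)
      tr <- 1L
      while (tr <= n_per_part) {
        nt <- min(chunk, n_per_part - tr + 1L)
        idx <- tr:(tr + nt - 1L)
        blk <- colored_noise(M_ind, n_ch * nt)
        sh <- colored_noise(M_sh, nt)
        blk <- .fuse_block(blk, sh, n_ch, gvec, p$line_amp,
                           2 * pi * p$line_freq * tvec, phases[idx])
        dim(blk) <- c(n_samp, n_ch, nt)
        data[, , trial0 + idx] <- blk
        tr <- tr + nt
      }
      pi_meta <- pi_meta + 1L
      meta[[pi_meta]] <- data.frame(
        participant_id = pid, cohort = cohort,
        phrase_id = rep(seq_len(p$n_phrases), each = p$trials_per_phrase),
        trial_index = rep(seq_len(p$trials_per_phrase), p$n_phrases),
        valid = TRUE, stringsAsFactors = FALSE)
      trial0 <- trial0 + n_per_part
    }
  }
  epoch_set(aperm(data, c(3, 2, 1)), fs = p$fs, t0 = p$t0,
            channel_ids = channel_ids, trials = do.call(rbind, meta))
}
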