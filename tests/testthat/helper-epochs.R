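# Small constructors shared across tests.

toy_trials <- function(n, participant = "H1", cohort = "healthy",
                       phrase = 1) {
  data.frame(participant_id = participant, cohort = cohort,
             phrase_id = phrase, trial_index = seq_len(n), valid = TRUE,
             stringsAsFactors = FALSE)
}

# Epoch set holding one or more explicit signals (list of n_channel x
# n_sample matrices, one per trial).
signal_epochs <- function(signals, fs, t0 = 0) {
  if (is.matrix(signals)) signals <- list(signals)
  nch <- nrow(signals[[1]])
  ns <- ncol(signals[[1]])
  dat <- array(NA_real_, c(length(signals), nch, ns))
  for (i in seq_along(signals)) dat[i, , ] <- signals[[i]]
  epoch_set(dat, fs = fs, t0 = t0,
            channel_ids = paste0("ch", seq_len(nch)),
            trials = toy_trials(length(signals)))
}

# Single-channel, single-trial epoch set around a vector.
vector_epochs <- function(x, fs, t0 = 0) {
  signal_epochs(matrix(x, nrow = 1), fs = fs, t0 = t0)
}

sine_epochs <- function(freq, fs, dur_s = 5, t0 = 0, amp = 1) {
  t <- (seq_len(round(dur_s * fs)) - 1) / fs
  vector_epochs(amp * sin(2 * pi * freq * t), fs = fs, t0 = t0)
}

rms <- function(x) sqrt(mean(x^2))

# Random epoch set with full cohort/participant/phrase structure and
# iid Gaussian signals (no cohort difference).
random_cohort_epochs <- function(n_participants = 2, n_phrases = 2,
                                 trials_per_phrase = 3, n_channels = 3,
                                 n_samples = 50, fs = 100, seed = 1) {
  set.seed(seed)
  meta <- list()
  for (cohort in c("healthy", "patient")) {
    for (p in seq_len(n_participants)) {
      pid <- paste0(if (cohort == "healthy") "H" else "A", p)
      meta[[length(meta) + 1L]] <- data.frame(
        participant_id = pid, cohort = cohort,
        phrase_id = rep(seq_len(n_phrases), each = trials_per_phrase),
        trial_index = rep(seq_len(trials_per_phrase), n_phrases),
        valid = TRUE, stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, meta)
  dat <- array(rnorm(nrow(trials) * n_channels * n_samples),
               c(nrow(trials), n_channels, n_samples))
  epoch_set(dat, fs = fs, t0 = 0,
            channel_ids = paste0("ch", seq_len(n_channels)),
            trials = trials)
}
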