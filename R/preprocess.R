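# Signal conditioning.  Pipeline order is fixed:
# lowpass/resample -> notch -> segment parsing -> channel/trial exclusion.
# All filters are applied forward-backward (zero phase).

#' Low-pass filter and resample an epoch set
#'
#' Applies a zero-phase Butterworth low-pass (default 4th order, 250 Hz)
#' and decimates to `target_fs`.  The low-pass serves as the anti-alias
#' guard for the decimation; the sampling-rate ratio must be an integer.
#' With `target_fs` equal to the input rate only the filter is applied.
#'
#' @param es an `epoch_set`.
#' @param cutoff low-pass cutoff in Hz.
#' @param order Butterworth order (single pass; doubled by the
#'   forward-backward application).
#' @param target_fs output sampling rate in Hz.
#' @return The filtered (and possibly decimated) `epoch_set`.
#' @export
lowpass_and_resample <- function(es, cutoff = 250, order = 4,
                                 target_fs = 1000) {
  validate_epoch_set(es)
  if (target_fs > es$fs) stop("target_fs must not exceed the input rate")
  if (cutoff >= target_fs / 2)
    stop("cutoff must be below the Nyquist frequency of target_fs")
  co <- butter_lowpass(order, cutoff, es$fs)
  es <- apply_filter(es, co$b, co$a)
  if (target_fs < es$fs) {
    fac <- es$fs / target_fs
    if (abs(fac - round(fac)) > 1e-9)
      stop("fs / target_fs must be an integer decimation factor")
    fac <- as.integer(round(fac))
    keep <- seq(1L, n_samples(es), by = fac)
    es$data <- es$data[, , keep, drop = FALSE]
    es$fs <- target_fs
  }
  es
}

#' Notch out power-line interference
#'
#' Applies a zero-phase 2nd-order IIR notch at `base` Hz and all its
#' harmonics below the Nyquist frequency.  The notch is narrow: the line
#' frequency is attenuated by well over 20 dB while tones 5 Hz away pass
#' essentially unchanged.
#'
#' @param es an `epoch_set`.
#' @param base line frequency in Hz.
#' @param bw approximate single-pass -3 dB width of each notch, Hz.
#' @return The filtered `epoch_set`.
#' @export
notch_line <- function(es, base = 60, bw = 3) {
  validate_epoch_set(es)
  if (base >= es$fs / 2) stop("notch base frequency at or above Nyquist")
  freqs <- seq(base, es$fs / 2 - 1e-9, by = base)
  apply_filter_cascade(es, lapply(freqs, design_notch, fs = es$fs, bw = bw))
}

# Filter every trial x channel signal of an epoch set (zero phase).
apply_filter <- function(es, b, a) {
  apply_filter_cascade(es, list(list(b = b, a = a)))
}

# Apply a cascade of filters to all signals with one layout permutation:
# work in sample x (channel * trial) form, then permute back.
apply_filter_cascade <- function(es, coefs) {
  d <- dim(es$data)
  X <- aperm(es$data, c(3, 2, 1))
  dim(X) <- c(d[3], d[2] * d[1])
  X <- filtfilt_cascade(coefs, X)
  dim(X) <- c(d[3], d[2], d[1])
  es$data <- aperm(X, c(3, 2, 1))
  es
}

#' Extract a time segment from every trial
#'
#' Cuts the sub-window of a [segment_spec()] out of each epoch and
#' re-anchors the time axis at the segment start.  At 1 kHz the covert
#' window (1-2 s) yields 1000 samples per trial and the overt window
#' (2-4.5 s) yields 2500.
#'
#' @param es an `epoch_set`.
#' @param seg a [segment_spec()], or the name of a default segment
#'   (`"covert"`, `"overt"`, `"full"`).
#' @return The segmented `epoch_set`.
#' @export
parse_segment <- function(es, seg) {
  validate_epoch_set(es)
  if (is.character(seg)) {
    segs <- default_segments(es$t0, es$t0 + n_samples(es) / es$fs)
    if (!seg %in% names(segs)) stop("unknown segment name: ", seg)
    seg <- segs[[seg]]
  }
  t_end <- es$t0 + n_samples(es) / es$fs
  if (seg$start_s < es$t0 - 1e-9 || seg$end_s > t_end + 1e-9)
    stop(sprintf("segment [%g, %g] s outside epoch window [%g, %g] s",
                 seg$start_s, seg$end_s, es$t0, t_end))
  i0 <- round((seg$start_s - es$t0) * es$fs) + 1L
  count <- round((seg$end_s - seg$start_s) * es$fs)
  es$data <- es$data[, , i0:(i0 + count - 1L), drop = FALSE]
  es$t0 <- seg$start_s
  es
}

#' Exclude bad channels by label
#'
#' Removes the listed channels from the recording, preserving the order
#' of the survivors.  The same exclusion list is applied to every
#' participant.  Unknown labels raise an error naming them; duplicates
#' in the list are collapsed with a warning.
#'
#' @param es an `epoch_set`.
#' @param bad character vector of channel labels to drop.
#' @return The reduced `epoch_set`.
#' @export
exclude_channels <- function(es, bad) {
  validate_epoch_set(es)
  if (length(bad) == 0) return(es)
  if (anyDuplicated(bad)) {
    warning("duplicate labels in bad-channel list; deduplicating")
    bad <- unique(bad)
  }
  unknown <- setdiff(bad, es$channel_ids)
  if (length(unknown))
    stop("unknown channel label(s): ", paste(unknown, collapse = ", "))
  keep <- !(es$channel_ids %in% bad)
  es$data <- es$data[, keep, , drop = FALSE]
  es$channel_ids <- es$channel_ids[keep]
  es
}

#' Amplitude-based trial rejection and per-cell trial cap
#'
#' A deterministic stand-in for visual artifact screening: trials whose
#' peak absolute amplitude exceeds `amp_thresh` are dropped, and of the
#' survivors only the first `cap` trials (in original order) of each
#' (participant, phrase) cell are kept.  The default threshold is 5
#' times the median per-trial peak amplitude.
#'
#' @param es an `epoch_set`.
#' @param amp_thresh absolute amplitude threshold; `NULL` for the
#'   median-based default; `Inf` disables rejection (cap only).
#' @param cap maximum trials kept per (participant, phrase) cell.
#' @param mult multiplier for the median-based default threshold.
#' @return The reduced `epoch_set`.
#' @export
reject_and_cap_trials <- function(es, amp_thresh = NULL, cap = 60,
                                  mult = 5) {
  validate_epoch_set(es)
  if (cap < 1) stop("cap must be >= 1")
  peaks <- apply(abs(es$data), 1, max)
  if (is.null(amp_thresh)) amp_thresh <- mult * median(peaks)
  ok <- peaks <= amp_thresh
  cells <- interaction(es$trials$participant_id, es$trials$phrase_id,
                       drop = TRUE)
  empty <- tapply(ok, cells, sum) == 0
  if (any(empty)) {
    stop("no surviving trials in cell(s): ",
         paste(names(empty)[empty], collapse = ", "))
  }
  keep <- logical(length(ok))
  for (cell in levels(cells)) {
    idx <- which(cells == cell & ok)
    keep[head(idx, cap)] <- TRUE
  }
  subset_trials(es, keep)
}

#' Apply an externally supplied trial keep mask
#'
#' Hook for artifact screening performed outside the package (e.g., an
#' ICA-based cleanup): any per-trial logical keep/drop decision can be
#' injected here.
#'
#' @param es an `epoch_set`.
#' @param keep logical vector, one entry per trial.
#' @return The reduced `epoch_set`.
#' @export
apply_trial_mask <- function(es, keep) {
  validate_epoch_set(es)
  if (!is.logical(keep) || length(keep) != n_trials(es))
    stop("keep must be a logical vector with one entry per trial")
  subset_trials(es, keep)
}
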