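#' Epoched multichannel recording container
#'
#' The central data container: a 3-D numeric array of dimensions
#' trial x channel x sample together with the sampling rate, the time of
#' the first sample relative to stimulus onset, ordered channel labels and
#' a per-trial metadata table.
#'
#' @param data numeric array, trial x channel x sample.
#' @param fs sampling rate in Hz (> 0).
#' @param t0 time of the first sample relative to stimulus onset, seconds.
#' @param channel_ids character vector of channel labels, one per channel.
#' @param trials data frame with one row per trial and columns
#'   `participant_id`, `cohort` (one of `"healthy"`, `"patient"`),
#'   `phrase_id`, `trial_index` and `valid`.
#' @return An `epoch_set` object.
#' @examples
#' es <- epoch_set(array(rnorm(2 * 3 * 10), c(2, 3, 10)), fs = 100, t0 = 0,
#'                 channel_ids = c("ch1", "ch2", "ch3"),
#'                 trials = data.frame(participant_id = "H1",
#'                                     cohort = "healthy", phrase_id = 1,
#'                                     trial_index = 1:2, valid = TRUE))
#' n_trials(es)
#' @export
epoch_set <- function(data, fs, t0, channel_ids, trials) {
  es <- structure(list(data = data, fs = fs, t0 = t0,
                       channel_ids = as.character(channel_ids),
                       trials = as.data.frame(trials)),
                  class = "epoch_set")
  validate_epoch_set(es)
  es
}

#' Validate an epoch container
#'
#' Checks the structural invariants of an [epoch_set()]: array shape and
#' metadata alignment, a strictly positive sampling rate, and cohort
#' labels drawn from the declared set.  Returns the object invisibly on
#' success and raises an error naming the offending field otherwise.
#'
#' @param es an `epoch_set`.
#' @export
validate_epoch_set <- function(es) {
  if (!is.array(es$data) || length(dim(es$data)) != 3L)
    stop("field 'data': must be a 3-D array (trial x channel x sample)")
  if (!is.numeric(es$fs) || length(es$fs) != 1L || is.na(es$fs) || es$fs <= 0)
    stop("field 'fs': sampling rate must be a single positive number")
  if (!is.numeric(es$t0) || length(es$t0) != 1L || is.na(es$t0))
    stop("field 't0': must be a single finite number")
  d <- dim(es$data)
  if (length(es$channel_ids) != d[2])
    stop("field 'channel_ids': length must equal the channel dimension")
  if (anyDuplicated(es$channel_ids))
    stop("field 'channel_ids': labels must be unique")
  tr <- es$trials
  req <- c("participant_id", "cohort", "phrase_id", "trial_index", "valid")
  miss <- setdiff(req, names(tr))
  if (length(miss))
    stop("field 'trials': missing columns ", paste(miss, collapse = ", "))
  if (nrow(tr) != d[1])
    stop("field 'trials': row count must equal the trial dimension")
  if (!all(as.character(tr$cohort) %in% c("healthy", "patient")))
    stop("field 'trials': cohort labels must be 'healthy' or 'patient'")
  both <- tapply(as.character(tr$cohort), tr$participant_id,
                 function(x) length(unique(x)))
  if (any(both > 1))
    stop("field 'trials': participant appears in both cohorts: ",
         paste(names(both)[both > 1], collapse = ", "))
  invisible(es)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d trials x %d channels x %d samples @ %g Hz, t0 = %g s\n",
    d[1], d[2], d[3], x$fs, x$t0))
  cat(sprintf("  participants: %s\n",
              paste(unique(x$trials$participant_id), collapse = ", ")))
  invisible(x)
}

#' Number of trials, channels and samples
#'
#' @param es an `epoch_set`.
#' @return Integer count.
#' @export
n_trials <- function(es) dim(es$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(es) dim(es$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(es) dim(es$data)[3]

#' Time axis of an epoch set
#'
#' @param es an `epoch_set`.
#' @return Numeric vector of sample times in seconds relative to onset.
#' @export
epoch_times <- function(es) es$t0 + (seq_len(n_samples(es)) - 1L) / es$fs

#' Subset trials of an epoch set
#'
#' @param es an `epoch_set`.
#' @param idx integer or logical trial index.
#' @return The subsetted `epoch_set` (metadata rows carried along).
#' @export
subset_trials <- function(es, idx) {
  es$data <- es$data[idx, , , drop = FALSE]
  es$trials <- es$trials[idx, , drop = FALSE]
  rownames(es$trials) <- NULL
  validate_epoch_set(es)
  es
}

# One trial as a sample x channel matrix (the layout filters expect).
trial_matrix <- function(es, i) {
  t(matrix(es$data[i, , ], nrow = n_channels(es)))
}
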