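#' Frequency band specification
#'
#' A band is a named frequency interval in Hz.  Bands must be strictly
#' positive and non-degenerate; when a sampling rate is supplied the band
#' must also lie below the Nyquist frequency.
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @param fs optional sampling rate in Hz used to check `hi < fs / 2`.
#' @return A `band_spec` object (a named list with `name`, `lo`, `hi`).
#' @examples
#' band_spec("beta", 16, 30)
#' @export
band_spec <- function(name, lo, hi, fs = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L ||
      length(hi) != 1L || is.na(lo) || is.na(hi)) {
    stop("band edges must be single finite numbers")
  }
  if (!(lo > 0 && lo < hi)) {
    stop(sprintf("invalid band '%s': need 0 < lo < hi, got [%g, %g]",
                 name, lo, hi))
  }
  if (!is.null(fs) && hi >= fs / 2) {
    stop(sprintf("band '%s' upper edge %g Hz is at or above Nyquist (%g Hz)",
                 name, hi, fs / 2))
  }
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' Canonical frequency bands
#'
#' The six canonical neural oscillation bands used throughout the package:
#' delta (1-4 Hz), theta (4-8 Hz), alpha (8-16 Hz), beta (16-30 Hz),
#' gamma (30-59 Hz) and high gamma (61-119 Hz).  The gamma/high-gamma gap
#' leaves the 60 Hz power-line frequency outside every band.
#'
#' @return A named list of [band_spec()] objects.
#' @examples
#' names(canonical_bands())
#' @export
canonical_bands <- function() {
  defs <- list(
    delta     = c(1, 4),
    theta     = c(4, 8),
    alpha     = c(8, 16),
    beta      = c(16, 30),
    gamma     = c(30, 59),
    highgamma = c(61, 119)
  )
  lapply(setNames(names(defs), names(defs)),
         function(nm) band_spec(nm, defs[[nm]][1], defs[[nm]][2]))
}

#' Broadband feature range
#'
#' The wide band used for "all spectral content" classification features.
#' The default covers 1-119 Hz (the union of the canonical bands); the
#' `"wide"` variant covers 0.3-250 Hz.
#'
#' @param kind `"standard"` (1-119 Hz) or `"wide"` (0.3-250 Hz).
#' @return A [band_spec()] named `"broadband"`.
#' @export
broadband_spec <- function(kind = c("standard", "wide")) {
  kind <- match.arg(kind)
  if (kind == "standard") band_spec("broadband", 1, 119)
  else band_spec("broadband", 0.3, 250)
}

# Coerce a list/data.frame-ish band definition into a band_spec list.
as_band_list <- function(bands, fs = NULL) {
  if (inherits(bands, "band_spec")) bands <- list(bands)
  out <- lapply(bands, function(b) {
    if (inherits(b, "band_spec")) b
    else band_spec(b$name, b$lo, b$hi)
  })
  nm <- vapply(out, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate band names")
  if (!is.null(fs)) {
    for (b in out) {
      if (b$hi >= fs / 2)
        stop(sprintf("band '%s' exceeds Nyquist for fs = %g", b$name, fs))
    }
  }
  names(out) <- nm
  out
}

#' Segment specification
#'
#' Named sub-window of an epoch, in seconds relative to stimulus onset.
#' The conventional segments are `covert` (1-2 s), `overt` (2-4.5 s) and
#' `full` (the whole epoch).
#'
#' @param name segment label.
#' @param start_s,end_s window edges in seconds relative to stimulus onset.
#' @return A `segment_spec` object.
#' @examples
#' segment_spec("covert", 1, 2)
#' @export
segment_spec <- function(name, start_s, end_s) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(start_s < end_s)) stop("segment start must precede end")
  structure(list(name = name, start_s = start_s, end_s = end_s),
            class = "segment_spec")
}

#' Default segment windows
#'
#' @param t0,t_end epoch window, used for the `full` segment.
#' @return Named list of [segment_spec()] objects.
#' @export
default_segments <- function(t0 = -0.5, t_end = 4.5) {
  list(
    covert = segment_spec("covert", 1, 2),
    overt  = segment_spec("overt", 2, 4.5),
    full   = segment_spec("full", t0, t_end)
  )
}
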