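# Zero-phase filtering helpers.  All user-facing filtering in the package
# is forward-backward (zero-phase), so the effective magnitude response is
# |H|^2 and the effective order doubles.

# Steady-state initial filter state (direct form II transposed) so that
# the response to a step of height x[0] starts transient-free; used on
# both passes of the zero-phase application.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  bb <- c(b, numeric(n - length(b))) / a[1]
  aa <- c(a, numeric(n - length(a))) / a[1]
  if (n == 1) return(numeric(0))
  comp <- if (n == 2) matrix(-aa[2], 1, 1)
          else rbind(-aa[2:n], cbind(diag(n - 2), 0))
  B <- bb[2:n] - aa[2:n] * bb[1]
  solve(diag(n - 1) - t(comp), B)
}

prep_filter <- function(co) {
  list(b = as.numeric(co$b), a = as.numeric(co$a),
       zi = lfilter_zi(co$b, co$a))
}

# Apply a rational IIR filter (b, a) forward-backward to each column of X.
filtfilt_mat <- function(b, a, X) {
  filtfilt_cascade(list(list(b = b, a = a)), X)
}

# Apply a cascade of filters (list of list(b, a)) to each column of X.
filtfilt_cascade <- function(coefs, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1L)
  .filtfilt_cascade_cols(lapply(coefs, prep_filter), X)
}

filtfilt_vec <- function(b, a, x) drop(filtfilt_mat(b, a, x))

# Butterworth designs (delegated to the signal package).
butter_lowpass <- function(order, cutoff, fs) {
  if (cutoff >= fs / 2) stop("lowpass cutoff at or above Nyquist")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  list(b = bf$b, a = bf$a)
}

butter_bandpass <- function(order, lo, hi, fs) {
  if (hi >= fs / 2) stop("bandpass upper edge at or above Nyquist")
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  list(b = bf$b, a = bf$a)
}

# Classic second-order IIR notch: zeros on the unit circle at +/-w0,
# poles at radius r inside.  `bw` is the approximate -3 dB full width in
# Hz of a single pass.
design_notch <- function(f0, fs, bw = 3) {
  if (f0 >= fs / 2) stop("notch frequency at or above Nyquist")
  w0 <- 2 * pi * f0 / fs
  r <- 1 - pi * bw / fs
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1, -2 * r * cos(w0), r^2)
  # unit gain at DC
  k <- sum(a) / sum(b)
  list(b = k * b, a = a)
}

# Squared magnitude response |H(f)|^2 of (b, a) at frequencies f (Hz);
# a single forward pass.  Zero-phase application squares this again.
filter_mag2 <- function(b, a, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  num <- vapply(z, function(zz) sum(b * zz^(seq_along(b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(a * zz^(seq_along(a) - 1)), complex(1))
  Mod(num / den)^2
}
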