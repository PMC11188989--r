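# Naive reference implementations used as independent oracles: plain R
# loops over the textbook definitions (direct-form-II-transposed
# difference equation, steady-state startup state, odd-reflection
# padded forward-backward pass, FFT analytic signal, Pearson sums).

naive_zi <- function(b, a) {
  n <- max(length(a), length(b))
  bb <- c(b, numeric(n - length(b))) / a[1]
  aa <- c(a, numeric(n - length(a))) / a[1]
  comp <- if (n == 2) matrix(-aa[2], 1, 1)
          else rbind(-aa[2:n], cbind(diag(n - 2), 0))
  solve(diag(n - 1) - t(comp), bb[2:n] - aa[2:n] * bb[1])
}

naive_lfilter <- function(b, a, x, z) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b))) / a[1]
  a <- c(a, numeric(n - length(a))) / a[1]
  nz <- n - 1
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    if (nz > 1) {
      for (j in 1:(nz - 1)) z[j] <- b[j + 1] * xi + z[j + 1] - a[j + 1] * yi
    }
    z[nz] <- b[nz + 1] * xi - a[nz + 1] * yi
    y[i] <- yi
  }
  y
}

naive_oddext <- function(x, pad) {
  n <- length(x)
  c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
}

naive_filtfilt <- function(b, a, x) {
  pad <- 3 * max(length(a), length(b))
  ext <- naive_oddext(x, pad)
  zi <- naive_zi(b, a)
  y <- naive_lfilter(b, a, ext, zi * ext[1])
  y <- rev(naive_lfilter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + length(x))]
}

naive_hilbert_env <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

# AEC of one epoch array (trial x channel x sample), single-trial
# averaged, following the documented estimator step by step.
naive_aec <- function(dat, lo, hi, fs, edge_trim_s = 0.1) {
  nt <- dim(dat)[1]; nc <- dim(dat)[2]; ns <- dim(dat)[3]
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  ext <- min(ns - 1, round(0.25 * fs))
  ntrim <- round(edge_trim_s * fs)
  acc <- matrix(0, nc, nc)
  for (tr in seq_len(nt)) {
    env <- sapply(seq_len(nc), function(ch) {
      xe <- naive_oddext(dat[tr, ch, ], ext)
      e <- naive_hilbert_env(naive_filtfilt(bf$b, bf$a, xe))
      e[(ext + 1):(ext + ns)]
    })
    keep <- (ntrim + 1):(ns - ntrim)
    env <- env[keep, ]
    r <- matrix(1, nc, nc)
    for (i in seq_len(nc)) {
      for (j in seq_len(nc)) {
        xi <- env[, i] - mean(env[, i])
        yj <- env[, j] - mean(env[, j])
        r[i, j] <- sum(xi * yj) / sqrt(sum(xi^2) * sum(yj^2))
      }
    }
    acc <- acc + r
  }
  acc / nt
}
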