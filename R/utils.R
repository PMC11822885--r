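# Internal helpers shared across the pipeline.

# Sample index of time t (seconds from record start), 1-based.
# Convention: index = floor(t * fs) + 1, with a small epsilon so that times that
# are exact multiples of the sample period are not pushed down a sample by
# floating-point representation error.
.t2i <- function(t, fs) as.integer(floor(t * fs + 1e-9)) + 1L

# Deterministic fan-out of one user seed into named substreams, keeping every
# derived seed inside the 32-bit integer range R requires.
.sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

# Analytic signal via the frequency-domain Hilbert construction: zero out
# negative frequencies, double positive ones. Returns a complex vector whose
# modulus is the instantaneous amplitude of x.
.analytic <- function(x) {
  # Zero-pad to a 2-3-5-smooth length so the FFT stays O(n log n); the pad is
  # dropped again and only perturbs samples near the record edges, which the
  # envelope's validity mask excludes anyway.
  n0 <- length(x)
  m <- stats::nextn(n0, c(2, 3, 5))
  if (m > n0) {
    a <- .analytic(c(x, numeric(m - n0)))
    return(a[seq_len(n0)])
  }
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Real band-limited or power-law noise synthesised in the frequency domain.
# `shape(f)` gives the amplitude scaling for each positive frequency; the
# result is scaled to unit RMS. Deterministic given the RNG state.
.spectral_noise <- function(n, fs, shape) {
  nfreq <- n %/% 2
  f <- (1:nfreq) * fs / n
  amp <- shape(f)
  phase <- stats::runif(nfreq, 0, 2 * pi)
  pos <- amp * exp(1i * phase)
  X <- complex(n)
  X[2:(nfreq + 1)] <- pos
  if (n %% 2 == 0) {
    X[nfreq + 1] <- Re(X[nfreq + 1])  # Nyquist bin must be real
    if (nfreq > 1) X[n:(n - nfreq + 2)] <- Conj(pos[1:(nfreq - 1)])
  } else {
    X[n:(n - nfreq + 1)] <- Conj(pos)
  }
  x <- Re(stats::fft(X, inverse = TRUE) / n)
  r <- stats::sd(x)
  if (r > 0) x / r else x
}

.is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == round(x) && x > 0

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
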