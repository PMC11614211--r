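# Independent oracles used to freeze expected values.

# local equivalent of the package's seed guard, for oracles that must
# replicate a documented seed derivation
oracleWithSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# analytic-signal envelope via FFT (independent of the package's wavelets)
hilbertEnvelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * h, inverse = TRUE) / n)
}

# mean band-limited envelope of x (brick-wall band split + Hilbert)
bandEnvelope <- function(x, band, fs) {
  n <- length(x)
  k <- seq_len(n) - 1
  freq <- pmin(k, n - k) * fs / n
  xb <- Re(fft(fft(x) * (freq >= band[1] & freq <= band[2]), inverse = TRUE)) / n
  hilbertEnvelope(xb)
}

# exact binomial upper tail by direct summation of C(n, k) p^k (1-p)^(n-k)
binomTailOracle <- function(k, n, p = 0.5) {
  if (k > n) return(0)
  kk <- k:n
  sum(choose(n, kk) * p^kk * (1 - p)^(n - kk))
}

# Welch-style log-log spectral slope over a frequency band
welchSlope <- function(x, fs, band = c(2, 80), segS = 4) {
  seg <- segS * fs
  nSeg <- floor(length(x) / seg)
  psd <- 0
  for (s in seq_len(nSeg)) {
    v <- x[((s - 1) * seg + 1):(s * seg)]
    v <- v * (0.5 - 0.5 * cos(2 * pi * seq_along(v) / length(v)))  # Hann
    psd <- psd + Mod(fft(v)[seq_len(seg / 2)])^2
  }
  psd <- psd / nSeg
  freq <- (seq_len(seg / 2) - 1) * fs / seg
  sel <- freq >= band[1] & freq <= band[2]
  unname(coef(lm(log10(psd[sel]) ~ log10(freq[sel])))[2])
}

# direct (time-domain) Morlet convolution power for one epoch: the oracle
# for the FFT-based implementation
morletPowerDirect <- function(x, fs, freq, nCycles, timeIdx) {
  sigma <- nCycles / (2 * pi * freq)
  hw <- as.integer(round(2.5 * sigma * fs))
  tw <- (-hw:hw) / fs
  w <- exp(2i * pi * freq * tw) * exp(-tw^2 / (2 * sigma^2))
  w <- w / sqrt(sum(Mod(w)^2))
  vapply(timeIdx, function(s) {
    j <- (s - hw):(s + hw)
    ok <- j >= 1 & j <= length(x)
    Mod(sum(x[j[ok]] * Conj(rev(w))[ok]))^2
  }, 0)
}
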