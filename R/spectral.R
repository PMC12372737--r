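# Spectral helpers for uniformly sampled periodic signals.
#
# Retrospectively gated cine reconstructions are band-limited in cardiac phase,
# so a cycle sampled at n uniform timeframes determines a trigonometric
# interpolant exactly. All resampling and cycle integrals in this package act
# on that interpolant: resampling is spectral zero-padding/truncation and the
# cumulative integral is computed from the Fourier antiderivative.

#' Resample one period of a uniformly sampled signal
#'
#' Treats `y` as one full period sampled at `length(y)` uniform points starting
#' at phase zero and returns `m` uniform samples of the same period.
#'
#' @param y Numeric vector, one cycle of samples (first sample at cycle start).
#' @param m Integer, number of output samples.
#' @param method `"fourier"` (band-limited; exact for signals with harmonic
#'   content below the input Nyquist rate) or `"linear"` (periodic linear
#'   interpolation; monotone and overshoot-free but only second-order
#'   accurate).
#' @return Numeric vector of length `m`.
#' @export
#' @examples
#' y <- sin(2 * pi * (0:15) / 16)
#' max(abs(resample_periodic(y, 32) - sin(2 * pi * (0:31) / 32)))
resample_periodic <- function(y, m, method = c("fourier", "linear")) {
  method <- match.arg(method)
  n <- length(y)
  stopifnot(n >= 4L, m >= 1L)
  if (m == n) return(as.numeric(y))
  if (method == "linear") {
    tin <- (0:n) / n
    tout <- (0:(m - 1)) / m
    return(stats::approx(tin, c(y, y[1L]), xout = tout)$y)
  }
  co <- stats::fft(as.numeric(y)) / n
  Re(stats::fft(.pad_spectrum(co, m), inverse = TRUE))
}

# Zero-pad (m > n) or low-pass truncate (m < n) a length-n DFT coefficient
# vector (normalised, index 1 = DC) to length m, preserving conjugate symmetry
# so the inverse transform is real. The Nyquist bin of an even-length input is
# split (or re-folded) using the cosine convention.
.pad_spectrum <- function(co, m) {
  n <- length(co)
  cp <- complex(length.out = m)
  if (m > n) {
    h <- n %/% 2L
    if (n %% 2L == 0L) {
      cp[seq_len(h)] <- co[seq_len(h)]
      cp[h + 1L] <- co[h + 1L] / 2
      cp[m - h + 1L] <- Conj(co[h + 1L]) / 2
      if (h > 1L) cp[(m - h + 2L):m] <- co[(h + 2L):n]
    } else {
      cp[seq_len(h + 1L)] <- co[seq_len(h + 1L)]
      cp[(m - h + 1L):m] <- co[(h + 2L):n]
    }
  } else {
    hm <- m %/% 2L
    if (m %% 2L == 0L) {
      cp[seq_len(hm)] <- co[seq_len(hm)]
      cp[hm + 1L] <- co[hm + 1L] + co[n - hm + 1L]
      if (hm > 1L) cp[(hm + 2L):m] <- co[(n - hm + 2L):n]
    } else {
      cp[seq_len(hm + 1L)] <- co[seq_len(hm + 1L)]
      cp[(hm + 2L):m] <- co[(n - hm + 1L):n]
    }
  }
  cp
}

# Cumulative integral of the mean-removed trigonometric interpolant of one
# cycle, evaluated on `m` uniform points (m >= length(y) is forced up to
# `min_points` for accurate extrema location). Returns V(t) with arbitrary
# additive constant (DC of the antiderivative set to zero).
.cycle_antiderivative <- function(y, cycle_duration, min_points = 1024L) {
  n <- length(y)
  m <- if (n >= min_points) n else as.integer(min_points %/% n + 1L) * n
  q <- as.numeric(y) - mean(y)
  cp <- .pad_spectrum(stats::fft(q) / n, m)
  h <- m %/% 2L
  k <- c(0:h, if (m %% 2L == 0L) -((h - 1L):1L) else -(h:1L))
  omega <- 2 * pi * k / cycle_duration
  vc <- complex(length.out = m)
  nz <- omega != 0
  vc[nz] <- cp[nz] / (1i * omega[nz])
  if (m %% 2L == 0L) vc[h + 1L] <- 0  # Nyquist cosine integrates to a sine
                                      # that vanishes on the sample grid
  Re(stats::fft(vc, inverse = TRUE))
}

# Mean of |interpolant| over the cycle, via trigonometric upsampling before
# taking the absolute value (|.| introduces kinks that alias badly at the raw
# frame count).
.cycle_mean_abs <- function(y, min_points = 8192L) {
  n <- length(y)
  yy <- if (n >= min_points) as.numeric(y) else
    resample_periodic(y, as.integer(min_points %/% n + 1L) * n)
  mean(abs(yy))
}

# Evaluate RNG-consuming code under a seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
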