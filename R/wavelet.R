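# Orthogonal discrete wavelet transform used for baseline-wander removal.
#
# The environment ships no R wavelet package, so the pyramid transform is
# implemented here directly: a periodized (circular) DWT applied to a
# reflection-padded signal, with the Symlet-10 analysis filter bank
# hard-coded. Periodization gives exact perfect reconstruction; the
# reflection padding pushes the circular boundary artefacts outside the
# signal. Only what baseline removal needs is implemented: decompose to a
# fixed level, zero the final approximation, reconstruct.

# Symlet-10 decomposition low-pass filter (20 taps, orthonormal).
sym10_dec_lo <- c(
   7.7015980911449011e-04,  9.5632670722894754e-05,
  -8.6412992770224222e-03, -1.4653825813050513e-03,
   4.5927239231092203e-02,  1.1609893903711381e-02,
  -1.5949427888491757e-01, -7.0880535783243853e-02,
   4.7169066693843925e-01,  7.6951003702110710e-01,
   3.8382676106708546e-01, -3.5536740473817552e-02,
  -3.1990056882427800e-02,  4.9994972077376687e-02,
   5.7649120335819086e-03, -2.0354939812311290e-02,
  -8.0435893201654491e-04,  4.5931735853118284e-03,
   5.7036083618494284e-05, -4.5932942100465878e-04
)

# Quadrature-mirror high-pass from the low-pass.
sym10_dec_hi <- {
  L <- length(sym10_dec_lo)
  rev(sym10_dec_lo) * (-1)^(seq_len(L) - 1)
}

# One circular analysis step; x must have even length.
dwt_step_per <- function(x) {
  n <- length(x)
  L <- length(sym10_dec_lo)
  k <- seq.int(0L, n / 2 - 1L)
  idx <- outer(2L * k, seq.int(0L, L - 1L), `+`) %% n + 1L
  xm <- matrix(x[idx], nrow = length(k))
  list(a = as.numeric(xm %*% sym10_dec_lo),
       d = as.numeric(xm %*% sym10_dec_hi))
}

# Inverse of dwt_step_per.
idwt_step_per <- function(a, d) {
  n <- 2L * length(a)
  L <- length(sym10_dec_lo)
  x <- numeric(n)
  k <- seq.int(0L, length(a) - 1L)
  for (m in seq.int(0L, L - 1L)) {
    idx <- (2L * k + m) %% n + 1L
    x[idx] <- x[idx] + sym10_dec_lo[m + 1L] * a + sym10_dec_hi[m + 1L] * d
  }
  x
}

# Multi-level circular DWT of a vector whose length is divisible by 2^level.
dwt_per <- function(x, level) {
  stopifnot(length(x) %% 2^level == 0)
  details <- vector("list", level)
  a <- x
  for (j in seq_len(level)) {
    st <- dwt_step_per(a)
    a <- st$a
    details[[j]] <- st$d
  }
  list(approx = a, details = details)
}

idwt_per <- function(decomp) {
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    a <- idwt_step_per(a, decomp$details[[j]])
  }
  a
}

# Reflection-pad x so that (a) the circular boundary lies in padding and
# (b) the padded length is a multiple of 2^level. Returns the padded vector
# and the index range of the original samples.
reflect_pad_pow2 <- function(x, level, min_pad = 256L) {
  n <- length(x)
  block <- 2L^level
  total <- n + 2L * min_pad
  total <- as.integer(ceiling(total / block) * block)
  extra <- total - n
  left <- extra %/% 2L
  right <- extra - left
  if (left >= n || right >= n) {
    # short signal: tile reflections
    refl <- c(rev(x), x, rev(x))
    while (length(refl) < total) refl <- c(rev(x), refl, rev(x))
    mid <- (length(refl) - n) %/% 2
    start <- mid - left + 1L
    padded <- refl[start:(start + total - 1L)]
    return(list(x = padded, first = left + 1L, last = left + n))
  }
  padded <- c(rev(x[seq_len(left)]), x, rev(x[(n - right + 1L):n]))
  list(x = padded, first = left + 1L, last = left + n)
}

# Remove the level-`level` approximation band from a vector: decompose,
# zero the approximation coefficients, reconstruct. With fs = 500 Hz and
# level 8 the removed band is 0 to fs/2^9 ~ 0.98 Hz.
dwt_remove_approx <- function(x, level = 8L) {
  if (length(x) < 2L * length(sym10_dec_lo)) {
    stop("signal shorter than one wavelet support")
  }
  pad <- reflect_pad_pow2(x, level)
  dec <- dwt_per(pad$x, level)
  dec$approx <- numeric(length(dec$approx))
  rec <- idwt_per(dec)
  rec[pad$first:pad$last]
}
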