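# Independent oracles used by the test-suite. Deliberately written from the
# textbook definitions (explicit DFT sums, brute-force enumeration) so they
# share no code path with the package implementations they check.

# Welch magnitude-squared coherence by explicit DFT matrix multiplication
# and hand-averaged segment spectra.
oracle_welch_coherence <- function(x, y, segment_len, overlap_fraction,
                                   window = c("hann", "boxcar")) {
  window <- match.arg(window)
  n <- length(x)
  step <- round(segment_len * (1 - overlap_fraction))
  starts <- seq(1, n - segment_len + 1, by = step)
  w <- if (window == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, segment_len - 1) / (segment_len - 1))
  else rep(1, segment_len)
  k <- 0:(segment_len - 1)
  E <- exp(-2i * pi * outer(k, k) / segment_len)  # DFT matrix
  Sxx <- Syy <- numeric(segment_len)
  Sxy <- complex(segment_len)
  for (s in starts) {
    xs <- x[s:(s + segment_len - 1)]
    ys <- y[s:(s + segment_len - 1)]
    X <- as.vector(E %*% ((xs - mean(xs)) * w))
    Y <- as.vector(E %*% ((ys - mean(ys)) * w))
    Sxx <- Sxx + Mod(X)^2
    Syy <- Syy + Mod(Y)^2
    Sxy <- Sxy + X * Conj(Y)
  }
  K <- length(starts)
  Sxx <- Sxx / K; Syy <- Syy / K; Sxy <- Sxy / K
  nf <- segment_len %/% 2 + 1
  list(freqs = (seq_len(nf) - 1) / segment_len,
       coherence = (Mod(Sxy)^2 / (Sxx * Syy))[seq_len(nf)])
}

# Benjamini-Hochberg from the definition: sort ascending, q_i = p_i * m / i,
# running minimum from the largest rank down, clip at 1, restore order.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  if (m > 1) for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Exact Spearman rho and two-sided permutation p by full enumeration
# (n! permutations; use only for n <= 6, no ties).
oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_of <- function(a, b) {
    1 - 6 * sum((a - b)^2) / (n * (n^2 - 1))
  }
  rho <- rho_of(rx, ry)
  s_obs <- sum((rx - ry)^2)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  s_all <- vapply(perms(seq_len(n)), function(p) sum((rx - ry[p])^2),
                  numeric(1))
  # two-sided: double the tail that s_obs falls into (S small <-> rho large)
  p1 <- if (s_obs > (n^3 - n) / 6) mean(s_all >= s_obs) else
    mean(s_all <= s_obs)
  list(rho = rho, p = min(1, 2 * p1))
}

# quick deterministic test signals
sine_at <- function(f, fs, n, phase = 0) sin(2 * pi * f * (0:(n - 1)) / fs +
                                               phase)

make_recording <- function(left, right, fs = 64, subject_id = "s1",
                           phase = "pre") {
  perfusion_recording((seq_along(left) - 1) / fs, left, right, fs,
                      subject_id = subject_id, phase = phase)
}
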