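# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force or by a separate code path from the package
# implementation.

# Plain one-IMF EMD sifting: envelopes via stats::spline (natural end
# conditions) through mirrored extrema, no spike handling. Independent of
# the package's envelope code.
oracle_emd_imf1 <- function(x, max_sift = 8, sd_stop = 0.2) {
  extrema <- function(v) {
    n <- length(v)
    d <- sign(diff(v))
    for (i in seq_along(d)) if (d[i] == 0 && i > 1) d[i] <- d[i - 1]
    idx <- which(d[-1] != d[-length(d)] & d[-length(d)] != 0) + 1L
    list(mx = idx[d[idx - 1] > 0], mn = idx[d[idx - 1] < 0])
  }
  env_through <- function(v, idx) {
    n <- length(v)
    ii <- c(2L - idx[2L], idx, 2L * n - idx[length(idx) - 1L])
    vv <- c(v[idx[2L]], v[idx], v[idx[length(idx) - 1L]])
    stats::spline(ii, vv, xout = seq_len(n), method = "natural")$y
  }
  h <- x
  for (it in seq_len(max_sift)) {
    ex <- extrema(h)
    if (length(ex$mx) < 2 || length(ex$mn) < 2) break
    m <- (env_through(h, ex$mx) + env_through(h, ex$mn)) / 2
    ratio <- sum(m^2) / max(sum(h^2), .Machine$double.eps)
    h <- h - m
    if (ratio < sd_stop) break
  }
  h
}

# Brute-force Youden threshold: same candidate set and tie rule as the
# contract states, evaluated by exhaustive loops.
oracle_youden <- function(scores, labels) {
  u <- sort(unique(scores))
  if (length(u) == 1) return(u)
  cand <- (u[-1] + u[-length(u)]) / 2
  best_j <- -Inf; best_th <- cand[1]
  for (th in cand) {
    tp <- 0; fn <- 0; tn <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (labels[i] == 1) {
        if (scores[i] >= th) tp <- tp + 1 else fn <- fn + 1
      } else {
        if (scores[i] < th) tn <- tn + 1 else fp <- fp + 1
      }
    }
    j <- tp / (tp + fn) + tn / (tn + fp) - 1
    if (j >= best_j - 1e-12) {  # later (larger) threshold wins ties
      if (j > best_j + 1e-12 || th > best_th) best_th <- th
      best_j <- max(best_j, j)
    }
  }
  best_th
}

# Brute-force AUC by pair counting (Mann-Whitney U), ties counted 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Independent exact supercover rasterisation: a cell is traversed when the
# segment's parameter interval clipped to the cell rectangle (Liang-Barsky
# style interval intersection) is non-degenerate.
oracle_loop_length <- function(px, py, n_cells = 4900) {
  side <- as.integer(sqrt(n_cells))
  x0 <- min(px); x1 <- max(px); y0 <- min(py); y1 <- max(py)
  dx <- (x1 - x0) / side; dy <- (y1 - y0) / side
  cx <- c(px, px[1]); cy <- c(py, py[1])
  clip1 <- function(a, v, lo, hi) {
    # t-interval with lo <= a + t v <= hi
    if (v == 0) {
      if (a < lo || a > hi) c(1, 0) else c(0, 1)
    } else {
      sort(c((lo - a) / v, (hi - a) / v))
    }
  }
  ids <- integer(0)
  for (s in seq_len(length(cx) - 1)) {
    ax <- cx[s]; ay <- cy[s]; vx <- cx[s + 1] - ax; vy <- cy[s + 1] - ay
    ixr <- pmin(pmax(floor((sort(c(ax, ax + vx)) - x0) / dx) + 1L, 1L), side)
    iyr <- pmin(pmax(floor((sort(c(ay, ay + vy)) - y0) / dy) + 1L, 1L), side)
    for (ix in ixr[1]:ixr[2]) for (iy in iyr[1]:iyr[2]) {
      tx <- clip1(ax, vx, x0 + (ix - 1) * dx, x0 + ix * dx)
      ty <- clip1(ay, vy, y0 + (iy - 1) * dy, y0 + iy * dy)
      t_lo <- max(tx[1], ty[1], 0)
      t_hi <- min(tx[2], ty[2], 1)
      if (t_hi > t_lo) ids <- c(ids, (iy - 1L) * side + ix)
    }
  }
  length(unique(ids))
}

# Principal angles between column spans of two matrices.
oracle_principal_angles <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(pmin(1, pmax(-1, s)))
}

# A small randomised beat spec for property-style loops.
random_beat_spec <- function(seed) {
  set.seed(seed)
  unit <- function(v) v / sqrt(sum(v^2))
  w <- default_waves()
  w$P$amplitude <- runif(1, 0.1, 0.3)
  w$P$width <- runif(1, 0.016, 0.026)
  w$P$direction <- unit(w$P$direction + rnorm(3, 0, 0.1))
  w$R$amplitude <- runif(1, 0.8, 1.5)
  w$T$amplitude <- runif(1, 0.3, 0.6)
  dipole_beat_spec(waves = w)
}
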