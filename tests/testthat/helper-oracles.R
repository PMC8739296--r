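# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and direct definitions, used to freeze expected values.

# Rolling-ball background: grayscale opening with ball structuring element,
# computed by explicit erosion/dilation loops (replicate boundary).
oracle_rolling_ball_residual <- function(px, radius) {
  nr <- nrow(px); nc <- ncol(px)
  offs <- list()
  for (dr in -radius:radius) for (dc in -radius:radius) {
    d2 <- dr^2 + dc^2
    if (d2 <= radius^2) offs[[length(offs) + 1]] <- c(dr, dc, sqrt(radius^2 - d2))
  }
  at <- function(m, r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  ero <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    v <- Inf
    for (o in offs) v <- min(v, at(px, r + o[1], c + o[2]) - o[3])
    ero[r, c] <- v
  }
  opened <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    v <- -Inf
    for (o in offs) v <- max(v, at(ero, r - o[1], c - o[2]) + o[3])
    opened[r, c] <- v
  }
  px - opened
}

# Laplacian of Gaussian by direct loop convolution (replicate boundary):
# Gaussian smoothing (truncation 3 sigma) then 4-neighbour Laplacian.
oracle_log <- function(px, sigma) {
  nr <- nrow(px); nc <- ncol(px)
  rad <- max(1, ceiling(3 * sigma))
  w <- exp(-(-rad:rad)^2 / (2 * sigma^2)); w <- w / sum(w)
  at <- function(m, r, c) m[min(max(r, 1), nr), min(max(c, 1), nc)]
  tmp <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    s <- 0
    for (k in -rad:rad) s <- s + w[k + rad + 1] * at(px, r + k, c)
    tmp[r, c] <- s
  }
  sm <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    s <- 0
    for (k in -rad:rad) s <- s + w[k + rad + 1] * at(tmp, r, c + k)
    sm[r, c] <- s
  }
  out <- matrix(0, nr, nc)
  for (r in 1:nr) for (c in 1:nc)
    out[r, c] <- at(sm, r - 1, c) + at(sm, r + 1, c) +
      at(sm, r, c - 1) + at(sm, r, c + 1) - 4 * sm[r, c]
  out
}

# Renyi-entropy threshold by exhaustive scan, written from the definition.
oracle_renyi_threshold <- function(px) {
  counts <- tabulate(as.integer(px) + 1L, nbins = 256)
  p <- counts / sum(counts)
  occupied <- which(p > 0)
  lo <- occupied[1]; hi <- occupied[length(occupied)]
  crit_argmax <- function(alpha) {
    best_t <- NA; best <- -Inf
    for (t in lo:(hi - 1)) {
      Pb <- sum(p[1:t]); Pf <- 1 - Pb
      if (Pb <= 0 || Pf <= 0) next
      hb <- 0; hf <- 0
      if (abs(alpha - 1) < 1e-12) {
        for (i in 1:t) if (p[i] > 0) hb <- hb - (p[i] / Pb) * log(p[i] / Pb)
        for (i in (t + 1):256) if (p[i] > 0) hf <- hf - (p[i] / Pf) * log(p[i] / Pf)
      } else {
        sb <- 0; sf <- 0
        for (i in 1:t) if (p[i] > 0) sb <- sb + (p[i] / Pb)^alpha
        for (i in (t + 1):256) if (p[i] > 0) sf <- sf + (p[i] / Pf)^alpha
        hb <- log(sb) / (1 - alpha); hf <- log(sf) / (1 - alpha)
      }
      if (hb + hf > best) { best <- hb + hf; best_t <- t }
    }
    best_t - 1L
  }
  ts <- sort(c(crit_argmax(0.5), crit_argmax(1), crit_argmax(2)))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    betas <- if (abs(t2 - t3) <= 5) c(1, 2, 1) else c(0, 1, 3)
  } else {
    betas <- if (abs(t2 - t3) <= 5) c(3, 1, 0) else c(1, 2, 1)
  }
  P1 <- cumsum(p)
  omega <- P1[t3 + 1] - P1[t1 + 1]
  round(t1 * (P1[t1 + 1] + 0.25 * omega * betas[1]) +
        0.25 * t2 * omega * betas[2] +
        t3 * (1 - P1[t3 + 1] + 0.25 * omega * betas[3]))
}

# Two-sided Mann-Whitney p by full enumeration, counting pairs directly
# (no ranks): U = #{a > b} + 0.5 #{a == b} over all group assignments.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  m <- length(a); N <- length(pooled)
  count_u <- function(x, y) {
    u <- 0
    for (xi in x) for (yi in y) u <- u + (xi > yi) + 0.5 * (xi == yi)
    u
  }
  u_obs <- count_u(a, b)
  combs <- utils::combn(N, m)
  us <- apply(combs, 2, function(idx) count_u(pooled[idx], pooled[-idx]))
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Draw a disk mask of radius r centred in an n x n frame.
disk_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}

# Small separable 4-class Raman cube used across tests.
make_test_cube <- function(noise_sd = 0.02, cosmic_ray_rate = 0, seed = 9,
                           baseline_coeffs = c(0.5, 1, -0.5, 0.2)) {
  layout <- matrix(1L, 20, 20)
  layout[5:10, 5:10] <- 2L
  layout[12:18, 12:18] <- 3L
  layout[3:6, 14:17] <- 4L
  mixing <- list(background = c(lipid = 0),
                 cytoplasm = c(protein = 1, lipid = 0.1),
                 lb = c(lipid = 1.2),
                 nucleus = c(dna = 1, protein = 0.4))
  out <- make_raman_cube(layout, mixing, baseline_coeffs = baseline_coeffs,
                         cosmic_ray_rate = cosmic_ray_rate,
                         noise_sd = noise_sd, seed = seed,
                         spike_amplitude = 50)
  out$layout <- layout
  out
}

# Adjusted Rand index (Hubert & Arabie) from the contingency table.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(as.vector(tab))
  si <- sum_comb(rowSums(tab)); sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}
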