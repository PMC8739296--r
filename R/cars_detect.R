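# Lipid-body identification in CARS images: the fixed operator chain
# rolling-ball background subtraction -> Laplacian of Gaussian -> FFT
# bandpass -> invert + 8-bit quantization -> global threshold -> particle
# filtering by area and circularity.

#' Rolling-ball background subtraction
#'
#' Estimates the background as the grayscale opening of the image with a
#' ball-shaped structuring element (height profile `sqrt(r^2 - d^2)`) and
#' subtracts it. A constant image maps to zero; peaks narrower than the ball
#' are retained almost fully.
#'
#' @param img an [intensity_image()] or matrix.
#' @param radius ball radius in pixels (default 3).
#' @return intensity_image of the background-subtracted result.
#' @export
subtract_background_rolling_ball <- function(img, radius = 3) {
  stopifnot(radius >= 1)
  px <- as_pixels(img)
  if (!all(is.finite(px))) stop("non-finite pixels")
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  d2 <- off$dr^2 + off$dc^2
  keep <- d2 <= radius^2
  off <- off[keep, ]; h <- sqrt(radius^2 - d2[keep])
  nr <- nrow(px); nc <- ncol(px)
  # shift with replicate padding so the border is treated as flat
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[ri, ci, drop = FALSE]
  }
  ero <- matrix(Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    ero <- pmin(ero, shift(px, off$dr[k], off$dc[k]) - h[k])
  dil <- matrix(-Inf, nr, nc)
  for (k in seq_len(nrow(off)))
    dil <- pmax(dil, shift(ero, -off$dr[k], -off$dc[k]) + h[k])
  with_pixels(img, px - dil)
}

# Separable Gaussian kernel (1D), truncated at 3 sigma, normalized.
gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

gaussian_smooth <- function(px, sigma) {
  k1 <- gaussian_kernel_1d(sigma)
  kern <- outer(k1, k1)
  EBImage::filter2(px, kern, boundary = "replicate")
}

#' Laplacian of Gaussian
#'
#' Gaussian smoothing at scale `smoothing_scale` followed by the discrete
#' 4-neighbour Laplacian. Linear: `LoG(a*img) = a*LoG(img)`. Bright compact
#' blobs give a negative peak at their centre.
#'
#' @inheritParams subtract_background_rolling_ball
#' @param smoothing_scale Gaussian sigma in pixels (default 1).
#' @export
laplacian_of_gaussian <- function(img, smoothing_scale = 1) {
  stopifnot(smoothing_scale > 0)
  px <- as_pixels(img)
  if (!all(is.finite(px))) stop("non-finite pixels")
  sm <- gaussian_smooth(px, smoothing_scale)
  lap <- matrix(0, 3, 3)
  lap[2, ] <- lap[, 2] <- 1; lap[2, 2] <- -4
  with_pixels(img, EBImage::filter2(sm, lap, boundary = "replicate"))
}

#' FFT bandpass filter
#'
#' Frequency-domain filter passing spatial periods between
#' `small_structures` and `large_structures` pixels, with Gaussian roll-offs
#' spanning 20% of each band edge. The DC component is (effectively)
#' removed, so a zero-mean input stays zero-mean.
#'
#' @inheritParams subtract_background_rolling_ball
#' @param small_structures lower band edge, in pixels of spatial period.
#' @param large_structures upper band edge, in pixels of spatial period.
#' @export
fft_bandpass <- function(img, small_structures = 2, large_structures = 20) {
  px <- as_pixels(img)
  nr <- nrow(px); nc <- ncol(px)
  if (!(small_structures > 0 && small_structures < large_structures &&
        large_structures < min(nr, nc)))
    stop("band edges out of range: need 0 < small < large < min(image dims)")
  f_lo <- 1 / large_structures   # cycles / px
  f_hi <- 1 / small_structures
  s_lo <- 0.2 * f_lo
  s_hi <- 0.2 * f_hi
  fr <- function(n) { f <- (seq_len(n) - 1) / n; ifelse(f > 0.5, f - 1, f) }
  fx <- matrix(fr(nr), nr, nc)
  fy <- matrix(fr(nc), nr, nc, byrow = TRUE)
  f <- sqrt(fx^2 + fy^2)
  hp <- ifelse(f >= f_lo, 1, exp(-(f - f_lo)^2 / (2 * s_lo^2)))
  lp <- ifelse(f <= f_hi, 1, exp(-(f - f_hi)^2 / (2 * s_hi^2)))
  out <- Re(fft(fft(px) * hp * lp, inverse = TRUE)) / (nr * nc)
  with_pixels(img, out)
}

#' Invert and quantize to 8-bit
#'
#' Linear min-max rescaling to 0..255 followed by inversion `v -> 255 - v`;
#' the output is integer-valued. Rescaling first makes a double application
#' of the inversion step an exact involution on the 8-bit result. A constant
#' image (zero range) maps to all zeros by convention.
#'
#' @inheritParams subtract_background_rolling_ball
#' @export
invert_and_quantize <- function(img) {
  px <- as_pixels(img)
  if (!all(is.finite(px))) stop("non-finite pixels")
  rng <- range(px)
  if (diff(rng) == 0) {
    message("invert_and_quantize: constant image, emitting all zeros")
    q <- matrix(0, nrow(px), ncol(px))
  } else {
    q <- 255 - round((px - rng[1]) / diff(rng) * 255)
  }
  with_pixels(img, q, bit_depth = "8bit")
}

# Renyi entropy of order alpha of the histogram slice p[lo..t] normalized by
# its mass. Used for background (0..t) and foreground (t+1..255) halves.
renyi_half_entropy <- function(p, P, alpha) {
  # p: prob per bin restricted to the half; P: total mass of the half
  if (P <= 0) return(0)
  q <- p[p > 0] / P
  if (alpha == 1) -sum(q * log(q)) else log(sum(q^alpha)) / (1 - alpha)
}

# argmax over t of H_bg(t) + H_fg(t) for the given order; t scanned over the
# occupied range. Ties broken toward the smallest t (which.max).
renyi_argmax <- function(counts, alpha) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  first <- which(p > 0)[1]; last <- max(which(p > 0))
  ts <- first:(last - 1)
  crit <- vapply(ts, function(t) {
    renyi_half_entropy(p[1:t], P1[t], alpha) +
      renyi_half_entropy(p[(t + 1):256], 1 - P1[t], alpha)
  }, numeric(1))
  ts[which.max(crit)] - 1L  # bin index -> gray level
}

#' Rényi-entropy automatic threshold
#'
#' Global threshold of an 8-bit image by the Sahoo-Wilkins-Yeager
#' Rényi-entropy criterion: thresholds maximizing the summed
#' background/foreground Rényi entropies of order 0.5, 1 and 2 are combined
#' with mass-dependent weights (the rule used by the classic
#' "RenyiEntropy" auto-threshold). Pixels strictly above the threshold are
#' foreground.
#'
#' @param img8 an 8-bit [intensity_image()] or integer matrix in 0..255.
#' @return list with `threshold` (gray level), `binary` (logical matrix),
#'   and `method = "renyi"`.
#' @export
threshold_renyi_entropy <- function(img8) {
  px <- as_pixels(img8)
  if (any(px < 0 | px > 255)) stop("expected 8-bit data in 0..255")
  counts <- tabulate(as.integer(px) + 1L, nbins = 256)
  if (sum(counts > 0) < 2)
    stop("cannot threshold a single-valued image")
  t_half <- renyi_argmax(counts, 0.5)
  t_one  <- renyi_argmax(counts, 1)
  t_two  <- renyi_argmax(counts, 2)
  thr <- combine_renyi_thresholds(t_half, t_one, t_two, counts)
  list(threshold = thr, binary = px > thr, method = "renyi")
}

# Sahoo-Wilkins-Yeager combination of the three order-specific thresholds.
combine_renyi_thresholds <- function(t_half, t_one, t_two, counts) {
  p <- counts / sum(counts)
  P1 <- cumsum(p)
  ts <- sort(c(t_half, t_one, t_two))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) beta <- c(1, 2, 1) else beta <- c(0, 1, 3)
  } else {
    if (abs(t2 - t3) <= 5) beta <- c(3, 1, 0) else beta <- c(1, 2, 1)
  }
  omega <- P1[t3 + 1] - P1[t1 + 1]
  round(t1 * (P1[t1 + 1] + 0.25 * omega * beta[1]) +
        0.25 * t2 * omega * beta[2] +
        t3 * (1 - P1[t3 + 1] + 0.25 * omega * beta[3]))
}

#' Relative-mean threshold
#'
#' Foreground = pixels strictly greater than `factor` times the mean
#' brightness of the image being thresholded.
#'
#' @inheritParams threshold_renyi_entropy
#' @param factor multiplier of the image mean (default 1.4).
#' @export
threshold_relative_mean <- function(img8, factor = 1.4) {
  stopifnot(factor > 0)
  px <- as_pixels(img8)
  thr <- factor * mean(px)
  list(threshold = thr, binary = px > thr, method = "relative_mean",
       factor = factor)
}

#' Particle filtering by area and circularity
#'
#' Labels 8-connected components of a binary image, measures area, Crofton
#' perimeter and circularity `4*pi*A/P^2` (clamped at 1), and retains
#' particles with circularity >= `min_circularity` and area within
#' `[min_area, max_area]` px^2. Defaults reproduce the diameter gate 2-20 px:
#' `(2 px)^2*pi/4` to `(20 px)^2*pi/4`.
#'
#' @param binary logical matrix of candidate pixels.
#' @param min_area,max_area retained area interval in px^2.
#' @param min_circularity minimum circularity.
#' @param intensity optional image whose per-particle mean is recorded.
#' @return A `spot_set`: list with `spots` data frame (x, y, area, perimeter,
#'   circularity, mean_intensity), `n`, `excluded` audit data frame and
#'   `params`.
#' @export
filter_particles <- function(binary, min_area = pi * 2^2 / 4,
                             max_area = pi * 20^2 / 4,
                             min_circularity = 0.5, intensity = NULL) {
  lab <- label_components(binary)
  feats <- shape_features(lab, intensity)
  keep <- feats$circularity >= min_circularity &
    feats$area >= min_area & feats$area <= max_area
  reason <- rep("none", nrow(feats))
  reason[feats$area < min_area] <- "small"
  reason[feats$area > max_area] <- "large"
  reason[feats$circularity < min_circularity & reason == "none"] <- "circularity"
  spots <- feats[keep, c("x", "y", "area", "perimeter", "circularity",
                         "mean_intensity")]
  rownames(spots) <- NULL
  structure(list(spots = spots, n = nrow(spots),
                 excluded = data.frame(label = feats$label[!keep],
                                       reason = reason[!keep]),
                 labels = lab * 0L + ifelse(lab %in% feats$label[keep], lab, 0L),
                 params = list(min_area = min_area, max_area = max_area,
                               min_circularity = min_circularity)),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("<spot_set> %d spots retained, %d excluded (gates: area [%.3g, %.3g] px^2, circ >= %.2g)\n",
              x$n, nrow(x$excluded), x$params$min_area, x$params$max_area,
              x$params$min_circularity))
  invisible(x)
}

#' Detect lipid bodies in a CARS image
#'
#' Runs the full fixed chain: rolling-ball background subtraction (radius 3),
#' Laplacian of Gaussian (scale 1), FFT bandpass (2-20 px), inversion +
#' 8-bit conversion, global thresholding (Rényi entropy or 1.4x relative
#' mean) and particle filtering. The returned `spot_set` carries the full
#' parameter provenance.
#'
#' @inheritParams subtract_background_rolling_ball
#' @param config list of parameters; see [cars_config()].
#' @export
detect_lipid_bodies <- function(img, config = cars_config()) {
  cfg <- utils::modifyList(cars_config(), config)
  x <- subtract_background_rolling_ball(img, cfg$ball_radius)
  x <- laplacian_of_gaussian(x, cfg$log_scale)
  x <- fft_bandpass(x, cfg$band_small, cfg$band_large)
  x8 <- invert_and_quantize(x)
  th <- switch(cfg$threshold,
    renyi = threshold_renyi_entropy(x8),
    relative_mean = threshold_relative_mean(x8, cfg$factor),
    stop("unknown threshold mode: ", cfg$threshold))
  ss <- filter_particles(th$binary, cfg$min_area, cfg$max_area,
                         cfg$min_circularity, intensity = as_pixels(img))
  ss$params <- c(ss$params, cfg[c("ball_radius", "log_scale", "band_small",
                                  "band_large", "threshold", "factor")],
                 list(threshold_value = th$threshold))
  ss
}

#' Default CARS detection parameters
#'
#' All defaults are the published macro values: ball radius 3 px, LoG scale
#' 1, bandpass 2-20 px, relative-mean factor 1.4, circularity gate 0.5, area
#' gates `(2 px)^2*pi/4` to `(20 px)^2*pi/4`.
#'
#' @param threshold `"renyi"` or `"relative_mean"`.
#' @param ... overrides for individual parameters.
#' @export
cars_config <- function(threshold = "renyi", ...) {
  cfg <- list(threshold = threshold, factor = 1.4, ball_radius = 3,
              log_scale = 1, band_small = 2, band_large = 20,
              min_area = pi * 2^2 / 4, max_area = pi * 20^2 / 4,
              min_circularity = 0.5)
  utils::modifyList(cfg, list(...))
}
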