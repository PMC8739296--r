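# Raman hyperspectral pipeline: cosmic-ray removal, iterative polynomial
# baseline correction, band integration maps, k-means class extraction with
# marker-based labelling, class mean spectra, the 1660/1440 cm^-1 lipid
# unsaturation ratio and its C=C calibration, group ANOVA and cytoplasm PCA.

#' Cosmic-ray spike removal
#'
#' A spectral sample is flagged as a spike when its deviation above the
#' running median of its `filter_size` window exceeds `dynamic_factor`
#' times the spectrum's robust scale (1.4826 x median absolute deviation of
#' the sample-minus-running-median residuals). Spikes are replaced by the
#' window median; all other samples are untouched. Cosmic rays are
#' positive-going, so only positive deviations are tested.
#'
#' @param x a [spectral_cube()] or a single numeric spectrum.
#' @param filter_size odd window length >= 3.
#' @param dynamic_factor spike threshold in robust-scale units.
#' @return Object of the same kind as `x`; for cubes, the spike report is
#'   attached as attribute `spike_report` (data frame pixel / channel).
#' @export
remove_cosmic_rays <- function(x, filter_size = 3, dynamic_factor = 8) {
  stopifnot(filter_size >= 3, filter_size %% 2 == 1)
  fix_one <- function(s) {
    med <- stats::runmed(s, filter_size, endrule = "median")
    dev <- s - med
    # robust scale: MAD of the median residuals, floored at 2% of the
    # spike-free peak-to-peak so that sharp chemical band tops (whose
    # residual is bounded by band curvature) are never mistaken for the
    # much larger cosmic-ray transients
    scale <- max(1.4826 * stats::median(abs(dev)),
                 0.02 * diff(range(med)), 1e-12)
    spike <- dev > dynamic_factor * scale
    s[spike] <- med[spike]
    list(s = s, spike = which(spike))
  }
  if (inherits(x, "spectral_cube")) {
    rep_px <- integer(0); rep_ch <- integer(0)
    out <- x$spectra
    for (i in seq_len(nrow(out))) {
      f <- fix_one(out[i, ])
      out[i, ] <- f$s
      if (length(f$spike) > 0) {
        rep_px <- c(rep_px, rep(i, length(f$spike)))
        rep_ch <- c(rep_ch, f$spike)
      }
    }
    res <- x; res$spectra <- out
    attr(res, "spike_report") <- data.frame(pixel = rep_px, channel = rep_ch)
    res
  } else {
    f <- fix_one(as.numeric(x))
    structure(f$s, spike_channels = f$spike)
  }
}

#' Iterative polynomial baseline correction
#'
#' Modified polyfit baseline: a degree-`degree` polynomial is fitted to the
#' spectrum, the spectrum is clipped to the fit from above, and the fit is
#' repeated until the baseline changes by less than `tol` (relative to the
#' signal range) or `max_iter` is reached. Peaks are thereby excluded from
#' the baseline while the smooth underlying curve is captured.
#'
#' @param spectrum numeric vector (length >= degree + 2).
#' @param wavenumber_axis matching axis (defaults to sample index).
#' @param degree polynomial degree (default 3).
#' @param max_iter,tol convergence controls: iteration stops when the
#'   maximum baseline change, relative to the signal range, drops below
#'   `tol`. The clipping iteration contracts slowly on noisy spectra (the
#'   per-step change decays roughly as a power of the iteration count), so
#'   the defaults trade a sub-noise tolerance for a bounded iteration
#'   budget.
#' @return corrected spectrum with attribute `baseline`.
#' @export
baseline_correct <- function(spectrum, wavenumber_axis = seq_along(spectrum),
                             degree = 3, max_iter = 200, tol = 5e-4) {
  y <- as.numeric(spectrum)
  n <- length(y)
  if (n < degree + 2) stop("need at least degree + 2 samples")
  x <- (wavenumber_axis - wavenumber_axis[1])
  x <- if (max(x) > 0) x / max(x) else x
  X <- stats::poly(x, degree = degree, raw = TRUE)
  work <- y
  fit_prev <- rep(Inf, n)
  scale <- max(diff(range(y)), 1e-12)
  converged <- FALSE
  last_change <- Inf
  for (it in seq_len(max_iter)) {
    fit <- stats::lm.fit(cbind(1, X), work)$fitted.values
    last_change <- max(abs(fit - fit_prev)) / scale
    if (last_change < tol) { converged <- TRUE; break }
    fit_prev <- fit
    work <- pmin(work, fit)
  }
  if (!converged)
    stop(sprintf("baseline correction did not converge in %d iterations (last relative change %.3g, tol %.3g)",
                 max_iter, last_change, tol))
  structure(y - fit, baseline = fit)
}

#' Baseline-correct every spectrum of a cube
#' @param cube a [spectral_cube()].
#' @inheritParams baseline_correct
#' @export
baseline_correct_cube <- function(cube, degree = 3, max_iter = 200, tol = 5e-4) {
  stopifnot(inherits(cube, "spectral_cube"))
  out <- cube
  for (i in seq_len(nrow(cube$spectra)))
    out$spectra[i, ] <- baseline_correct(cube$spectra[i, ],
                                         cube$wavenumber_axis, degree,
                                         max_iter, tol)
  out
}

#' Integrated band intensity
#'
#' Trapezoidal integral over a wavenumber window after subtracting the local
#' linear baseline through the window's endpoint intensities.
#'
#' @param spectrum numeric spectrum.
#' @param wavenumber_axis matching cm^-1 axis.
#' @param window c(lo, hi) cm^-1, inside the axis range.
#' @export
band_integrate <- function(spectrum, wavenumber_axis, window) {
  if (window[1] < min(wavenumber_axis) || window[2] > max(wavenumber_axis))
    stop("integration window outside the wavenumber axis")
  sel <- which(wavenumber_axis >= window[1] & wavenumber_axis <= window[2])
  if (length(sel) < 2) stop("integration window too narrow for the axis")
  x <- wavenumber_axis[sel]; y <- as.numeric(spectrum)[sel]
  base <- y[1] + (y[length(y)] - y[1]) * (x - x[1]) / (x[length(x)] - x[1])
  yy <- y - base
  sum(diff(x) * (yy[-1] + yy[-length(yy)]) / 2)
}

#' Band-integration image
#'
#' Applies [band_integrate()] to every pixel of a cube and reshapes to the
#' cube's spatial grid (the construction behind Raman distribution images of
#' organic matter 2800-3030, lipids 2830-2900 and nuclei 780-800 cm^-1).
#'
#' @inheritParams baseline_correct_cube
#' @inheritParams band_integrate
#' @export
integration_map <- function(cube, window) {
  stopifnot(inherits(cube, "spectral_cube"))
  vals <- apply(cube$spectra, 1, band_integrate,
                wavenumber_axis = cube$wavenumber_axis, window = window)
  intensity_image(matrix(vals, cube$dims[1], cube$dims[2]))
}

# k-means++ initial centres (Arthur & Vassilvitskii seeding).
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1)
  centers[1, ] <- x[i, ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    i <- sample.int(n, 1, prob = p)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# Vector normalization for clustering/PCA: each spectrum scaled to unit L2
# norm over the fingerprint region. Spectra with norms below `floor_frac`
# of the 98th-percentile norm (noise-only background pixels, whatever their
# share of the cube) are scaled by the floor instead, so they stay near the
# origin rather than being inflated to unit-length random directions.
normalize_spectra <- function(spectra, wavenumber_axis,
                              region = c(600, 1800), mode = "l2",
                              floor_frac = 0.1) {
  if (mode == "none") return(spectra)
  sel <- wavenumber_axis >= region[1] & wavenumber_axis <= region[2]
  nrm <- sqrt(rowSums(spectra[, sel, drop = FALSE]^2))
  fl <- floor_frac * stats::quantile(nrm, 0.98, names = FALSE)
  spectra / pmax(nrm, max(fl, 1e-12))
}

#' k-means segmentation of a spectral cube
#'
#' Clusters (optionally vector-normalized) spectra with Lloyd k-means under
#' k-means++ seeding, `restarts` restarts and a fixed seed (best total
#' within-cluster sum of squares retained), then auto-labels clusters by
#' marker-band scores on the cluster mean spectra: highest 2830-2900 cm^-1
#' integral -> LB, highest 780-800 -> nucleus, lowest total organic
#' 2800-3030 -> background, remainder -> cytoplasm. A cluster winning two
#' markers is reported as a labelling collision.
#'
#' @inheritParams baseline_correct_cube
#' @param k number of clusters (default 4: the three biological classes
#'   plus off-cell background).
#' @param seed integer seed.
#' @param restarts number of k-means++ restarts.
#' @param normalize `"l2"` (default) or `"none"`.
#' @return the cube with `labels`/`class_names` set (names from
#'   `c("background", "cytoplasm", "lb", "nucleus")`), plus attributes
#'   `cluster` (raw cluster ids) and `cluster_means`.
#' @export
kmeans_segment <- function(cube, k = 4, seed = 1, restarts = 10,
                           normalize = "l2") {
  stopifnot(inherits(cube, "spectral_cube"), k >= 2)
  x <- normalize_spectra(cube$spectra, cube$wavenumber_axis, mode = normalize)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      km <- stats::kmeans(x, centers = kmeanspp_init(x, k), iter.max = 100,
                          algorithm = "Lloyd")
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  cl <- best$cluster
  # marker scores on raw-intensity cluster means
  means <- t(vapply(seq_len(k), function(j)
    colMeans(cube$spectra[cl == j, , drop = FALSE]), numeric(ncol(cube$spectra))))
  score <- function(w) apply(means, 1, band_integrate,
                             wavenumber_axis = cube$wavenumber_axis, window = w)
  lb_win <- score(c(2830, 2900)); nuc_win <- score(c(780, 800))
  org_win <- score(c(2800, 3030))
  lb_cl <- which.max(lb_win); nuc_cl <- which.max(nuc_win)
  bg_cl <- which.min(org_win)
  winners <- c(lb = lb_cl, nucleus = nuc_cl, background = bg_cl)
  if (anyDuplicated(winners))
    stop("marker-label collision: one cluster wins two markers (",
         paste(names(winners), winners, sep = "=", collapse = ", "), ")")
  class_names <- c("background", "cytoplasm", "lb", "nucleus")
  map <- rep(2L, k)                 # default: cytoplasm
  map[bg_cl] <- 1L; map[lb_cl] <- 3L; map[nuc_cl] <- 4L
  out <- cube
  out$labels <- matrix(map[cl], cube$dims[1], cube$dims[2])
  out$class_names <- class_names
  attr(out, "cluster") <- cl
  attr(out, "cluster_means") <- means
  out
}

#' Per-class mean and SD spectra
#'
#' Pointwise mean and standard deviation over the member pixels of each
#' class of a labelled cube. Empty classes are omitted with a warning.
#'
#' @inheritParams baseline_correct_cube
#' @return named list per class: list(mean, sd, n).
#' @export
class_mean_spectra <- function(cube) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (is.null(cube$labels)) stop("cube has no class labels")
  lv <- sort(unique(as.vector(cube$labels)))
  nm <- if (!is.null(cube$class_names)) cube$class_names else
    as.character(seq_len(max(lv)))
  out <- list()
  for (l in lv) {
    sel <- as.vector(cube$labels) == l
    m <- cube$spectra[sel, , drop = FALSE]
    out[[nm[l]]] <- list(mean = colMeans(m),
                         sd = apply(m, 2, stats::sd),
                         n = nrow(m))
  }
  missing <- setdiff(nm, names(out))
  if (length(missing) > 0)
    warning("empty classes omitted: ", paste(missing, collapse = ", "))
  out
}

#' Lipid unsaturation ratio
#'
#' Integrated intensity of the 1660 cm^-1 C=C stretch over the 1440 cm^-1
#' CH2 scissoring band (default half-widths 20 and 25 cm^-1). Invariant to
#' overall intensity scaling.
#'
#' @inheritParams band_integrate
#' @param centers band centres (cm^-1).
#' @param half_widths integration half-widths (cm^-1).
#' @export
unsaturation_ratio <- function(spectrum, wavenumber_axis,
                               centers = c(1660, 1440),
                               half_widths = c(20, 25)) {
  num <- band_integrate(spectrum, wavenumber_axis,
                        centers[1] + c(-1, 1) * half_widths[1])
  den <- band_integrate(spectrum, wavenumber_axis,
                        centers[2] + c(-1, 1) * half_widths[2])
  if (abs(den) < 1e-12) stop("zero 1440 cm^-1 band integral")
  num / den
}

#' Fit the unsaturation calibration
#'
#' Least-squares line of the 1660/1440 integrated-intensity ratio against
#' the number of C=C bonds of reference fatty acids; the inverse map
#' [estimate_double_bonds()] converts a measured ratio to a C=C count.
#'
#' @param references output of [reference_fatty_acid_spectra()], or a named
#'   list of spectra with attributes as there.
#' @param ... passed to [unsaturation_ratio()].
#' @return An `unsaturation_calibration`: slope, intercept, reference points
#'   and R^2.
#' @export
fit_unsaturation_calibration <- function(references, ...) {
  counts <- attr(references, "counts")
  wn <- attr(references, "wavenumber_axis")
  if (length(counts) < 2 || length(unique(counts)) < 2)
    stop("need at least two references with distinct C=C counts")
  ratios <- vapply(references, unsaturation_ratio, numeric(1),
                   wavenumber_axis = wn, ...)
  fit <- stats::lm(ratios ~ counts)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) stop("calibration slope must be > 0")
  ss_tot <- sum((ratios - mean(ratios))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 points = data.frame(count = counts, ratio = unname(ratios)),
                 r_squared = r2),
            class = "unsaturation_calibration")
}

#' @export
print.unsaturation_calibration <- function(x, ...) {
  cat(sprintf("<unsaturation_calibration> ratio = %.4g + %.4g * C=C (R^2 = %.6f, %d refs)\n",
              x$intercept, x$slope, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' @rdname fit_unsaturation_calibration
#' @param calibration an `unsaturation_calibration`.
#' @param ratio measured 1660/1440 ratio(s).
#' @export
estimate_double_bonds <- function(calibration, ratio) {
  stopifnot(inherits(calibration, "unsaturation_calibration"))
  (ratio - calibration$intercept) / calibration$slope
}

#' One-way ANOVA of per-cell unsaturation ratios across groups
#'
#' F and p from a one-way ANOVA, plus per-pair two-sample t-tests of every
#' group against the control with significance stars (raw p-values, the
#' convention of the figure captions; choice recorded in the output).
#'
#' @param values numeric vector of per-cell ratios.
#' @param groups factor/character of group membership.
#' @param control name of the reference group.
#' @export
anova_groups <- function(values, groups, control = "control") {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with n >= 2 each")
  if (!control %in% names(tab)) stop("control group not present")
  fit <- stats::aov(values ~ factor(groups))
  s <- summary(fit)[[1]]
  others <- setdiff(names(tab), control)
  pw <- data.frame(group = others, p = NA_real_, stars = "",
                   stringsAsFactors = FALSE)
  for (i in seq_along(others)) {
    tt <- stats::t.test(values[groups == others[i]],
                        values[groups == control])
    pw$p[i] <- tt$p.value
    pw$stars[i] <- star_code(tt$p.value)
  }
  list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1], pairwise = pw,
       method = "one-way ANOVA + per-pair Welch t vs control, raw p")
}

#' Principal component analysis of cytoplasm spectra
#'
#' Mean-centred PCA of (vector-normalized) per-cell cytoplasm mean spectra
#' restricted to a fingerprint region. Loadings are sign-fixed so the
#' largest-magnitude element of each loading is positive.
#'
#' @param spectra cells x wavenumbers matrix (>= 3 rows).
#' @param wavenumber_axis matching axis.
#' @param region c(lo, hi) cm^-1 restriction (default 600-1800).
#' @param normalize `"l2"` or `"none"`.
#' @return list with `scores`, `loadings`, `explained_variance`,
#'   `wavenumber_axis` (restricted) and `normalize`.
#' @export
pca_cytoplasm <- function(spectra, wavenumber_axis, region = c(600, 1800),
                          normalize = "l2") {
  spectra <- as.matrix(spectra)
  if (nrow(spectra) < 3) stop("need at least 3 spectra")
  sel <- wavenumber_axis >= region[1] & wavenumber_axis <= region[2]
  x <- spectra[, sel, drop = FALSE]
  if (normalize == "l2") {
    nrm <- sqrt(rowSums(x^2))
    x <- x / pmax(nrm, 1e-12)
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, `*`)
  loadings <- sweep(pc$rotation, 2, flip, `*`)
  list(scores = scores, loadings = loadings,
       explained_variance = pc$sdev^2,
       wavenumber_axis = wavenumber_axis[sel], normalize = normalize)
}

# p-value star codes used in figure captions.
star_code <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}
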