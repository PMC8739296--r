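# Synthetic Raman spectra: component library (lipid, protein, DNA, EPO),
# fatty-acid reference spectra of known C=C count, and hyperspectral cube
# generation with polynomial baselines, cosmic-ray spikes and noise.

# Gaussian band with total area `area` centred at `center` (cm^-1).
gauss_band <- function(wn, center, width, area) {
  area / (width * sqrt(2 * pi)) * exp(-(wn - center)^2 / (2 * width^2))
}

#' Default wavenumber axis
#'
#' Ascending grid covering 600-3100 cm^-1 at 3 cm^-1 spacing (the spectral
#' resolution of typical confocal Raman measurements of cells).
#' @export
default_wavenumber_axis <- function() seq(600, 3102, by = 3)

#' Raman component spectra
#'
#' Noise-free nonnegative component spectra on a shared wavenumber axis:
#' \describe{
#'   \item{lipid}{acyl-chain bands at 2850 (CH2 stretch), 1744 (C=O ester),
#'     1660 (C=C stretch), 1440 (CH2 scissoring), 1304 (CH2 twist) and
#'     1269 cm^-1 (=CH deformation).}
#'   \item{protein}{phenylalanine 1003, CH deformation 1450, amide I 1657,
#'     CH stretch 2935 cm^-1.}
#'   \item{dna}{nucleobase/backbone bands at 785 (within the 780-800 cm^-1
#'     marker window), 1095, 1578 and 2953 cm^-1.}
#'   \item{epo}{eosinophil peroxidase resonance bands at 753, 1311, 1374,
#'     1554, 1564 and 1588 cm^-1.}
#' }
#'
#' @param wavenumber_axis ascending cm^-1 grid.
#' @return A `spectral_components` object: list with `wavenumber_axis`,
#'   `components` (named list of spectra) and `band_table`.
#' @export
spectral_components <- function(wavenumber_axis = default_wavenumber_axis()) {
  wn <- wavenumber_axis
  stopifnot(all(diff(wn) > 0))
  bt <- rbind(
    data.frame(component = "lipid",
               center = c(2850, 2880, 3008, 1744, 1660, 1440, 1304, 1269),
               width  = c(14, 12, 10, 8, 9, 10, 9, 8),
               area   = c(500, 180, 60, 70, 60, 100, 55, 35)),
    data.frame(component = "protein",
               center = c(1003, 1450, 1657, 2935),
               width  = c(5, 11, 12, 16),
               area   = c(40, 90, 110, 320)),
    data.frame(component = "dna",
               center = c(785, 1095, 1578, 2953),
               width  = c(7, 9, 9, 15),
               area   = c(80, 60, 55, 120)),
    data.frame(component = "epo",
               center = c(753, 1311, 1374, 1554, 1564, 1588),
               width  = c(6, 7, 7, 6, 6, 7),
               area   = c(70, 50, 60, 45, 40, 55)))
  comps <- lapply(split(bt, bt$component), function(b) {
    s <- rep(0, length(wn))
    for (i in seq_len(nrow(b)))
      s <- s + gauss_band(wn, b$center[i], b$width[i], b$area[i])
    s
  })
  structure(list(wavenumber_axis = wn,
                 components = comps[c("lipid", "protein", "dna", "epo")],
                 band_table = bt),
            class = "spectral_components")
}

#' Reference fatty-acid spectra of known unsaturation
#'
#' Noise-free spectra standing in for oleic (18:1), linoleic (18:2) and
#' alpha-linolenic (18:3) acid. By construction the integrated 1660 cm^-1
#' band area is proportional to the C=C count while the 1440 cm^-1 band is
#' identical across references, so the 1660/1440 integrated-intensity ratio
#' is exactly linear (through zero) in the number of double bonds.
#'
#' @param double_bond_counts subset of `c(1, 2, 3)`.
#' @param wavenumber_axis ascending cm^-1 grid.
#' @return named list (`"1"`, `"2"`, ...) of spectra plus attributes
#'   `wavenumber_axis` and `counts`.
#' @export
reference_fatty_acid_spectra <- function(double_bond_counts,
                                         wavenumber_axis = default_wavenumber_axis()) {
  if (!all(double_bond_counts %in% 1:3))
    stop("supported C=C counts are 1 (oleic), 2 (linoleic), 3 (alpha-linolenic)")
  wn <- wavenumber_axis
  base <- function(k) {
    gauss_band(wn, 2850, 14, 500) + gauss_band(wn, 2880, 12, 180) +
      gauss_band(wn, 3008, 10, 30 * k) +           # olefinic =C-H, scales with k
      gauss_band(wn, 1744, 8, 70) +
      gauss_band(wn, 1660, 9, 40 * k) +            # C=C stretch, scales with k
      gauss_band(wn, 1440, 10, 100) +              # CH2 scissoring, fixed
      gauss_band(wn, 1304, 9, 55) +
      gauss_band(wn, 1269, 8, 20 * k)              # =CH deformation, scales with k
  }
  out <- lapply(double_bond_counts, base)
  names(out) <- as.character(double_bond_counts)
  attr(out, "wavenumber_axis") <- wn
  attr(out, "counts") <- double_bond_counts
  out
}

#' Spectral cube
#'
#' Per-pixel Raman spectra on a shared strictly-monotonic wavenumber axis.
#' Rows of `spectra` are pixels in column-major order of the `dims` spatial
#' grid; `labels`, when present, is an integer matrix over the same grid
#' whose levels are named by `class_names`.
#'
#' @param spectra pixels x wavenumbers matrix.
#' @param wavenumber_axis cm^-1 axis (length = ncol(spectra)).
#' @param dims spatial c(rows, cols); prod(dims) = nrow(spectra).
#' @param labels optional integer matrix of per-pixel classes.
#' @param class_names optional character vector naming label values.
#' @export
spectral_cube <- function(spectra, wavenumber_axis, dims, labels = NULL,
                          class_names = NULL) {
  spectra <- as.matrix(spectra)
  stopifnot(all(diff(wavenumber_axis) > 0),
            length(wavenumber_axis) == ncol(spectra),
            prod(dims) == nrow(spectra))
  if (!is.null(labels)) {
    stopifnot(all(dim(labels) == dims), !anyNA(labels))
  }
  structure(list(spectra = unname(spectra),
                 wavenumber_axis = as.numeric(wavenumber_axis),
                 dims = as.integer(dims), labels = labels,
                 class_names = class_names),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %d x %d px, %d wavenumbers (%.0f-%.0f cm^-1)%s\n",
              x$dims[1], x$dims[2], length(x$wavenumber_axis),
              min(x$wavenumber_axis), max(x$wavenumber_axis),
              if (is.null(x$labels)) "" else ", labelled"))
  invisible(x)
}

#' Generate a synthetic Raman hyperspectral cube
#'
#' Each pixel's spectrum is a nonnegative mixture of component spectra for
#' its class, plus a polynomial baseline, optional cosmic-ray spikes and
#' Gaussian noise. Spike positions are recorded in the ground truth.
#'
#' @param layout integer matrix of per-pixel class ids (1-based into
#'   `names(mixing)`).
#' @param mixing named list: class name -> named nonnegative weight vector
#'   over the components of [spectral_components()]. A class named in
#'   `layout` but absent from `mixing` is an error.
#' @param baseline_coeffs polynomial coefficients (intercept first, degree
#'   <= 3) evaluated on the axis normalized to [0, 1].
#' @param cosmic_ray_rate per-spectrum spike probability.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed integer seed.
#' @param components a [spectral_components()] library.
#' @param spike_amplitude intensity of injected spikes.
#' @return list with `cube` (a [spectral_cube()] carrying the true labels)
#'   and `spikes` (data frame pixel / channel / amplitude).
#' @export
make_raman_cube <- function(layout, mixing, baseline_coeffs = c(0, 0, 0, 0),
                            cosmic_ray_rate = 0, noise_sd = 0, seed = 1,
                            components = spectral_components(),
                            spike_amplitude = 50) {
  layout <- as.matrix(layout)
  classes <- names(mixing)
  if (is.null(classes) || any(!(unique(as.vector(layout)) %in%
                                seq_along(classes))))
    stop("layout references a class id with no entry in mixing")
  if (length(baseline_coeffs) > 4) stop("baseline degree must be <= 3")
  wn <- components$wavenumber_axis
  if (min(wn) > 600 || max(wn) < 3100 - max(diff(wn)))
    stop("wavenumber axis must cover 600-3100 cm^-1")
  nwn <- length(wn)
  xn <- (wn - min(wn)) / (max(wn) - min(wn))
  baseline <- as.vector(outer(xn, seq_along(baseline_coeffs) - 1, `^`) %*%
                          baseline_coeffs)
  comp_mat <- do.call(cbind, components$components)  # nwn x 4
  class_spec <- sapply(classes, function(cl) {
    w <- mixing[[cl]]
    if (any(w < 0)) stop("mixing weights must be nonnegative")
    v <- rep(0, nwn)
    for (nm in names(w)) {
      if (!nm %in% colnames(comp_mat)) stop("unknown component: ", nm)
      v <- v + w[[nm]] * comp_mat[, nm]
    }
    v
  })
  with_seed(seed, {
    npx <- length(layout)
    spec <- t(class_spec[, as.vector(layout), drop = FALSE])
    spec <- spec + matrix(baseline, npx, nwn, byrow = TRUE)
    spikes <- data.frame(pixel = integer(0), channel = integer(0),
                         amplitude = numeric(0))
    if (cosmic_ray_rate > 0) {
      hit <- which(stats::runif(npx) < cosmic_ray_rate)
      if (length(hit) > 0) {
        ch <- sample.int(nwn, length(hit), replace = TRUE)
        spec[cbind(hit, ch)] <- spec[cbind(hit, ch)] + spike_amplitude
        spikes <- data.frame(pixel = hit, channel = ch,
                             amplitude = spike_amplitude)
      }
    }
    if (noise_sd > 0)
      spec <- spec + matrix(stats::rnorm(npx * nwn, 0, noise_sd), npx, nwn)
    cube <- spectral_cube(spec, wn, dim(layout), labels = layout,
                          class_names = classes)
    list(cube = cube, spikes = spikes)
  })
}
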