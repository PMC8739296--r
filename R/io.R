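# Readers/writers and the reproducible pipeline driver. Images travel as
# TIFF (8/16-bit, multi-page) with a JSON sidecar for pixel-size metadata;
# spectral cubes as either a documented binary format or a plain-text
# matrix (first row = wavenumber axis, then one row per pixel).

#' Read / write intensity images as TIFF
#'
#' 16-bit (default) or 8-bit TIFF, single or multi-page. Intensities are
#' stored as `round(pixels)` in integer counts; `pixel_size` is preserved
#' in a `<path>.json` sidecar (TIFF resolution tags are not relied upon).
#'
#' @param img an [intensity_image()] or a list of them (multi-page).
#' @param path file path.
#' @param bits 8 or 16.
#' @export
write_image <- function(img, path, bits = 16) {
  if (!bits %in% c(8, 16)) stop("unsupported bit depth: ", bits)
  imgs <- if (inherits(img, "intensity_image")) list(img) else img
  mx <- 2^bits - 1
  planes <- lapply(imgs, function(im) {
    px <- round(as_pixels(im))
    if (any(px < 0 | px > mx)) stop("pixel values out of ", bits, "-bit range")
    px / mx
  })
  tiff::writeTIFF(if (length(planes) == 1) planes[[1]] else planes,
                  path, bits.per.sample = bits, compression = "none")
  meta <- list(bits = bits,
               pixel_size = lapply(imgs, function(im)
                 if (is.null(im$pixel_size)) NA else im$pixel_size))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else
    list(bits = 16, pixel_size = NULL)
  mx <- 2^meta$bits - 1
  out <- lapply(seq_along(pages), function(i) {
    ps <- meta$pixel_size[[i]]
    if (is.null(ps) || is.na(ps)) ps <- NULL
    intensity_image(round(pages[[i]] * mx), pixel_size = ps)
  })
  if (length(out) == 1) out[[1]] else out
}

#' Read / write spectral cubes
#'
#' Two interchangeable on-disk forms:
#' \describe{
#'   \item{text}{plain matrix, whitespace-separated; a header comment
#'     `# dims <rows> <cols>`, then the wavenumber axis as the first data
#'     row and one row per pixel (column-major pixel order).}
#'   \item{binary}{magic `"EQCB"`, three int32 (rows, cols, n_wavenumbers),
#'     then the axis and the spectra matrix as little-endian doubles.}
#' }
#' Both round-trip losslessly within float tolerance.
#'
#' @param cube a [spectral_cube()].
#' @param path file path.
#' @param format `"text"` or `"binary"`.
#' @export
write_cube <- function(cube, path, format = c("text", "binary")) {
  stopifnot(inherits(cube, "spectral_cube"))
  format <- match.arg(format)
  if (format == "text") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# dims %d %d", cube$dims[1], cube$dims[2]), con)
    writeLines(paste(format(cube$wavenumber_axis, digits = 17),
                     collapse = " "), con)
    utils::write.table(format(cube$spectra, digits = 17), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar("EQCB", con, 4, eos = NULL)
    writeBin(as.integer(c(cube$dims, length(cube$wavenumber_axis))), con,
             size = 4, endian = "little")
    writeBin(as.numeric(cube$wavenumber_axis), con, size = 8,
             endian = "little")
    writeBin(as.numeric(cube$spectra), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path, format = c("text", "binary")) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format)
  if (format == "text") {
    lines <- readLines(path)
    if (length(lines) < 3 || !startsWith(lines[1], "# dims"))
      stop("malformed cube file: missing '# dims' header")
    dims <- as.integer(strsplit(trimws(sub("# dims", "", lines[1])),
                                "\\s+")[[1]])
    wn <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
    spec <- do.call(rbind, lapply(lines[-(1:2)], function(l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
    if (nrow(spec) != prod(dims) || any(vapply(seq_len(nrow(spec)),
        function(i) sum(!is.na(spec[i, ])), integer(1)) != length(wn)))
      stop("cube dimensions do not match the matrix")
    spectral_cube(spec, wn, dims)
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    magic <- readChar(con, 4, useBytes = TRUE)
    if (!identical(magic, "EQCB")) stop("not a binary cube file")
    hdr <- readBin(con, "integer", 3, size = 4, endian = "little")
    wn <- readBin(con, "numeric", hdr[3], size = 8, endian = "little")
    npx <- hdr[1] * hdr[2]
    spec <- readBin(con, "numeric", npx * hdr[3], size = 8,
                    endian = "little")
    if (length(wn) < hdr[3] || length(spec) < npx * hdr[3])
      stop("truncated cube file")
    spectral_cube(matrix(spec, npx, hdr[3]), wn, hdr[1:2])
  }
}

#' Default run configuration
#'
#' Every stage parameter at its published default: ball radius 3 px, LoG
#' scale 1, bandpass 2-20 px, relative-mean factor 1.4, circularity 0.5,
#' area gates `pi*2^2/4` to `pi*20^2/4` px^2, hole fill 500 px, minimum
#' cell 2500 px, contrast saturation 3.5%, spot gate 2 um^2, nucleus gate
#' 5 um^2, cosmic-ray filter size 3 / dynamic factor 8, baseline degree 3,
#' PCA region 600-1800 cm^-1. Round-trips losslessly through JSON.
#'
#' @param seed global seed fanned out per stage via named substreams.
#' @param ... overrides.
#' @export
default_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = seed,
    cars = list(threshold = "renyi", factor = 1.4, ball_radius = 3,
                log_scale = 1, band_small = 2, band_large = 20,
                min_area = pi * 2^2 / 4, max_area = pi * 20^2 / 4,
                min_circularity = 0.5),
    cells = list(saturation_fraction = 0.035, hole_max = 500,
                 min_cell_area = 2500, watershed_h = 2),
    fluor = list(nucleus_min_area_um2 = 5, spot_min_area_um2 = 2),
    raman = list(cosmic_filter_size = 3, cosmic_dynamic_factor = 8,
                 baseline_degree = 3, k = 4, restarts = 10,
                 ratio_centers = c(1660, 1440), ratio_half_widths = c(20, 25),
                 pca_region = c(600, 1800)))
  utils::modifyList(cfg, list(...))
}

#' Save / load a run configuration
#' @param config a [default_config()] list.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg
}

#' Run the CARS per-cell pipeline end to end
#'
#' Drives detection, cell segmentation and per-cell counting on a pair of
#' CARS/TPEF images (or on a synthetic demo scene when `simulate = TRUE`),
#' writing a per-cell CSV, a summary JSON and a log. Identical config +
#' seed give identical result bundles.
#'
#' @param config a [default_config()] list.
#' @param cars_path,tpef_path input TIFFs (ignored when `simulate`).
#' @param model a [train_pixel_classifier()] model, or NULL to train on the
#'   simulated scene's ground truth.
#' @param out_dir output directory.
#' @param simulate generate a synthetic demo scene instead of reading
#'   files.
#' @param n_cells cells in the simulated scene.
#' @return list with `per_cell`, `summary`, `paths`.
#' @export
run_pipeline <- function(config = default_config(), cars_path = NULL,
                         tpef_path = NULL, model = NULL, out_dir = tempdir(),
                         simulate = is.null(cars_path), n_cells = 9) {
  if (!simulate) {
    for (p in c(cars_path, tpef_path))
      if (!file.exists(p)) stop("pre-flight: missing input ", p)
    cars <- read_image(cars_path)
    tpef <- read_image(tpef_path)
    gt <- NULL
  } else {
    sc <- make_cars_tpef_scene(n_cells,
                               seed = substream_seed(config$seed, "scene"),
                               frame = c(384, 384))
    cars <- sc$cars; tpef <- sc$tpef; gt <- sc$ground_truth
  }
  rgb <- compose_rgb(cars, tpef, config$cells$saturation_fraction)
  if (is.null(model)) {
    if (is.null(gt)) stop("pre-flight: a trained model is required for file input")
    model <- train_pixel_classifier(
      list(list(rgb = rgb, mask = gt$cell_labels > 0)),
      seed = substream_seed(config$seed, "train"))
  }
  mask <- predict_cell_mask(rgb, model)
  cms <- clean_mask(mask, config$cells$hole_max, config$cells$min_cell_area,
                    config$cells$watershed_h)
  spots <- detect_lipid_bodies(cars, config$cars)
  pcc <- assign_spots_to_cells(cms, spots)
  summ <- list(n_cells = nrow(pcc$counts),
               total_spots = spots$n,
               orphan_spots = pcc$orphans,
               assigned_spots = sum(pcc$counts$lb_count),
               mean_lbs_per_cell = if (nrow(pcc$counts))
                 mean(pcc$counts$lb_count) else NA,
               seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(per_cell = file.path(out_dir, "per_cell.csv"),
                summary = file.path(out_dir, "summary.json"),
                log = file.path(out_dir, "run.log"))
  utils::write.csv(pcc$counts, paths$per_cell, row.names = FALSE)
  jsonlite::write_json(summ, paths$summary, auto_unbox = TRUE, digits = NA)
  writeLines(c(sprintf("eosiquant run, seed %s", config$seed),
               sprintf("stages: compose_rgb -> classify -> clean_mask -> detect_lipid_bodies(%s) -> assign",
                       config$cars$threshold),
               sprintf("cells retained %d / candidates %d", summ$n_cells,
                       nrow(cms$records)),
               sprintf("spots %d (assigned %d, orphaned %d)",
                       spots$n, summ$assigned_spots, summ$orphan_spots)),
             paths$log)
  list(per_cell = pcc, summary = summ, paths = paths,
       spot_set = spots, cell_masks = cms)
}
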