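# Fluorescence quantification: nucleus detection on the Hoechst channel,
# BODIPY lipid-body spot detection, per-image LBs/cell ratios, the
# multi-parametric morphology profile, and Mann-Whitney group comparison.

#' Find nuclei in a Hoechst image
#'
#' Gaussian smoothing, Otsu thresholding and distance-transform watershed
#' splitting, followed by the area gate: regions with area <= `min_area`
#' um^2 are discarded. The nucleus count is the cell count. Pixel-size
#' metadata is required because the gate is in um^2.
#'
#' @param hoechst an [intensity_image()] with `pixel_size` set.
#' @param min_area minimum nucleus area in um^2 (default 5).
#' @param smooth_sigma smoothing sigma in px.
#' @return A `region_set`: `labels` matrix, `regions` data frame (label, x,
#'   y, area_px, area_um2) and `params`.
#' @export
find_nuclei <- function(hoechst, min_area = 5, smooth_sigma = 2) {
  if (!inherits(hoechst, "intensity_image") || is.null(hoechst$pixel_size))
    stop("pixel size metadata (um/px) is required for the area gate")
  ps <- hoechst$pixel_size
  px <- hoechst$pixels
  rng <- range(px)
  nm <- if (diff(rng) > 0) (px - rng[1]) / diff(rng) else px * 0
  sm <- gaussian_smooth(nm, smooth_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > thr
  ws <- EBImage::watershed(EBImage::distmap(mask * 1), tolerance = 1, ext = 1)
  lab <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  region_gate(lab, ps, min_area, intensity = px,
              params = list(min_area_um2 = min_area,
                            smooth_sigma = smooth_sigma, otsu = thr))
}

#' Find lipid-body spots in a BODIPY image
#'
#' Local-contrast spot detection: white top-hat with a disc of radius
#' `tophat_radius`, threshold at `rel_height` of the top-hat maximum, then
#' the area gate: spots with area <= `min_area` um^2 are discarded.
#'
#' @param bodipy an [intensity_image()] with `pixel_size` set.
#' @param nuclei optional nucleus `region_set` (carried through for
#'   provenance; spots are detected on the whole frame).
#' @param min_area minimum spot area in um^2 (default 2).
#' @param tophat_radius structuring disc radius in px.
#' @param rel_height detection threshold as a fraction of the top-hat
#'   maximum.
#' @export
find_spots <- function(bodipy, nuclei = NULL, min_area = 2,
                       tophat_radius = 6, rel_height = 0.2) {
  if (!inherits(bodipy, "intensity_image") || is.null(bodipy$pixel_size))
    stop("pixel size metadata (um/px) is required for the area gate")
  ps <- bodipy$pixel_size
  px <- bodipy$pixels
  brush <- EBImage::makeBrush(2 * tophat_radius + 1, shape = "disc")
  th <- EBImage::whiteTopHat(px, brush)
  mx <- max(th)
  if (mx <= 0) {
    lab <- matrix(0L, nrow(px), ncol(px))
  } else {
    mask <- th > rel_height * mx
    lab <- label_components(mask)
  }
  region_gate(lab, ps, min_area, intensity = px,
              params = list(min_area_um2 = min_area,
                            tophat_radius = tophat_radius,
                            rel_height = rel_height))
}

# Apply the um^2 area gate to a label image and assemble a region_set.
region_gate <- function(lab, pixel_size, min_area_um2, intensity = NULL,
                        params = list()) {
  feats <- shape_features(lab, intensity)
  feats$area_um2 <- feats$area * pixel_size^2
  keep <- feats$area_um2 > min_area_um2
  kept <- feats[keep, ]
  newid <- integer(max(lab, 1L))
  newid[kept$label] <- seq_len(nrow(kept))
  out <- matrix(0L, nrow(lab), ncol(lab))
  out[lab > 0 & matrix(lab %in% kept$label, nrow(lab))] <-
    newid[lab[lab > 0 & matrix(lab %in% kept$label, nrow(lab))]]
  kept$label <- seq_len(nrow(kept))
  rownames(kept) <- NULL
  structure(list(labels = out, regions = kept, n = nrow(kept),
                 pixel_size = pixel_size, params = params),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions (area gate %g um^2)\n", x$n,
              x$params$min_area_um2))
  invisible(x)
}

#' Per-image LBs-per-cell ratio and group aggregation
#'
#' Computes spot count / nucleus count per image, and summarizes a group of
#' images as the mean of the image means with the SEM between images.
#' Images with zero nuclei are excluded and reported.
#'
#' @param spot_counts,nucleus_counts integer vectors, one entry per image.
#' @return list with `per_image`, `mean`, `sem`, `n_images`, `excluded`.
#' @export
lbs_per_cell_ratio <- function(spot_counts, nucleus_counts) {
  stopifnot(length(spot_counts) == length(nucleus_counts))
  bad <- nucleus_counts < 1
  if (any(bad))
    message(sum(bad), " image(s) with zero nuclei excluded from the ratio")
  sc <- spot_counts[!bad]; nc <- nucleus_counts[!bad]
  if (length(sc) == 0) stop("no image with at least one nucleus")
  ratios <- sc / nc
  list(per_image = data.frame(image = which(!bad), spots = sc, nuclei = nc,
                              ratio = ratios),
       mean = mean(ratios),
       sem = if (length(ratios) > 1) stats::sd(ratios) / sqrt(length(ratios))
             else NA_real_,
       n_images = length(ratios), excluded = which(bad))
}

# 180-degree rotational symmetry of a mask about its centroid:
# 1 - |mask XOR rot180(mask)| / (2 * area), computed on the bounding box
# around the centroid. 1 for point-symmetric shapes, lower otherwise.
mask_symmetry <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  ry <- round(2 * cy) - idx[, 1]
  rx <- round(2 * cx) - idx[, 2]
  ok <- ry >= 1 & ry <= nrow(mask) & rx >= 1 & rx <= ncol(mask)
  hits <- sum(ok & mask[cbind(pmax(ry, 1), pmax(rx, 1))])
  # |A xor rot(A)| = 2 * (|A| - |A intersect rot(A)|)
  1 - (nrow(idx) - hits) / nrow(idx)
}

# Compactness: area / convex hull area of the pixel centres (1 for convex
# shapes up to discretization; lower for ragged or concave shapes).
mask_compactness <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(1)
  h <- grDevices::chull(idx[, 2], idx[, 1])
  xs <- idx[h, 2]; ys <- idx[h, 1]
  a <- abs(sum(xs * c(ys[-1], ys[1]) - c(xs[-1], xs[1]) * ys)) / 2
  if (a <= 0) return(1)
  min(1, nrow(idx) / a)
}

#' Multi-parametric morphology profile
#'
#' Per-object features for a region set: area (um^2), roundness
#' (`4*pi*A/P^2`, Crofton perimeter, clamped at 1), 180-degree rotational
#' symmetry, compactness (area / convex-hull area), object mean intensity,
#' and local-background-corrected spot mean intensity. Group means +- SD
#' can be normalized to a designated reference profile (reference mean of
#' each parameter = 1).
#'
#' @param regions a `region_set`.
#' @param intensity the matching [intensity_image()].
#' @param group group tag.
#' @param reference optional `morphology_profile` whose per-parameter means
#'   become the unit.
#' @return A `morphology_profile`: `objects` data frame, `summary` (mean,
#'   sd, normalized mean per parameter), `group`.
#' @export
morphology_profile <- function(regions, intensity, group = "group",
                               reference = NULL) {
  stopifnot(inherits(regions, "region_set"))
  if (regions$n == 0) stop("empty region set")
  px <- as_pixels(intensity)
  lab <- regions$labels
  bgval <- stats::median(px[lab == 0])
  objs <- regions$regions
  sym <- cmp <- numeric(regions$n)
  for (i in seq_len(regions$n)) {
    m <- lab == i
    sym[i] <- mask_symmetry(m)
    cmp[i] <- mask_compactness(m)
  }
  objects <- data.frame(
    label = objs$label, area_um2 = objs$area_um2,
    roundness = objs$circularity, symmetry = sym, compactness = cmp,
    mean_intensity = objs$mean_intensity,
    spot_intensity = objs$mean_intensity - bgval, group = group)
  pars <- c("area_um2", "roundness", "symmetry", "compactness",
            "mean_intensity", "spot_intensity")
  summ <- data.frame(parameter = pars,
                     mean = vapply(pars, function(p) mean(objects[[p]]),
                                   numeric(1)),
                     sd = vapply(pars, function(p) stats::sd(objects[[p]]),
                                 numeric(1)))
  summ$sd[is.na(summ$sd)] <- 0
  if (!is.null(reference)) {
    ref <- reference$summary
    summ$norm_mean <- summ$mean / ref$mean[match(summ$parameter,
                                                 ref$parameter)]
    summ$norm_sd <- summ$sd / ref$mean[match(summ$parameter, ref$parameter)]
  } else {
    summ$norm_mean <- summ$mean / summ$mean
    summ$norm_sd <- summ$sd / summ$mean
  }
  rownames(summ) <- NULL
  structure(list(objects = objects, summary = summ, group = group),
            class = "morphology_profile")
}

#' Mann-Whitney comparison with exact tied-data p-values
#'
#' Mann-Whitney U with midranks for ties. For small samples
#' (`choose(m + n, n)` <= `exact_limit`) the two-sided p-value is exact:
#' the U distribution is enumerated over all assignments of the pooled
#' values to groups and p = min(1, 2 * min(P(U <= u), P(U >= u))). Larger
#' samples use the normal approximation with tie correction and continuity
#' correction. Stars: * p < 0.05, ** p < 0.01, *** p < 0.001.
#'
#' @param a,b numeric samples (each n >= 1).
#' @param exact_limit maximum number of enumerated assignments.
#' @return list with `U` (statistic of group `a`), `p`, `stars`, `method`.
#' @export
mann_whitney_compare <- function(a, b, exact_limit = 2e5) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (choose(m + n, m) <= exact_limit) {
    combs <- utils::combn(m + n, m)
    us <- colSums(matrix(r[combs], nrow = m)) - m * (m + 1) / 2
    p_le <- mean(us <= U + 1e-9)
    p_ge <- mean(us >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact enumeration"
  } else {
    mu <- m * n / 2
    ties <- table(pooled)
    sig2 <- m * n / 12 * ((m + n + 1) -
      sum(ties^3 - ties) / ((m + n) * (m + n - 1)))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U = U, p = p, stars = star_code(p), method = method)
}
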