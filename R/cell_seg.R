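# Whole-cell identification in CARS/TPEF composites: contrast-enhanced RGB
# composition, a trainable random-forest pixel classifier over a multi-scale
# filter bank, two-step mask cleaning (hole filling + distance-transform
# watershed + area/edge exclusion), replayable manual edits, and per-cell
# assignment of detected lipid bodies.

#' Compose a contrast-enhanced RGB image from CARS and TPEF channels
#'
#' Each channel is linearly rescaled so that `saturation_fraction` of its
#' pixels saturate (split between both tails), clipped to 0..255 and placed
#' in red (CARS) and green (TPEF); blue is zero.
#'
#' @param cars,tpef [intensity_image()]s or matrices of equal size.
#' @param saturation_fraction fraction of saturated pixels (default 0.035).
#' @return numeric array h x w x 3 with values in 0..255.
#' @export
compose_rgb <- function(cars, tpef, saturation_fraction = 0.035) {
  a <- as_pixels(cars); b <- as_pixels(tpef)
  if (!all(dim(a) == dim(b))) stop("channel dimension mismatch")
  rescale <- function(m) {
    q <- stats::quantile(m, c(saturation_fraction / 2,
                              1 - saturation_fraction / 2), names = FALSE)
    if (diff(q) == 0) return(matrix(128, nrow(m), ncol(m)))
    pmin(255, pmax(0, round((m - q[1]) / diff(q) * 255)))
  }
  out <- array(0, c(dim(a), 3))
  out[, , 1] <- rescale(a)
  out[, , 2] <- rescale(b)
  out
}

# Multi-scale filter bank over the red and green channels: per sigma in
# `sigmas`: Gaussian blur, gradient magnitude, Laplacian, and the two
# structure-tensor eigenvalues. Returns a pixels x features matrix and the
# feature names (logged in the trained model for provenance).
pixel_features <- function(rgb, sigmas = c(1, 2, 4, 8)) {
  stopifnot(length(dim(rgb)) == 3)
  chans <- list(R = rgb[, , 1], G = rgb[, , 2])
  lap <- matrix(0, 3, 3); lap[2, ] <- lap[, 2] <- 1; lap[2, 2] <- -4
  feats <- list(); nms <- character(0)
  for (cn in names(chans)) {
    ch <- chans[[cn]]
    for (s in sigmas) {
      sm <- gaussian_smooth(ch, s)
      gx <- (rbind(sm[-1, ], sm[nrow(sm), ]) - rbind(sm[1, ], sm[-nrow(sm), ])) / 2
      gy <- (cbind(sm[, -1], sm[, ncol(sm)]) - cbind(sm[, 1], sm[, -ncol(sm)])) / 2
      gm <- sqrt(gx^2 + gy^2)
      lp <- EBImage::filter2(sm, lap, boundary = "replicate")
      j11 <- gaussian_smooth(gx * gx, s)
      j12 <- gaussian_smooth(gx * gy, s)
      j22 <- gaussian_smooth(gy * gy, s)
      tr2 <- (j11 + j22) / 2
      dd <- sqrt(pmax(((j11 - j22) / 2)^2 + j12^2, 0))
      feats <- c(feats, list(sm, gm, lp, tr2 + dd, tr2 - dd))
      nms <- c(nms, paste0(cn, "_", c("gauss", "gradmag", "laplace",
                                      "steig1", "steig2"), "_s", s))
    }
  }
  out <- do.call(cbind, lapply(feats, as.vector))
  colnames(out) <- nms
  out
}

#' Train the pixel classifier
#'
#' Supervised per-pixel foreground/background model: a random forest over a
#' multi-scale filter bank (Gaussian blur, gradient magnitude, Laplacian,
#' structure-tensor eigenvalues at sigma 1, 2, 4, 8 on the red and green
#' channels). Training is seed-deterministic; a balanced subsample of
#' labelled pixels is used.
#'
#' @param labelled_examples list of `list(rgb = array, mask = logical
#'   matrix)` training images; every class must occur.
#' @param n_sample pixels sampled per class per image.
#' @param num_trees forest size.
#' @param seed integer seed.
#' @return A `pixel_classifier` (serializable list holding the forest and
#'   the feature definition).
#' @export
train_pixel_classifier <- function(labelled_examples, n_sample = 5000,
                                   num_trees = 50, seed = 1) {
  if (length(labelled_examples) < 1) stop("need at least one labelled image")
  xs <- list(); ys <- list()
  with_seed(seed, {
    for (ex in labelled_examples) {
      fb <- pixel_features(ex$rgb)
      y <- as.vector(ex$mask > 0)
      if (length(unique(y)) < 2)
        stop("training image must contain both classes")
      for (cls in c(TRUE, FALSE)) {
        idx <- which(y == cls)
        take <- sample(idx, min(n_sample, length(idx)))
        xs[[length(xs) + 1]] <- fb[take, , drop = FALSE]
        ys[[length(ys) + 1]] <- y[take]
      }
    }
  })
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = c(FALSE, TRUE))
  d <- data.frame(x, .y = y)
  rf <- ranger::ranger(.y ~ ., data = d, num.trees = num_trees,
                       probability = TRUE, seed = substream_seed(seed, "rf"),
                       num.threads = 1)
  structure(list(forest = rf, feature_names = colnames(x),
                 sigmas = c(1, 2, 4, 8), seed = seed,
                 num_trees = num_trees),
            class = "pixel_classifier")
}

#' Predict a cell mask
#'
#' Applies the trained classifier's filter bank to an RGB composite and
#' thresholds the per-pixel foreground probability at 0.5.
#'
#' @param rgb an array from [compose_rgb()].
#' @param model a [train_pixel_classifier()] model.
#' @return logical matrix.
#' @export
predict_cell_mask <- function(rgb, model) {
  stopifnot(inherits(model, "pixel_classifier"))
  fb <- pixel_features(rgb, model$sigmas)
  p <- stats::predict(model$forest, data.frame(fb), num.threads = 1)$predictions
  prob_fg <- p[, "TRUE"]
  matrix(prob_fg > 0.5, dim(rgb)[1], dim(rgb)[2])
}

# Fill background components of area < hole_max that do not touch the
# border ("holes" of the foreground).
fill_small_holes <- function(mask, hole_max) {
  bg <- EBImage::bwlabel(1 - (mask > 0))
  if (max(bg) == 0) return(mask > 0)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  areas <- tabulate(bg[bg > 0], nbins = max(bg))
  fill <- setdiff(which(areas < hole_max), border)
  out <- mask > 0
  out[bg %in% fill] <- TRUE
  out
}

#' Clean a predicted cell mask
#'
#' Two-step cleaning: holes smaller than `hole_max` px are filled, touching
#' cells are split by a watershed on the negated distance transform (with
#' h-maxima suppression via the watershed tolerance `h`), and components
#' smaller than `min_cell_area` px or touching the image edge are excluded
#' with an audit trail.
#'
#' @param mask logical matrix.
#' @param hole_max maximum hole area filled (default 500 px).
#' @param min_cell_area minimum retained cell area (default 2500 px).
#' @param h watershed tolerance (h-maxima suppression depth, default 2).
#' @return A `cell_mask_set`: `labels` (retained cells renumbered 1..K),
#'   `records` (per-candidate area / touches_edge / exclusion_reason) and
#'   `params`.
#' @export
clean_mask <- function(mask, hole_max = 500, min_cell_area = 2500, h = 2) {
  m <- as_pixels(mask) > 0
  filled <- fill_small_holes(m, hole_max)
  n_pre <- max(label_components(filled))
  dm <- EBImage::distmap(filled * 1)
  ws <- EBImage::watershed(dm, tolerance = h, ext = 1)
  ws <- matrix(as.integer(ws), nrow(ws), ncol(ws))
  n <- max(ws)
  if (n < n_pre)
    stop("watershed merged components (internal error)")
  records <- data.frame(candidate = seq_len(n),
                        area = tabulate(ws[ws > 0], nbins = n),
                        touches_edge = seq_len(n) %in% edge_labels(ws),
                        exclusion_reason = rep("none", n),
                        stringsAsFactors = FALSE)
  records$exclusion_reason[records$area < min_cell_area] <- "small"
  records$exclusion_reason[records$touches_edge] <- "edge"
  keep <- records$exclusion_reason == "none"
  newid <- integer(n); newid[records$candidate[keep]] <- seq_len(sum(keep))
  labels <- matrix(0L, nrow(ws), ncol(ws))
  labels[ws > 0] <- newid[ws[ws > 0]]
  records$label <- newid[records$candidate]
  cell_mask_set(labels, records,
                params = list(hole_max = hole_max,
                              min_cell_area = min_cell_area, h = h,
                              pre_watershed_components = n_pre))
}

#' Cell mask set
#'
#' Labelled cell regions after cleaning. Retained labels are contiguous
#' positive integers with area >= the gate and no edge contact; the records
#' table audits every removed candidate.
#'
#' @param labels integer label matrix.
#' @param records audit data frame.
#' @param params cleaning parameters (provenance).
#' @export
cell_mask_set <- function(labels, records, params = list()) {
  kept <- records$label[records$exclusion_reason == "none"]
  kept <- kept[!is.na(kept) & kept > 0]
  if (length(kept) > 0 && !identical(sort(kept), seq_along(kept)))
    stop("retained labels must be contiguous positive integers")
  structure(list(labels = labels, records = records, params = params),
            class = "cell_mask_set")
}

#' @export
print.cell_mask_set <- function(x, ...) {
  k <- sum(x$records$exclusion_reason == "none")
  cat(sprintf("<cell_mask_set> %d cells retained, %d excluded (%s)\n",
              k, nrow(x$records) - k,
              paste(names(table(x$records$exclusion_reason[x$records$exclusion_reason != "none"])),
                    collapse = "/")))
  invisible(x)
}

#' Replay a manual-edit script on a cell mask set
#'
#' Deterministic replay of add / remove / merge operations, standing in for
#' interactive correction of segmentation output. The audit trail is
#' extended with reason `"manual"` for removed labels; replaying the same
#' script twice is idempotent.
#'
#' @param cms a [cell_mask_set()].
#' @param edits list of edits: `list(op = "remove", label = i)`,
#'   `list(op = "merge", labels = c(i, j))` (result keeps the smaller
#'   label), or `list(op = "add", mask = logical matrix)`.
#' @export
apply_manual_edits <- function(cms, edits) {
  stopifnot(inherits(cms, "cell_mask_set"))
  labels <- cms$labels; records <- cms$records
  for (e in edits) {
    op <- e$op
    if (op == "remove") {
      if (!e$label %in% labels) stop("edit references absent label ", e$label)
      labels[labels == e$label] <- 0L
      records$exclusion_reason[which(records$label == e$label)] <- "manual"
      records$label[which(records$label == e$label)] <- NA_integer_
    } else if (op == "merge") {
      if (!all(e$labels %in% labels))
        stop("edit references absent label(s) ",
             paste(setdiff(e$labels, labels), collapse = ", "))
      tgt <- min(e$labels)
      for (l in setdiff(e$labels, tgt)) {
        labels[labels == l] <- tgt
        records$exclusion_reason[which(records$label == l)] <- "manual"
        records$label[which(records$label == l)] <- NA_integer_
      }
    } else if (op == "add") {
      newl <- max(labels, 0L) + 1L
      add <- as_pixels(e$mask) > 0
      labels[add & labels == 0L] <- newl
      records <- rbind(records,
        data.frame(candidate = max(records$candidate, 0L) + 1L,
                   area = sum(add), touches_edge = FALSE,
                   exclusion_reason = "none", label = newl))
    } else stop("unknown edit op: ", op)
  }
  # renumber retained labels contiguously, preserving order
  kept <- sort(unique(labels[labels > 0]))
  newid <- integer(max(labels, 1L)); newid[kept] <- seq_along(kept)
  labels[labels > 0] <- newid[labels[labels > 0]]
  records$label[!is.na(records$label) & records$label > 0] <-
    newid[records$label[!is.na(records$label) & records$label > 0]]
  cell_mask_set(labels, records, cms$params)
}

#' Assign detected spots to cells
#'
#' A spot belongs to the cell whose region contains its centroid; spots on
#' background are dropped into an orphan tally. Per-cell counts cover every
#' retained cell (zero included).
#'
#' @param cms a [cell_mask_set()].
#' @param spots a `spot_set` from [detect_lipid_bodies()] /
#'   [filter_particles()], detected on the same frame.
#' @param group optional group tag carried into the result.
#' @return A `per_cell_counts`: `counts` data frame (cell_label, lb_count),
#'   `orphans`, `group`.
#' @export
assign_spots_to_cells <- function(cms, spots, group = "custom") {
  stopifnot(inherits(cms, "cell_mask_set"), inherits(spots, "spot_set"))
  labels <- cms$labels
  n_cells <- max(labels)
  sp <- spots$spots
  if (nrow(sp) > 0) {
    ri <- pmin(pmax(round(sp$y), 1), nrow(labels))
    ci <- pmin(pmax(round(sp$x), 1), ncol(labels))
    if (any(round(sp$y) < 1 | round(sp$y) > nrow(labels) |
            round(sp$x) < 1 | round(sp$x) > ncol(labels)))
      stop("spot centroid outside the frame: geometry mismatch")
    owner <- labels[cbind(ri, ci)]
  } else owner <- integer(0)
  counts <- tabulate(owner[owner > 0], nbins = n_cells)
  structure(list(counts = data.frame(cell_label = seq_len(max(n_cells, 0)),
                                     lb_count = as.integer(counts)),
                 orphans = sum(owner == 0), group = group,
                 total_spots = nrow(sp)),
            class = "per_cell_counts")
}

#' @export
print.per_cell_counts <- function(x, ...) {
  cat(sprintf("<per_cell_counts> group %s: %d cells, mean %.3g LBs/cell, %d orphan spots\n",
              x$group, nrow(x$counts),
              if (nrow(x$counts)) mean(x$counts$lb_count) else 0, x$orphans))
  invisible(x)
}
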