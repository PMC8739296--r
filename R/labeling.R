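# Connected-component labeling and shape measurement shared by the particle
# analyzer (cars_lb), mask cleaning (cell_seg) and the fluorescence detectors.

#' Label connected components of a binary image
#'
#' 8-connected labeling (the convention of ImageJ-style particle analyzers),
#' built on [EBImage::bwlabel()] (4-connected) followed by a union-find merge
#' of labels that touch diagonally.
#'
#' @param mask logical or 0/1 numeric matrix.
#' @return integer matrix of labels, 0 = background, components numbered
#'   1..n in raster order of first occurrence.
#' @export
label_components <- function(mask) {
  m <- as_pixels(mask)
  m <- (m > 0) * 1
  lab <- EBImage::bwlabel(m)
  n <- max(lab)
  if (n <= 1L) return(matrix(as.integer(lab), nrow(lab), ncol(lab)))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nr <- nrow(lab); nc <- ncol(lab)
  # diagonal neighbour pairs: (r, c) vs (r+dr, c+dc) for dr = 1, dc = +-1
  for (dc in c(-1L, 1L)) {
    a <- lab[1:(nr - 1), if (dc == 1L) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr,       if (dc == 1L) 2:nc       else 1:(nc - 1)]
    sel <- which(a > 0 & b > 0 & a != b)
    for (i in sel) {
      ra <- find(a[i]); rb <- find(b[i])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # renumber compactly; roots carry the minimal original label of each set,
  # so ordering follows bwlabel's raster numbering and is deterministic
  uroots <- unique(roots)
  newid <- integer(n); newid[uroots] <- seq_along(uroots)
  out <- lab
  out[lab > 0] <- newid[roots[lab[lab > 0]]]
  matrix(as.integer(out), nr, nc)
}

# Crofton perimeter estimate per label.
# P = pi/8 * (nh + nv + (nd1 + nd2)/sqrt(2)), where n* count, per label,
# ordered adjacent pixel pairs along each of the 4 digital directions in which
# membership changes (image border counts as background).
crofton_perimeter <- function(lab) {
  n <- max(lab)
  if (n == 0L) return(numeric(0))
  nr <- nrow(lab); nc <- ncol(lab)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- lab
  count_dir <- function(dr, dc) {
    a <- pad[2:(nr + 1), 2:(nc + 1)]
    b <- pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
    sel <- a > 0 & a != b
    tabulate(a[sel], nbins = n)
  }
  nh <- count_dir(0L, 1L) + count_dir(0L, -1L)
  nv <- count_dir(1L, 0L) + count_dir(-1L, 0L)
  nd <- count_dir(1L, 1L) + count_dir(-1L, -1L) +
        count_dir(1L, -1L) + count_dir(-1L, 1L)
  pi / 8 * (nh + nv + nd / sqrt(2))
}

# Per-label area, centroid, perimeter, circularity and mean intensity.
# Circularity = 4*pi*A/P^2, clamped at 1 (discretization can push it above).
shape_features <- function(lab, intensity = NULL) {
  n <- max(lab)
  if (n == 0L)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                      area = numeric(0), perimeter = numeric(0),
                      circularity = numeric(0), mean_intensity = numeric(0)))
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- ((idx - 1L) %% nrow(lab)) + 1L
  cols <- ((idx - 1L) %/% nrow(lab)) + 1L
  area <- tabulate(l, nbins = n)
  cx <- vapply(split(cols, l), mean, numeric(1))
  cy <- vapply(split(rows, l), mean, numeric(1))
  per <- crofton_perimeter(lab)
  circ <- pmin(1, 4 * pi * area / per^2)
  mi <- if (is.null(intensity)) rep(NA_real_, n) else
    vapply(split(as_pixels(intensity)[idx], l), mean, numeric(1))
  data.frame(label = seq_len(n), x = unname(cx), y = unname(cy),
             area = as.numeric(area), perimeter = per,
             circularity = circ, mean_intensity = unname(mi))
}

# Labels touching the image border.
edge_labels <- function(lab) {
  border <- c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)])
  sort(unique(border[border > 0]))
}
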