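#' Single-channel intensity image
#'
#' Light-weight carrier for a 2D raster of real-valued intensities, the unit
#' all image operators in the package act on. Pixels are stored as a numeric
#' matrix indexed `[row = y, col = x]`; coordinates reported by detectors are
#' `(x = column, y = row)`.
#'
#' @param pixels numeric matrix of finite intensities.
#' @param pixel_size optional pixel size in micrometres per pixel.
#' @param bit_depth either `"native"` (arbitrary real scale) or `"8bit"`
#'   (integers in 0..255, as produced by [invert_and_quantize()]).
#' @return An object of class `intensity_image`.
#' @export
intensity_image <- function(pixels, pixel_size = NULL, bit_depth = "native") {
  pixels <- as.matrix(pixels)
  if (length(dim(pixels)) != 2L || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("pixels must be a non-empty 2D matrix")
  if (!all(is.finite(pixels)))
    stop("pixels must be finite")
  if (!is.null(pixel_size)) {
    stopifnot(is.numeric(pixel_size), length(pixel_size) == 1L, pixel_size > 0)
  }
  bit_depth <- match.arg(bit_depth, c("native", "8bit"))
  structure(list(pixels = unname(pixels), pixel_size = pixel_size,
                 bit_depth = bit_depth),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d px, %s%s, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              if (is.null(x$pixel_size)) "" else
                sprintf(", %.3g um/px", x$pixel_size),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

# Accept either an intensity_image or a bare matrix; return the matrix.
as_pixels <- function(img) {
  if (inherits(img, "intensity_image")) return(img$pixels)
  if (is.matrix(img)) return(img)
  stop("expected an intensity_image or a matrix")
}

# Rebuild an intensity_image with new pixels, keeping metadata.
with_pixels <- function(img, pixels, bit_depth = NULL) {
  ps <- if (inherits(img, "intensity_image")) img$pixel_size else NULL
  bd <- if (!is.null(bit_depth)) bit_depth
        else if (inherits(img, "intensity_image")) img$bit_depth else "native"
  intensity_image(pixels, pixel_size = ps, bit_depth = bd)
}

# Evaluate code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operators funnel through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage substream seed from a global seed and a stage name,
# keeping the result inside the 32-bit integer range.
substream_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + h) %% .Machine$integer.max)
}
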