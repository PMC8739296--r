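# Synthetic CARS/TPEF and fluorescence scene generation with exact ground
# truth. Scenes emulate the statistical structure the analysis assumes:
# non-overlapping round cells with textured cytoplasm, Gaussian lipid-body
# (LB) spots of known centre/radius/amplitude, nucleus blobs in the second
# channel, and additive Gaussian noise. All randomness flows from one seed.

#' Lipid-body count laws
#'
#' Pluggable per-cell LB count distributions: constant, Poisson, or
#' zero-inflated Poisson (a point mass at zero mixed with a Poisson,
#' mirroring the observation that the largest fraction of cells shows no LB
#' in the focal plane).
#'
#' @param n constant count.
#' @param mean Poisson mean (of the non-inflated component for `zip`).
#' @param pi0 extra zero-inflation probability.
#' @return A `count_law` object with fields `sample(n)` and `mean`.
#' @export
count_law_constant <- function(n) {
  stopifnot(n >= 0, n == round(n))
  structure(list(sample = function(k) rep(as.integer(n), k), mean = n,
                 name = sprintf("constant(%d)", as.integer(n))),
            class = "count_law")
}

#' @rdname count_law_constant
#' @export
count_law_poisson <- function(mean) {
  stopifnot(mean >= 0)
  structure(list(sample = function(k) stats::rpois(k, mean), mean = mean,
                 name = sprintf("poisson(%g)", mean)),
            class = "count_law")
}

#' @rdname count_law_constant
#' @export
count_law_zip <- function(mean, pi0) {
  stopifnot(mean >= 0, pi0 >= 0, pi0 < 1)
  structure(list(
    sample = function(k) ifelse(stats::runif(k) < pi0, 0L,
                                stats::rpois(k, mean)),
    mean = (1 - pi0) * mean,
    name = sprintf("zip(%g, pi0=%g)", mean, pi0)), class = "count_law")
}

# Non-overlapping cell centres on a jittered grid. Errors out explicitly if
# the frame cannot hold n_cells at the requested radius + margin.
place_cells <- function(n_cells, frame, cell_radius, margin) {
  spacing <- 2 * cell_radius + 2 * margin
  usable <- frame - 2 * (cell_radius + margin)
  per_row <- floor(usable / spacing) + 1
  if (n_cells > prod(per_row))
    stop(sprintf("infeasible packing: %d cells do not fit a %dx%d frame at radius %g",
                 n_cells, frame[1], frame[2], cell_radius))
  grid <- expand.grid(gy = seq_len(per_row[1]), gx = seq_len(per_row[2]))
  grid <- grid[seq_len(n_cells), , drop = FALSE]
  jit <- margin * 0.6
  data.frame(
    y = cell_radius + margin + (grid$gy - 1) * spacing +
      stats::runif(n_cells, -jit, jit),
    x = cell_radius + margin + (grid$gx - 1) * spacing +
      stats::runif(n_cells, -jit, jit))
}

# Dart-throwing placement of n_lb spot centres inside a disc of radius
# r_inner around (cx, cy), keeping pairwise distance >= sep(i, j). The
# separation is relaxed geometrically (never below touching) if a strict
# draw fails, so heavy counts still place; an error is raised only if even
# touching placement fails.
place_spots <- function(n_lb, cx, cy, r_inner, radii, extra_sep = 4) {
  if (n_lb == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  for (relax in c(1, 0.75, 0.5, 0.25, 0)) {
    xs <- ys <- numeric(0)
    ok <- TRUE
    for (i in seq_len(n_lb)) {
      placed <- FALSE
      for (try in 1:400) {
        a <- stats::runif(1, 0, 2 * pi)
        r <- r_inner * sqrt(stats::runif(1))
        x <- cx + r * cos(a); y <- cy + r * sin(a)
        if (i == 1 || all(sqrt((xs - x)^2 + (ys - y)^2) >=
                          radii[seq_len(i - 1)] + radii[i] + extra_sep * relax)) {
          xs <- c(xs, x); ys <- c(ys, y); placed <- TRUE; break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(data.frame(x = xs, y = ys))
  }
  stop(sprintf("could not place %d lipid bodies inside cell of radius %g",
               n_lb, r_inner))
}

# Render isotropic Gaussian spots (radius = 2*sigma) onto an image.
render_spots <- function(px, xs, ys, radii, amps) {
  nr <- nrow(px); nc <- ncol(px)
  for (i in seq_along(xs)) {
    s <- radii[i] / 2
    ext <- ceiling(4 * s)
    r0 <- max(1, round(ys[i]) - ext); r1 <- min(nr, round(ys[i]) + ext)
    c0 <- max(1, round(xs[i]) - ext); c1 <- min(nc, round(xs[i]) + ext)
    rr <- r0:r1; cc <- c0:c1
    g <- outer(exp(-(rr - ys[i])^2 / (2 * s^2)),
               exp(-(cc - xs[i])^2 / (2 * s^2)))
    px[rr, cc] <- px[rr, cc] + amps[i] * g
  }
  px
}

# Low-amplitude smoothed-noise texture restricted to a mask.
texture_field <- function(nr, nc, amplitude, sigma = 4) {
  raw <- matrix(stats::rnorm(nr * nc), nr, nc)
  sm <- gaussian_smooth(raw, sigma)
  amplitude * sm / stats::sd(sm)
}

#' Generate a synthetic CARS/TPEF scene
#'
#' Renders `n_cells` non-overlapping round cells. The CARS channel contains
#' cytoplasm texture plus Gaussian LB spots (radius defined as 2 sigma, so a
#' thresholded spot covers roughly `pi * r^2` px) plus additive Gaussian
#' noise; the TPEF channel contains nucleus blobs. Ground truth (cell
#' regions, LB records, per-cell counts) is exact and seed-reproducible.
#'
#' @param n_cells number of cells (>= 0).
#' @param lb_count_law a count law from [count_law_poisson()] and friends.
#' @param lb_radius_range LB radius interval in px (within [1, 10]).
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed integer seed; identical seeds give identical scenes.
#' @param frame c(rows, cols) image size.
#' @param cell_radius cell radius in px (cells must exceed the 2500 px area
#'   gate to survive mask cleaning; the default 34 px gives ~3630 px^2).
#' @param lb_amplitude peak LB intensity above cytoplasm.
#' @param cytoplasm_level,cytoplasm_texture cytoplasm base level and texture
#'   amplitude in the CARS channel.
#' @return list with `cars`, `tpef` ([intensity_image()]s) and
#'   `ground_truth` (a `scene_ground_truth`).
#' @export
make_cars_tpef_scene <- function(n_cells, lb_count_law = count_law_poisson(2),
                                 lb_radius_range = c(3, 6), noise_sd = 60,
                                 seed = 1, frame = c(512, 512),
                                 cell_radius = 34, lb_amplitude = 6000,
                                 cytoplasm_level = 1500,
                                 cytoplasm_texture = 250) {
  stopifnot(n_cells >= 0, length(lb_radius_range) == 2,
            lb_radius_range[1] >= 1, lb_radius_range[2] <= 10,
            inherits(lb_count_law, "count_law"))
  with_seed(seed, {
    nr <- frame[1]; nc <- frame[2]
    cars <- matrix(0, nr, nc); tpef <- matrix(0, nr, nc)
    cell_lab <- matrix(0L, nr, nc)
    lb_records <- data.frame(cell_label = integer(0), x = numeric(0),
                             y = numeric(0), radius = numeric(0),
                             amplitude = numeric(0))
    if (n_cells > 0) {
      centers <- place_cells(n_cells, frame, cell_radius, margin = 10)
      tex <- texture_field(nr, nc, cytoplasm_texture)
      counts <- lb_count_law$sample(n_cells)
      ns <- 0.4 * cell_radius                 # nucleus sigma in TPEF
      win <- ceiling(max(cell_radius, 3 * ns)) + 1L
      for (i in seq_len(n_cells)) {
        rr <- max(1, round(centers$y[i]) - win):min(nr, round(centers$y[i]) + win)
        cc <- max(1, round(centers$x[i]) - win):min(nc, round(centers$x[i]) + win)
        d2 <- outer((rr - centers$y[i])^2, (cc - centers$x[i])^2, `+`)
        inside <- d2 <= cell_radius^2
        cell_lab[rr, cc][inside] <- i
        cars[rr, cc][inside] <- cytoplasm_level + tex[rr, cc][inside]
        # nucleus blob in TPEF: Gaussian, sigma = 40% of cell radius
        tpef[rr, cc] <- tpef[rr, cc] + 3000 * exp(-d2 / (2 * ns^2))
        if (counts[i] > 0) {
          radii <- stats::runif(counts[i], lb_radius_range[1],
                                lb_radius_range[2])
          pos <- place_spots(counts[i], centers$x[i], centers$y[i],
                             cell_radius - lb_radius_range[2] - 2, radii)
          amps <- lb_amplitude * stats::runif(counts[i], 0.8, 1.2)
          cars <- render_spots(cars, pos$x, pos$y, radii, amps)
          lb_records <- rbind(lb_records,
            data.frame(cell_label = i, x = pos$x, y = pos$y,
                       radius = radii, amplitude = amps))
        }
      }
      cars <- cars + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      tpef <- tpef + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
      cars <- pmax(cars, 0); tpef <- pmax(tpef, 0)
    }
    gt <- scene_ground_truth(cell_lab, lb_records, n_cells)
    list(cars = intensity_image(cars), tpef = intensity_image(tpef),
         ground_truth = gt)
  })
}

#' Generate a synthetic two-channel fluorescence scene
#'
#' Channel 1 emulates a Hoechst nuclear stain (one round nucleus per cell,
#' diameter ~10 um so the 5 um^2 nucleus gate passes), channel 2 a BODIPY
#' lipid stain (Gaussian LB spots with thresholded areas above the 2 um^2
#' spot gate). Ground truth is exact and seed-reproducible.
#'
#' @inheritParams make_cars_tpef_scene
#' @param pixel_size um per px (> 0); stored in both channels' metadata.
#' @param nucleus_diameter_um nucleus diameter in um.
#' @param spot_radius_range_px LB spot radius (2 sigma) interval in px.
#' @return list with `hoechst`, `bodipy` and `ground_truth`.
#' @export
make_fluorescence_scene <- function(n_cells,
                                    lb_count_law = count_law_poisson(2.35),
                                    pixel_size = 0.65, seed = 1,
                                    frame = c(400, 400),
                                    nucleus_diameter_um = 10,
                                    spot_radius_range_px = c(2.4, 3.2),
                                    noise_sd = 0.01) {
  stopifnot(pixel_size > 0, n_cells >= 0,
            inherits(lb_count_law, "count_law"))
  with_seed(seed, {
    nr <- frame[1]; nc <- frame[2]
    hoechst <- matrix(0, nr, nc); bodipy <- matrix(0, nr, nc)
    cell_lab <- matrix(0L, nr, nc)
    lb_records <- data.frame(cell_label = integer(0), x = numeric(0),
                             y = numeric(0), radius = numeric(0),
                             amplitude = numeric(0))
    nuc_r <- nucleus_diameter_um / 2 / pixel_size        # px
    cell_r <- 2.0 * nuc_r                                 # cytoplasm extent
    if (n_cells > 0) {
      centers <- place_cells(n_cells, frame, cell_r, margin = 4)
      counts <- lb_count_law$sample(n_cells)
      win <- ceiling(cell_r) + 2L
      for (i in seq_len(n_cells)) {
        rr <- max(1, round(centers$y[i]) - win):min(nr, round(centers$y[i]) + win)
        cc <- max(1, round(centers$x[i]) - win):min(nc, round(centers$x[i]) + win)
        d2 <- outer((rr - centers$y[i])^2, (cc - centers$x[i])^2, `+`)
        inside <- d2 <= cell_r^2
        cell_lab[rr, cc][inside] <- i
        # nucleus: smooth-edged disc (supergaussian) of radius nuc_r
        hoechst[rr, cc] <- hoechst[rr, cc] + 0.8 * exp(-(d2 / nuc_r^2)^3)
        if (counts[i] > 0) {
          radii <- stats::runif(counts[i], spot_radius_range_px[1],
                                spot_radius_range_px[2])
          pos <- place_spots(counts[i], centers$x[i], centers$y[i],
                             cell_r - spot_radius_range_px[2] / 2 - 1, radii,
                             extra_sep = 3)
          amps <- stats::runif(counts[i], 0.6, 1.0)
          bodipy <- render_spots(bodipy, pos$x, pos$y, radii, amps)
          lb_records <- rbind(lb_records,
            data.frame(cell_label = i, x = pos$x, y = pos$y,
                       radius = radii, amplitude = amps))
        }
      }
      hoechst <- pmin(hoechst + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 1)
      bodipy <- pmin(bodipy + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc), 1)
      hoechst <- pmax(hoechst, 0); bodipy <- pmax(bodipy, 0)
    }
    gt <- scene_ground_truth(cell_lab, lb_records, n_cells)
    list(hoechst = intensity_image(hoechst, pixel_size = pixel_size),
         bodipy = intensity_image(bodipy, pixel_size = pixel_size),
         ground_truth = gt)
  })
}

#' Scene ground truth
#'
#' Exact record of a generated scene: the cell label image, one row per LB
#' (owning cell, centre, radius, amplitude) and the per-cell count tally.
#' Invariants (every LB's cell exists; tallies match; centres lie inside
#' their cell) are enforced at construction.
#'
#' @param cell_labels integer label matrix (0 = background).
#' @param lb_records data frame with columns cell_label, x, y, radius,
#'   amplitude.
#' @param n_cells declared number of cells.
#' @export
scene_ground_truth <- function(cell_labels, lb_records, n_cells) {
  per_cell <- integer(n_cells)
  if (nrow(lb_records) > 0) {
    if (!all(lb_records$cell_label %in% seq_len(n_cells)))
      stop("lb_record references unknown cell label")
    tal <- table(factor(lb_records$cell_label, levels = seq_len(n_cells)))
    per_cell <- as.integer(tal)
    own <- cell_labels[cbind(round(lb_records$y), round(lb_records$x))]
    if (!all(own == lb_records$cell_label))
      stop("lipid-body centre outside its cell region")
  }
  structure(list(cell_labels = cell_labels, lb_records = lb_records,
                 per_cell_lb_count = per_cell, n_cells = n_cells),
            class = "scene_ground_truth")
}

#' @export
print.scene_ground_truth <- function(x, ...) {
  cat(sprintf("<scene_ground_truth> %d cells, %d lipid bodies (mean %.3g / cell)\n",
              x$n_cells, nrow(x$lb_records),
              if (x$n_cells > 0) mean(x$per_cell_lb_count) else 0))
  invisible(x)
}
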