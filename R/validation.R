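# Parameter-recovery experiments: generate synthetic data whose ground-truth
# group mean is known, run the corresponding quantification pipeline end to
# end, and report the estimated against the generating mean. These drivers
# are the package's self-validation surface: detection and counting are
# considered faithful when the recovered group means land within sampling
# error of the generator's law.

#' CARS per-cell parameter recovery
#'
#' Generates CARS/TPEF frames with per-cell LB counts drawn from a Poisson
#' law of mean `true_mean` (high SNR, isolated in-gate LBs), trains the
#' pixel classifier on a dedicated training frame, then runs the full
#' chain: [compose_rgb()] -> [predict_cell_mask()] -> [clean_mask()] ->
#' [detect_lipid_bodies()] -> [assign_spots_to_cells()], pooling per-cell
#' counts over frames.
#'
#' @param true_mean generating Poisson mean (LBs/cell).
#' @param n_cells total cells to generate (>= 150 for a recovery study).
#' @param threshold `"renyi"` or `"relative_mean"`.
#' @param seed integer seed (fanned out per frame).
#' @param cells_per_frame cells per 512x512 frame.
#' @return list with `estimate` (mean LBs/cell over retained cells),
#'   `true_mean`, `truth_sample_mean` and `truth_sem` (mean and SEM of the
#'   generated ground-truth counts), `n_cells_retained`, `n_cells_generated`,
#'   `per_cell`, `orphans`.
#' @export
simulate_cars_recovery <- function(true_mean, n_cells = 150,
                                   threshold = "renyi", seed = 1,
                                   cells_per_frame = 25) {
  n_frames <- ceiling(n_cells / cells_per_frame)
  train <- make_cars_tpef_scene(9, count_law_poisson(true_mean),
                                seed = substream_seed(seed, "train-scene"),
                                frame = c(384, 384))
  model <- train_pixel_classifier(
    list(list(rgb = compose_rgb(train$cars, train$tpef),
              mask = train$ground_truth$cell_labels > 0)),
    seed = substream_seed(seed, "train"))
  cfg <- cars_config(threshold = threshold)
  all_counts <- integer(0)
  truth_counts <- integer(0)
  orphans <- 0L
  for (f in seq_len(n_frames)) {
    nf <- min(cells_per_frame, n_cells - (f - 1) * cells_per_frame)
    sc <- make_cars_tpef_scene(nf, count_law_poisson(true_mean),
                               seed = substream_seed(seed, paste0("frame", f)),
                               frame = c(512, 512), cell_radius = 34)
    truth_counts <- c(truth_counts, sc$ground_truth$per_cell_lb_count)
    rgb <- compose_rgb(sc$cars, sc$tpef)
    cms <- clean_mask(predict_cell_mask(rgb, model))
    spots <- detect_lipid_bodies(sc$cars, cfg)
    pcc <- assign_spots_to_cells(cms, spots)
    all_counts <- c(all_counts, pcc$counts$lb_count)
    orphans <- orphans + pcc$orphans
  }
  list(estimate = mean(all_counts), true_mean = true_mean,
       truth_sample_mean = mean(truth_counts),
       truth_sem = stats::sd(truth_counts) / sqrt(length(truth_counts)),
       n_cells_retained = length(all_counts),
       n_cells_generated = length(truth_counts),
       per_cell = all_counts, orphans = orphans, threshold = threshold)
}

#' Fluorescence parameter recovery
#'
#' Generates `n_images` two-channel fluorescence images with per-cell LB
#' counts from a Poisson law of mean `true_mean`, runs [find_nuclei()]
#' (area gate 5 um^2) and [find_spots()] (area gate 2 um^2) per image and
#' aggregates with [lbs_per_cell_ratio()] (mean of image means, SEM between
#' images).
#'
#' @param true_mean generating Poisson mean (LBs/cell).
#' @param n_images number of images.
#' @param cells_per_image cells per image.
#' @param pixel_size um/px.
#' @param seed integer seed.
#' @return list with `estimate` (mean of image means), `between_image_sem`,
#'   `true_mean`, `truth_sample_mean`, `per_image`, `n_cells`.
#' @export
simulate_fluor_recovery <- function(true_mean, n_images = 4,
                                    cells_per_image = 75, pixel_size = 0.65,
                                    seed = 1) {
  spot_counts <- nucleus_counts <- integer(n_images)
  truth_counts <- integer(0)
  for (i in seq_len(n_images)) {
    sc <- make_fluorescence_scene(cells_per_image,
                                  count_law_poisson(true_mean),
                                  pixel_size = pixel_size,
                                  seed = substream_seed(seed, paste0("img", i)),
                                  frame = c(400, 400))
    truth_counts <- c(truth_counts, sc$ground_truth$per_cell_lb_count)
    nucleus_counts[i] <- find_nuclei(sc$hoechst)$n
    spot_counts[i] <- find_spots(sc$bodipy)$n
  }
  agg <- lbs_per_cell_ratio(spot_counts, nucleus_counts)
  list(estimate = agg$mean, between_image_sem = agg$sem,
       true_mean = true_mean, truth_sample_mean = mean(truth_counts),
       per_image = agg$per_image, n_cells = length(truth_counts))
}

#' Lipid-unsaturation parameter recovery
#'
#' Fits the 1660/1440 calibration on noise-free references (1, 2, 3 C=C
#' bonds), generates `n_spectra` lipid-body spectra as oleic/linoleic
#' mixtures whose per-spectrum linoleic fractions average to the target
#' C=C count, adds a polynomial baseline and noise, then recovers the mean
#' C=C count via [baseline_correct()], [unsaturation_ratio()] and
#' [estimate_double_bonds()].
#'
#' @param true_count target mean number of C=C bonds (between 1 and 2).
#' @param n_spectra number of mixture spectra.
#' @param noise_sd additive noise SD (reference peak heights are ~1-15).
#' @param seed integer seed.
#' @return list with `estimate` (mean recovered C=C), `true_count`,
#'   `truth_sample_mean`, `truth_sem`, `per_spectrum`, `calibration`.
#' @export
simulate_unsaturation_recovery <- function(true_count = 1.5, n_spectra = 50,
                                           noise_sd = 0.02, seed = 1) {
  stopifnot(true_count >= 1, true_count <= 2)
  refs <- reference_fatty_acid_spectra(1:3)
  wn <- attr(refs, "wavenumber_axis")
  cal <- fit_unsaturation_calibration(refs)
  with_seed(seed, {
    # per-spectrum linoleic fraction: jittered around the target so the
    # expected mixture C=C count equals true_count
    f0 <- true_count - 1
    f <- pmin(1, pmax(0, f0 + stats::runif(n_spectra, -0.2, 0.2)))
    xn <- (wn - min(wn)) / diff(range(wn))
    est <- truth <- numeric(n_spectra)
    for (i in seq_len(n_spectra)) {
      s <- (1 - f[i]) * refs[["1"]] + f[i] * refs[["2"]] +
        0.6 + 0.8 * xn - 0.4 * xn^2 +          # smooth baseline
        stats::rnorm(length(wn), 0, noise_sd)
      sc <- baseline_correct(s, wn)
      est[i] <- estimate_double_bonds(cal, unsaturation_ratio(sc, wn))
      truth[i] <- 1 + f[i]
    }
    list(estimate = mean(est), true_count = true_count,
         truth_sample_mean = mean(truth),
         truth_sem = stats::sd(truth) / sqrt(n_spectra),
         per_spectrum = est, calibration = cal)
  })
}
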