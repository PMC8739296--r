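# Raman pipeline: cosmic-ray removal, baseline correction, band integration,
# k-means class extraction, unsaturation calibration, ANOVA, PCA.

test_that("cosmic-ray removal fixes spikes, spares structure, is idempotent", {
  wn <- default_wavenumber_axis()
  smooth <- 2 + sin(wn / 150) + 10 * exp(-(wn - 1440)^2 / 200)
  out <- remove_cosmic_rays(smooth)
  expect_equal(as.numeric(out), smooth, tolerance = 1e-12)
  expect_length(attr(out, "spike_channels"), 0)

  spiked <- smooth; spiked[300] <- spiked[300] + 50
  fixed <- remove_cosmic_rays(spiked)
  expect_equal(attr(fixed, "spike_channels"), 300)
  expect_equal(as.numeric(fixed)[-300], smooth[-300], tolerance = 1e-12)
  expect_lt(abs(fixed[300] - smooth[300]), 0.1)

  # idempotence: a second pass on cleaned output changes nothing
  again <- remove_cosmic_rays(as.numeric(fixed))
  expect_equal(as.numeric(again), as.numeric(fixed), tolerance = 1e-12)

  # audit on a cube: flagged set equals the injected set
  mk <- make_test_cube(noise_sd = 0.02, cosmic_ray_rate = 0.08, seed = 5)
  cr <- remove_cosmic_rays(mk$cube)
  rep_tab <- attr(cr, "spike_report")
  expect_equal(nrow(rep_tab), nrow(mk$spikes))
  expect_setequal(paste(rep_tab$pixel, rep_tab$channel),
                  paste(mk$spikes$pixel, mk$spikes$channel))
})

test_that("baseline correction represents cubics exactly and preserves bands", {
  wn <- default_wavenumber_axis()
  x <- (wn - 600) / 2502
  cubic <- 2 + 3 * x - 1.5 * x^2 + 0.8 * x^3
  res <- baseline_correct(cubic, wn)
  expect_lt(max(abs(res)), 1e-8)

  band <- 8 * exp(-(wn - 1660)^2 / (2 * 9^2))
  res2 <- baseline_correct(cubic + band, wn)
  a_before <- band_integrate(band, wn, c(1600, 1720))
  a_after <- band_integrate(as.numeric(res2), wn, c(1600, 1720))
  expect_lt(abs(a_after - a_before) / a_before, 0.05)

  expect_equal(max(abs(baseline_correct(rep(0, 100)))), 0, tolerance = 1e-12)
  expect_error(baseline_correct(1:4), "at least")
})

test_that("band integration is exact on triangles and additive", {
  wn <- seq(1000, 1200, by = 1)
  expect_equal(band_integrate(rep(0, length(wn)), wn, c(1050, 1150)), 0)

  tri <- pmax(0, 1 - abs(wn - 1100) / 10)     # unit height, base 20
  expect_equal(band_integrate(tri, wn, c(1080, 1120)), 10, tolerance = 0.01)

  withr::with_seed(2, {
    y <- abs(rnorm(length(wn)))
    # additivity over adjacent windows holds for zero-endpoint signal
    y[wn <= 1052 | wn >= 1148] <- 0
    whole <- band_integrate(y, wn, c(1050, 1150))
    parts <- band_integrate(y, wn, c(1050, 1100)) +
      band_integrate(y, wn, c(1100, 1150))
    expect_equal(whole, parts, tolerance = 1e-9 + 2 * y[wn == 1100])
  })
  expect_error(band_integrate(tri, wn, c(900, 1000)), "outside")
})

test_that("integration maps equal the per-pixel scalar oracle", {
  mk <- make_test_cube(noise_sd = 0.01, seed = 3)
  img <- integration_map(mk$cube, c(2830, 2900))
  oracle <- vapply(seq_len(nrow(mk$cube$spectra)), function(i)
    band_integrate(mk$cube$spectra[i, ], mk$cube$wavenumber_axis,
                   c(2830, 2900)), numeric(1))
  expect_equal(as.vector(img$pixels), oracle, tolerance = 1e-12)

  zero <- make_raman_cube(matrix(1L, 4, 4), list(bg = c(lipid = 0)))
  expect_true(all(integration_map(zero$cube, c(780, 800))$pixels == 0))
})

test_that("k-means segmentation recovers separable classes and marker labels", {
  mk <- make_test_cube(noise_sd = 0.02, seed = 9)
  bc <- baseline_correct_cube(mk$cube)
  seg <- kmeans_segment(bc, k = 4, seed = 7)
  expect_gte(adjusted_rand(as.vector(seg$labels), as.vector(mk$layout)), 0.95)
  expect_equal(adjusted_rand(as.vector(seg$labels), as.vector(mk$layout)),
               mclust::adjustedRandIndex(as.vector(seg$labels),
                                         as.vector(mk$layout)),
               tolerance = 1e-12)
  # marker labelling: generator classes were laid out in the same order
  expect_equal(as.vector(seg$labels), as.vector(mk$layout))

  # permuting pixel order permutes labels identically
  perm <- withr::with_seed(1, sample(nrow(bc$spectra)))
  cube_p <- spectral_cube(bc$spectra[perm, ], bc$wavenumber_axis, bc$dims)
  seg_p <- kmeans_segment(cube_p, k = 4, seed = 7)
  expect_equal(as.vector(seg_p$labels), as.vector(seg$labels)[perm])

  # two well-separated classes, k = 2: would collide on markers, so check
  # raw clustering recovery via the cluster attribute
  lay2 <- matrix(rep(1:2, each = 50), 10, 10)
  two <- make_raman_cube(lay2, list(a = c(protein = 1), b = c(lipid = 1)),
                         noise_sd = 0.01, seed = 2)
  seg2 <- try(kmeans_segment(two$cube, k = 2, seed = 3), silent = TRUE)
  if (inherits(seg2, "try-error")) {
    expect_match(attr(seg2, "condition")$message, "collision")
  } else {
    expect_gte(adjusted_rand(attr(seg2, "cluster"), as.vector(lay2)), 1)
  }
})

test_that("class mean spectra match the loop oracle", {
  mk <- make_test_cube(noise_sd = 0.05, seed = 21)
  cube <- mk$cube
  cms <- class_mean_spectra(cube)
  for (cl in seq_along(cms)) {
    sel <- as.vector(cube$labels) == cl
    expect_equal(cms[[cl]]$mean, colMeans(cube$spectra[sel, , drop = FALSE]),
                 tolerance = 1e-12)
    expect_equal(cms[[cl]]$n, sum(sel))
  }
  # single-member class: SD identically zero
  one <- spectral_cube(matrix(1:5, 1, 5), 1:5, c(1, 1),
                       labels = matrix(1L, 1, 1), class_names = "only")
  expect_true(all(class_mean_spectra(one)$only$sd == 0 |
                  is.na(class_mean_spectra(one)$only$sd)))
  # two members: mean is the midpoint
  twoc <- spectral_cube(rbind(rep(0, 5), rep(2, 5)), 1:5, c(2, 1),
                        labels = matrix(1L, 2, 1), class_names = "c")
  expect_equal(class_mean_spectra(twoc)$c$mean, rep(1, 5))
})

test_that("unsaturation ratio and calibration are exact on references", {
  wn <- default_wavenumber_axis()
  # narrow enough that both windows capture the full band
  equal_bands <- exp(-(wn - 1660)^2 / (2 * 5^2)) +
    exp(-(wn - 1440)^2 / (2 * 5^2))
  expect_equal(unsaturation_ratio(equal_bands, wn), 1, tolerance = 0.01)
  expect_equal(unsaturation_ratio(5 * equal_bands, wn),
               unsaturation_ratio(equal_bands, wn), tolerance = 1e-12)

  refs <- reference_fatty_acid_spectra(1:2)
  r1 <- unsaturation_ratio(refs[["1"]], wn)
  cal <- fit_unsaturation_calibration(refs)
  expect_equal(cal$slope, r1, tolerance = 1e-9)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  # round trip at the nodes
  expect_equal(estimate_double_bonds(cal, cal$points$ratio),
               cal$points$count, tolerance = 1e-9)
  # equal-weight oleic/linoleic mixture -> 1.5
  mix <- 0.5 * refs[["1"]] + 0.5 * refs[["2"]]
  expect_equal(estimate_double_bonds(cal, unsaturation_ratio(mix, wn)), 1.5,
               tolerance = 1e-9)

  expect_error(unsaturation_ratio(rep(0, length(wn)), wn), "zero")
  one_ref <- refs["1"]
  attr(one_ref, "counts") <- 1; attr(one_ref, "wavenumber_axis") <- wn
  expect_error(fit_unsaturation_calibration(one_ref), "at least two")
})

test_that("group ANOVA matches t^2 for two groups and responds to shifts", {
  withr::with_seed(5, {
    x <- rnorm(20); y <- rnorm(20)
    res <- anova_groups(c(x, y), rep(c("control", "g2"), each = 20))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-9)

    ident <- anova_groups(c(x, x), rep(c("control", "g2"), each = 20))
    expect_lt(ident$F, 1e-20)
    expect_gt(ident$p, 0.999)

    res_shift <- anova_groups(c(x, y + 2), rep(c("control", "g2"), each = 20))
    expect_gt(res_shift$F, res$F)
    expect_equal(res_shift$pairwise$stars, "***")
  })
  expect_error(anova_groups(1:4, c("a", "a", "b", "c")), "n >= 2")
})

test_that("PCA of cytoplasm spectra has the stated algebraic properties", {
  wn <- default_wavenumber_axis()
  comps <- spectral_components()

  ident <- matrix(rep(comps$components$protein, 5), 5, length(wn),
                  byrow = TRUE)
  p0 <- pca_cytoplasm(ident, wn)
  expect_lt(sum(p0$explained_variance), 1e-12)

  # rank-1 variation + tiny noise: PC1 dominates
  withr::with_seed(6, {
    w <- runif(20)
    x <- outer(rep(1, 20), comps$components$protein) +
      outer(w, comps$components$epo) +
      matrix(rnorm(20 * length(wn), 0, 1e-5), 20)
  })
  p1 <- pca_cytoplasm(x, wn, normalize = "none")
  expect_gte(p1$explained_variance[1] / sum(p1$explained_variance), 0.95)

  # scores have zero mean; variances sum to total variance; reconstruction
  expect_lt(max(abs(colMeans(p1$scores))), 1e-9)
  sel <- wn >= 600 & wn <= 1800
  xc <- scale(x[, sel], center = TRUE, scale = FALSE)
  expect_equal(sum(p1$explained_variance), sum(xc^2) / (nrow(x) - 1),
               tolerance = 1e-9)
  recon <- p1$scores %*% t(p1$loadings)
  expect_equal(recon, unclass(xc), tolerance = 1e-8, ignore_attr = TRUE)
  # sign convention: largest-magnitude loading element is positive
  for (j in 1:3) {
    v <- p1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_cytoplasm(x[1:2, ], wn), "at least 3")
})
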