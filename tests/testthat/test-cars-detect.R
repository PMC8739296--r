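# The CARS spot-calling operator chain, each stage against an independent
# brute-force oracle where one is defined.

test_that("rolling-ball subtraction matches the grayscale-opening oracle", {
  # flat background is fully removed
  flat <- matrix(100, 12, 12)
  expect_true(all(subtract_background_rolling_ball(flat, 3)$pixels == 0))

  # single hot pixel on constant background: spike survives subtraction
  px <- matrix(10, 15, 15); px[8, 8] <- 200
  res <- subtract_background_rolling_ball(px, 3)$pixels
  expect_equal(res, oracle_rolling_ball_residual(px, 3), tolerance = 1e-10)
  expect_gt(res[8, 8], 185)

  # shallow ramp: residual far below the ramp range, and equal to oracle
  ramp <- matrix(rep(seq(0, 3, length.out = 20), each = 20), 20, 20)
  res2 <- subtract_background_rolling_ball(ramp, 3)$pixels
  expect_equal(res2, oracle_rolling_ball_residual(ramp, 3), tolerance = 1e-10)
  expect_lt(max(res2), 0.05 * diff(range(ramp)))

  expect_error(subtract_background_rolling_ball(matrix(c(1, NA, 1, 1), 2)),
               "finite")
})

test_that("Laplacian of Gaussian matches direct convolution and is linear", {
  expect_true(all(abs(laplacian_of_gaussian(matrix(7, 10, 10))$pixels) < 1e-9))

  n <- 21
  blob <- outer(exp(-((1:n) - 11)^2 / 18), exp(-((1:n) - 11)^2 / 18))
  got <- laplacian_of_gaussian(blob, 1)$pixels
  expect_equal(got, oracle_log(blob, 1), tolerance = 1e-8)
  expect_equal(which.min(got), which.min(as.vector(oracle_log(blob, 1))))
  expect_equal(arrayInd(which.min(got), dim(got)), matrix(c(11L, 11L), 1))

  expect_equal(laplacian_of_gaussian(2 * blob, 1)$pixels, 2 * got,
               tolerance = 1e-12)
})

test_that("FFT bandpass passes in-band periods and rejects out-of-band", {
  n <- 120
  # DC removal
  out <- fft_bandpass(matrix(5, n, n), 2, 20)$pixels
  expect_lt(max(abs(out)), 5 * 1e-3)

  sinus <- function(period) {
    matrix(sin(2 * pi * (0:(n - 1)) / period), n, n)
  }
  inband <- fft_bandpass(sinus(8), 2, 20)$pixels
  expect_gt(max(abs(inband)) / 1, 0.9)          # amplitude preserved >90%
  outband <- fft_bandpass(sinus(60), 2, 20)$pixels
  expect_lt(max(abs(outband)), 0.1)             # attenuated below 10%
  # zero-mean input stays (essentially) zero-mean
  expect_lt(abs(mean(inband)), 1e-9)

  expect_error(fft_bandpass(matrix(0, 30, 30), 20, 2), "band edges")
})

test_that("invert_and_quantize maps endpoints and is an involution", {
  img <- matrix(seq(0, 1, length.out = 25), 5, 5)
  q <- invert_and_quantize(img)$pixels
  expect_equal(q[1, 1], 255)                    # min -> 255
  expect_equal(q[5, 5], 0)                      # max -> 0
  expect_true(all(q == round(q) & q >= 0 & q <= 255))

  two <- matrix(c(0, 1), 2, 4)
  expect_setequal(unique(as.vector(invert_and_quantize(two)$pixels)),
                  c(255, 0))

  # involution on the canonical 8-bit result (which spans the full range)
  r <- invert_and_quantize(matrix(rnorm(64), 8, 8))$pixels
  expect_equal(invert_and_quantize(invert_and_quantize(r)$pixels)$pixels, r)

  expect_message(invert_and_quantize(matrix(3, 4, 4)), "constant")
})

test_that("Renyi threshold equals the exhaustive-scan oracle", {
  withr::with_seed(42, {
    for (i in 1:25) {
      img <- switch(1 + i %% 3,
        matrix(sample(0:255, 400, replace = TRUE), 20, 20),
        matrix(pmin(255, pmax(0, round(c(rnorm(200, 60, 20),
                                         rnorm(200, 190, 25))))), 20, 20),
        matrix(pmin(255, pmax(0, round(rexp(400, 1 / 40)))), 20, 20))
      expect_equal(threshold_renyi_entropy(img)$threshold,
                   oracle_renyi_threshold(img))
    }
  })

  # bimodal delta histogram: the strict > rule puts exactly the high peak
  # in the foreground (ties between 50..199 break to the smallest level)
  bi <- matrix(rep(c(50, 200), each = 128), 16, 16)
  th <- threshold_renyi_entropy(bi)
  expect_gte(th$threshold, 50)
  expect_lt(th$threshold, 200)
  expect_equal(th$binary, bi > 50)

  # histogram shift property
  base <- matrix(pmin(200, pmax(20, round(rnorm(400, 90, 30)))), 20, 20)
  t0 <- threshold_renyi_entropy(base)$threshold
  t1 <- threshold_renyi_entropy(base + 30)$threshold
  expect_equal(t1, t0 + 30)

  expect_error(threshold_renyi_entropy(matrix(7, 5, 5)), "single-valued")
})

test_that("relative-mean threshold follows its definition", {
  expect_equal(sum(threshold_relative_mean(matrix(100, 8, 8))$binary), 0)
  img <- matrix(50, 10, 10); img[1, 1] <- 71; img[1, 2] <- 69
  img <- img - (mean(img) - 50)                 # force mean exactly 50
  th <- threshold_relative_mean(img, 1.4)
  expect_equal(th$threshold, 70)
  expect_true(th$binary[1, 1] >= th$binary[1, 2])

  chk <- matrix(c(0, 200), 10, 10)
  res <- threshold_relative_mean(chk, 1.4)
  expect_equal(res$threshold, 140)
  expect_equal(res$binary, chk == 200)
})

test_that("particle filter applies the published gates exactly", {
  gal <- matrix(FALSE, 60, 160)
  d <- disk_mask(60, 5, 30, 20); gal[, 1:60][d[, 1:60]] <- TRUE   # disk r=5
  gal[10, 70:99] <- TRUE                                          # 1x30 line
  gal[30:31, 120] <- TRUE                                         # 2 px blob
  ss <- filter_particles(gal)
  expect_equal(ss$n, 1)                          # only the disk survives
  expect_equal(nrow(ss$excluded), 2)
  expect_setequal(ss$excluded$reason, c("circularity", "small"))
  expect_gt(ss$spots$circularity[1], 0.85)
  expect_equal(ss$spots$area[1], sum(d), tolerance = 1e-9)

  # 30-px-radius blob: excluded by the upper area gate
  big <- disk_mask(80, 30)
  ssb <- filter_particles(big)
  expect_equal(ssb$n, 0)
  expect_equal(ssb$excluded$reason, "large")

  # empty image
  expect_equal(filter_particles(matrix(FALSE, 10, 10))$n, 0)
})

test_that("raising the circularity gate never increases the retained count", {
  withr::with_seed(11, {
    img <- matrix(runif(2500) > 0.75, 50, 50)
    ns <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(c0) filter_particles(img, min_area = 0,
                                               max_area = Inf,
                                               min_circularity = c0)$n,
                 numeric(1))
    expect_true(all(diff(ns) <= 0))
  })
})

test_that("detect_lipid_bodies recovers isolated in-gate spots end to end", {
  blank <- matrix(0, 128, 128)
  expect_equal(detect_lipid_bodies(blank, cars_config("relative_mean"))$n, 0)

  sc <- make_cars_tpef_scene(12, count_law_constant(3), seed = 21,
                             frame = c(512, 512))
  truth <- sc$ground_truth$lb_records
  for (mode in c("renyi", "relative_mean")) {
    ss <- detect_lipid_bodies(sc$cars, cars_config(mode))
    hits <- sum(vapply(seq_len(nrow(truth)), function(i)
      any(sqrt((ss$spots$x - truth$x[i])^2 +
               (ss$spots$y - truth$y[i])^2) < 4), logical(1)))
    expect_gte(hits / nrow(truth), 0.95)   # recall
    expect_gte(hits / ss$n, 0.95)          # precision
  }
  # provenance is recorded
  ss <- detect_lipid_bodies(sc$cars, cars_config("relative_mean"))
  expect_equal(ss$params$ball_radius, 3)
  expect_equal(ss$params$factor, 1.4)
  expect_equal(ss$params$threshold, "relative_mean")

  # a giant blob fails the size gate
  big <- matrix(0, 128, 128)
  d <- disk_mask(128, 30)
  big[d] <- 1000
  big <- big + matrix(rnorm(128^2, 0, 1), 128, 128)
  ssb <- detect_lipid_bodies(big, cars_config("relative_mean"))
  expect_equal(sum(ssb$spots$area > 300), 0)
})
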