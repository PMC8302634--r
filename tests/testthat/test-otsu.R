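test_that("roi_histogram counts exactly the masked pixels", {
  f <- roi_fixture(rep(71L, 10))
  h <- roi_histogram(f$slice, f$mask)
  expect_identical(h[72L], 10L)
  expect_identical(sum(h), 10L)

  f2 <- roi_fixture(c(rep(50L, 100), rep(200L, 100)), ncol_roi = 20)
  h2 <- roi_histogram(f2$slice, f2$mask)
  expect_identical(h2[c(51L, 201L)], c(100L, 100L))
  expect_identical(sum(h2), 200L)

  # random fixture: histogram total equals mask area (brute-force scan)
  set.seed(7)
  px <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
  mask <- random_mask(64, 64, 0.4)
  h3 <- roi_histogram(grayscale_slice(px), mask)
  expect_identical(sum(h3), sum(mask))
  for (b in sample(0:255, 10)) {
    expect_identical(h3[b + 1L], sum(px[mask] == b))
  }
  expect_error(roi_histogram(grayscale_slice(px), mask & FALSE), "empty")
})

test_that("otsu_threshold maximizes between-class variance, lowest tie", {
  # two equal spikes: any t in [50, 199] maximizes; lowest-tie gives 50
  h <- integer(256)
  h[c(51L, 201L)] <- 100L
  expect_identical(otsu_threshold(h), 50L)

  # single spike: degenerate convention returns the level itself, so the
  # strictly-above fat class is empty
  h1 <- integer(256)
  h1[72L] <- 10L
  expect_identical(otsu_threshold(h1), 71L)
  expect_identical(sum(h1[(otsu_threshold(h1) + 2L):256L]), 0L)

  expect_error(otsu_threshold(integer(256)), "empty")
  expect_error(otsu_threshold(integer(10)), "256")

  # oracle equivalence on random histograms, including sparse ones
  set.seed(11)
  for (i in 1:60) {
    h <- integer(256)
    k <- sample(1:12, 1)
    h[sample(1:256, k)] <- sample(1:500, k, replace = TRUE)
    expect_identical(otsu_threshold(h), oracle_otsu(h))
  }
})

test_that("equalize_roi flattens the ROI CDF and touches nothing else", {
  # two-valued ROI {10 x50, 20 x50}: hand-computed round(255 * CDF)
  f <- roi_fixture(c(rep(10L, 50), rep(20L, 50)), ncol_roi = 10)
  eq <- equalize_roi(f$slice, f$mask)
  expect_setequal(unique(eq$pixels[f$mask]), c(128L, 255L))
  expect_identical(eq$pixels[f$mask][f$slice$pixels[f$mask] == 10L][1], 128L)
  # locality: pixels outside the mask bit-exact
  expect_identical(eq$pixels[!f$mask], f$slice$pixels[!f$mask])

  # uniform ROI over 0..255 -> mapping within one level of identity
  f2 <- roi_fixture(rep(0:255, each = 2), ncol_roi = 32)
  eq2 <- equalize_roi(f2$slice, f2$mask)
  expect_lte(max(abs(eq2$pixels[f2$mask] - f2$slice$pixels[f2$mask])), 1L)

  # monotone non-decreasing mapping on a random ROI
  set.seed(13)
  px <- matrix(sample(0:255, 48 * 48, replace = TRUE), 48, 48)
  mask <- random_mask(48, 48, 0.5)
  eq3 <- equalize_roi(grayscale_slice(px), mask)
  ord <- order(px[mask])
  expect_true(all(diff(eq3$pixels[mask][ord]) >= 0L))
})

test_that("quantify_fat recovers known fat fractions on clean phantoms", {
  pc <- tiny_phantom(seed = 31L, fat_fraction_true = 0.30, intensity_sd = 0)
  res <- quantify_fat(pc$slice, pc$masks$muscle)
  expect_lte(abs(res$fatty_infiltration_pct - 30), 1)
  expect_true(all(pc$masks$muscle[res$fat_mask]))
  expect_equal(res$fatty_infiltration_pct,
               100 * sum(res$fat_mask) / sum(pc$masks$muscle))

  # fat-free muscle: near-zero fatty infiltration
  z <- tiny_phantom(seed = 32L, fat_fraction_true = 0, intensity_sd = 0)
  expect_lte(quantify_fat(z$slice, z$masks$muscle)$fatty_infiltration_pct, 1)

  expect_error(
    quantify_fat(pc$slice, pc$masks$muscle & FALSE),
    "below the usable floor"
  )
})

test_that("the equalization gate toggles exactly at ROI SD 35", {
  # half/half two-valued ROI: population SD = gap / 2
  below <- roi_fixture(c(rep(60L, 200), rep(129L, 200)), ncol_roi = 20)
  res_b <- quantify_fat(below$slice, below$mask)
  expect_false(res_b$equalization_applied)
  expect_equal(res_b$roi_sd, 34.5)

  above <- roi_fixture(c(rep(60L, 200), rep(131L, 200)), ncol_roi = 20)
  res_a <- quantify_fat(above$slice, above$mask)
  expect_true(res_a$equalization_applied)
  expect_equal(res_a$roi_sd, 35.5)

  at <- roi_fixture(c(rep(60L, 200), rep(130L, 200)), ncol_roi = 20)
  expect_true(quantify_fat(at$slice, at$mask)$equalization_applied)

  # forcing flags override the gate
  expect_true(quantify_fat(below$slice, below$mask,
                           equalize = "always")$equalization_applied)
  expect_false(quantify_fat(above$slice, above$mask,
                            equalize = "never")$equalization_applied)
})

test_that("a single noisy population is declared fat-free, mixtures are not", {
  # pure noise around one tissue intensity: no fat class may be invented
  noisy <- tiny_phantom(seed = 91L, fat_fraction_true = 0, intensity_sd = 10)
  res <- quantify_fat(noisy$slice, noisy$masks$muscle)
  expect_false(res$separable)
  expect_equal(res$fatty_infiltration_pct, 0)
  # threshold sits at the ROI maximum, so the count above it is zero
  expect_identical(res$threshold,
                   max(noisy$slice$pixels[noisy$masks$muscle]))
  # the same noise level with a genuine fat population is detected
  fatty <- tiny_phantom(seed = 92L, fat_fraction_true = 0.05,
                        intensity_sd = 10)
  res2 <- quantify_fat(fatty$slice, fatty$masks$muscle)
  expect_true(res2$separable)
  expect_gt(res2$separability, res$separability)
  expect_lte(abs(res2$fatty_infiltration_pct - 5), 3)
  # the safeguard can be disabled explicitly
  raw <- quantify_fat(noisy$slice, noisy$masks$muscle,
                      separability_floor = 0)
  expect_gt(raw$fatty_infiltration_pct, 10)
})

test_that("pixels outside the muscle never influence the result", {
  pc <- tiny_phantom(seed = 41L, n_distractors = 0L)
  res <- quantify_fat(pc$slice, pc$masks$muscle)
  # same ROI content, very different surroundings
  px2 <- pc$slice$pixels
  px2[!pc$masks$muscle] <- sample(0:255, sum(!pc$masks$muscle),
                                  replace = TRUE)
  res2 <- quantify_fat(grayscale_slice(px2), pc$masks$muscle)
  expect_identical(res2$threshold, res$threshold)
  expect_identical(res2$fat_mask, res$fat_mask)
  expect_equal(res2$fatty_infiltration_pct, res$fatty_infiltration_pct)
})

test_that("fatty infiltration increases strictly with the true fat fraction", {
  ffs <- seq(0, 0.6, by = 0.1)
  fis <- vapply(seq_along(ffs), function(i) {
    pc <- tiny_phantom(seed = 50L, fat_fraction_true = ffs[i],
                       intensity_sd = 0)
    quantify_fat(pc$slice, pc$masks$muscle)$fatty_infiltration_pct
  }, numeric(1))
  expect_true(all(diff(fis) > 0))
})

test_that("binary rendering is white fat on black muscle", {
  pc <- tiny_phantom(seed = 61L, fat_fraction_true = 0.2, intensity_sd = 0)
  res <- quantify_fat(pc$slice, pc$masks$muscle)
  img <- render_fat_binary(res)
  expect_setequal(unique(as.vector(img)), c(0L, 255L))
  expect_identical(img == 255L, res$fat_mask)
})
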