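test_that("normalize_to_8bit maps ranges, is monotone, handles degenerates", {
  expect_error(normalize_to_8bit(matrix("a", 2, 2)), "numeric")
  # hand-computed: round(v * 255 / 100) for {0, 50, 100}
  raw <- matrix(rep(c(0, 50, 100), length.out = 32 * 32), 32, 32)
  sl <- normalize_to_8bit(raw)
  expect_setequal(unique(as.vector(sl$pixels)), c(0L, 128L, 255L))
  expect_identical(sl$pixels[raw == 50][1], 128L)

  # constant image: all zeros by convention
  expect_true(all(normalize_to_8bit(matrix(7, 40, 40))$pixels == 0L))

  # monotone: raw_a <= raw_b => out_a <= out_b
  set.seed(42)
  raw <- matrix(runif(40 * 40, 0, 1e4), 40, 40)
  sl <- normalize_to_8bit(raw)
  ord <- order(raw)
  expect_true(all(diff(sl$pixels[ord]) >= 0L))

  # idempotent on already-8-bit minmax-spanning input
  base <- matrix(sample(0:255, 40 * 40, replace = TRUE), 40, 40)
  base[1] <- 0L
  base[2] <- 255L
  expect_identical(normalize_to_8bit(base)$pixels,
                   normalize_to_8bit(normalize_to_8bit(base)$pixels * 1)$pixels)

  # percentile policy clips an outlier before scaling
  raw <- matrix(runif(40 * 40, 0, 200), 40, 40)
  raw[1, 1] <- 10000
  clipped <- normalize_to_8bit(raw, "percentile", p_lo = 0.5, p_hi = 99.5)
  q <- quantile(raw, c(0.005, 0.995), names = FALSE)
  oracle <- pmin(pmax(raw, q[1]), q[2])
  oracle <- round((oracle - min(oracle)) * 255 / diff(range(oracle)))
  expect_identical(clipped$pixels[1, 1], 255L)
  expect_true(max(abs(clipped$pixels - oracle)) <= 1)
  expect_error(normalize_to_8bit(raw, "percentile", p_lo = 99, p_hi = 1),
               "p_lo < p_hi")
})

test_that("read_slice is the identity on 8-bit PNG and rescales deep input", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "const.png")
  png::writePNG(matrix(100 / 255, 64, 64), p)
  sl <- read_slice(p)
  expect_s3_class(sl, "grayscale_slice")
  expect_true(all(sl$pixels == 100L))

  # 16-bit NIfTI, min 0 / max 4095: default policy gives round(v*255/4095)
  deep <- matrix(sample(0:4095, 64 * 64, replace = TRUE), 64, 64)
  deep[1] <- 0L
  deep[2] <- 4095L
  pn <- file.path(tmp, "deep.nii.gz")
  RNifti::writeNifti(deep, pn, datatype = "int16")
  sl16 <- read_slice(pn)
  expect_identical(sl16$pixels,
                   array(as.integer(round(deep * 255 / 4095)), dim(deep)))

  expect_error(read_slice(file.path(tmp, "missing.png")), "no such file")

  # multi-slice volume requires a slice index
  vol <- array(sample(0:255, 64 * 64 * 3, replace = TRUE), c(64, 64, 3))
  pv <- file.path(tmp, "vol.nii.gz")
  RNifti::writeNifti(vol, pv, datatype = "int16")
  expect_error(read_slice(pv), "slice_index")
  expect_identical(read_slice(pv, slice_index = 2)$pixels,
                   array(as.integer(vol[, , 2]), c(64, 64)))
})

test_that("minimal DICOM reader round-trips and rejects truncated files", {
  tmp <- withr::local_tempdir()
  px <- matrix(sample(0:4095, 48 * 40, replace = TRUE), 48, 40)
  p <- file.path(tmp, "slice.dcm")
  write_dicom_gray(px, p, bits_allocated = 16L)
  back <- read_dicom_gray(p)
  expect_identical(back$pixels, px)
  expect_identical(back$bits_allocated, 16L)

  px8 <- matrix(sample(0:255, 36 * 34, replace = TRUE), 36, 34)
  p8 <- file.path(tmp, "slice8.dcm")
  write_dicom_gray(px8, p8, bits_allocated = 8L)
  expect_identical(read_dicom_gray(p8)$pixels, px8)

  # read_slice integrates DICOM with normalization
  px[1] <- 0L
  px[2] <- 4095L
  write_dicom_gray(px, p, bits_allocated = 16L)
  sl <- read_slice(p, format = "dicom")
  expect_identical(sl$pixels,
                   array(as.integer(round(px * 255 / 4095)), dim(px)))

  # truncated file -> I/O error naming the path
  full <- readBin(p, "raw", file.info(p)$size)
  pt <- file.path(tmp, "trunc.dcm")
  writeBin(full[1:(length(full) - 500)], pt)
  expect_error(read_slice(pt, format = "dicom"), "trunc")
  writeBin(full[1:80], pt)
  expect_error(read_dicom_gray(pt), "truncated")
  # non-DICOM bytes
  writeBin(as.raw(rep(7, 200)), pt)
  expect_error(read_dicom_gray(pt), "DICM")
})

test_that("label maps round-trip and report containment", {
  tmp <- withr::local_tempdir()
  fossa <- matrix(FALSE, 64, 64)
  fossa[10:40, 10:40] <- TRUE
  muscle <- matrix(FALSE, 64, 64)
  muscle[15:30, 15:30] <- TRUE
  masks <- region_masks(fossa, muscle)
  expect_identical(masks$containment_violations, 0L)

  p <- file.path(tmp, "labels.nii.gz")
  write_label_map(masks, p)
  back <- read_label_map(p)
  expect_identical(back$fossa, fossa)
  expect_identical(back$muscle, muscle)
  # round-trip preserves every pixel label
  lab <- array(0L, dim(fossa)); lab[fossa] <- 1L; lab[muscle] <- 2L
  write_label_map(back, p)
  vol <- RNifti::readNifti(p)
  expect_identical(array(as.integer(vol), dim(fossa)), lab)

  # missing label -> data error naming it
  lab_only1 <- array(0L, c(64, 64)); lab_only1[5:10, 5:10] <- 1L
  p2 <- file.path(tmp, "bad.nii.gz")
  RNifti::writeNifti(lab_only1, p2, datatype = "int16")
  expect_error(read_label_map(p2), "label 2")

  # predicted masks may violate containment; count by brute-force scan
  pred_muscle <- muscle
  pred_muscle[60:64, 60] <- TRUE # 5 px outside the fossa
  pred <- region_masks(fossa, pred_muscle, ground_truth = FALSE)
  expect_identical(pred$containment_violations,
                   as.integer(sum(pred_muscle & !fossa)))
  expect_identical(pred$containment_violations, 5L)
  expect_error(region_masks(fossa, pred_muscle, ground_truth = TRUE),
               "outside the fossa")

  # per-region mask file round-trip (prediction exchange format)
  p3 <- file.path(tmp, "pred.nii.gz")
  write_region_masks(pred, p3)
  back2 <- read_region_masks(p3)
  expect_identical(back2$muscle, pred_muscle)
  expect_identical(back2$containment_violations, 5L)
})

test_that("grade CSV sidecars validate and round-trip", {
  tmp <- withr::local_tempdir()
  g <- data.frame(source_id = c("a", "b"), grade = c(0L, 4L))
  p <- file.path(tmp, "grades.csv")
  write_grades(g, p)
  expect_identical(read_grades(p), g)
  write.csv(data.frame(source_id = "a", grade = 7), p, row.names = FALSE)
  expect_error(read_grades(p), "0..4")
})
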