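test_that("illumination correction is the identity on flat fields", {
  flat <- matrix(200, 64, 64)
  expect_equal(correct_illumination(flat), flat, tolerance = 1e-10)
})

test_that("illumination correction warns and passes through on zero fields", {
  zero <- matrix(0, 32, 32)
  expect_warning(out <- correct_illumination(zero), "uncorrected")
  expect_identical(out, zero)
})

test_that("Otsu segmentation finds planted disks with the right areas", {
  img <- matrix(10, 128, 128)
  centers <- list(c(25, 25), c(25, 95), c(64, 64), c(100, 30), c(100, 100))
  for (cc in centers) img[disk_mask(128, 128, cc[1], cc[2], 8)] <- 200
  labels <- segment_nuclei(img, min_area = 20)
  expect_equal(max(labels), 5)
  areas <- tabulate(labels[labels > 0])
  # pixel-count oracle: rasterized disk of radius 8
  expect_true(all(abs(areas - sum(disk_mask(41, 41, 21, 21, 8))) <=
                    0.05 * pi * 64))
})

test_that("segmentation of blank or uniform fields returns an empty mask", {
  expect_warning(lab <- segment_nuclei(matrix(7, 50, 50)), "Otsu")
  expect_equal(max(lab), 0)
})

test_that("objects separated by background get distinct labels", {
  img <- matrix(0, 64, 64)
  img[disk_mask(64, 64, 20, 20, 6)] <- 100
  img[disk_mask(64, 64, 20, 40, 6)] <- 100
  labels <- segment_nuclei(img, min_area = 10)
  expect_equal(max(labels), 2)
})

test_that("diagonally touching pixels join one component (8-connectivity)", {
  img <- matrix(0, 32, 32)
  img[10, 10] <- 100  # single pixels below min_area; use blocks instead
  blk <- matrix(0, 32, 32)
  blk[5:10, 5:10] <- 100   # block A
  blk[11:16, 11:16] <- 100 # block B touches A only at the (10,10)/(11,11) corner
  labels <- segment_nuclei(blk, min_area = 10)
  expect_equal(max(labels), 1)
})

test_that("cytoplasm rings match a brute-force distance oracle", {
  nuclei <- matrix(0L, 60, 60)
  nuclei[disk_mask(60, 60, 30, 30, 8)] <- 1L
  rings <- extend_cytoplasm(nuclei, width = 10)
  d <- brute_force_distance(nuclei > 0)
  expected <- d > 0 & d <= 10
  expect_identical(rings > 0, expected)
  # discretized annulus area is close to pi (18^2 - 8^2)
  expect_lt(abs(sum(rings > 0) - pi * (18^2 - 8^2)), 0.05 * pi * (18^2 - 8^2))
})

test_that("contested ring pixels go to the nearest nucleus", {
  nuclei <- matrix(0L, 60, 80)
  nuclei[disk_mask(60, 80, 30, 30, 5)] <- 1L
  nuclei[disk_mask(60, 80, 30, 42, 5)] <- 2L  # centers 12 px apart, width 10
  rings <- extend_cytoplasm(nuclei, width = 10)
  d1 <- brute_force_distance(nuclei == 1L)
  d2 <- brute_force_distance(nuclei == 2L)
  ring_px <- which(rings > 0)
  expect_true(all(rings[ring_px][d1[ring_px] < d2[ring_px]] == 1L))
  expect_true(all(rings[ring_px][d2[ring_px] < d1[ring_px]] == 2L))
  # rings never overlap nuclei
  expect_true(all(nuclei[rings > 0] == 0))
})

test_that("well-separated nuclei get complete disjoint rings", {
  nuclei <- matrix(0L, 100, 100)
  nuclei[disk_mask(100, 100, 25, 25, 6)] <- 1L
  nuclei[disk_mask(100, 100, 75, 75, 6)] <- 2L
  rings <- extend_cytoplasm(nuclei, width = 10)
  a1 <- sum(rings == 1L); a2 <- sum(rings == 2L)
  expect_equal(a1, a2, tolerance = 0.01)
})

test_that("ring width must be positive", {
  expect_error(extend_cytoplasm(matrix(0L, 10, 10), width = 0),
               class = "rescuekit_parameter_error")
})

test_that("per-cell medians and ratios are computed exactly", {
  nuclei <- matrix(0L, 40, 40)
  nuclei[disk_mask(40, 40, 20, 20, 6)] <- 1L
  rings <- extend_cytoplasm(nuclei, width = 5)
  reporter <- matrix(0, 40, 40)
  reporter[nuclei == 1L] <- 100
  reporter[rings == 1L] <- 250
  m <- measure_ktr(nuclei, rings, reporter)
  expect_equal(m$cn_ratio, 2.5)
  reporter[rings == 1L] <- 100
  expect_equal(measure_ktr(nuclei, rings, reporter)$cn_ratio, 1)
})

test_that("zero-median nuclei are flagged and excluded from summaries", {
  nuclei <- matrix(0L, 30, 30)
  nuclei[disk_mask(30, 30, 15, 15, 5)] <- 1L
  rings <- extend_cytoplasm(nuclei, width = 4)
  reporter <- matrix(0, 30, 30)
  reporter[rings == 1L] <- 50
  m <- measure_ktr(nuclei, rings, reporter)
  expect_true(m$flag_zero_nucleus)
  expect_true(is.na(m$cn_ratio))
  expect_warning(out <- suppressMessages(remove_artifacts(m)),
                 "no measurements")
  expect_equal(nrow(out), 0)
})

test_that("C/N ratios are invariant to positive scaling of the reporter", {
  f <- sim_ktr_field(field_size = c(160, 160), n_cells = 5,
                     true_cn_ratio = 1.8, seed = 4)
  nuclei <- segment_nuclei(f$nuclear)
  rings <- extend_cytoplasm(nuclei)
  m1 <- measure_ktr(nuclei, rings, f$reporter)
  m2 <- measure_ktr(nuclei, rings, f$reporter * 3.7)
  expect_equal(m1$cn_ratio, m2$cn_ratio, tolerance = 1e-12)
})

test_that("noise-free flat-illumination fields recover planted ratios exactly", {
  f <- sim_ktr_field(field_size = c(192, 192), n_cells = 8,
                     true_cn_ratio = 2.5, seed = 5)
  m <- suppressMessages(ktr_pipeline(f$nuclear, f$reporter, correct = FALSE))
  expect_equal(nrow(m), 8)
  expect_equal(m$cn_ratio, rep(2.5, 8))
})

test_that("gradient-distorted fields recover planted ratios within 5%", {
  f <- sim_ktr_field(field_size = c(256, 256), n_cells = 20,
                     true_cn_ratio = 2.5, illumination_gradient = 0.3,
                     noise_sd = 0.02, seed = 6)
  m <- suppressMessages(ktr_pipeline(f$nuclear, f$reporter))
  expect_gte(nrow(m), 18)
  expect_lt(abs(median(m$cn_ratio) - 2.5) / 2.5, 0.05)
})

test_that("exactly the artifact-overlapped cells are removed", {
  f <- sim_ktr_field(field_size = c(256, 256), n_cells = 15,
                     true_cn_ratio = 2, n_artifacts = 3, seed = 7)
  nuclei <- segment_nuclei(f$nuclear)
  rings <- extend_cytoplasm(nuclei)
  m <- measure_ktr(nuclei, rings, f$reporter)
  kept <- suppressMessages(remove_artifacts(m))
  # map labels back to planted cells by nucleus center proximity
  label_of <- function(row, col) nuclei[round(row), round(col)]
  planted_labels <- mapply(label_of, f$truth$row, f$truth$col)
  artifact_labels <- planted_labels[f$truth$artifact]
  expect_setequal(setdiff(m$cell, kept$cell), artifact_labels)
})

test_that("condition summaries aggregate replicate medians correctly", {
  meas <- tibble::tibble(
    condition = rep(c("ctrl", "ctrl", "drug"), each = 4),
    replicate = rep(c(1, 2, 1), each = 4),
    cn_ratio = c(rep(1.0, 4), rep(2.0, 4), rep(0.6, 4)))
  s <- summarize_condition(meas, reference = "ctrl")
  ctrl <- s$conditions[s$conditions$condition == "ctrl", ]
  expect_equal(ctrl$mean_cn, 1.5)
  expect_equal(s$conditions$sd_cn[s$conditions$condition == "drug"], 0)
  expect_equal(
    s$conditions$relative_activity[s$conditions$condition == "drug"],
    0.6 / 1.5)
  expect_error(summarize_condition(meas, reference = "absent"),
               class = "rescuekit_parameter_error")
})
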