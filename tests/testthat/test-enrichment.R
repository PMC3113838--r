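# Normalization and enrichment classification.

test_that("net intensity is signal minus background and may go negative", {
  spot <- data.frame(hy5_signal = 100, hy5_background = 30,
                     hy3_signal = 20, hy3_background = 30)
  expect_equal(net_intensity(spot, "hy5"), 70)
  expect_equal(net_intensity(spot, "hy3"), -10)
  expect_equal(net_intensity(data.frame(hy5_signal = 30, hy5_background = 30),
                             "hy5"), 0)
})

test_that("background threshold is the mean-of-middle-two median", {
  scan <- data.frame(hy5_signal = 0, hy5_background = c(10, 20, 30, 40),
                     hy3_signal = 0, hy3_background = c(7, 7, 7, 7),
                     is_calibrator = FALSE)
  expect_equal(background_threshold(scan, "hy5"), 25)
  expect_equal(background_threshold(scan, "hy3"), 7)
  # against a sort-and-index oracle on a large draw
  set.seed(42)
  bg <- rgamma(1000, 2, 0.1)
  scan2 <- data.frame(hy5_signal = 0, hy5_background = bg,
                      hy3_signal = 0, hy3_background = bg,
                      is_calibrator = FALSE)
  s <- sort(bg)
  expect_equal(background_threshold(scan2, "hy5"), (s[500] + s[501]) / 2)
  expect_error(background_threshold(scan2[0, ], "hy5"), "empty")
})

test_that("spots are kept only when the net passes the threshold in both channels", {
  d <- array_design(30, 6, 4, 4)
  tr <- planted_truth(d, n_mito = 3, n_cyto = 3, seed = 2)
  scan <- gen_array_scans(d, tr, 1, seed = 3)[[1]]
  f <- filter_spots(scan)
  n5 <- net_intensity(scan, "hy5"); n3 <- net_intensity(scan, "hy3")
  t5 <- background_threshold(scan, "hy5"); t3 <- background_threshold(scan, "hy3")
  expect_equal(f$kept, n5 >= t5 & n3 >= t3)
})

test_that("spot ratios behave symmetrically under channel swap", {
  spot <- data.frame(hy5_signal = 80, hy5_background = 10,
                     hy3_signal = 45, hy3_background = 10)
  expect_equal(spot_ratio(spot), 2)
  swapped <- data.frame(hy5_signal = 45, hy5_background = 10,
                        hy3_signal = 80, hy3_background = 10)
  expect_equal(spot_ratio(swapped), 0.5)
  neg <- data.frame(hy5_signal = 80, hy5_background = 10,
                    hy3_signal = 5, hy3_background = 10)
  expect_true(is.na(spot_ratio(neg)))
})

test_that("calibrator normalization divides out the dye bias", {
  expect_equal(calibrator_normalize(3, rep(2, 8)), 1.5)
  expect_equal(calibrator_normalize(c(1, 2, 4), rep(1, 5)), c(1, 2, 4))
  r <- c(2.1, 1.9, 2.0, 2.2)
  expect_equal(exp(median(log(calibrator_normalize(r, r)))), 1, tolerance = 1e-12)
  expect_error(calibrator_normalize(1, numeric(0)), "calibrator")
})

test_that("probe means follow the stated conventions", {
  expect_equal(probe_mean_ratio(c(2, 2, 2, 2)), 2)
  expect_equal(probe_mean_ratio(c(1, 3)), 2)
  set.seed(1)
  x <- rlnorm(50)
  expect_equal(probe_mean_ratio(x), mean(x))
  expect_equal(probe_mean_ratio(x, "geometric"), exp(mean(log(x))))
  expect_true(is.na(probe_mean_ratio(numeric(0))))
})

test_that("classification follows the per-array reproducibility rule", {
  m <- rbind(a = c(1.6, 1.8, 2.0),
             b = c(0.5, 0.6, 0.55),
             c = c(1.6, 1.2, 1.8),
             d = c(2.0, NA, 2.5))
  res <- classify_enrichment(m, cutoff = 1.5)
  expect_equal(res$class, c("mito", "cyto", "unchanged", "filtered"))
  expect_equal(res$fold[1], mean(c(1.6, 1.8, 2.0)))
  expect_equal(res$fold[2], 1 / mean(c(0.5, 0.6, 0.55)))
  # with min_arrays relaxed, the partially filtered probe is callable
  res2 <- classify_enrichment(m, cutoff = 1.5, min_arrays = 2)
  expect_equal(res2$class[4], "mito")
  # mean-based mode calls the irreproducible probe
  res3 <- classify_enrichment(m, cutoff = 1.5, mode = "mean")
  expect_equal(res3$class[3], "mito")
  expect_error(classify_enrichment(m, cutoff = 1), "cutoff")
})

test_that("a global dye bias is absorbed by the calibrators exactly", {
  d <- array_design(10, 6, 4, 4)
  tr <- planted_truth(d, n_mito = 0, n_cyto = 0, noise_cv = 0,
                      background_sd = 0, dye_bias = c(hy5 = 2, hy3 = 1),
                      seed = 8)
  tr$fold[["miR-0003"]] <- 4
  scan <- gen_array_scans(d, tr, 1, seed = 9)[[1]]
  per <- normalize_scan(scan)
  expect_equal(per$mean_ratio[per$probe_id == "miR-0003"], 4, tolerance = 1e-12)
})

test_that("the full chain matches a straight-line brute-force recomputation", {
  d <- array_design(40, 10, 4, 6)
  tr <- planted_truth(d, n_mito = 5, n_cyto = 5, noise_cv = 0.15, seed = 12)
  scans <- gen_array_scans(d, tr, 3, seed = 13)
  for (scan in scans) {
    per <- normalize_scan(scan)
    oracle <- brute_normalize_scan(scan)
    expect_equal(per$mean_ratio, unname(oracle[per$probe_id]), tolerance = 1e-12)
  }
})

test_that("per-channel intensity scaling changes no call", {
  d <- array_design(30, 8, 4, 4)
  tr <- planted_truth(d, n_mito = 4, n_cyto = 4, seed = 17)
  scans <- gen_array_scans(d, tr, 2, seed = 18)
  res <- enrich_scans(scans)
  scaled <- lapply(scans, function(s) {
    s$hy5_signal <- s$hy5_signal * 7.3
    s$hy5_background <- s$hy5_background * 7.3
    s$hy3_signal <- s$hy3_signal * 0.2
    s$hy3_background <- s$hy3_background * 0.2
    s
  })
  res2 <- enrich_scans(scaled)
  expect_equal(res2$class, res$class)
  expect_equal(res2$mean_ratio, res$mean_ratio, tolerance = 1e-9)
})

test_that("swapping the channels swaps mito and cyto calls and negates log2 ratios", {
  d <- array_design(30, 8, 4, 4)
  tr <- planted_truth(d, n_mito = 4, n_cyto = 4, seed = 19)
  scans <- gen_array_scans(d, tr, 3, seed = 20)
  res <- enrich_scans(scans, mean_type = "geometric")
  swapped <- lapply(scans, function(s) {
    data.frame(probe_id = s$probe_id, spot_index = s$spot_index,
               hy5_signal = s$hy3_signal, hy5_background = s$hy3_background,
               hy3_signal = s$hy5_signal, hy3_background = s$hy5_background,
               is_calibrator = s$is_calibrator)
  })
  res_sw <- enrich_scans(swapped, mean_type = "geometric")
  map <- c(mito = "cyto", cyto = "mito", unchanged = "unchanged",
           filtered = "filtered")
  expect_equal(res_sw$class, unname(map[res$class]))
  both <- !is.na(res$log2_ratio) & !is.na(res_sw$log2_ratio)
  expect_equal(res_sw$log2_ratio[both], -res$log2_ratio[both], tolerance = 1e-9)
})

test_that("the heatmap table holds the differential probes in log2 scale", {
  d <- array_design(30, 8, 4, 4)
  tr <- planted_truth(d, n_mito = 5, n_cyto = 3, seed = 23)
  scans <- gen_array_scans(d, tr, 3, seed = 24)
  res <- enrich_scans(scans)
  hm <- heatmap_table(res)
  expect_equal(nrow(hm), sum(res$class %in% c("mito", "cyto")))
  rm_ <- attr(res, "ratio_matrix")
  expect_equal(hm[1, ], log2(rm_[rownames(hm)[1], ]))
  csv <- withr::local_tempfile(fileext = ".csv")
  heatmap_table(res, file = csv)
  expect_equal(nrow(read.csv(csv)), nrow(hm))
})
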