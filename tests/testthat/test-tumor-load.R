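test_that("threshold segmentation follows its definition with no editing", {
  # intensities {0, 10, 50, 100}: at th = 40 of reference 100, keep {50, 100}
  vol <- image_volume(array(c(0, 10, 50, 100, 0, 10, 50, 100), c(2, 2, 2)),
                      c(1, 1, 1))
  msk <- segment_threshold(vol, 40, reference = "max")
  expect_equal(sum(msk$mask), 4L)
  expect_true(all(vol$data[msk$mask] >= 40))
  expect_equal(msk$reference_intensity, 100)

  expect_error(segment_threshold(vol, 0), "0, 100")
  expect_error(segment_threshold(vol, 150), "0, 100")
  allneg <- image_volume(array(-1, c(2, 2, 2)), c(1, 1, 1))
  expect_error(segment_threshold(allneg, 40), "no positive voxels")
})

test_that("masks nest monotonically across the six thresholds", {
  for (seed in 1:5) {
    vol <- random_volume(c(12, 12, 10), seed = seed)
    masks <- lapply(c(5, 10, 20, 40, 60, 80), function(th)
      segment_threshold(vol, th)$mask)
    for (i in seq_len(length(masks) - 1L)) {
      # higher threshold is a subset of the lower one
      expect_true(all(masks[[i]][masks[[i + 1L]]]))
    }
    dvs <- vapply(masks, function(m) diffusion_volume(m, vol$spacing),
                  numeric(1))
    expect_true(all(diff(dvs) <= 0))
  }
})

test_that("diffusion volume is voxel count times voxel volume", {
  m <- array(FALSE, c(20, 10, 10))
  m[seq_len(1000)] <- TRUE
  expect_equal(diffusion_volume(m, c(2, 2, 6)), 24)
  expect_equal(diffusion_volume(array(FALSE, c(3, 3, 3)), c(1, 1, 1)), 0)

  # digitised sphere r = 10 mm at 1 mm isotropic: within 2% of (4/3)pi r^3
  dim <- c(24, 24, 24)
  sphere_count <- oracle_ellipsoid_voxels(c(12, 12, 12), c(10, 10, 10),
                                          dim, c(1, 1, 1))
  dv <- sphere_count * 1 / 1000
  expect_equal(dv, 4 / 3 * pi, tolerance = 0.02)
  # and the packaged mask arithmetic agrees with the enumeration
  g <- expand.grid(x = 1:24 - 0.5, y = 1:24 - 0.5, z = 1:24 - 0.5)
  inside <- (g$x - 12)^2 + (g$y - 12)^2 + (g$z - 12)^2 <= 100
  expect_equal(diffusion_volume(array(inside, dim), c(1, 1, 1)), dv)
})

test_that("histogram features match the direct-formula oracle", {
  # five-point worked example, expected values frozen from the oracle
  x <- c(400, 600, 800, 1000, 1200)
  adc <- as_adc_map(image_volume(array(x, c(5, 1, 1)), c(1, 1, 1)))
  hf <- histogram_features(adc, array(TRUE, c(5, 1, 1)))
  expect_equal(hf$ADCmean, 800)
  expect_equal(hf$ADCmd, 800)
  expect_equal(hf$ADCsd, sqrt(100000))
  expect_equal(hf$ADC5p, 440)    # h = 1.2 between 400 and 600
  expect_equal(hf$ADC95p, 1160)  # h = 4.8 between 1000 and 1200
  expect_equal(hf$ADCsk, 0)
  expect_equal(hf$ADCkurt, -1.3)
  expect_equal(hf$ADCentr, log2(5))  # five distinct bins, equal mass
  orc <- oracle_histogram(x)
  for (nm in names(orc)) expect_equal(hf[[nm]], orc[[nm]], info = nm)

  # random small masks against the oracle
  set.seed(2024)
  for (i in 1:50) {
    n <- sample(4:60, 1)
    vals <- round(runif(n, -100, 4200), 3)
    adc <- as_adc_map(image_volume(array(vals, c(n, 1, 1)), c(1, 1, 1)))
    hf <- histogram_features(adc, array(TRUE, c(n, 1, 1)))
    orc <- oracle_histogram(vals)
    for (nm in names(orc))
      expect_equal(hf[[nm]], orc[[nm]], tolerance = 1e-9, info = nm)
  }
})

test_that("degenerate masks yield defined subsets of the statistics", {
  # constant sample: location statistics collapse, moments undefined
  adc <- as_adc_map(image_volume(array(700, c(4, 1, 1)), c(1, 1, 1)))
  hf <- histogram_features(adc, array(TRUE, c(4, 1, 1)))
  expect_equal(hf$ADCmean, 700)
  expect_equal(hf$ADCmd, 700)
  expect_equal(hf$ADC5p, 700)
  expect_equal(hf$ADC95p, 700)
  expect_equal(hf$ADCsd, 0)
  expect_equal(hf$ADCentr, 0)
  expect_true(is.na(hf$ADCsk))
  expect_true(is.na(hf$ADCkurt))

  # empty mask errors; invalid voxels are excluded from the statistics
  expect_error(histogram_features(adc, array(FALSE, c(4, 1, 1))), "empty mask")
  vals <- c(NA, 500, 600, 700)
  adc2 <- as_adc_map(image_volume(array(vals, c(4, 1, 1)), c(1, 1, 1)))
  hf2 <- histogram_features(adc2, array(TRUE, c(4, 1, 1)))
  expect_equal(hf2$n_voxels, 3L)
  expect_equal(hf2$ADCmean, 600)

  # entropy approaches its log2(bins) = 10-bit ceiling from below
  set.seed(8)
  big <- runif(2e5, 0, 4000)
  adcu <- as_adc_map(image_volume(array(big, c(length(big), 1, 1)), c(1, 1, 1)))
  hfu <- histogram_features(adcu, array(TRUE, dim(adcu$volume$data)))
  expect_lt(hfu$ADCentr, 10)
  expect_gt(hfu$ADCentr, 9.9)
})

test_that("percentage change is exact arithmetic with flagged zero denominators", {
  expect_equal(pct_change(1500, 2000), -25)
  expect_equal(pct_change(7, 7), 0)
  # algebraic inverse: f_later reconstructed from f_earlier and the delta
  set.seed(3)
  f0 <- runif(20, 10, 100)
  f1 <- runif(20, 10, 100)
  d <- pct_change(f1, f0)
  expect_equal(f0 * (1 + d / 100), f1, tolerance = 1e-12)
  expect_warning(out <- pct_change(5, 0), "zero denominator")
  expect_true(is.na(out))
})

test_that("per-patient extraction yields the full feature grid and deltas", {
  spec <- clean_lesion_spec(seed = 21, noise_sigma = 5,
                            dim = c(24, 24, 30), spacing = c(6, 6, 8),
                            radii = c(30, 30, 40))
  ph <- render_phantom(spec)
  f <- extract_patient_features(ph$series)
  expect_equal(nrow(f), 54L)  # 6 thresholds x 9 features
  expect_setequal(unique(f$feature_name),
                  c("DV", "ADCmean", "ADCsd", "ADCmd", "ADC5p", "ADC95p",
                    "ADCsk", "ADCkurt", "ADCentr"))
  dv <- f[f$feature_name == "DV", ]
  expect_true(all(diff(dv$value[order(dv$threshold_percent)]) <= 0))

  # identical inputs give bit-identical records
  f2 <- extract_patient_features(render_phantom(spec)$series)
  expect_identical(f, f2)

  # deltas across three rendered timepoints: one record per pair
  fall <- do.call(rbind, lapply(0:2, function(tp) {
    ph <- render_phantom(clean_lesion_spec(seed = 21 + tp, noise_sigma = 5,
                                           dim = c(24, 24, 30),
                                           spacing = c(6, 6, 8),
                                           radii = c(30, 30, 40)))
    f <- extract_patient_features(ph$series)
    f$patient_id <- "P01"
    f$timepoint <- tp
    f
  }))
  d <- compute_deltas(fall)
  expect_equal(nrow(d), 3L * 54L)
  expect_setequal(unique(d$pair), c("01", "02", "12"))
  # spot-check one delta against the two feature values it came from
  pick <- fall[fall$feature_name == "DV" & fall$threshold_percent == 40, ]
  d40 <- d[d$feature_name == "DV" & d$threshold_percent == 40 & d$pair == "02", ]
  expect_equal(d40$value,
               100 * (pick$value[pick$timepoint == 2] -
                        pick$value[pick$timepoint == 0]) /
                 pick$value[pick$timepoint == 0])
})
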