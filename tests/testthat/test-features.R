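test_that("the marker registry matches the measurement protocol", {
  reg <- marker_registry()
  expect_equal(nrow(reg), 16)
  n400 <- reg[reg$marker == "N400_auditory", ]
  expect_equal(c(n400$window_start_ms, n400$window_end_ms), c(450, 650))
  expect_setequal(n400$electrodes[[1]], c("CCP1h", "CCP2h", "P3", "P4"))
  # N80 belongs to the non-living analysis only
  n80 <- reg[reg$marker == "N80_nonliving", ]
  expect_setequal(n80$applies_to[[1]],
                  c("word_visual", "checkerboard", "object"))
  expect_false(any(grepl("N80", setdiff(reg$marker, "N80_nonliving"))))
  # every window lies inside the -100..1500 ms epoch
  expect_true(all(reg$window_start_ms >= 0 & reg$window_end_ms <= 1500))
  expect_true(all(reg$window_start_ms < reg$window_end_ms))
  # PN300 applies to all ten categories
  expect_length(reg$applies_to[reg$marker == "PN300"][[1]], 10)
})

test_that("ms windows convert to half-open floor sample ranges", {
  # 150-190 ms at 512 Hz: samples 76 .. 97 (exclusive)
  expect_equal(erpmarkers:::.window_samples(150, 190, 512), 76:96)
  expect_equal(erpmarkers:::.window_samples(0, 1500, 512), 0:767)
})

test_that("mean amplitude averages baseline-referenced voltage over the window", {
  ev <- cached_noiseless()$evokeds$adult_face
  const <- ev
  const$data[] <- 2
  for (mk in c("N170_living", "P300_living", "LP_auditory")) {
    amp <- mean_amplitude(const, mk)
    expect_true(all(abs(amp$amplitude_uv - 2) < 1e-12))
  }
  # Gaussian pulse: discrete window mean matches the continuous integral
  g <- ev
  g$data[] <- 0
  A <- -5; mu <- 170; s <- 12
  p7 <- which(rownames(g$data) == "P7")
  g$data[p7, ] <- A * exp(-((g$time_ms - mu)^2) / (2 * s^2))
  amp <- mean_amplitude(g, "N170_living")
  # oracle: integral of the Gaussian over the sampled span (samples 76..96,
  # midpoint-rule correspondence), divided by the span width
  f <- function(t) A * exp(-((t - mu)^2) / (2 * s^2))
  delta <- 1000 / 512
  t0 <- 76 * delta - delta / 2
  t1 <- 96 * delta + delta / 2
  oracle <- integrate(f, t0, t1)$value / (t1 - t0)
  got <- amp$amplitude_uv[amp$electrode == "P7"]
  expect_equal(got, oracle, tolerance = 1e-3)
  # pooled = mean over the electrode set
  per <- amp$amplitude_uv[amp$electrode != "pooled"]
  expect_equal(amp$amplitude_uv[amp$electrode == "pooled"], mean(per))
  expect_error(mean_amplitude(const, "not_a_marker"), "unknown marker")
})

test_that("feature extraction is dense, restricted and deterministic", {
  ft <- cached_noiseless_features()$restricted
  # living N170: 3 face categories x (4 electrodes + pooled) per subject
  n170 <- ft[ft$marker == "N170_living", ]
  expect_equal(nrow(n170), 15)
  expect_equal(nrow(n170[n170$electrode != "pooled", ]), 12)
  expect_setequal(unique(n170$category),
                  c("adult_face", "infant_face", "animal_face"))
  # auditory markers carry no rows for visual categories
  aud <- ft[ft$marker %in% c("P2_auditory", "N400_auditory"), ]
  expect_true(all(aud$category %in% stimulus_categories()$auditory))
  expect_true(all(is.finite(ft$amplitude_uv)))
  # re-extraction from the same evokeds is identical
  ev <- list(S01 = cached_noiseless()$evokeds)
  expect_identical(extract_feature_table(ev), ft)
  # unrestricted extraction measures every marker on every category
  full <- cached_noiseless_features()$full
  expect_equal(nrow(full[full$marker == "N170_living" &
                           full$electrode == "pooled", ]), 10)
  # a missing evoked is an explicit gap error
  broken <- list(S01 = cached_noiseless()$evokeds[-1])
  expect_error(extract_feature_table(broken), "missing evoked")
})

test_that("noiseless amplitudes satisfy every registered ordering", {
  ft <- cached_noiseless_features()$restricted
  pooled <- ft[ft$electrode == "pooled", ]
  reg <- marker_registry()
  cats <- stimulus_categories()
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    vals <- pooled[pooled$marker == r$marker, ]
    if (r$marker == "PN300") {
      expect_true(all(vals$amplitude_uv[vals$category %in% cats$visual] < 0))
      expect_true(all(vals$amplitude_uv[vals$category %in% cats$auditory] > 0))
      next
    }
    adj <- erpmarkers:::.adjust_polarity(vals$amplitude_uv, r$polarity)
    names(adj) <- vals$category
    for (pair in r$contrast[[1]]) {
      expect_gt(adj[[pair[1]]], adj[[pair[2]]])
    }
  }
})

test_that("feature tables round-trip through CSV", {
  ft <- cached_noiseless_features()$restricted
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-9)
})
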