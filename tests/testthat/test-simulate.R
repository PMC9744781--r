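test_that("default schedule delivers the full stimulus set in runs", {
  cfg <- sim_config()
  sch <- generate_schedule(cfg, subject_seed = 7)
  expect_equal(nrow(sch), 400)
  expect_equal(sum(sch$modality == "visual"), 280)
  expect_equal(sum(sch$modality == "auditory"), 120)
  expect_equal(as.vector(table(sch$run)), c(rep(35, 8), rep(30, 4)))
  expect_equal(as.vector(table(sch$category)), rep(40, 10))
  expect_true(all(diff(sch$onset_sample) > 0))
  # inter-onset intervals within a run: 1500 ms stimulus + 400-600 ms ISI
  ms <- sch$onset_s * 1000
  within_run <- diff(sch$run) == 0
  iois <- diff(ms)[within_run]
  expect_true(all(iois >= 1900 - 2 & iois <= 2100 + 2))
})

test_that("schedules are deterministic given the seed", {
  cfg <- sim_config()
  expect_identical(generate_schedule(cfg, subject_seed = 3),
                   generate_schedule(cfg, subject_seed = 3))
  expect_false(identical(generate_schedule(cfg, subject_seed = 3),
                         generate_schedule(cfg, subject_seed = 4)))
})

test_that("uneven trial counts fall back to nearest-balanced runs", {
  cfg <- sim_config(trials_per_category = 6)
  expect_message(sch <- generate_schedule(cfg, subject_seed = 1),
                 "nearest-balanced")
  expect_equal(nrow(sch), 60)
  expect_equal(as.vector(table(sch$category)), rep(6, 10))
})

test_that("background noise hits its per-channel sd and spectral exponent", {
  cfg <- sim_config(noise_sd = 4)
  set.seed(11)
  nz <- synthesize_noise(4, 512 * 90, cfg)  # 90 s
  sds <- apply(nz, 1, sd)
  expect_true(all(abs(sds - 4) / 4 < 0.05))
  expect_equal(synthesize_noise(3, 100, sim_config(noise_sd = 0)),
               matrix(0, 3, 100))
  # log-periodogram slope of the power-law part recovers the exponent
  for (a in c(0.7, 1, 1.5)) {
    set.seed(100 + a * 10)
    x <- pink_noise(2^18, exponent = a)
    sp <- stats::spec.pgram(stats::ts(x, frequency = 512), spans = 31,
                            plot = FALSE, taper = 0)
    sel <- sp$freq >= 1 & sp$freq <= 30
    slope <- unname(stats::coef(
      stats::lm(log(sp$spec[sel]) ~ log(sp$freq[sel]))
    )[2])
    expect_lt(abs(-slope - a), 0.3)
  }
})

test_that("the 10 Hz alpha component shows as a spectral peak", {
  cfg <- sim_config(noise_sd = 4, alpha_amplitude = 2)
  set.seed(5)
  x <- synthesize_noise(1, 512 * 60, cfg)[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 512), spans = 15,
                          plot = FALSE, taper = 0)
  in_band <- mean(sp$spec[sp$freq >= 9 & sp$freq <= 11])
  flank <- mean(sp$spec[(sp$freq >= 6 & sp$freq <= 7.5) |
                          (sp$freq >= 13 & sp$freq <= 15)])
  expect_gt(in_band / flank, 2)
})

test_that("blink injection is frontal, biphasic and rate-controlled", {
  cfg <- sim_config(blink_rate = 10, blink_amplitude = 120)
  m <- build_default_montage()
  rec <- make_recording(matrix(0, 128, 512 * 60))
  set.seed(2)
  out <- inject_blinks(rec, cfg)
  expect_gt(length(out$blink_onsets), 0)
  # caller's matrix untouched (no in-place surprise)
  expect_equal(max(abs(rec$data)), 0)
  veog <- out$data[rownames(out$data) == "VEOG", ]
  # isolated blink peak-to-peak equals blink_amplitude
  o1 <- out$blink_onsets[1]
  seg <- veog[o1:(o1 + 160)]
  expect_equal(max(seg) - min(seg), 120, tolerance = 1e-6)
  # posterior channels barely affected
  oz <- out$data[rownames(out$data) == "Oz", ]
  expect_lt(max(abs(oz)), 0.05 * 120)
  # zero rate: recording unchanged
  expect_identical(inject_blinks(rec, sim_config(blink_rate = 0))$data,
                   rec$data)
})

test_that("simulate_subject is bit-reproducible and additive", {
  cfg <- sim_config(trials_per_category = 4, seed = 42)
  s1 <- simulate_subject(cfg, 1)
  s2 <- simulate_subject(cfg, 1)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_identical(s1$schedule, s2$schedule)
  s3 <- simulate_subject(cfg, 2)
  expect_false(identical(s1$recording$data, s3$recording$data))

  # additivity: recording minus the same-seed noise equals the deterministic
  # template sum (blink-free configuration)
  cfg0 <- sim_config(trials_per_category = 4, seed = 42, blink_rate = 0)
  sim <- simulate_subject(cfg0, 1)
  set.seed(erpmarkers:::.subject_seed(cfg0, 1))
  sch <- generate_schedule(cfg0)
  tpl <- default_templates()
  gains <- stats::setNames(
    stats::rlnorm(length(tpl), -cfg0$subject_gain_sd^2 / 2,
                  cfg0$subject_gain_sd), names(tpl))
  noise <- synthesize_noise(nrow(sim$recording$data),
                            ncol(sim$recording$data), cfg0)
  resid <- sim$recording$data - noise
  expect_identical(sch, sim$schedule)
  m <- build_default_montage()
  expected <- matrix(0, nrow(resid), ncol(resid))
  n_pre <- 51
  for (cat in unique(sch$category)) {
    pat <- Reduce(`+`, lapply(names(tpl), function(nm) {
      render_component(tpl[[nm]], cat, gains[[nm]], cfg0$fs, m)
    }))
    for (on in sch$onset_sample[sch$category == cat]) {
      cols <- (on - n_pre):(on - n_pre + 818)
      expected[, cols] <- expected[, cols] + pat
    }
  }
  expect_equal(unname(resid), expected, tolerance = 1e-9)
})

test_that("a noiseless simulation reproduces the injected templates", {
  res <- cached_noiseless()
  expect_equal(res$n_rejected, 0)
  tpl <- default_templates()
  m <- build_default_montage()
  fs <- 512
  for (cat in c("adult_face", "music")) {
    expected <- Reduce(`+`, lapply(names(tpl), function(nm) {
      render_component(tpl[[nm]], cat, 1, fs, m)
    }))
    # baseline correction subtracts the (tiny) pre-stimulus template mean
    bl <- rowMeans(expected[, 1:51])
    expected <- expected - bl
    expect_equal(unname(res$evokeds[[cat]]$data), expected,
                 tolerance = 1e-6)
  }
})

test_that("default blink calibration rejects roughly 5% of epochs", {
  # one-subject spot check; the cohort-level band is covered in acceptance
  cfg <- sim_config(seed = 99)
  res <- process_subject(cfg, 1)
  expect_gt(res$n_rejected / res$n_epochs, 0.01)
  expect_lt(res$n_rejected / res$n_epochs, 0.12)
})
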