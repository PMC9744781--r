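# Synthetic continuous EEG under the passive audiovisual paradigm:
# X = s_i + n_i, with s_i the summed component templates of the stimulated
# category and n_i background noise (white + 1/f + alpha) plus ocular
# artifacts.

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults reproduce the study
#' conditions: 20 analysed subjects, 10 stimulus categories x 40 trials
#' (280 visual stimuli in 8 runs, 120 auditory in 4 runs), 1500 ms stimulus
#' duration, ISI 500 +/- 100 ms, 512 Hz, 126-channel 10/5 montage + HEOG/VEOG.
#'
#' @param n_subjects subjects in the cohort.
#' @param trials_per_category trials per stimulus category.
#' @param fs sampling rate (Hz).
#' @param stimulus_duration_ms,isi_base_ms,isi_jitter_ms trial timing (ms);
#'   the inter-stimulus interval is drawn uniformly from
#'   `isi_base_ms +/- isi_jitter_ms`.
#' @param noise_sd total background-noise standard deviation per channel (uV).
#' @param one_over_f_exponent spectral exponent `a` of the 1/f^a part.
#' @param alpha_amplitude RMS amplitude (uV) of the 10 Hz alpha component
#'   (must be < `noise_sd`; set 0 to disable).
#' @param blink_rate ocular-artifact rate (blinks/min); the default is
#'   calibrated so that the 50 uV peak-to-peak criterion rejects ~5% of
#'   epochs on the default cohort.
#' @param blink_amplitude VEOG peak-to-peak amplitude of one blink (uV).
#' @param subject_gain_sd sd (log scale) of the per-subject, per-component
#'   multiplicative gain (mean gain 1).
#' @param seed cohort master seed; per-subject seeds derive from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 20, trials_per_category = 40, fs = 512,
                       stimulus_duration_ms = 1500, isi_base_ms = 500,
                       isi_jitter_ms = 100, noise_sd = 4,
                       one_over_f_exponent = 1, alpha_amplitude = 1.5,
                       blink_rate = 1.75, blink_amplitude = 120,
                       subject_gain_sd = 0.2, seed = 1) {
  stopifnot(fs > 0, isi_jitter_ms < isi_base_ms, noise_sd >= 0,
            alpha_amplitude >= 0, blink_rate >= 0, trials_per_category >= 1)
  # alpha is a component of the total noise_sd budget
  alpha_amplitude <- min(alpha_amplitude, noise_sd)
  structure(
    list(n_subjects = n_subjects, categories = stimulus_categories(),
         trials_per_category = trials_per_category, fs = fs,
         stimulus_duration_ms = stimulus_duration_ms,
         isi_base_ms = isi_base_ms, isi_jitter_ms = isi_jitter_ms,
         noise_sd = noise_sd, one_over_f_exponent = one_over_f_exponent,
         alpha_amplitude = alpha_amplitude, blink_rate = blink_rate,
         blink_amplitude = blink_amplitude,
         subject_gain_sd = subject_gain_sd, seed = seed,
         n_visual_runs = 8, n_auditory_runs = 4,
         run_gap_ms = 2000, start_pad_ms = 2000),
    class = "sim_config"
  )
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML; keys are the arguments of [sim_config()]; absent keys
#' keep their defaults.
#' @param path YAML file path.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package")
  }
  vals <- yaml::read_yaml(path)
  ok <- intersect(names(vals), names(formals(sim_config)))
  do.call(sim_config, vals[ok])
}

.subject_seed <- function(config, subject_index) {
  (config$seed %% 100000L) * 10007L + subject_index * 7919L
}

# Split `total` trials as evenly as possible over `n_runs`, rotating the
# remainder by `offset` so run sizes balance across categories.
.split_runs <- function(total, n_runs, offset = 0) {
  base <- total %/% n_runs
  extra <- total %% n_runs
  out <- rep(base, n_runs)
  if (extra > 0) {
    pos <- ((offset + seq_len(extra) - 1L) %% n_runs) + 1L
    out[pos] <- out[pos] + 1L
    message("trials per category (", total, ") not divisible by ", n_runs,
            " runs; using nearest-balanced assignment")
  }
  out
}

#' Generate a stimulus schedule for one subject
#'
#' Visual stimuli are presented in random order within 8 runs, auditory
#' stimuli within 4 runs. With defaults: 280 visual + 120 auditory = 400
#' events, inter-onset interval = 1500 ms stimulus + uniform 400-600 ms ISI.
#'
#' @param config a [sim_config()].
#' @param subject_seed optional integer; when given, seeds the RNG so the
#'   schedule is reproducible in isolation.
#' @return tibble: `onset_sample` (1-based), `onset_s`, `category`, `run`,
#'   `modality`; onsets strictly increasing.
#' @export
generate_schedule <- function(config, subject_seed = NULL) {
  if (!is.null(subject_seed)) set.seed(subject_seed)
  cats <- config$categories
  tpc <- config$trials_per_category
  runs <- list()
  for (r in seq_len(config$n_visual_runs)) runs[[r]] <- character(0)
  for (ci in seq_along(cats$visual)) {
    counts <- .split_runs(tpc, config$n_visual_runs, ci)
    for (r in seq_len(config$n_visual_runs)) {
      runs[[r]] <- c(runs[[r]], rep(cats$visual[ci], counts[r]))
    }
  }
  n_vr <- config$n_visual_runs
  for (r in seq_len(config$n_auditory_runs)) runs[[n_vr + r]] <- character(0)
  for (ci in seq_along(cats$auditory)) {
    counts <- .split_runs(tpc, config$n_auditory_runs, ci)
    for (r in seq_len(config$n_auditory_runs)) {
      runs[[n_vr + r]] <- c(runs[[n_vr + r]], rep(cats$auditory[ci], counts[r]))
    }
  }
  entries <- list()
  t_ms <- config$start_pad_ms
  for (r in seq_along(runs)) {
    seq_cat <- sample(runs[[r]])
    for (cat in seq_cat) {
      entries[[length(entries) + 1L]] <- list(onset_ms = t_ms, category = cat,
                                              run = r)
      isi <- stats::runif(1, config$isi_base_ms - config$isi_jitter_ms,
                          config$isi_base_ms + config$isi_jitter_ms)
      t_ms <- t_ms + config$stimulus_duration_ms + isi
    }
    t_ms <- t_ms + config$run_gap_ms
  }
  onset_ms <- vapply(entries, `[[`, numeric(1), "onset_ms")
  tibble::tibble(
    onset_sample = as.integer(round(onset_ms / 1000 * config$fs)) + 1L,
    onset_s = onset_ms / 1000,
    category = vapply(entries, `[[`, character(1), "category"),
    run = vapply(entries, `[[`, integer(1), "run"),
    modality = ifelse(.data$category %in% cats$visual, "visual", "auditory")
  )
}

#' Write / read an event schedule as TSV
#' @param schedule tibble from [generate_schedule()].
#' @param path file path.
#' @export
write_schedule_tsv <- function(schedule, path) {
  utils::write.table(schedule, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule_tsv
#' @export
read_schedule_tsv <- function(path) {
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      stringsAsFactors = FALSE))
}

# First-order pole/zero cascade approximating an f^(-a/2) amplitude response
# between ~0.01 Hz and ~100 Hz (log-spaced poles, zeros offset by g^(a/2)).
# Returns biquad coefficient vectors for the bilinear-transformed sections.
.pink_sections <- function(exponent, fs, n_sections = 9, f_lo = 0.01,
                           f_hi = 100) {
  if (exponent <= 0) {
    return(list(b0 = 1, b1 = 0, a1 = 0))
  }
  g <- (f_hi / f_lo)^(1 / n_sections)
  fp <- f_lo * g^(seq_len(n_sections) - 1)
  fz <- fp * g^(exponent / 2)
  K <- 2 * fs
  wp <- 2 * pi * fp
  wz <- 2 * pi * fz
  list(
    b0 = (wp / wz) * (wz + K) / (wp + K),
    b1 = (wp / wz) * (wz - K) / (wp + K),
    a1 = (wp - K) / (wp + K)
  )
}

# Relative weights of the flat and power-law parts of the broadband noise
# (pre-normalization; the channel is rescaled to noise_sd afterwards).
.white_weight <- 0.02
.pink_weight <- 1
.alpha_hz <- 10
.alpha_env_hz <- 4

#' Synthesize multichannel background EEG noise
#'
#' Channel-wise independent noise with a flat (white) + `1/f^a` power-law +
#' 10 Hz alpha-band composite spectrum. The broadband part is one white
#' stream passed through a linear shaping filter (flat gain plus a log-spaced
#' pole/zero cascade approximating the power law); the alpha part is an
#' independently drawn, slowly amplitude-modulated 10 Hz narrowband
#' oscillation. Each channel is scaled so its total standard deviation is
#' `noise_sd` (alpha contributing `alpha_amplitude` RMS of it).
#'
#' @param n_channels,n_samples output dimensions.
#' @param config a [sim_config()] (fields `noise_sd`, `one_over_f_exponent`,
#'   `alpha_amplitude`, `fs`).
#' @return numeric matrix `n_channels x n_samples` (uV).
#' @export
synthesize_noise <- function(n_channels, n_samples, config = sim_config()) {
  stopifnot(n_channels > 0, n_samples > 0)
  if (config$noise_sd == 0) return(matrix(0, n_channels, n_samples))
  sec <- .pink_sections(config$one_over_f_exponent, config$fs)
  alpha <- min(config$alpha_amplitude, config$noise_sd)
  sd_bb <- sqrt(config$noise_sd^2 - alpha^2)
  cpp_shaped_noise(as.integer(n_samples), as.integer(n_channels),
                   sec$b0, sec$b1, sec$a1,
                   .white_weight, .pink_weight, sd_bb,
                   alpha, .alpha_hz, .alpha_env_hz, config$fs)
}

#' Power-law (1/f^a) noise, single channel
#'
#' The power-law part of the background-noise model in isolation, unit
#' variance. Exposed so its spectral exponent can be checked directly.
#'
#' @param n_samples length.
#' @param exponent spectral exponent `a` (PSD proportional to `1/f^a`).
#' @param fs sampling rate (Hz).
#' @export
pink_noise <- function(n_samples, exponent = 1, fs = 512) {
  sec <- .pink_sections(exponent, fs)
  drop(cpp_shaped_noise(as.integer(n_samples), 1L, sec$b0, sec$b1, sec$a1,
                        0, 1, 1, 0, .alpha_hz, .alpha_env_hz, fs))
}

# Biphasic 300 ms blink waveform, peak-to-peak normalized to 1.
.blink_wave <- function(fs, dur_ms = 300) {
  n <- floor(dur_ms / 1000 * fs)
  t <- seq_len(n) / n
  w <- sin(2 * pi * t) * sin(pi * t)^2
  w / (max(w) - min(w))
}

# Channel weights of a blink: VEOG 1, HEOG 0.25, scalp decaying away from the
# anterior pole (Fpz).
.blink_weights <- function(montage) {
  d <- .nearest_center_deg(montage, "Fpz")
  c(0.5 * exp(-d / 30), HEOG = 0.25, VEOG = 1)
}

#' Inject ocular (blink) artifacts into a recording
#'
#' Adds frontally dominant biphasic deflections at Poisson-distributed times:
#' full amplitude (peak-to-peak `blink_amplitude` uV) on VEOG, decaying
#' toward posterior scalp channels. With `blink_rate = 0` the recording is
#' returned unchanged.
#'
#' @param recording an `erp_recording` (with EOG channels).
#' @param config a [sim_config()].
#' @param in_place allow mutating the supplied voltage matrix (internal use).
#' @return The recording with artifacts added; blink onset samples are stored
#'   in `recording$blink_onsets`.
#' @export
inject_blinks <- function(recording, config = sim_config(),
                          in_place = FALSE) {
  if (config$blink_rate == 0) return(recording)
  n <- ncol(recording$data)
  dur_min <- n / recording$fs / 60
  n_blinks <- stats::rpois(1, config$blink_rate * dur_min)
  if (n_blinks == 0) return(recording)
  wave <- .blink_wave(recording$fs) * config$blink_amplitude
  weights <- .blink_weights(recording$montage)
  pattern <- weights %o% wave
  onsets <- sort(as.integer(stats::runif(n_blinks, 1, n - length(wave) - 1)))
  if (!in_place) recording$data <- recording$data + 0  # preserve caller copy
  cpp_add_pattern(recording$data, onsets - 1L, pattern,
                  seq_len(nrow(pattern)) - 1L)
  recording$blink_onsets <- onsets
  recording
}

.new_recording <- function(data, fs, montage) {
  rownames(data) <- c(montage$channels$label, montage$eog_channels)
  structure(
    list(data = data, fs = fs, montage = montage,
         eog_index = nrow(montage$channels) + seq_along(montage$eog_channels)),
    class = "erp_recording"
  )
}

#' @export
print.erp_recording <- function(x, ...) {
  cat("<erp_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples (", round(ncol(x$data) / x$fs, 1), " s @ ", x$fs, " Hz)\n",
      sep = "")
  invisible(x)
}

# Precomputed rank-1 bases of all templates over the epoch span: per
# template, the unit spatial weight vector (montage channels + zero EOG
# rows, split by hemisphere for asymmetric templates) and the Gaussian time
# course. A category's deterministic pattern is then one small matrix
# product: sum_t gain_t * amp_t(category) * w_t %o% course_t.
.template_basis <- function(templates, montage, fs, t_pre_ms = 100,
                            t_post_ms = 1500) {
  n_pre <- floor(t_pre_ms / 1000 * fs)
  n_post <- floor(t_post_ms / 1000 * fs)
  t_ms <- (seq_len(n_pre + n_post) - n_pre - 1) / fs * 1000
  n_eog <- length(montage$eog_channels)
  hemi <- montage$channels$hemisphere
  lapply(templates, function(tpl) {
    w <- c(.template_weights(tpl, montage), rep(0, n_eog))
    list(
      w = w,
      hemi = c(hemi, rep("midline", n_eog)),
      course = exp(-((t_ms - tpl$peak_ms)^2) / (2 * tpl$sd_ms^2)),
      amps = tpl$amps, amps_right = tpl$amps_right
    )
  })
}

# Deterministic signal for one category: summed applicable templates scaled
# by the subject's per-component gains, over the epoch span. Returns NULL
# when no template applies, else list(pattern, rows) with `rows` the
# channels carrying signal.
.category_pattern <- function(category, basis, gains) {
  cols <- list()
  courses <- list()
  for (nm in names(basis)) {
    b <- basis[[nm]]
    amp_l <- b$amps[category]
    amp_r <- b$amps_right[category]
    if (is.na(amp_l)) next
    amp_ch <- if (isTRUE(all.equal(unname(amp_l), unname(amp_r)))) {
      b$w * amp_l
    } else {
      b$w * ifelse(b$hemi == "right", amp_r,
                   ifelse(b$hemi == "left", amp_l, (amp_l + amp_r) / 2))
    }
    cols[[nm]] <- gains[[nm]] * amp_ch
    courses[[nm]] <- b$course
  }
  if (length(cols) == 0) return(NULL)
  A <- do.call(cbind, cols)
  pattern <- A %*% do.call(rbind, courses)
  list(pattern = pattern, rows = seq_len(nrow(A)))
}

#' Simulate one subject's continuous recording
#'
#' Renders the additive model: background noise plus, at every stimulus
#' onset, the summed component templates of the stimulated category (scaled
#' by per-subject log-normal component gains), plus injected blink
#' artifacts. Fully determined by `(config, subject_index)`.
#'
#' @param config a [sim_config()].
#' @param subject_index subject number (seeds the subject's RNG stream).
#' @param templates component templates, default [default_templates()].
#' @param montage default montage.
#' @param noiseless logical: skip noise and blinks (deterministic signal
#'   only), regardless of config.
#' @return list with elements `recording` (`erp_recording`), `schedule`
#'   (tibble) and `gains` (named numeric).
#' @export
simulate_subject <- function(config = sim_config(), subject_index = 1,
                             templates = default_templates(),
                             montage = build_default_montage(),
                             noiseless = FALSE) {
  set.seed(.subject_seed(config, subject_index))
  schedule <- generate_schedule(config)
  gains <- stats::setNames(
    stats::rlnorm(length(templates), meanlog = -config$subject_gain_sd^2 / 2,
                  sdlog = config$subject_gain_sd),
    names(templates)
  )
  n_ch <- nrow(montage$channels) + length(montage$eog_channels)
  n <- max(schedule$onset_sample) + as.integer(2.5 * config$fs)
  if (noiseless || config$noise_sd == 0) {
    data <- matrix(0, n_ch, n)
  } else {
    data <- synthesize_noise(n_ch, n, config)
  }
  rec <- .new_recording(data, config$fs, montage)
  n_pre <- floor(100 / 1000 * config$fs)
  basis <- .template_basis(templates, montage, config$fs)
  for (cat in config$categories$all) {
    cp <- .category_pattern(cat, basis, gains)
    onsets <- schedule$onset_sample[schedule$category == cat]
    if (!is.null(cp) && length(onsets) > 0) {
      cpp_add_pattern(rec$data, onsets - 1L - n_pre, cp$pattern, cp$rows - 1L)
    }
  }
  if (!noiseless) rec <- inject_blinks(rec, config, in_place = TRUE)
  list(recording = rec, schedule = schedule, gains = gains)
}
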