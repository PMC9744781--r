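# Shared fixtures. Full-scale cohorts are expensive (~1 min each), so they
# are simulated once per test run and cached for every block that needs them.

.fixture_cache <- new.env(parent = emptyenv())

# Default-condition cohort (20 subjects, 400 epochs each) for a given seed.
cached_cohort <- function(seed) {
  key <- paste0("cohort_", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_cohort(sim_config(seed = seed))
  }
  .fixture_cache[[key]]
}

# One noiseless, gain-free subject processed end to end: the deterministic
# reference for template-recovery and ordering tests.
cached_noiseless <- function() {
  if (is.null(.fixture_cache$noiseless)) {
    cfg <- sim_config(noise_sd = 0, blink_rate = 0, subject_gain_sd = 0)
    .fixture_cache$noiseless <- suppressMessages(
      process_subject(cfg, 1, noiseless = TRUE)
    )
  }
  .fixture_cache$noiseless
}

cached_noiseless_features <- function() {
  if (is.null(.fixture_cache$noiseless_features)) {
    ev <- list(S01 = cached_noiseless()$evokeds)
    .fixture_cache$noiseless_features <- list(
      restricted = extract_feature_table(ev),
      full = extract_feature_table(ev, restrict = FALSE)
    )
  }
  .fixture_cache$noiseless_features
}

# Minimal single/multi-channel recording for filter and epoching tests.
make_recording <- function(data, fs = 512, montage = build_default_montage()) {
  n_needed <- nrow(montage$channels) + length(montage$eog_channels)
  if (nrow(data) < n_needed) {
    data <- rbind(data, matrix(0, n_needed - nrow(data), ncol(data)))
  }
  erpmarkers:::.new_recording(data, fs, montage)
}

# Small epochs object built directly from a tensor.
make_epochs <- function(tensor, fs = 512, n_pre = 51,
                        categories = rep("adult_face", dim(tensor)[3])) {
  montage <- build_default_montage()
  n_ch <- dim(tensor)[1]
  labels <- c(montage$channels$label,
              montage$eog_channels)[seq_len(n_ch)]
  structure(
    list(tensor = tensor,
         time_ms = (seq_len(dim(tensor)[2]) - n_pre - 1) / fs * 1000,
         categories = categories, fs = fs, montage = montage,
         channel_names = labels,
         eog_index = integer(0),
         kept = rep(TRUE, dim(tensor)[3]),
         rejection_log = tibble::tibble(epoch = integer(0),
                                        channel = character(0),
                                        peak_to_peak_uv = numeric(0))),
    class = "erp_epochs"
  )
}

# A synthetic unrestricted feature table (pooled rows only) with a given
# per-(subject, category, marker) amplitude function.
make_feature_table <- function(n_subjects, amp_fun) {
  cats <- stimulus_categories()$all
  markers <- marker_registry()$marker
  grid <- expand.grid(subject = sprintf("S%02d", seq_len(n_subjects)),
                      category = cats, marker = markers,
                      stringsAsFactors = FALSE)
  tibble::tibble(
    subject = grid$subject, category = grid$category, marker = grid$marker,
    electrode = "pooled",
    amplitude_uv = mapply(amp_fun, grid$subject, grid$category, grid$marker)
  )
}
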