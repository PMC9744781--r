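# Marker registry and mean-area amplitude extraction.

.pairs <- function(...) {
  lapply(list(...), function(p) c(p[[1]], p[[2]]))
}

#' ERP marker registry
#'
#' The 16 category-sensitive ERP markers analysed by the package, with their
#' measurement windows (ms post-stimulus, half-open `[start, end)`), electrode
#' sets, polarity, the stimulus categories each marker applies to, and the
#' expected category orderings (pairs `greater > lesser` in magnitude; for
#' negative components "greater" means more negative). PN300 carries no pair
#' ordering: its registered property is its sign, negative under visual and
#' positive under auditory stimulation.
#'
#' Markers: visual-living N170 (150-190 ms, occipitotemporal), anterior N2
#' (250-350), centroparietal P2 (300-350), frontal P300 (400-600), CPP
#' (400-600), LCPP (600-900), AN (200-600), AP (600-800); visual-non-living
#' N80 (90-130, mesial occipital) and N170; auditory P2 (150-300), P300
#' (400-500), N400 (450-650), AN (400-600), LP (900-1200); and the
#' cross-modal PN300 (200-400, fronto-central).
#'
#' @return A tibble with one row per marker: `marker`, `modality`,
#'   `window_start_ms`, `window_end_ms`, `electrodes` (list), `polarity`,
#'   `applies_to` (list of category labels), `contrast` (list of ordered
#'   category pairs).
#' @export
marker_registry <- function() {
  cats <- stimulus_categories()
  faces <- c("adult_face", "infant_face", "animal_face")
  living4 <- c("infant_face", "adult_face", "animal_face", "body")
  nonliving <- c("word_visual", "checkerboard", "object")
  aud <- cats$auditory
  reg <- tibble::tribble(
    ~marker, ~modality, ~window_start_ms, ~window_end_ms, ~electrodes, ~polarity, ~applies_to, ~contrast,
    "N170_living", "visual", 150, 190, c("PPO9h", "PPO10h", "P7", "P8"), "-", faces,
      .pairs(c("adult_face", "animal_face"), c("infant_face", "animal_face")),
    "N2_living", "visual", 250, 350, c("AFp3h", "AFp4h", "Fpz", "CPz", "Cz"), "-", living4,
      .pairs(c("infant_face", "adult_face"), c("infant_face", "animal_face"),
             c("infant_face", "body")),
    "P2_living", "visual", 300, 350, c("CPz", "Pz"), "+", living4,
      .pairs(c("body", "infant_face"), c("body", "adult_face"),
             c("body", "animal_face"), c("animal_face", "adult_face")),
    "P300_living", "visual", 400, 600, c("AFz", "Fz"), "+", living4,
      .pairs(c("animal_face", "infant_face"), c("animal_face", "adult_face"),
             c("animal_face", "body"), c("infant_face", "adult_face")),
    "CPP_living", "visual", 400, 600, c("CPz", "Pz"), "+", c("infant_face", "body"),
      .pairs(c("infant_face", "body")),
    "LCPP_living", "visual", 600, 900, c("CPz", "Pz"), "+", c("infant_face", "body"),
      .pairs(c("infant_face", "body")),
    "AN_living", "visual", 200, 600, c("AFp3h", "AFp4h", "AFz", "Fpz", "Fz"), "-", living4,
      .pairs(c("infant_face", "adult_face"), c("infant_face", "body"),
             c("infant_face", "animal_face"), c("adult_face", "body"),
             c("adult_face", "animal_face")),
    "AP_living", "visual", 600, 800, c("AFz", "Fz"), "+", c("animal_face", "adult_face"),
      .pairs(c("animal_face", "adult_face")),
    "N80_nonliving", "visual", 90, 130, c("Oz", "Iz"), "-", nonliving,
      .pairs(c("checkerboard", "word_visual"), c("checkerboard", "object")),
    "N170_nonliving", "visual", 150, 190, c("PPO9h", "PPO10h", "P7", "P8"), "-", nonliving,
      .pairs(c("word_visual", "checkerboard"), c("checkerboard", "object")),
    "P2_auditory", "auditory", 150, 300, c("FFC1h", "FFC2h", "C1", "C2"), "+", aud,
      .pairs(c("vocalization", "music"), c("word_auditory", "music")),
    "P300_auditory", "auditory", 400, 500, c("FFC1h", "FFC2h", "C1", "C2"), "+", aud,
      .pairs(c("music", "vocalization"), c("music", "word_auditory")),
    "N400_auditory", "auditory", 450, 650, c("CCP1h", "CCP2h", "P3", "P4"), "-", aud,
      .pairs(c("word_auditory", "music"), c("word_auditory", "vocalization")),
    "AN_auditory", "auditory", 400, 600, c("AF3", "AF4", "AF7", "AF8"), "-", aud,
      .pairs(c("vocalization", "word_auditory"), c("vocalization", "music")),
    "LP_auditory", "auditory", 900, 1200, c("AF3", "AF4", "AF7", "AF8"), "+", aud,
      .pairs(c("vocalization", "music"), c("word_auditory", "music")),
    "PN300", "both", 200, 400, c("Fz", "Cz"), "+/-", cats$all, list()
  )
  # every registry electrode must resolve in the default montage
  m <- build_default_montage()
  for (els in reg$electrodes) .match_label(els, m)
  reg
}

# ms -> post-stimulus sample indices (0-based), half-open [start, end),
# floor conversion; the single convention shared with epoch extraction.
.window_samples <- function(start_ms, end_ms, fs) {
  i0 <- floor(start_ms / 1000 * fs)
  i1 <- floor(end_ms / 1000 * fs)
  seq.int(i0, i1 - 1L)
}

#' Mean area amplitude of a marker on an evoked waveform
#'
#' Mean of the baseline-referenced voltage over the marker's measurement
#' window (half-open in ms, floor sample conversion), per electrode, plus the
#' mean pooled over the marker's electrode set. This is the conventional
#' "mean area amplitude" in uV (an average, not an integral in uV*ms).
#'
#' @param evoked an `erp_evoked` (see [average_epochs()]), baseline-corrected.
#' @param marker a marker name from [marker_registry()], or a one-row subset
#'   of the registry.
#' @param registry marker registry tibble.
#' @return A tibble with columns `electrode` and `amplitude_uv`; the pooled
#'   mean is the row with `electrode == "pooled"`.
#' @export
mean_amplitude <- function(evoked, marker, registry = marker_registry()) {
  if (is.character(marker)) {
    row <- registry[registry$marker == marker, ]
    if (nrow(row) != 1) abort(paste0("unknown marker '", marker, "'"))
  } else {
    row <- marker
  }
  fs <- evoked$fs
  smp <- .window_samples(row$window_start_ms, row$window_end_ms, fs)
  post0 <- which(evoked$time_ms >= 0)[1]  # column of sample t = 0
  cols <- smp + post0
  if (min(cols) < 1 || max(cols) > length(evoked$time_ms)) {
    abort(paste0(row$marker, ": window outside the epoch span"))
  }
  els <- .match_label(row$electrodes[[1]], evoked$montage)
  ei <- match(els, rownames(evoked$data))
  if (anyNA(ei)) abort("marker electrode missing from evoked data")
  per <- unname(rowMeans(evoked$data[ei, cols, drop = FALSE]))
  tibble::tibble(
    electrode = c(els, "pooled"),
    amplitude_uv = c(per, mean(per))
  )
}

#' Extract the ANOVA-ready feature table
#'
#' Long-format table of mean area amplitudes for every subject x category x
#' marker x electrode combination. Markers are measured only on the stimulus
#' categories they apply to (`restrict = TRUE`, the registry's applicability;
#' PN300 applies to all ten categories). With `restrict = FALSE` every marker
#' is measured on every category's evoked - the form consumed by the
#' classifier, where a fixed-length feature vector is needed per evoked.
#'
#' @param evokeds nested list: `evokeds[[subject]][[category]]` of
#'   `erp_evoked` objects (as produced by [simulate_cohort()] /
#'   [run_pipeline()]).
#' @param registry marker registry tibble.
#' @param restrict honour the registry's category applicability?
#' @return A tibble `subject, category, marker, electrode, amplitude_uv`
#'   (electrode includes the `"pooled"` row per marker).
#' @export
extract_feature_table <- function(evokeds, registry = marker_registry(),
                                  restrict = TRUE) {
  rows <- list()
  for (subj in names(evokeds)) {
    subj_ev <- evokeds[[subj]]
    for (i in seq_len(nrow(registry))) {
      row <- registry[i, ]
      cats <- if (restrict) row$applies_to[[1]] else names(subj_ev)
      missing <- setdiff(cats, names(subj_ev))
      if (length(missing) > 0) {
        abort(paste0("subject ", subj, ": missing evoked for categories ",
                     paste(missing, collapse = ", "), " (marker ",
                     row$marker, ")"))
      }
      for (cat in cats) {
        amp <- mean_amplitude(subj_ev[[cat]], row, registry)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          subject = subj, category = cat, marker = row$marker,
          electrode = amp$electrode, amplitude_uv = amp$amplitude_uv
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  stopifnot(all(is.finite(out$amplitude_uv)))
  out
}

#' Write / read a feature table as CSV
#'
#' @param features tibble from [extract_feature_table()].
#' @param path file path.
#' @return `read_feature_csv` returns the feature tibble.
#' @export
write_feature_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
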