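# End-to-end driver: simulate -> epoch -> reject -> baseline -> average ->
# features -> contrasts -> decoder.

#' Process one subject end to end
#'
#' Simulates (or takes) a continuous recording, epochs it around the event
#' onsets, applies peak-to-peak rejection and baseline correction, and
#' averages per category.
#'
#' @param config a [sim_config()].
#' @param subject_index subject number.
#' @param threshold_uv rejection threshold (uV).
#' @param templates,montage generator assets.
#' @param noiseless deterministic-signal-only simulation.
#' @return list: `evokeds` (named by category), `epochs` summary fields
#'   `n_epochs`, `n_rejected`, and the `rejection_log`.
#' @export
process_subject <- function(config = sim_config(), subject_index = 1,
                            threshold_uv = 50,
                            templates = default_templates(),
                            montage = build_default_montage(),
                            noiseless = FALSE) {
  sim <- simulate_subject(config, subject_index, templates, montage,
                          noiseless = noiseless)
  ep <- extract_epochs(sim$recording, sim$schedule)
  rm(sim)
  ep <- reject_artifacts(ep, threshold_uv)
  ep <- baseline_correct(ep)
  cats <- config$categories$all
  # grouped fast path; numerically the per-category mean of average_epochs()
  grp <- match(ep$categories, cats)
  means <- cpp_group_means(ep$tensor, dim(ep$tensor), grp, ep$kept,
                           length(cats))
  counts <- attr(means, "counts")
  if (any(counts == 0)) {
    abort(paste0("no kept epochs to average for category '",
                 cats[which(counts == 0)[1]], "'"))
  }
  d <- dim(ep$tensor)
  evokeds <- stats::setNames(lapply(seq_along(cats), function(ci) {
    data <- matrix(means[, ci], d[1], d[2])
    rownames(data) <- ep$channel_names
    .new_evoked(data, ep, cats[ci], "subject", subject_index, counts[ci])
  }), cats)
  list(evokeds = evokeds, n_epochs = length(ep$kept),
       n_rejected = sum(!ep$kept), rejection_log = ep$rejection_log)
}

#' Simulate and process a full cohort
#'
#' Runs [process_subject()] for every subject of the configuration and
#' collects the restricted (ANOVA-ready) and unrestricted (classifier-ready)
#' feature tables plus per-subject rejection statistics. Waveforms are
#' dropped after feature extraction unless `keep_evokeds`.
#'
#' @param config a [sim_config()].
#' @param threshold_uv rejection threshold (uV).
#' @param keep_evokeds retain all per-subject evoked waveforms (memory!).
#' @param progress print one line per subject.
#' @return An `erp_cohort` list: `features` (restricted), `features_full`
#'   (unrestricted), `rejection` tibble (`subject`, `n_epochs`,
#'   `n_rejected`), optional `evokeds`, and `config`.
#' @export
simulate_cohort <- function(config = sim_config(), threshold_uv = 50,
                            keep_evokeds = FALSE, progress = FALSE) {
  registry <- marker_registry()
  templates <- default_templates()
  montage <- build_default_montage()
  feats <- list()
  feats_full <- list()
  rej <- list()
  evokeds <- if (keep_evokeds) list() else NULL
  for (s in seq_len(config$n_subjects)) {
    res <- process_subject(config, s, threshold_uv, templates, montage)
    key <- sprintf("S%02d", s)
    ev <- stats::setNames(list(res$evokeds), key)
    feats[[s]] <- extract_feature_table(ev, registry, restrict = TRUE)
    feats_full[[s]] <- extract_feature_table(ev, registry, restrict = FALSE)
    rej[[s]] <- tibble::tibble(subject = key, n_epochs = res$n_epochs,
                               n_rejected = res$n_rejected)
    if (keep_evokeds) evokeds[[key]] <- res$evokeds
    if (progress) {
      message(key, ": ", res$n_rejected, "/", res$n_epochs,
              " epochs rejected")
    }
  }
  structure(
    list(features = dplyr::bind_rows(feats),
         features_full = dplyr::bind_rows(feats_full),
         rejection = dplyr::bind_rows(rej),
         evokeds = evokeds, config = config),
    class = "erp_cohort"
  )
}

#' @export
print.erp_cohort <- function(x, ...) {
  r <- x$rejection
  cat("<erp_cohort> ", nrow(r), " subjects, ",
      sum(r$n_epochs), " epochs (",
      sprintf("%.1f%%", 100 * sum(r$n_rejected) / sum(r$n_epochs)),
      " rejected)\n", sep = "")
  invisible(x)
}

#' Design arithmetic of the stimulation paradigm
#'
#' The bookkeeping constants of the recorded study design: participants,
#' stimuli per modality, single-trial ERPs, channels, and total processed
#' waveforms.
#'
#' @return one-row tibble.
#' @export
design_counts <- function() {
  recorded <- 30
  visual <- length(stimulus_categories()$visual) * 40
  auditory <- length(stimulus_categories()$auditory) * 40
  channels <- 126
  tibble::tibble(
    participants_recorded = recorded,
    participants_analyzed = 20,
    visual_stimuli = visual,
    auditory_stimuli = auditory,
    stimuli_per_subject = visual + auditory,
    single_trial_erps = recorded * (visual + auditory),
    channels = channels,
    waveforms = recorded * (visual + auditory) * channels
  )
}

#' Run the complete analysis pipeline
#'
#' simulate -> preprocess -> average -> extract -> contrasts -> classify.
#' Optionally writes the artifact bundle (features.csv, anova.json,
#' confusion.csv, report.txt, manifest.csv) to `out_dir`; every written file
#' gets a manifest entry with its stage, seed and md5 content hash.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param threshold_uv rejection threshold (uV).
#' @param progress print per-stage progress.
#' @return An `erp_pipeline` list: `cohort`, `contrasts`, `evaluation`,
#'   `report` (character lines), `manifest` (tibble or NULL).
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         threshold_uv = 50, progress = FALSE) {
  cohort <- simulate_cohort(config, threshold_uv, progress = progress)
  contrasts <- run_paper_contrasts(cohort$features)
  evaluation <- evaluate_loso(cohort$features_full)
  report <- c(
    sprintf("subjects: %d, epochs: %d, rejected: %d (%.2f%%)",
            nrow(cohort$rejection), sum(cohort$rejection$n_epochs),
            sum(cohort$rejection$n_rejected),
            100 * sum(cohort$rejection$n_rejected) /
              sum(cohort$rejection$n_epochs)),
    format_contrast_report(contrasts),
    sprintf("LOSO accuracy: %.1f%% (modality: %.1f%%)",
            100 * evaluation$accuracy, 100 * evaluation$modality_accuracy)
  )
  manifest <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      features = write_feature_csv(cohort$features,
                                   file.path(out_dir, "features.csv")),
      confusion = write_confusion_csv(evaluation,
                                      file.path(out_dir, "confusion.csv"))
    )
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(contrasts$anova,
                           file.path(out_dir, "anova.json"),
                           digits = NA)
      paths <- c(paths, anova = file.path(out_dir, "anova.json"))
    }
    writeLines(report, file.path(out_dir, "report.txt"))
    paths <- c(paths, report = file.path(out_dir, "report.txt"))
    manifest <- tibble::tibble(
      path = unname(paths), stage = names(paths),
      seed = config$seed,
      md5 = unname(tools::md5sum(unname(paths)))
    )
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  structure(
    list(cohort = cohort, contrasts = contrasts, evaluation = evaluation,
         report = report, manifest = manifest),
    class = "erp_pipeline"
  )
}

#' @export
print.erp_pipeline <- function(x, ...) {
  cat(x$report, sep = "\n")
  invisible(x)
}
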