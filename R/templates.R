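# Component templates: the deterministic ERP signal injected by the simulator.
#
# Each template is a rank-1 space-time pattern: a Gaussian time course peaking
# at `peak_ms` (sd `sd_ms`), times a spatial map equal to 1 at its center
# electrodes and decaying as exp(-(d/decay)^2) with great-circle distance d
# (degrees) to the nearest center. Per-category signed peak amplitudes (uV)
# encode the category selectivity of the marker; every pair constrained by the
# marker registry differs by >= 1 uV. Absolute magnitudes are package defaults
# on a 1-8 uV scale (the source study constrains orderings, not magnitudes).

#' Visual and auditory stimulus categories
#'
#' The ten stimulus categories of the paradigm: seven visual (three face
#' categories, bodies, written words, checkerboards, objects) and three
#' auditory (spoken words, emotional vocalizations, music).
#'
#' @return Named list with `visual`, `auditory` and `all` character vectors.
#' @export
stimulus_categories <- function() {
  visual <- c("infant_face", "adult_face", "animal_face", "body",
              "word_visual", "checkerboard", "object")
  auditory <- c("word_auditory", "vocalization", "music")
  list(visual = visual, auditory = auditory, all = c(visual, auditory))
}

.new_template <- function(name, modality, peak_ms, sd_ms, channels, amps,
                          amps_right = NULL, spatial_decay = 15) {
  structure(
    list(name = name, modality = modality, peak_ms = peak_ms, sd_ms = sd_ms,
         channels = channels, amps = amps,
         amps_right = if (is.null(amps_right)) amps else amps_right,
         spatial_decay = spatial_decay),
    class = "erp_template"
  )
}

#' @export
print.erp_template <- function(x, ...) {
  cat("<erp_template> ", x$name, " (", x$modality, "), peak ", x$peak_ms,
      " ms, centers: ", paste(x$channels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Default ERP component templates
#'
#' One template per marker in [marker_registry()] (16 in total). Peak
#' latencies sit inside the marker measurement windows; polarities follow the
#' component names (N* negative, P*/CPP/LCPP/LP/AP positive; PN300 negative
#' for visual and positive for auditory stimulation); and the per-category
#' amplitude maps reproduce every registered category ordering, e.g. a larger
#' (more negative) N170 to human than animal faces, a larger N80 to
#' checkerboards than words or objects, and a larger auditory P300 to music
#' than to the human voice. The word-selective N170 is left-lateralized: its
#' left-hemisphere amplitudes differ by category while the right-hemisphere
#' amplitudes do not.
#'
#' @return Named list of `erp_template` objects.
#' @export
default_templates <- function() {
  v <- stimulus_categories()$visual
  tpl <- list(
    .new_template("N170_living", "visual", 170, 10,
                  c("PPO9h", "PPO10h", "P7", "P8"),
                  c(adult_face = -8, infant_face = -8, animal_face = -5,
                    body = -4)),
    .new_template("N2_living", "visual", 300, 25,
                  c("AFp3h", "AFp4h", "Fpz", "CPz", "Cz"),
                  c(infant_face = -6, adult_face = -4.5, animal_face = -3.5,
                    body = -2)),
    .new_template("P2_living", "visual", 325, 12.5, c("CPz", "Pz"),
                  c(body = 6, animal_face = 4, infant_face = 3,
                    adult_face = 2.5)),
    .new_template("P300_living", "visual", 500, 50, c("AFz", "Fz"),
                  c(animal_face = 6, infant_face = 4, body = 3,
                    adult_face = 2.5)),
    .new_template("CPP_living", "visual", 500, 50, c("CPz", "Pz"),
                  c(infant_face = 5, body = 3)),
    .new_template("LCPP_living", "visual", 750, 75, c("CPz", "Pz"),
                  c(infant_face = 4, body = 2)),
    .new_template("AN_living", "visual", 280, 60,
                  c("AFp3h", "AFp4h", "AFz", "Fpz", "Fz"),
                  c(infant_face = -6, adult_face = -4.5, animal_face = -3,
                    body = -2)),
    .new_template("AP_living", "visual", 700, 50, c("AFz", "Fz"),
                  c(animal_face = 4, infant_face = 2.5, adult_face = 2,
                    body = 2)),
    .new_template("N80_nonliving", "visual", 110, 10, c("Oz", "Iz"),
                  c(checkerboard = -6, word_visual = -3.5, object = -2.5)),
    .new_template("N170_nonliving", "visual", 170, 10,
                  c("PPO9h", "PPO10h", "P7", "P8"),
                  amps = c(word_visual = -9, checkerboard = -5, object = -3),
                  amps_right = c(word_visual = -4, checkerboard = -4,
                                 object = -4)),
    .new_template("P2_auditory", "auditory", 225, 35,
                  c("FFC1h", "FFC2h", "C1", "C2"),
                  c(vocalization = 6, word_auditory = 5.5, music = 3)),
    .new_template("P300_auditory", "auditory", 450, 25,
                  c("FFC1h", "FFC2h", "C1", "C2"),
                  c(music = 6, word_auditory = 3.5, vocalization = 3)),
    .new_template("N400_auditory", "auditory", 550, 50,
                  c("CCP1h", "CCP2h", "P3", "P4"),
                  c(word_auditory = -6, vocalization = -3.5, music = -2.5)),
    .new_template("AN_auditory", "auditory", 500, 50,
                  c("AF3", "AF4", "AF7", "AF8"),
                  c(vocalization = -5, word_auditory = -3, music = -2)),
    .new_template("LP_auditory", "auditory", 1050, 75,
                  c("AF3", "AF4", "AF7", "AF8"),
                  c(vocalization = 5, word_auditory = 4.5, music = 2.5)),
    .new_template("PN300", "both", 300, 50, c("Fz", "Cz"),
                  c(stats::setNames(rep(-4, length(v)), v),
                    word_auditory = 4, vocalization = 4, music = 4))
  )
  stats::setNames(tpl, vapply(tpl, `[[`, character(1), "name"))
}

# Great-circle angular distance (degrees) between montage channels and a set
# of center labels; returns per-channel distance to the nearest center.
.nearest_center_deg <- function(montage, centers) {
  ch <- montage$channels
  th <- ch$theta * pi / 180
  ph <- ch$phi * pi / 180
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  centers <- .match_label(centers, montage)
  ci <- match(centers, ch$label)
  d <- matrix(NA_real_, nrow(ch), length(ci))
  for (j in seq_along(ci)) {
    dot <- dirs %*% dirs[ci[j], ]
    d[, j] <- acos(pmin(1, pmax(-1, dot))) * 180 / pi
  }
  apply(d, 1, min)
}

# Spatial weight vector over montage channels (EOG rows excluded): 1 at the
# template centers, Gaussian falloff with nearest-center distance elsewhere.
# Hemisphere-asymmetric templates weight left/right centers separately.
.template_weights <- function(template, montage) {
  w <- exp(-(.nearest_center_deg(montage, template$channels) /
               template$spatial_decay)^2)
  w
}

#' Render a component template for one category
#'
#' Produces the deterministic space-time pattern (channels x time, uV) that
#' the simulator adds at each stimulus onset of `category`: a Gaussian time
#' course peaking at the template latency, scaled by the category amplitude
#' and the per-subject gain, with Gaussian spatial falloff away from the
#' template's center electrodes. Categories absent from the amplitude map
#' yield an all-zero pattern. Rows follow `montage$channels` plus zero rows
#' for the EOG channels.
#'
#' @param template an `erp_template`.
#' @param category stimulus category label.
#' @param subject_gain multiplicative per-subject gain (default 1).
#' @param fs sampling rate, Hz.
#' @param montage an `erp_montage`.
#' @param t_pre_ms,t_post_ms epoch span rendered, ms around stimulus onset.
#' @return numeric matrix, `(n_channels + n_eog) x n_samples`.
#' @export
render_component <- function(template, category, subject_gain = 1, fs = 512,
                             montage = build_default_montage(),
                             t_pre_ms = 100, t_post_ms = 1500) {
  n_pre <- floor(t_pre_ms / 1000 * fs)
  n_post <- floor(t_post_ms / 1000 * fs)
  t_ms <- (seq_len(n_pre + n_post) - n_pre - 1) / fs * 1000
  n_ch <- nrow(montage$channels)
  n_eog <- length(montage$eog_channels)
  out <- matrix(0, n_ch + n_eog, length(t_ms))
  amp_l <- template$amps[category]
  amp_r <- template$amps_right[category]
  if (is.na(amp_l) || is.na(amp_r)) return(out)
  course <- exp(-((t_ms - template$peak_ms)^2) / (2 * template$sd_ms^2))
  w <- .template_weights(template, montage)
  if (isTRUE(all.equal(unname(amp_l), unname(amp_r)))) {
    amp_ch <- w * amp_l
  } else {
    hemi <- montage$channels$hemisphere
    amp_ch <- w * ifelse(hemi == "right", amp_r,
                         ifelse(hemi == "left", amp_l, (amp_l + amp_r) / 2))
  }
  out[seq_len(n_ch), ] <- (subject_gain * amp_ch) %o% course
  out
}

#' Validate templates against the marker registry
#'
#' Checks, for every template: (i) the peak latency lies inside its marker's
#' measurement window; (ii) amplitude signs match the component polarity;
#' (iii) the amplitude map satisfies every category ordering registered for
#' the marker (in magnitude, with the >= `min_gap` uV separation the
#' generator promises). Errors with an informative message on the first
#' violation; returns `TRUE` invisibly when all templates validate.
#'
#' @param templates list of `erp_template`s, default [default_templates()].
#' @param registry marker registry tibble, default [marker_registry()].
#' @param min_gap minimum amplitude separation (uV) for constrained pairs.
#' @export
validate_templates <- function(templates = default_templates(),
                               registry = marker_registry(), min_gap = 1) {
  for (i in seq_len(nrow(registry))) {
    marker <- registry$marker[i]
    tpl <- templates[[marker]]
    if (is.null(tpl)) abort(paste0("no template for marker ", marker))
    win <- c(registry$window_start_ms[i], registry$window_end_ms[i])
    if (tpl$peak_ms < win[1] || tpl$peak_ms >= win[2]) {
      abort(paste0(marker, ": peak ", tpl$peak_ms, " ms outside window [",
                   win[1], ", ", win[2], ")"))
    }
    pol <- registry$polarity[i]
    amps <- c(tpl$amps, tpl$amps_right)
    if (marker == "PN300") {
      vis <- stimulus_categories()$visual
      aud <- stimulus_categories()$auditory
      if (any(tpl$amps[vis] >= 0) || any(tpl$amps[aud] <= 0)) {
        abort("PN300 must be negative for visual, positive for auditory")
      }
    } else if (pol == "-" && any(amps > 0) || pol == "+" && any(amps < 0)) {
      abort(paste0(marker, ": amplitude sign inconsistent with polarity ", pol))
    }
    for (pair in registry$contrast[[i]]) {
      hi <- mean(c(tpl$amps[pair[1]], tpl$amps_right[pair[1]]))
      lo <- mean(c(tpl$amps[pair[2]], tpl$amps_right[pair[2]]))
      if (is.na(hi) || is.na(lo)) {
        abort(paste0(marker, ": contrast categories missing from amplitude map"))
      }
      if (abs(hi) - abs(lo) < min_gap) {
        abort(paste0(marker, ": |", pair[1], "| must exceed |", pair[2],
                     "| by >= ", min_gap, " uV"))
      }
    }
  }
  invisible(TRUE)
}
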