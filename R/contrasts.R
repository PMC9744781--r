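# The fixed battery of marker ANOVAs: stimulus category x electrode (x
# hemisphere where the marker is measured at homologous lateral pairs), plus
# Tukey HSD post hocs on the registered category orderings.

# electrode -> homologous-pair site label ("P7|P8") and hemisphere
.site_info <- function(electrodes, montage) {
  hemis <- hemisphere_of(electrodes, montage)
  pairs <- vapply(seq_along(electrodes), function(i) {
    lbl <- .match_label(electrodes[i], montage)
    paste(sort(c(lbl, homolog(lbl, montage))), collapse = "|")
  }, character(1))
  tibble::tibble(electrode = .match_label(electrodes, montage),
                 site = pairs, hemisphere = hemis)
}

# polarity-adjusted value: "larger" always means larger adjusted value
.adjust_polarity <- function(x, polarity) {
  if (polarity == "-") -x else x
}

.marker_anova <- function(rows, reg_row, montage) {
  els <- .match_label(reg_row$electrodes[[1]], montage)
  per_el <- rows[rows$electrode %in% els, ]
  info <- .site_info(els, montage)
  lateral <- all(info$hemisphere != "midline") &&
    length(unique(info$site)) == length(els) / 2
  if (reg_row$marker == "PN300") {
    cats <- stimulus_categories()
    per_el$modality <- ifelse(per_el$category %in% cats$visual, "visual",
                              "auditory")
    d <- dplyr::summarise(
      dplyr::group_by(per_el, .data$subject, .data$modality,
                      .data$electrode),
      amplitude_uv = mean(.data$amplitude_uv), .groups = "drop"
    )
    return(rm_anova(d, "amplitude_uv", c("modality", "electrode")))
  }
  if (lateral) {
    d <- dplyr::left_join(per_el, info, by = "electrode")
    within <- c("category", "site", "hemisphere")
    if (length(unique(info$site)) < 2) within <- c("category", "hemisphere")
    rm_anova(d, "amplitude_uv", within)
  } else {
    rm_anova(per_el, "amplitude_uv", c("category", "electrode"))
  }
}

# HSD on the subject x category pooled means of one marker, using the
# category x subject error term of the pooled one-factor RM-ANOVA.
.marker_posthoc <- function(pooled, reg_row) {
  a <- rm_anova(pooled, "amplitude_uv", "category")
  tab <- tidy(a)
  cat_row <- tab[tab$effect == "category", ]
  ms_error <- cat_row$ss_den / cat_row$df_den
  means <- tapply(pooled$amplitude_uv, pooled$category, mean)
  hsd <- tukey_hsd(means, ms_error, cat_row$df_den,
                   n_per_level = a$n_subjects)
  hsd$marker <- reg_row$marker
  hsd
}

#' Run the full battery of marker contrasts
#'
#' For every marker in the registry, runs the repeated-measures ANOVA
#' (category x electrode, with site x hemisphere factors where the marker is
#' measured at homologous lateral pairs; modality x electrode for PN300) and
#' Tukey HSD post hoc comparisons on the category-pooled amplitudes, then
#' scores each registered category ordering: was the pair difference in the
#' expected direction and significant? For the word-selective N170 the
#' hemisphere-specific claim is scored too (a word advantage over the left
#' hemisphere, no reliable category ordering over the right). For PN300 the
#' claim is its modality sign rule (negative visual, positive auditory).
#'
#' @param features restricted feature table from [extract_feature_table()].
#' @param registry marker registry.
#' @param montage default montage.
#' @param alpha significance level for scoring a contrast as recovered.
#' @return An `erp_contrasts` object: `anova` (per marker x effect tibble),
#'   `posthoc` (pairwise tibble), `recovery` (one row per registered
#'   ordering with `recovered`).
#' @export
run_paper_contrasts <- function(features, registry = marker_registry(),
                                montage = build_default_montage(),
                                alpha = 0.01) {
  anova_rows <- list()
  posthoc_rows <- list()
  recovery_rows <- list()
  for (i in seq_len(nrow(registry))) {
    reg_row <- registry[i, ]
    rows <- features[features$marker == reg_row$marker, ]
    if (nrow(rows) == 0) abort(paste0("no features for ", reg_row$marker))
    a <- .marker_anova(rows, reg_row, montage)
    at <- tidy(a)
    at$marker <- reg_row$marker
    anova_rows[[i]] <- at
    pooled <- rows[rows$electrode == "pooled", ]
    if (reg_row$marker == "PN300") {
      cats <- stimulus_categories()
      mod_mean <- tapply(pooled$amplitude_uv,
                         pooled$category %in% cats$visual, mean)
      mod_p <- at$p_adjusted[at$effect == "modality"]
      recovery_rows[[length(recovery_rows) + 1L]] <- tibble::tibble(
        marker = "PN300", greater = "auditory", lesser = "visual",
        difference = unname(mod_mean["FALSE"] - mod_mean["TRUE"]),
        p_adjusted = mod_p,
        recovered = mod_mean[["TRUE"]] < 0 && mod_mean[["FALSE"]] > 0 &&
          mod_p < alpha
      )
      next
    }
    hsd <- .marker_posthoc(pooled, reg_row)
    posthoc_rows[[length(posthoc_rows) + 1L]] <- hsd
    means <- tapply(.adjust_polarity(pooled$amplitude_uv, reg_row$polarity),
                    pooled$category, mean)
    for (pair in reg_row$contrast[[1]]) {
      hit <- hsd[(hsd$level_1 == pair[1] & hsd$level_2 == pair[2]) |
                   (hsd$level_1 == pair[2] & hsd$level_2 == pair[1]), ]
      dir_ok <- means[[pair[1]]] > means[[pair[2]]]
      recovery_rows[[length(recovery_rows) + 1L]] <- tibble::tibble(
        marker = reg_row$marker, greater = pair[1], lesser = pair[2],
        difference = means[[pair[1]]] - means[[pair[2]]],
        p_adjusted = hit$p_adjusted[1],
        recovered = dir_ok && hit$p_adjusted[1] < alpha
      )
    }
    if (reg_row$marker == "N170_nonliving") {
      lat <- .lateralization_check(rows, reg_row, montage, alpha)
      recovery_rows[[length(recovery_rows) + 1L]] <- lat
    }
  }
  structure(
    list(anova = dplyr::bind_rows(anova_rows),
         posthoc = dplyr::bind_rows(posthoc_rows),
         recovery = dplyr::bind_rows(recovery_rows),
         alpha = alpha),
    class = "erp_contrasts"
  )
}

# Left-lateralized word N170: word > checkerboard (magnitude) restricted to
# left-hemisphere electrodes, and a hemisphere-dependent word advantage
# (word-minus-checkerboard larger over the left than the right hemisphere).
.lateralization_check <- function(rows, reg_row, montage, alpha) {
  info <- .site_info(.match_label(reg_row$electrodes[[1]], montage), montage)
  d <- dplyr::left_join(rows[rows$electrode != "pooled", ], info,
                        by = "electrode")
  hemi_mean <- dplyr::summarise(
    dplyr::group_by(d, .data$subject, .data$category, .data$hemisphere),
    amplitude_uv = mean(.data$amplitude_uv), .groups = "drop"
  )
  left <- hemi_mean[hemi_mean$hemisphere == "left", ]
  ph <- .marker_posthoc(dplyr::rename(left, amplitude_uv = "amplitude_uv"),
                        reg_row)
  hit <- ph[(ph$level_1 == "word_visual" & ph$level_2 == "checkerboard") |
              (ph$level_1 == "checkerboard" & ph$level_2 == "word_visual"), ]
  means <- tapply(.adjust_polarity(left$amplitude_uv, reg_row$polarity),
                  left$category, mean)
  tibble::tibble(
    marker = "N170_nonliving", greater = "word_visual (left hemisphere)",
    lesser = "checkerboard (left hemisphere)",
    difference = means[["word_visual"]] - means[["checkerboard"]],
    p_adjusted = hit$p_adjusted[1],
    recovered = means[["word_visual"]] > means[["checkerboard"]] &&
      hit$p_adjusted[1] < alpha
  )
}

#' @export
print.erp_contrasts <- function(x, ...) {
  cat("<erp_contrasts> ", length(unique(x$anova$marker)), " markers, ",
      nrow(x$recovery), " registered orderings, ",
      sum(x$recovery$recovered), " recovered at alpha = ", x$alpha, "\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.erp_contrasts <- function(x, ...) x$anova

#' @export
glance.erp_contrasts <- function(x, ...) {
  tibble::tibble(
    n_markers = length(unique(x$anova$marker)),
    n_orderings = nrow(x$recovery),
    n_recovered = sum(x$recovery$recovered),
    alpha = x$alpha
  )
}

#' Human-readable contrast report
#'
#' Formats the ANOVA battery in bracket notation, e.g.
#' `N170_living category: [F(2, 38) = 12.3, p < 0.001; eps = 0.98; pes = 0.39]`.
#' @param contrasts an `erp_contrasts`.
#' @return character vector of report lines (invisibly printed with `cat`).
#' @export
format_contrast_report <- function(contrasts) {
  tab <- contrasts$anova
  lines <- sprintf(
    "%s %s: [F(%g, %g) = %.2f, p = %.2g; eps = %.2f, adjusted p = %.2g; partial eta2 = %.2f]",
    tab$marker, tab$effect, tab$df_num, tab$df_den, tab$F, tab$p,
    tab$epsilon, tab$p_adjusted, tab$partial_eta_sq
  )
  rec <- contrasts$recovery
  lines <- c(lines, sprintf(
    "%s: %s > %s, diff = %.2f uV, adjusted p = %.2g [%s]",
    rec$marker, rec$greater, rec$lesser, rec$difference, rec$p_adjusted,
    ifelse(rec$recovered, "recovered", "NOT recovered")
  ))
  lines
}
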