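# Trial averaging: ERP_i = (1/m) * sum_k a(i,k) over kept epochs.

.new_evoked <- function(data, epochs_or_evoked, category, level, subject,
                        m_contributing) {
  src <- epochs_or_evoked
  structure(
    list(data = data, time_ms = src$time_ms, fs = src$fs,
         montage = src$montage, category = category, level = level,
         subject = subject, m_contributing = m_contributing),
    class = "erp_evoked"
  )
}

#' @export
print.erp_evoked <- function(x, ...) {
  cat("<erp_evoked> ", x$category, " (", x$level,
      if (!is.null(x$subject)) paste0(", subject ", x$subject), "), ",
      nrow(x$data), " channels x ", ncol(x$data), " samples, m = ",
      x$m_contributing, "\n", sep = "")
  invisible(x)
}

#' Average kept epochs into an evoked response
#'
#' Arithmetic mean over the kept epochs (of one category if `category` is
#' given), per channel and sample - the averaging step that improves the
#' signal-to-noise ratio by 1/sqrt(m). Errors explicitly if no kept epoch
#' matches (never returns silent zeros).
#'
#' @param epochs an `erp_epochs` (after rejection/baseline correction).
#' @param category stimulus category to average; `NULL` averages all kept
#'   epochs.
#' @param subject optional subject id carried into the result.
#' @return An `erp_evoked`: `data` (channels x samples, uV, with channel
#'   rownames), `m_contributing`, `category`, `level = "subject"`.
#' @export
average_epochs <- function(epochs, category = NULL, subject = NULL) {
  idx <- epochs$kept
  if (!is.null(category)) idx <- idx & epochs$categories == category
  m <- sum(idx)
  if (m == 0) {
    abort(paste0("no kept epochs to average",
                 if (!is.null(category)) paste0(" for category '", category,
                                                "'")))
  }
  d <- dim(epochs$tensor)
  flat <- matrix(epochs$tensor[, , idx], d[1] * d[2], m)
  data <- matrix(rowMeans(flat), d[1], d[2])
  rownames(data) <- epochs$channel_names
  .new_evoked(data, epochs, category %||% "all", "subject", subject, m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_compatible <- function(evokeds) {
  if (length(evokeds) == 0) abort("no evoked responses supplied")
  ref <- evokeds[[1]]
  for (ev in evokeds[-1]) {
    if (!identical(dim(ev$data), dim(ref$data)) || ev$fs != ref$fs) {
      abort("evoked responses have mismatching dimensions or sampling rates")
    }
  }
  ref
}

#' Grand average across subjects
#'
#' Unweighted mean of per-subject evoked waveforms of one category.
#'
#' @param evokeds list of `erp_evoked` (same category and shape).
#' @return An `erp_evoked` with `level = "grand"`.
#' @export
grand_average <- function(evokeds) {
  ref <- .check_compatible(evokeds)
  cats <- unique(vapply(evokeds, `[[`, character(1), "category"))
  if (length(cats) != 1) {
    abort("grand_average requires evoked responses of a single category")
  }
  data <- Reduce(`+`, lapply(evokeds, `[[`, "data")) / length(evokeds)
  rownames(data) <- rownames(ref$data)
  .new_evoked(data, ref, cats, "grand", NULL, length(evokeds))
}

#' Pool categories into composite evoked responses
#'
#' Unweighted mean of member-category evokeds, e.g. a "living" waveform as
#' the mean of the face, body and animal evokeds (mean of evokeds, not a
#' re-average of pooled trials).
#'
#' @param evokeds named list of `erp_evoked`, keyed by category.
#' @param groups named list: group name -> member category labels.
#' @return Named list of pooled `erp_evoked` (category = group name).
#' @export
pool_categories <- function(evokeds, groups) {
  out <- list()
  for (g in names(groups)) {
    members <- groups[[g]]
    missing <- setdiff(members, names(evokeds))
    if (length(missing) > 0) {
      abort(paste0("group '", g, "': unknown member categories ",
                   paste(missing, collapse = ", ")))
    }
    ref <- .check_compatible(evokeds[members])
    data <- Reduce(`+`, lapply(evokeds[members], `[[`, "data")) /
      length(members)
    rownames(data) <- rownames(ref$data)
    out[[g]] <- .new_evoked(data, ref, g, ref$level, NULL,
                            length(members))
  }
  out
}

#' Export an evoked waveform as CSV
#'
#' Rows are samples (first column `time_ms`), remaining columns channels.
#' @param evoked an `erp_evoked`.
#' @param path file path.
#' @export
write_evoked_csv <- function(evoked, path) {
  df <- data.frame(time_ms = evoked$time_ms, t(evoked$data),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
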