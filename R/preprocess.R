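# Epoching, artifact rejection, baseline correction, band-pass filtering.

#' Zero-phase band-pass filter
#'
#' Filters a continuous recording with a zero-phase frequency-domain filter
#' whose magnitude is the squared Butterworth response (the response that
#' forward-backward filtering of an order-`order` Butterworth produces), so
#' the half-amplitude (0.5 gain) points sit exactly at the stated corner
#' frequencies. Defaults reproduce the 0.016-30 Hz display band.
#'
#' @param recording an `erp_recording`.
#' @param low_hz,high_hz corner frequencies (half-amplitude points), Hz.
#' @param order Butterworth order of each edge (before squaring).
#' @return The filtered recording.
#' @export
bandpass <- function(recording, low_hz = 0.016, high_hz = 30, order = 2) {
  fs <- recording$fs
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < fs / 2)) {
    abort("invalid band: need 0 <= low < high < fs/2")
  }
  n <- ncol(recording$data)
  nfft <- stats::nextn(n, c(2, 3, 5))
  f <- c(seq(0, floor(nfft / 2)), seq(ceiling(nfft / 2) - 1, 1)) * fs / nfft
  gain <- 1 / (1 + (f / high_hz)^(2 * order))
  if (low_hz > 0) {
    hp <- (f / low_hz)^(2 * order)
    gain <- gain * hp / (1 + hp)
  }
  out <- recording$data
  for (ch in seq_len(nrow(out))) {
    padded <- c(out[ch, ], rep(0, nfft - n))
    filt <- Re(stats::fft(stats::fft(padded) * gain, inverse = TRUE)) / nfft
    out[ch, ] <- filt[seq_len(n)]
  }
  recording$data <- out
  recording
}

.epoch_pre_samples <- function(fs, t_pre_ms) floor(t_pre_ms / 1000 * fs)
.epoch_post_samples <- function(fs, t_post_ms) floor(t_post_ms / 1000 * fs)

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per schedule event, spanning `[-t_pre_ms, t_post_ms)` around the
#' stimulus onset (half-open, floor sample conversion): with defaults at
#' 512 Hz, 51 baseline samples + 768 post-stimulus samples. Events whose
#' window exceeds the record bounds are dropped (with a message).
#'
#' @param recording an `erp_recording`.
#' @param schedule event tibble (columns `onset_sample`, `category`).
#' @param t_pre_ms,t_post_ms epoch window (ms).
#' @return An `erp_epochs` object: voltage tensor `channels x time x epochs`
#'   (uV), `time_ms`, per-epoch `categories`, `kept` mask and
#'   `rejection_log`.
#' @export
extract_epochs <- function(recording, schedule, t_pre_ms = 100,
                           t_post_ms = 1500) {
  fs <- recording$fs
  n_pre <- .epoch_pre_samples(fs, t_pre_ms)
  n_post <- .epoch_post_samples(fs, t_post_ms)
  n <- ncol(recording$data)
  ok <- schedule$onset_sample - n_pre >= 1 &
    schedule$onset_sample + n_post - 1 <= n
  if (any(!ok)) {
    message(sum(!ok), " event(s) dropped: epoch window outside the record")
  }
  onsets <- schedule$onset_sample[ok]
  n_ep <- length(onsets)
  n_t <- n_pre + n_post
  if (n_ep == 0) {
    tensor <- array(0, dim = c(nrow(recording$data), n_t, 0))
  } else {
    tensor <- cpp_extract_epochs(recording$data, onsets - n_pre - 1L, n_t)
  }
  structure(
    list(tensor = tensor,
         time_ms = seq.int(-n_pre, n_post - 1L) / fs * 1000,
         categories = schedule$category[ok],
         fs = fs, montage = recording$montage,
         channel_names = rownames(recording$data),
         eog_index = recording$eog_index,
         kept = rep(TRUE, n_ep),
         rejection_log = tibble::tibble(epoch = integer(0),
                                        channel = character(0),
                                        peak_to_peak_uv = numeric(0))),
    class = "erp_epochs"
  )
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat("<erp_epochs> ", dim(x$tensor)[3], " epochs (", sum(x$kept), " kept) x ",
      dim(x$tensor)[1], " channels x ", dim(x$tensor)[2], " samples\n",
      sep = "")
  invisible(x)
}

#' Peak-to-peak artifact rejection
#'
#' Marks an epoch as rejected iff the within-epoch peak-to-peak amplitude
#' (max minus min) on any channel - scalp and EOG alike - strictly exceeds
#' `threshold_uv`. An epoch whose worst peak-to-peak equals the threshold
#' exactly is kept ("exceeding" read strictly). The tensor is retained; only
#' the `kept` mask and `rejection_log` change.
#'
#' @param epochs an `erp_epochs`.
#' @param threshold_uv rejection threshold (uV), default 50.
#' @return The epochs with updated `kept` and `rejection_log` (worst channel
#'   and its peak-to-peak value per rejected epoch).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 50) {
  stopifnot(threshold_uv > 0)
  n_ep <- dim(epochs$tensor)[3]
  if (n_ep == 0) return(epochs)
  pp <- cpp_peak_to_peak(epochs$tensor, dim(epochs$tensor))
  rejected <- pp[1, ] > threshold_uv
  epochs$kept <- !rejected
  epochs$rejection_log <- tibble::tibble(
    epoch = which(rejected),
    channel = epochs$channel_names[pp[2, rejected]],
    peak_to_peak_uv = pp[1, rejected]
  )
  epochs
}

#' Baseline correction
#'
#' Subtracts, per epoch and channel, the mean voltage over the pre-stimulus
#' interval (samples with `time_ms < 0`), so components are measured with
#' reference to the average baseline voltage. Idempotent.
#'
#' @param epochs an `erp_epochs` containing a pre-stimulus segment.
#' @return The baseline-corrected epochs.
#' @export
baseline_correct <- function(epochs) {
  pre <- epochs$time_ms < 0
  if (!any(pre)) abort("no pre-stimulus samples: cannot baseline-correct")
  if (any(diff(pre) > 0)) abort("pre-stimulus samples must be contiguous")
  d <- dim(epochs$tensor)
  if (d[3] == 0) return(epochs)
  tensor <- epochs$tensor + 0  # fresh copy; corrected in place below
  cpp_baseline_correct(tensor, d, sum(pre))
  epochs$tensor <- tensor
  epochs
}
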