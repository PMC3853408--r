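# zero-phase 4th-order Butterworth bandpass applied row-wise
bandpass_matrix <- function(M, low_hz, high_hz, rate) {
  bf <- signal::butter(4, c(low_hz, high_hz) / (rate / 2), type = "pass")
  out <- M
  for (ch in seq_len(nrow(M)))
    out[ch, ] <- signal::filtfilt(bf, M[ch, ])
  out
}

#' Zero-phase bandpass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase, squared
#' magnitude response) to every channel; signal length is preserved.
#'
#' @param rec a [recording()].
#' @param low_hz,high_hz band edges, `0 < low < high < rate/2`.
#' @return a filtered [recording()].
#' @examples
#' lay <- channel_layout("c1", 0, 0)
#' t <- seq(0, 2, by = 1/200)
#' rec <- recording(matrix(sin(2 * pi * 20 * t), 1), 200, lay, "rest")
#' filtered <- bandpass(rec, 8, 30)
#' @export
bandpass <- function(rec, low_hz, high_hz) {
  stopifnot(inherits(rec, "recording"))
  if (!(0 < low_hz && low_hz < high_hz && high_hz < rec$rate / 2))
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < rate/2 = %g",
                 low_hz, high_hz, rec$rate / 2))
  recording(bandpass_matrix(rec$samples, low_hz, high_hz, rec$rate),
            rec$rate, rec$layout, rec$state)
}

#' Remove bad channels
#'
#' Drops channels from the signal matrix and the layout consistently. With
#' `auto = TRUE`, channels whose signal variance deviates from the median
#' channel variance by more than `k` MADs are flagged in addition to any
#' named ones.
#'
#' @param rec a [recording()].
#' @param bad character vector of channel names to remove (may be empty).
#' @param auto flag outlier-variance channels automatically.
#' @param k MAD multiplier for the automatic rule (default 5).
#' @return a [recording()] without the bad channels.
#' @export
exclude_bad_channels <- function(rec, bad = character(), auto = FALSE, k = 5) {
  stopifnot(inherits(rec, "recording"))
  labels <- rec$layout$label
  missing <- setdiff(bad, labels)
  if (length(missing))
    stop("unknown channel(s): ", paste(missing, collapse = ", "))
  flagged <- bad
  if (auto) {
    v <- apply(rec$samples, 1, stats::var)
    dev <- abs(v - stats::median(v))
    flagged <- union(flagged, labels[dev > k * stats::mad(v)])
  }
  keep <- !(labels %in% flagged)
  if (!any(keep)) stop("cannot remove all channels")
  lay <- channel_layout(labels[keep], rec$layout$x[keep], rec$layout$y[keep],
                        attr(rec$layout, "modality"))
  recording(rec$samples[keep, , drop = FALSE], rec$rate, lay, rec$state)
}

#' Epoched trials
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels class per trial (length = trial count).
#' @param t_start,t_end window bounds in seconds relative to cue onset,
#'   `t_end > t_start`.
#' @param rate sampling rate in Hz.
#' @param layout optional [channel_layout()].
#' @return object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, t_start, t_end, rate, layout = NULL) {
  if (t_end <= t_start) stop("t_end must exceed t_start")
  if (length(dim(data)) != 3) stop("data must be trials x channels x samples")
  if (dim(data)[1] != length(labels))
    stop("trial count must equal label count")
  structure(list(data = data, labels = as.factor(labels),
                 t_start = t_start, t_end = t_end, rate = rate,
                 layout = layout),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples, window [%g, %g) s\n",
              d[1], d[2], d[3], x$t_start, x$t_end))
  print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an [epoch_set()].
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]

#' Cut trials around cue onsets
#'
#' Cuts one trial per event over the half-open window
#' `[onset + t_start, onset + t_end)` seconds, so a 2 s window at 500 Hz is
#' exactly 1000 samples. Trial order follows event order.
#'
#' @param rec a [recording()].
#' @param events an [event_list()] (0-based onset samples).
#' @param t_start,t_end window in seconds relative to cue onset.
#' @return an [epoch_set()].
#' @export
epoch <- function(rec, events, t_start, t_end) {
  stopifnot(inherits(rec, "recording"))
  if (t_end <= t_start) stop("t_end must exceed t_start")
  n_samp <- round((t_end - t_start) * rec$rate)
  n_ev <- nrow(events)
  nc <- nrow(rec$samples)
  nt <- ncol(rec$samples)
  data <- array(0, dim = c(n_ev, nc, n_samp))
  if (n_ev > 0) {
    off <- round(t_start * rec$rate)
    for (i in seq_len(n_ev)) {
      first <- events$onset_sample[i] + off + 1L  # to 1-based
      last <- first + n_samp - 1L
      if (first < 1 || last > nt)
        stop(sprintf("trial %d window [%d, %d] exceeds recording bounds [1, %d]",
                     i, first, last, nt))
      data[i, , ] <- rec$samples[, first:last]
    }
  }
  epoch_set(data, if (n_ev > 0) events$label else factor(character()),
            t_start, t_end, rec$rate, rec$layout)
}
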