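#' Continuous multichannel recording
#'
#' @param samples numeric matrix, channels x time, in consistent arbitrary
#'   units.
#' @param rate sampling rate in Hz (> 0).
#' @param layout a [channel_layout()] with one row per sample row.
#' @param state `"rest"` or `"task"`.
#' @return An object of class `recording`.
#' @export
recording <- function(samples, rate, layout, state = c("rest", "task")) {
  state <- match.arg(state)
  samples <- as.matrix(samples)
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a positive scalar (Hz)")
  if (!inherits(layout, "channel_layout")) stop("layout must be a channel_layout")
  if (nrow(samples) != nrow(layout))
    stop(sprintf("samples has %d rows but layout has %d channels",
                 nrow(samples), nrow(layout)))
  rownames(samples) <- layout$label
  structure(list(samples = samples, rate = rate, layout = layout,
                 state = state),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s, %d channels x %d samples @ %g Hz (%.1f s)\n",
              x$state, nrow(x$samples), ncol(x$samples), x$rate,
              ncol(x$samples) / x$rate))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [recording()].
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate

#' Trial event list
#'
#' Cue-onset events for a motor-imagery session. Onsets are 0-based sample
#' indices of the moment the directional cue appears (start of the imagery
#' phase).
#'
#' @param onsets integer 0-based sample indices, strictly increasing.
#' @param labels class per trial; coerced to a factor with levels
#'   `c("left", "right")` when those are the values present.
#' @param run_id integer run index per trial.
#' @return data frame of class `event_list` with columns
#'   `onset_sample`, `label`, `run_id`.
#' @export
event_list <- function(onsets, labels, run_id) {
  if (is.unsorted(onsets, strictly = TRUE)) stop("onsets must be strictly increasing")
  labels <- as.factor(labels)
  if (nlevels(labels) != 2)
    stop("labels must come from exactly two classes")
  if (length(labels) != length(onsets) || length(run_id) != length(onsets))
    stop("onsets, labels and run_id must have equal length")
  out <- data.frame(onset_sample = as.integer(onsets), label = labels,
                    run_id = as.integer(run_id))
  class(out) <- c("event_list", "data.frame")
  out
}

# run expr with a private, restored RNG stream
with_rng_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}
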