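#' Channel layout
#'
#' A sensor layout: channel labels plus 2-D positions on the head seen from
#' above, normalized to the unit square. `x` is lateral (negative = left),
#' `y` is anterior-posterior with `y = +1` most anterior.
#'
#' @param labels character vector of unique channel names.
#' @param x,y numeric position per channel in `[-1, 1]`.
#' @param modality `"MEG-like"` or `"EEG-like"`.
#' @return An object of class `channel_layout`: a data frame with columns
#'   `label`, `x`, `y` and attribute `modality`.
#' @examples
#' lay <- channel_layout(c("a", "b"), x = c(-0.5, 0.5), y = c(0, 0))
#' n_channels(lay)
#' @export
channel_layout <- function(labels, x, y, modality = c("MEG-like", "EEG-like")) {
  modality <- match.arg(modality)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (length(x) != length(labels) || length(y) != length(labels))
    stop("positions count must equal labels count")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("positions must be finite")
  out <- data.frame(label = labels, x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "modality") <- modality
  class(out) <- c("channel_layout", "data.frame")
  out
}

#' @rdname channel_layout
#' @param layout a `channel_layout`.
#' @export
n_channels <- function(layout) nrow(layout)

#' @export
print.channel_layout <- function(x, ...) {
  cat(sprintf("<channel_layout> %d %s channels\n", nrow(x), attr(x, "modality")))
  invisible(x)
}

#' Regular-grid MEG-like layout on the unit disk
#'
#' Places channels on a regular square grid restricted to the unit disk,
#' dropping the outermost points until exactly `n` remain. The default
#' `n = 152` mimics a whole-head axial gradiometer array; smaller `n` keeps
#' full-scalp coverage, which matters for the anterior-posterior region
#' analysis and the sensorimotor zones used by the simulator.
#'
#' @param n number of channels.
#' @return a [channel_layout()].
#' @export
meg_grid_layout <- function(n = 152) {
  if (n < 1) stop("n must be positive")
  k <- 2
  repeat {
    g <- seq(-1, 1, length.out = k)
    pts <- expand.grid(x = g, y = g)
    pts <- pts[pts$x^2 + pts$y^2 <= 1 + 1e-12, , drop = FALSE]
    if (nrow(pts) >= n) break
    k <- k + 1
  }
  # drop outermost points first so coverage of the scalp edge degrades last
  r <- sqrt(pts$x^2 + pts$y^2)
  ord <- order(r, atan2(pts$y, pts$x))
  pts <- pts[ord[seq_len(n)], , drop = FALSE]
  ord2 <- order(-pts$y, pts$x)
  pts <- pts[ord2, , drop = FALSE]
  channel_layout(sprintf("MEG%03d", seq_len(n)), pts$x, pts$y, "MEG-like")
}

#' 10-20 style 19-channel EEG layout
#'
#' The classic 19-electrode montage with nominal normalized positions.
#'
#' @return a [channel_layout()].
#' @export
eeg_1020_layout <- function() {
  pos <- matrix(c(
    "Fp1", -0.31,  0.95,
    "Fp2",  0.31,  0.95,
    "F7",  -0.81,  0.59,
    "F3",  -0.55,  0.49,
    "Fz",   0.00,  0.50,
    "F4",   0.55,  0.49,
    "F8",   0.81,  0.59,
    "T3",  -1.00,  0.00,
    "C3",  -0.50,  0.00,
    "Cz",   0.00,  0.00,
    "C4",   0.50,  0.00,
    "T4",   1.00,  0.00,
    "T5",  -0.81, -0.59,
    "P3",  -0.55, -0.49,
    "Pz",   0.00, -0.50,
    "P4",   0.55, -0.49,
    "T6",   0.81, -0.59,
    "O1",  -0.31, -0.95,
    "O2",   0.31, -0.95), ncol = 3, byrow = TRUE)
  channel_layout(pos[, 1], as.numeric(pos[, 2]), as.numeric(pos[, 3]),
                 "EEG-like")
}

# Channels within `radius` of a point (x0, y0); returns indices.
zone_channels <- function(layout, x0, y0, radius = 0.25) {
  which(sqrt((layout$x - x0)^2 + (layout$y - y0)^2) <= radius)
}

#' Standard scalp zones used by the simulator
#'
#' Sensorimotor zones are disks of radius 0.25 around (+/-0.5, 0); the
#' prefrontal zone is `y > 0.6` and the occipital zone `y < -0.6`.
#'
#' @param layout a [channel_layout()].
#' @return named list of integer channel index vectors:
#'   `sm_left`, `sm_right`, `prefrontal`, `occipital`.
#' @export
scalp_zones <- function(layout) {
  list(
    sm_left    = zone_channels(layout, -0.5, 0, 0.25),
    sm_right   = zone_channels(layout,  0.5, 0, 0.25),
    prefrontal = which(layout$y > 0.6),
    occipital  = which(layout$y < -0.6)
  )
}
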