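#' Default spectral band definitions
#'
#' theta 4-8, alpha 8-13, beta 13-30, gamma 30-70 Hz; together they tile the
#' 4-70 Hz total band used by the RPL normalization.
#'
#' @return data frame with columns `name`, `low_hz`, `high_hz`.
#' @export
default_bands <- function() {
  data.frame(name = c("theta", "alpha", "beta", "gamma"),
             low_hz = c(4, 8, 13, 30),
             high_hz = c(8, 13, 30, 70),
             stringsAsFactors = FALSE)
}

#' Welch power spectral density
#'
#' Averaged modified periodogram per channel: the signal is split into
#' Hamming-tapered segments (default 2 s, 50% overlap), each segment is
#' mean-detrended, and one-sided periodograms scaled to density
#' (units^2/Hz) are averaged.
#'
#' @param rec a [recording()] at least one segment long.
#' @param seg_s segment length in seconds (default 2).
#' @param overlap_frac fractional overlap between segments (default 0.5).
#' @return object of class `psd_table`: list with `freqs` (Hz) and `power`
#'   (channels x frequencies), channel labels as row names.
#' @export
power_spectrum <- function(rec, seg_s = 2, overlap_frac = 0.5) {
  stopifnot(inherits(rec, "recording"))
  nseg <- round(seg_s * rec$rate)
  n <- ncol(rec$samples)
  if (n < nseg)
    stop(sprintf("recording (%d samples) is shorter than one %g s segment",
                 n, seg_s))
  step <- max(1L, round(nseg * (1 - overlap_frac)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.54 - 0.46 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))  # Hamming
  u <- sum(w^2)
  n_keep <- floor(nseg / 2) + 1L
  freqs <- (seq_len(n_keep) - 1) * rec$rate / nseg

  nc <- nrow(rec$samples)
  P <- matrix(0, nc, n_keep)
  for (s in starts) {
    seg <- rec$samples[, s:(s + nseg - 1L), drop = FALSE]
    seg <- (seg - rowMeans(seg)) * matrix(w, nc, nseg, byrow = TRUE)
    sp <- stats::mvfft(t(seg))[seq_len(n_keep), , drop = FALSE]
    pg <- t(Mod(sp)^2) / (rec$rate * u)
    # one-sided: double everything except DC and (for even nseg) Nyquist
    dbl <- rep(2, n_keep); dbl[1] <- 1
    if (nseg %% 2 == 0) dbl[n_keep] <- 1
    P <- P + pg * matrix(dbl, nc, n_keep, byrow = TRUE)
  }
  P <- P / length(starts)
  rownames(P) <- rec$layout$label
  structure(list(freqs = freqs, power = P, rate = rec$rate,
                 layout = rec$layout),
            class = "psd_table")
}

#' @export
print.psd_table <- function(x, ...) {
  cat(sprintf("<psd_table> %d channels x %d frequencies (0-%g Hz, df = %g)\n",
              nrow(x$power), length(x$freqs), max(x$freqs),
              x$freqs[2] - x$freqs[1]))
  invisible(x)
}

# trapezoidal integral of y(f) over [low, high] with linear interpolation at
# the band edges; adjacent bands therefore tile an interval exactly
trapz_band <- function(freqs, y, low, high) {
  yl <- stats::approx(freqs, y, xout = low)$y
  yh <- stats::approx(freqs, y, xout = high)$y
  inside <- freqs > low & freqs < high
  fx <- c(low, freqs[inside], high)
  fy <- c(yl, y[inside], yh)
  sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
}

#' Integrated band power per channel
#'
#' Trapezoidal integral of the PSD over `[low_hz, high_hz]` with linear
#' interpolation at the band edges, so the four default bands tile 4-70 Hz
#' without double counting.
#'
#' @param psd a [power_spectrum()] result.
#' @param low_hz,high_hz band edges; must lie within the PSD frequency grid.
#' @return named numeric vector of per-channel band power.
#' @export
band_power <- function(psd, low_hz, high_hz) {
  if (low_hz >= high_hz) stop("low_hz must be below high_hz")
  if (low_hz < min(psd$freqs) || high_hz > max(psd$freqs))
    stop(sprintf("band [%g, %g] Hz outside the PSD grid [%g, %g] Hz",
                 low_hz, high_hz, min(psd$freqs), max(psd$freqs)))
  apply(psd$power, 1, function(y) trapz_band(psd$freqs, y, low_hz, high_hz))
}

#' Relative power level (RPL)
#'
#' The two-step normalized band statistic: first each channel's band power is
#' divided by that channel's total 4-70 Hz power (`rel`, the per-channel band
#' fraction; the four default bands sum to 1 per channel), then each band's
#' `rel` profile is divided by its sum over channels, so every band's RPL
#' profile sums to 1. The result is comparable across channels and subjects
#' with no channel or band bias.
#'
#' @param psd a [power_spectrum()] result.
#' @param bands band definition data frame, see [default_bands()].
#' @param total_band normalization interval in Hz (default `c(4, 70)`).
#' @return object of class `rpl_table`: matrix channels x bands with the
#'   per-channel `rel` fractions in attribute `"rel"`.
#' @export
compute_rpl <- function(psd, bands = default_bands(), total_band = c(4, 70)) {
  tot <- band_power(psd, total_band[1], total_band[2])
  if (any(tot <= 0))
    stop("zero total-band power on channel(s): ",
         paste(rownames(psd$power)[tot <= 0], collapse = ", "))
  rel <- sapply(seq_len(nrow(bands)), function(b)
    band_power(psd, bands$low_hz[b], bands$high_hz[b]) / tot)
  rel <- matrix(rel, nrow = nrow(psd$power),
                dimnames = list(rownames(psd$power), bands$name))
  rpl <- sweep(rel, 2, colSums(rel), "/")
  structure(rpl, rel = rel, bands = bands, total_band = total_band,
            layout = psd$layout, class = c("rpl_table", "matrix"))
}

#' Resting-state RPL pipeline
#'
#' Convenience wrapper: bandpass the resting recording 1-100 Hz, estimate
#' the Welch PSD, and compute the RPL table.
#'
#' @param rec a resting [recording()].
#' @param bands band definitions (default [default_bands()]).
#' @param seg_s,overlap_frac Welch parameters, see [power_spectrum()].
#' @return an [compute_rpl()] table.
#' @export
resting_rpl <- function(rec, bands = default_bands(), seg_s = 2,
                        overlap_frac = 0.5) {
  rec <- bandpass(rec, 1, 100)
  compute_rpl(power_spectrum(rec, seg_s, overlap_frac), bands)
}
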