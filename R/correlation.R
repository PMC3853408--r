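#' Pearson correlation with Student t test
#'
#' Sample Pearson r with `t = r sqrt((n - 2) / (1 - r^2))` and the two-sided
#' p value on `n - 2` degrees of freedom (computed via [stats::cor.test()]).
#'
#' @param x,y numeric vectors, `n >= 3`, each with nonzero variance.
#' @return list with `r`, `t`, `p`.
#' @export
pearson_with_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       p = unname(ct$p.value))
}

#' Benjamini-Hochberg significance mask
#'
#' @param p vector of p values.
#' @param q false-discovery-rate level (default 0.1).
#' @return logical mask: `TRUE` where the BH-adjusted p value is <= `q`.
#' @export
fdr_bh <- function(p, q = 0.1) stats::p.adjust(p, method = "BH") <= q

#' Anterior-posterior midline regions
#'
#' Channels within `midline_width` of the midline (`|x| <= midline_width`)
#' are split into `n_regions` contiguous anterior-posterior bands at
#' quantiles of their `y` coordinate, ordered anterior first. With five
#' regions the names are prefrontal, frontal, central, parietal, occipital.
#'
#' @param layout a [channel_layout()].
#' @param n_regions number of regions (default 5).
#' @param midline_width lateral half-width of the midline strip (default
#'   0.35).
#' @return object of class `region_map`: list with `names` (anterior ->
#'   posterior) and `members`, a named list of channel index vectors.
#' @export
define_regions <- function(layout, n_regions = 5L, midline_width = 0.35) {
  mid <- which(abs(layout$x) <= midline_width)
  if (length(mid) < n_regions)
    stop("fewer midline channels than regions; widen midline_width")
  y <- layout$y[mid]
  breaks <- unique(stats::quantile(y, probs = seq(0, 1, length.out = n_regions + 1)))
  if (length(breaks) < n_regions + 1)
    stop("cannot form ", n_regions,
         " nonempty regions from the midline channels; widen midline_width")
  bin <- cut(y, breaks, include.lowest = TRUE, labels = FALSE)
  members <- lapply(seq_len(n_regions), function(b) mid[bin == b])
  if (any(lengths(members) == 0))
    stop("empty region produced; widen midline_width")
  # anterior (largest mean y) first
  ord <- order(-vapply(members, function(i) mean(layout$y[i]), numeric(1)))
  members <- members[ord]
  nm <- if (n_regions == 5)
    c("prefrontal", "frontal", "central", "parietal", "occipital")
  else sprintf("region%d", seq_len(n_regions))
  names(members) <- nm
  structure(list(names = nm, members = members), class = "region_map")
}

#' Per-subject record joining accuracy and resting RPL
#'
#' @param subject_id identifier.
#' @param accuracy_pct best-window MI accuracy in percent, in `[0, 100]`.
#' @param rpl the subject's resting [compute_rpl()] table.
#' @export
subject_record <- function(subject_id, accuracy_pct, rpl) {
  if (accuracy_pct < 0 || accuracy_pct > 100)
    stop("accuracy_pct must lie in [0, 100]")
  if (!inherits(rpl, "rpl_table")) stop("rpl must be an rpl_table")
  structure(list(subject_id = subject_id, accuracy_pct = accuracy_pct,
                 rpl = rpl), class = "subject_record")
}

# extract an n_subjects x n_units matrix of band RPL and the accuracy vector
records_band_matrix <- function(records, band) {
  stopifnot(length(records) >= 3)
  ch0 <- rownames(records[[1]]$rpl)
  vals <- t(vapply(records, function(rec) {
    if (!identical(rownames(rec$rpl), ch0))
      stop("subjects have inconsistent channel sets (subject ",
           rec$subject_id, ")")
    if (!band %in% colnames(rec$rpl))
      stop("band '", band, "' absent from the RPL table")
    rec$rpl[, band]
  }, numeric(length(ch0))))
  list(rpl = vals, accuracy = vapply(records, `[[`, numeric(1), "accuracy_pct"),
       channels = ch0)
}

# shared core: correlate each column of X against accuracy y
correlate_units <- function(X, y, unit_names, q) {
  res <- lapply(seq_len(ncol(X)), function(j) {
    pt <- pearson_with_test(X[, j], y)
    fit <- stats::lsfit(X[, j], y)
    c(r = pt$r, t = pt$t, p = pt$p,
      fit_slope = unname(fit$coefficients[2]),
      fit_intercept = unname(fit$coefficients[1]))
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(unit = unit_names, out)
  out$significant <- fdr_bh(out$p, q)
  rownames(out) <- NULL
  out
}

#' Region-wise correlation of band RPL with accuracy
#'
#' For each anterior-posterior region: each subject's band RPL is averaged
#' over the region's member channels and correlated (Pearson, two-sided
#' Student t test) against the subjects' MI accuracies; a least-squares line
#' of accuracy on mean RPL is fitted.
#'
#' @param records list of [subject_record()]s (>= 3 subjects, identical
#'   channel sets).
#' @param region_map a [define_regions()] map.
#' @param band band name (default `"gamma"`).
#' @param q FDR level for the significance mask (default 0.1).
#' @return data frame with one row per region: `unit`, `n_channels`, `r`,
#'   `t`, `p`, `fit_slope`, `fit_intercept`, `significant`.
#' @export
region_correlation <- function(records, region_map, band = "gamma", q = 0.1) {
  rb <- records_band_matrix(records, band)
  X <- vapply(region_map$members,
              function(idx) rowMeans(rb$rpl[, idx, drop = FALSE]),
              numeric(length(records)))
  out <- correlate_units(X, rb$accuracy, region_map$names, q)
  out <- cbind(out[1], n_channels = lengths(region_map$members),
               out[-1])
  rownames(out) <- NULL
  out
}

#' Channel-wise correlation map with FDR correction
#'
#' Pearson correlation of each channel's band RPL against subject accuracy,
#' with a Benjamini-Hochberg significance mask over all channels at level
#' `q` (default 0.1).
#'
#' @inheritParams region_correlation
#' @return data frame with one row per channel: `unit`, `x`, `y`, `r`, `t`,
#'   `p`, `fit_slope`, `fit_intercept`, `significant`.
#' @export
channel_correlation_map <- function(records, band = "gamma", q = 0.1) {
  rb <- records_band_matrix(records, band)
  out <- correlate_units(rb$rpl, rb$accuracy, rb$channels, q)
  lay <- attr(records[[1]]$rpl, "layout")
  if (!is.null(lay)) {
    pos <- lay[match(rb$channels, lay$label), ]
    out <- cbind(out[1], x = pos$x, y = pos$y, out[-1])
    rownames(out) <- NULL
  }
  out
}
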