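# Minimal European Data Format (EDF, 16-bit) writer/reader. One data record
# holds the whole signal; physical scaling is per channel min/max, so a
# write/read round trip is exact up to the 16-bit quantization step.

edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

edf_num <- function(x, width = 8) {
  for (digits in 7:1) {
    s <- formatC(x, format = "g", digits = digits)
    if (nchar(s) <= width) return(edf_field(s, width))
  }
  edf_field(s, width)
}

#' Write a recording to an EDF file
#'
#' 16-bit EDF with per-channel physical scaling; the recording state is
#' stored in the recording-id header field. Quantization error is bounded by
#' the per-channel range divided by 65534.
#'
#' @param rec a [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  nc <- nrow(rec$samples); n <- ncol(rec$samples)
  pmin_ <- apply(rec$samples, 1, min)
  pmax_ <- apply(rec$samples, 1, max)
  flat <- pmax_ - pmin_ <= 0
  pmax_[flat] <- pmin_[flat] + 1
  # scale with the bounds exactly as stored in the 8-char header fields
  pmin_ <- vapply(pmin_, function(v) as.numeric(edf_num(v)), numeric(1))
  pmax_ <- vapply(pmax_, function(v) as.numeric(edf_num(v)), numeric(1))
  dmin <- -32767; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, eos = NULL, useBytes = TRUE)
  wr(edf_field("0", 8))
  wr(edf_field("migamma synthetic", 80))
  wr(edf_field(paste0("state=", rec$state), 80))
  wr(edf_field("01.01.00", 8)); wr(edf_field("00.00.00", 8))
  wr(edf_field(256 * (nc + 1), 8))
  wr(edf_field("", 44))
  wr(edf_field(1, 8))                     # one data record
  wr(edf_num(n / rec$rate, 8))            # record duration (s)
  wr(edf_field(nc, 4))
  for (f in list(function(i) edf_field(rec$layout$label[i], 16),
                 function(i) edf_field("", 80),
                 function(i) edf_field("au", 8),
                 function(i) edf_num(pmin_[i]),
                 function(i) edf_num(pmax_[i]),
                 function(i) edf_field(dmin, 8),
                 function(i) edf_field(dmax, 8),
                 function(i) edf_field("", 80),
                 function(i) edf_field(n, 32),
                 function(i) edf_field(sprintf("x=%.6g;y=%.6g",
                                               rec$layout$x[i],
                                               rec$layout$y[i]), 32)))
    for (i in seq_len(nc)) wr(f(i))
  for (i in seq_len(nc)) {
    dig <- round((rec$samples[i, ] - pmin_[i]) / (pmax_[i] - pmin_[i]) *
                   (dmax - dmin) + dmin)
    dig <- pmin(pmax(dig, dmin), dmax)
    writeBin(as.integer(dig), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Channel positions are recovered from the per-signal reserved field when
#' present (as written by this package), otherwise set to 0.
#'
#' @param path EDF file path.
#' @return a [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rd(8)                                   # version
  rd(80)                                  # patient id
  recid <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  labels <- vapply(seq_len(nc), function(i) rd(16), character(1))
  for (i in seq_len(nc)) rd(80)           # transducer
  for (i in seq_len(nc)) rd(8)            # dimension
  pmin_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nc), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nc)) rd(80)           # prefiltering
  nsamp <- vapply(seq_len(nc), function(i) as.integer(rd(32)), integer(1))
  reserved <- vapply(seq_len(nc), function(i) rd(32), character(1))

  pos <- regmatches(reserved, regexec("x=([-0-9.e]+);y=([-0-9.e]+)", reserved))
  x <- vapply(pos, function(m) if (length(m) == 3) as.numeric(m[2]) else 0,
              numeric(1))
  y <- vapply(pos, function(m) if (length(m) == 3) as.numeric(m[3]) else 0,
              numeric(1))

  M <- matrix(0, nc, nsamp[1] * n_rec)
  for (r in seq_len(n_rec)) for (i in seq_len(nc)) {
    dig <- readBin(con, integer(), n = nsamp[i], size = 2, endian = "little")
    M[i, (r - 1) * nsamp[i] + seq_len(nsamp[i])] <-
      (dig - dmin[i]) / (dmax[i] - dmin[i]) * (pmax_[i] - pmin_[i]) + pmin_[i]
  }
  rate <- nsamp[1] / (dur / 1)
  state <- if (grepl("state=task", recid)) "task" else "rest"
  recording(M, rate, channel_layout(labels, x, y), state)
}

#' Write / read a trial event table (TSV)
#'
#' Columns: `onset_sample` (0-based), `duration_samples`, `label`, `run_id`.
#'
#' @param events an [event_list()].
#' @param path file path.
#' @param duration_samples imagery-phase length in samples stored with each
#'   event (default 0 when unknown).
#' @return `path` invisibly; `read_events()` returns an [event_list()].
#' @export
write_events <- function(events, path, duration_samples = 0L) {
  df <- data.frame(onset_sample = events$onset_sample,
                   duration_samples = as.integer(duration_samples),
                   label = as.character(events$label),
                   run_id = events$run_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  event_list(df$onset_sample, df$label, df$run_id)
}

#' Write / read a ground-truth sidecar (key-value text)
#'
#' @param truth named list or one-row data frame of scalar values.
#' @param path file path.
#' @return `path` invisibly; `read_ground_truth()` returns a named list with
#'   numeric values where possible.
#' @export
write_ground_truth <- function(truth, path) {
  truth <- as.list(truth)
  writeLines(paste(names(truth), vapply(truth, as.character, character(1)),
                   sep = "\t"), path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  out <- lapply(lines, function(kv) {
    v <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(v)) kv[2] else v
  })
  names(out) <- vapply(lines, `[[`, character(1), 1)
  out
}

#' Serialize a fitted model to plain text
#'
#' Writes CSP or FLDA models as a tab-separated matrix with a `#`-prefixed
#' metadata header, readable by [read_model()].
#'
#' @param model a `csp_model` or `flda_model`.
#' @param path file path.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "csp_model")) {
    hdr <- c("#migamma csp_model",
             paste0("#eigenvalues\t",
                    paste(format(model$eigenvalues, digits = 17), collapse = "\t")))
    body <- apply(model$filters, 1, function(r)
      paste(format(r, digits = 17), collapse = "\t"))
  } else if (inherits(model, "flda_model")) {
    hdr <- c("#migamma flda_model",
             paste0("#bias\t", format(model$bias, digits = 17)),
             paste0("#class_map\t", model$class_map["positive"], "\t",
                    model$class_map["negative"]))
    body <- paste(format(model$weights, digits = 17), collapse = "\t")
  } else stop("unsupported model class")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  lines <- readLines(path)
  kind <- sub("^#migamma ", "", lines[1])
  num <- function(s) as.numeric(strsplit(s, "\t", fixed = TRUE)[[1]][-1])
  if (kind == "csp_model") {
    ev <- num(lines[2])
    W <- do.call(rbind, lapply(lines[-(1:2)], function(l)
      as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]])))
    structure(list(filters = W, eigenvalues = ev), class = "csp_model")
  } else if (kind == "flda_model") {
    cm <- strsplit(lines[3], "\t", fixed = TRUE)[[1]][-1]
    structure(list(weights = as.numeric(strsplit(lines[4], "\t")[[1]]),
                   bias = num(lines[2]),
                   class_map = c(positive = cm[1], negative = cm[2])),
              class = "flda_model")
  } else stop("unrecognized model file")
}
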