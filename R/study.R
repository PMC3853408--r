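#' Full-study configuration
#'
#' Bundles the cohort definition with every pipeline parameter and seed, so a
#' study is reproducible from its config alone.
#'
#' @param cohort a [cohort_config()].
#' @param window_s,step_s,span sliding-window design (defaults 2 s, 0.1 s,
#'   span 0-3 s from cue onset).
#' @param n_groups,n_train,n_filters CV design (defaults 10, 7, 10).
#' @param cv_seed base seed for group randomization (per subject `i` the
#'   seed `cv_seed + i` is used and logged).
#' @param bands band definitions for the RPL analysis.
#' @param q FDR level for channel-wise maps (default 0.1).
#' @export
study_config <- function(cohort = cohort_config(), window_s = 2, step_s = 0.1,
                         span = c(0, 3), n_groups = 10L, n_train = 7L,
                         n_filters = 10, cv_seed = 1L,
                         bands = default_bands(), q = 0.1) {
  stopifnot(inherits(cohort, "cohort_config"))
  structure(list(cohort = cohort, window_s = window_s, step_s = step_s,
                 span = span, n_groups = as.integer(n_groups),
                 n_train = as.integer(n_train), n_filters = n_filters,
                 cv_seed = as.integer(cv_seed), bands = bands, q = q),
            class = "study_config")
}

#' Run a full synthetic study
#'
#' Generates the cohort, estimates every subject's MI accuracy with the
#' sliding-window CV pipeline, computes every subject's resting RPL, and
#' runs the region-wise and channel-wise correlation analyses for each band.
#' Deterministic for a fixed config. When `out_dir` is given, all result
#' tables are written as CSV alongside a parameter/seed log.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory (created if missing).
#' @param verbose print per-subject progress.
#' @return object of class `study_report`: list with `subjects` (per-subject
#'   summary data frame), `records` ([subject_record()] list), `region` and
#'   `channel` (named lists of correlation data frames, one per band),
#'   `region_map`, and `config`.
#' @export
run_study <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- generate_cohort(config$cohort)

  records <- vector("list", length(cohort))
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    sub <- cohort[[i]]
    acc <- tryCatch(
      sliding_accuracy(sub$task, sub$events, config$window_s, config$step_s,
                       config$span, config$n_groups, config$n_train,
                       config$n_filters, seed = config$cv_seed + i),
      error = function(e) stop("accuracy stage failed for subject ",
                               sub$subject_id, ": ", conditionMessage(e)))
    rpl <- tryCatch(resting_rpl(sub$rest, config$bands),
                    error = function(e) stop("rpl stage failed for subject ",
                                             sub$subject_id, ": ",
                                             conditionMessage(e)))
    records[[i]] <- subject_record(sub$subject_id, acc$best_acc, rpl)
    rows[[i]] <- data.frame(subject_id = sub$subject_id,
                            erd_depth = sub$erd_depth,
                            prefrontal_gamma_amp = sub$prefrontal_gamma_amp,
                            occipital_gamma_amp = sub$occipital_gamma_amp,
                            best_start_s = acc$best_start,
                            best_acc_pct = acc$best_acc)
    if (verbose)
      message(sprintf("%s: best %.1f%% at %.1f s", sub$subject_id,
                      acc$best_acc, acc$best_start))
  }
  subjects <- do.call(rbind, rows)

  region_map <- define_regions(config$cohort$layout)
  band_names <- config$bands$name
  region <- lapply(band_names, function(b)
    region_correlation(records, region_map, b, config$q))
  channel <- lapply(band_names, function(b)
    channel_correlation_map(records, b, config$q))
  names(region) <- names(channel) <- band_names

  report <- structure(list(subjects = subjects, records = records,
                           region = region, channel = channel,
                           region_map = region_map, config = config),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects\n", nrow(x$subjects)))
  print(x$subjects, digits = 3)
  cat("\nGamma region correlations:\n")
  print(x$region$gamma, digits = 3)
  invisible(x)
}

# write every result table plus a parameter/seed log
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(report$subjects, "subjects.csv")
  for (rec in report$records)
    wcsv(data.frame(channel = rownames(rec$rpl), unclass(rec$rpl)),
         sprintf("rpl_%s.csv", rec$subject_id))
  for (b in names(report$region)) {
    wcsv(report$region[[b]], sprintf("region_%s.csv", b))
    wcsv(report$channel[[b]], sprintf("channel_%s.csv", b))
  }
  cfg <- report$config
  log <- c(sprintf("migamma %s", as.character(utils::packageVersion("migamma"))),
           sprintf("n_subjects\t%d", cfg$cohort$n_subjects),
           sprintf("cohort_seed\t%d", cfg$cohort$seed),
           sprintf("cv_seed_base\t%d", cfg$cv_seed),
           sprintf("link_slope\t%g", cfg$cohort$link_slope),
           sprintf("occipital_link_slope\t%g", cfg$cohort$occipital_link_slope),
           sprintf("link_noise_sd\t%g", cfg$cohort$link_noise_sd),
           sprintf("erd_range\t%g %g", cfg$cohort$erd_range[1], cfg$cohort$erd_range[2]),
           sprintf("rate_hz\t%g", cfg$cohort$rate),
           sprintf("n_channels\t%d", nrow(cfg$cohort$layout)),
           sprintf("window_s\t%g", cfg$window_s),
           sprintf("step_s\t%g", cfg$step_s),
           sprintf("span_s\t%g %g", cfg$span[1], cfg$span[2]),
           sprintf("n_groups\t%d", cfg$n_groups),
           sprintf("n_train\t%d", cfg$n_train),
           sprintf("n_filters\t%g", cfg$n_filters),
           sprintf("fdr_q\t%g", cfg$q))
  writeLines(log, file.path(out_dir, "study_log.txt"))
  invisible(out_dir)
}

#' Compare two sessions of the same subjects
#'
#' Pairs two study reports subject by subject and tabulates the change in
#' prefrontal gamma RPL (mean over the prefrontal region's channels) against
#' the change in MI accuracy, with the sign of the within-subject
#' association (`+1` when both quantities moved in the same direction).
#'
#' @param report_a,report_b two [run_study()] reports over the same subjects
#'   (same order).
#' @return data frame with columns `subject_id`,
#'   `delta_prefrontal_gamma_rpl`, `delta_accuracy_pct`, `association_sign`.
#' @export
compare_sessions <- function(report_a, report_b) {
  if (!identical(report_a$subjects$subject_id, report_b$subjects$subject_id))
    stop("reports cover different subjects")
  pf <- report_a$region_map$members[[1]]
  pf_rpl <- function(report) vapply(report$records, function(rec)
    mean(rec$rpl[pf, "gamma"]), numeric(1))
  d_rpl <- pf_rpl(report_b) - pf_rpl(report_a)
  d_acc <- report_b$subjects$best_acc_pct - report_a$subjects$best_acc_pct
  data.frame(subject_id = report_a$subjects$subject_id,
             delta_prefrontal_gamma_rpl = d_rpl,
             delta_accuracy_pct = d_acc,
             association_sign = sign(d_rpl * d_acc))
}
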