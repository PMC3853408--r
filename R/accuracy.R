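#' Class-stratified trial groups
#'
#' Randomly assigns trials to `n_groups` groups of equal size, with each
#' class represented as equally as possible in every group (exactly equally
#' when the class counts are divisible by `n_groups`, as in the standard
#' 120-trial design). Shuffled trials are dealt round-robin within class,
#' with the deal position carried across classes so group sizes come out
#' exactly equal. Deterministic for a fixed seed.
#'
#' @param labels two-class label vector, one per trial; the total trial
#'   count must be divisible by `n_groups`.
#' @param n_groups number of groups (default 10).
#' @param seed integer seed (required, so the assignment is reproducible).
#' @return object of class `group_assignment`: list with `group_of_trial`
#'   (0-based group index per trial) and `n_groups`.
#' @export
make_groups <- function(labels, n_groups = 10L, seed) {
  labs <- droplevels(as.factor(labels))
  n <- length(labs)
  if (n %% n_groups != 0)
    stop(sprintf("%d trials are not divisible into %d groups", n, n_groups))
  g <- integer(n)
  with_rng_seed(seed, {
    offset <- 0L
    for (cl in levels(labs)) {
      idx <- sample(which(labs == cl))
      g[idx] <- (offset + seq_along(idx) - 1L) %% n_groups
      offset <- offset + length(idx)
    }
  })
  structure(list(group_of_trial = as.integer(g),
                 n_groups = as.integer(n_groups)),
            class = "group_assignment")
}

#' Enumerate all train/test group partitions
#'
#' All `choose(n_groups, n_train)` ways of selecting training groups, each
#' paired with the complementary test groups, in deterministic lexicographic
#' order.
#'
#' @param n_groups total number of groups.
#' @param n_train training groups per partition, `0 < n_train < n_groups`.
#' @return list of lists with 0-based integer vectors `train` and `test`.
#' @examples
#' length(enumerate_partitions(10, 7))  # 120
#' @export
enumerate_partitions <- function(n_groups, n_train) {
  if (!(n_train > 0 && n_train < n_groups))
    stop("n_train must satisfy 0 < n_train < n_groups")
  all_g <- seq_len(n_groups) - 1L
  combos <- utils::combn(all_g, n_train, simplify = FALSE)
  lapply(combos, function(tr) list(train = tr, test = setdiff(all_g, tr)))
}

#' Cross-validated accuracy at one fixed window
#'
#' For every partition, CSP is fitted on the training trials only, variance
#' features are extracted, a Fisher discriminant is trained, and the hit
#' rate (%) is scored on the held-out test trials. No information flows from
#' test to training data.
#'
#' @param epochs an [epoch_set()] cut to one fixed window.
#' @param assignment a [make_groups()] assignment for these trials.
#' @param partitions partitions from [enumerate_partitions()].
#' @param n_filters CSP filters per fit (default 10).
#' @return list with `mean_acc` and `sd_acc` (percent, over partitions) and
#'   `per_partition`, the individual hit rates.
#' @export
window_accuracy <- function(epochs, assignment, partitions, n_filters = 10) {
  labs <- droplevels(epochs$labels)
  if (nlevels(labs) != 2) stop("epochs must contain exactly two classes")
  if (length(assignment$group_of_trial) != length(labs))
    stop("assignment does not match trial count")
  cls <- levels(labs)
  covs_norm <- trial_covariances(epochs, normalize = TRUE)
  covs_raw <- trial_covariances(epochs, normalize = FALSE)
  grp <- assignment$group_of_trial

  acc <- vapply(partitions, function(p) {
    tr <- which(grp %in% p$train)
    te <- which(grp %in% p$test)
    if (nlevels(droplevels(labs[tr])) != 2)
      stop("a partition produced a single-class training set")
    avg <- function(idx) {
      C <- Reduce(`+`, covs_norm[idx]) / length(idx)
      (C + t(C)) / 2
    }
    model <- fit_csp(avg(tr[labs[tr] == cls[1]]),
                     avg(tr[labs[tr] == cls[2]]), n_filters)
    W <- model$filters
    feat <- function(idx)
      t(vapply(covs_raw[idx], function(C) diag(W %*% C %*% t(W)),
               numeric(nrow(W))))
    flda <- fit_flda(feat(tr), labs[tr])
    pred <- predict(flda, feat(te))
    100 * mean(as.character(pred) == as.character(labs[te]))
  }, numeric(1))

  list(mean_acc = mean(acc), sd_acc = stats::sd(acc), per_partition = acc)
}

#' Sliding-window accuracy curve
#'
#' The motor-imagery performance estimator: the recording is bandpass
#' filtered (default 8-30 Hz), trials are cut to 2 s windows sliding in
#' 100 ms steps across the imagery phase (default span 0-3 s from cue
#' onset), and [window_accuracy()] is evaluated at each start. One group
#' assignment (drawn from `seed`) is reused for all windows so curves are
#' comparable across starts. The best mean accuracy over windows is the
#' subject's MI accuracy; ties go to the earliest start.
#'
#' @param rec a task [recording()].
#' @param events an [event_list()].
#' @param window_s window length in seconds (default 2).
#' @param step_s step between window starts in seconds (default 0.1).
#' @param span two-element span of the imagery phase in seconds from cue
#'   onset (default `c(0, 3)`).
#' @param n_groups,n_train CV design (default 10 groups, 7 training).
#' @param n_filters CSP filters (default 10).
#' @param seed group-randomization seed (required).
#' @param filter_band bandpass applied before epoching, or `NULL` to skip
#'   (e.g. if the recording is already filtered).
#' @return object of class `accuracy_curve`: list with `curve` (data frame
#'   `window_start_s`, `mean_acc_pct`, `sd_acc_pct`), `best_start`,
#'   `best_acc`, and the parameters used.
#' @export
sliding_accuracy <- function(rec, events, window_s = 2, step_s = 0.1,
                             span = c(0, 3), n_groups = 10L, n_train = 7L,
                             n_filters = 10, seed, filter_band = c(8, 30)) {
  if (window_s > span[2] - span[1] + 1e-9)
    stop("window_s cannot exceed the span length")
  if (!is.null(filter_band))
    rec <- bandpass(rec, filter_band[1], filter_band[2])
  n_win <- floor((span[2] - span[1] - window_s) / step_s + 1e-9) + 1
  starts <- span[1] + (seq_len(n_win) - 1) * step_s
  assignment <- make_groups(events$label, n_groups, seed)
  partitions <- enumerate_partitions(n_groups, n_train)

  res <- lapply(starts, function(s0) {
    ep <- epoch(rec, events, s0, s0 + window_s)
    window_accuracy(ep, assignment, partitions, n_filters)
  })
  curve <- data.frame(window_start_s = starts,
                      mean_acc_pct = vapply(res, `[[`, numeric(1), "mean_acc"),
                      sd_acc_pct = vapply(res, `[[`, numeric(1), "sd_acc"))
  best <- which.max(curve$mean_acc_pct)   # which.max takes the earliest tie
  structure(list(curve = curve,
                 best_start = curve$window_start_s[best],
                 best_acc = curve$mean_acc_pct[best],
                 params = list(window_s = window_s, step_s = step_s,
                               span = span, n_groups = n_groups,
                               n_train = n_train, n_filters = n_filters,
                               seed = seed, filter_band = filter_band)),
            class = "accuracy_curve")
}

#' @export
print.accuracy_curve <- function(x, ...) {
  cat(sprintf("<accuracy_curve> %d windows; best %.1f%% at start %.1f s\n",
              nrow(x$curve), x$best_acc, x$best_start))
  invisible(x)
}
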