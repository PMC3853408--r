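#' Per-band topographic amplitude components
#'
#' Each spectral band is given one or more spatial components; a component is
#' a Gaussian gain profile `amp * exp(-d^2 / (2 sigma^2))` around a scalp
#' position, so band power concentrates where real rhythms do: theta
#' fronto-midline, alpha occipital, beta over the two sensorimotor areas,
#' gamma prefrontal with a weaker occipital counterpart. The two gamma
#' component amplitudes are the handles by which a cohort embeds (anti-)
#' couplings with imagery ability.
#'
#' @param gamma_prefrontal,gamma_occipital amplitudes (arbitrary units,
#'   >= 0) of the prefrontal and occipital gamma components.
#' @return named list (theta, alpha, beta, gamma) of component lists; each
#'   component has `amp`, `center = c(x, y)`, `sigma`.
#' @export
default_band_amp <- function(gamma_prefrontal = 0.5, gamma_occipital = 0.3) {
  comp <- function(amp, x, y, sigma) list(amp = amp, center = c(x, y), sigma = sigma)
  list(
    theta = list(comp(0.6, 0,  0.7, 0.5)),
    alpha = list(comp(1.2, 0, -0.8, 0.5)),
    beta  = list(comp(0.8, -0.5, 0, 0.35), comp(0.8, 0.5, 0, 0.35)),
    gamma = list(comp(gamma_prefrontal, 0,  0.8, 0.4),
                 comp(gamma_occipital,  0, -0.8, 0.4))
  )
}

#' Ground-truth subject parameters for the simulator
#'
#' @param erd_depth fractional attenuation of 8-30 Hz variance during motor
#'   imagery on contralateral sensorimotor channels, in `[0, 1)`.
#' @param band_amp per-band topographic components, see [default_band_amp()].
#' @param noise_scale amplitude of the 1/f background (>= 0).
#' @param seed integer seed making this subject's recordings reproducible.
#' @return object of class `subject_params`.
#' @export
subject_params <- function(erd_depth = 0.4, band_amp = default_band_amp(),
                           noise_scale = 1, seed = 1L) {
  if (!is.numeric(erd_depth) || erd_depth < 0 || erd_depth >= 1)
    stop("erd_depth must lie in [0, 1)")
  if (noise_scale < 0) stop("noise_scale must be >= 0")
  for (b in names(band_amp)) for (cmp in band_amp[[b]])
    if (cmp$amp < 0) stop("band amplitudes must be >= 0")
  structure(list(erd_depth = erd_depth, band_amp = band_amp,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "subject_params")
}

#' Motor-imagery session plan
#'
#' Defaults follow the standard design: 3 runs of 40 trials, 20 per class.
#'
#' @param runs number of runs (>= 1).
#' @param trials_per_class trials per class per run (>= 1).
#' @export
session_plan <- function(runs = 3L, trials_per_class = 20L) {
  if (runs < 1 || trials_per_class < 1)
    stop("runs and trials_per_class must be >= 1")
  structure(list(runs = as.integer(runs),
                 trials_per_class = as.integer(trials_per_class)),
            class = "session_plan")
}

# --- internal synthesis primitives -----------------------------------------

# Shape white noise by a gain profile over |frequency|; works on a padded
# highly-composite FFT length and truncates back, returns unit variance.
shaped_noise <- function(n, rate, gain_fun) {
  m <- stats::nextn(n, c(2, 3, 5))
  z <- stats::rnorm(m)
  f <- seq(0, m - 1) * rate / m
  f <- pmin(f, rate - f)            # two-sided |frequency|
  gain <- gain_fun(f)
  gain[1] <- 0                      # zero mean
  x <- Re(stats::fft(stats::fft(z) * gain, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# White noise spectrally shaped to a 1/f amplitude spectrum (flattened below
# 1 Hz to avoid the DC divergence), unit variance.
pink_noise <- function(n, rate) {
  shaped_noise(n, rate, function(f) 1 / pmax(f, 1))
}

# Band-limited noise: FFT mask with half-cosine edges of `edge` Hz, unit
# variance. Amplitude-modulated narrowband noise rather than a sinusoid, so
# Welch estimates on it behave like real oscillations.
narrowband_noise <- function(n, rate, low, high, edge = 1) {
  shaped_noise(n, rate, function(f) {
    gain <- numeric(length(f))
    gain[f >= low & f <= high] <- 1
    lo <- f >= low - edge & f < low
    gain[lo] <- 0.5 * (1 + cos(pi * (low - f[lo]) / edge))
    hi <- f > high & f <= high + edge
    gain[hi] <- 0.5 * (1 + cos(pi * (f[hi] - high) / edge))
    gain
  })
}

# frequency ranges of the simulated rhythms (Hz)
synth_band_ranges <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 70))
}

# channels x 1 gain vector for one band's component list
band_gain <- function(layout, components) {
  g <- numeric(nrow(layout))
  for (cmp in components) {
    d2 <- (layout$x - cmp$center[1])^2 + (layout$y - cmp$center[2])^2
    g <- g + cmp$amp * exp(-d2 / (2 * cmp$sigma^2))
  }
  g
}

# Slow log-normal amplitude envelope (cutoff ~0.1 Hz, log-sd `lsd`): real
# rhythms wax and wane over seconds, which is what gives single-trial band
# variances their spread. Normalized so E[env^2] = 1.
slow_envelope <- function(n, rate, lsd = 0.5) {
  slow <- shaped_noise(n, rate, function(f) as.numeric(f <= 0.1))
  env <- exp(lsd * slow)
  env / sqrt(mean(env^2))
}

# background + shared amplitude-modulated band sources; assumes RNG state
# already set
synth_base_signal <- function(layout, params, n, rate) {
  nc <- nrow(layout)
  M <- matrix(0, nc, n)
  if (params$noise_scale > 0)
    for (ch in seq_len(nc))
      M[ch, ] <- params$noise_scale * pink_noise(n, rate)
  ranges <- synth_band_ranges()
  for (b in names(ranges)) {
    comps <- params$band_amp[[b]]
    if (is.null(comps)) next
    g <- band_gain(layout, comps)
    if (all(g == 0)) next
    src <- narrowband_noise(n, rate, ranges[[b]][1], ranges[[b]][2]) *
      slow_envelope(n, rate)
    M <- M + tcrossprod(g, src)
  }
  M
}

# --- generators -------------------------------------------------------------

#' Generate a resting-state recording
#'
#' Each channel is a 1/f background plus shared band-limited oscillatory
#' sources (theta, alpha, beta, gamma) weighted by the channel's topographic
#' gain. Deterministic for a fixed `params$seed`.
#'
#' @param layout a [channel_layout()].
#' @param params a [subject_params()].
#' @param duration_s recording length in seconds (default 60, the standard
#'   eyes-open resting acquisition).
#' @param rate sampling rate in Hz (default 500).
#' @return a [recording()] with `state = "rest"`.
#' @examples
#' lay <- meg_grid_layout(20)
#' rec <- generate_resting(lay, subject_params(seed = 7), duration_s = 10)
#' @export
generate_resting <- function(layout, params, duration_s = 60, rate = 500) {
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("duration_s must be positive")
  if (nrow(layout) < 1) stop("layout must contain at least one channel")
  n <- round(duration_s * rate)
  M <- with_rng_seed(params$seed,
                     synth_base_signal(layout, params, n, rate))
  recording(M, rate, layout, "rest")
}

#' Generate a motor-imagery session
#'
#' Builds a continuous task recording plus its event table. Each trial is
#' 2 s preparation (fixation), a 3 s imagery phase starting at cue onset,
#' 2 s blank rest, then a uniform random 0-2 s inter-trial interval. Within
#' each run the two classes appear equally often in random order. During the
#' imagery phase the 8-30 Hz component of contralateral sensorimotor channels
#' (see [scalp_zones()]) is attenuated so its variance drops by
#' `params$erd_depth`, with 200 ms raised-cosine ramps at the phase
#' boundaries. Deterministic for a fixed `params$seed`.
#'
#' @inheritParams generate_resting
#' @param plan a [session_plan()].
#' @return list with elements `recording` (state `"task"`) and `events`
#'   (an [event_list()]; onsets are 0-based cue-onset samples).
#' @export
generate_mi_session <- function(layout, params, plan = session_plan(),
                                rate = 500) {
  if (nrow(layout) < 1) stop("layout must contain at least one channel")
  stopifnot(inherits(plan, "session_plan"))
  prep_s <- 2; mi_s <- 3; rest_s <- 2; lead_s <- 1; tail_s <- 1
  n_trials <- plan$runs * 2L * plan$trials_per_class

  out <- with_rng_seed(params$seed + 1L, {
    labels <- unlist(lapply(seq_len(plan$runs), function(r)
      sample(rep(c("left", "right"), each = plan$trials_per_class))))
    run_id <- rep(seq_len(plan$runs), each = 2L * plan$trials_per_class)
    jitter <- stats::runif(n_trials, 0, 2)

    onsets <- integer(n_trials)
    t_cursor <- lead_s
    for (i in seq_len(n_trials)) {
      onsets[i] <- round((t_cursor + prep_s) * rate)
      t_cursor <- t_cursor + prep_s + mi_s + rest_s + jitter[i]
    }
    n <- round((t_cursor + tail_s) * rate)
    M <- synth_base_signal(layout, params, n, rate)
    list(M = M, onsets = onsets, labels = labels, run_id = run_id, n = n)
  })

  M <- out$M
  if (params$erd_depth > 0) {
    zones <- scalp_zones(layout)
    g <- sqrt(1 - params$erd_depth)
    ramp_n <- round(0.2 * rate)
    mi_n <- round(mi_s * rate)
    make_env <- function(attenuated_class) {
      env <- rep(1, out$n)
      for (i in which(out$labels == attenuated_class)) {
        s <- out$onsets[i] + 1L               # 1-based start of MI phase
        down <- 1 - (1 - g) * 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
        env[s:(s + ramp_n - 1L)] <- down
        env[(s + ramp_n):(s + mi_n - 1L)] <- g
        up <- g + (1 - g) * 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
        env[(s + mi_n):(s + mi_n + ramp_n - 1L)] <- up
      }
      env
    }
    apply_erd <- function(M, idx, env) {
      if (length(idx) == 0) return(M)
      B <- bandpass_matrix(M[idx, , drop = FALSE], 8, 30, rate)
      M[idx, ] <- M[idx, , drop = FALSE] - B +
        B * matrix(env, length(idx), out$n, byrow = TRUE)
      M
    }
    # contralateral organization: left-hand imagery suppresses the right
    # hemisphere's sensorimotor rhythm and vice versa
    M <- apply_erd(M, zones$sm_right, make_env("left"))
    M <- apply_erd(M, zones$sm_left,  make_env("right"))
  }

  list(recording = recording(M, rate, layout, "task"),
       events = event_list(out$onsets, out$labels, out$run_id))
}

#' Cohort configuration
#'
#' Defines a synthetic cohort in which each subject's imagery ability
#' (`erd_depth`) is drawn from a uniform spread and the subject's prefrontal
#' resting gamma amplitude follows
#' `gamma_base + link_slope * erd_depth + N(0, link_noise_sd)`; the occipital
#' gamma amplitude follows the same law with `occipital_link_slope`
#' (negative by default, embedding the anterior-positive / posterior-negative
#' gradient).
#'
#' @param n_subjects number of subjects (>= 3).
#' @param link_slope slope of the prefrontal gamma ~ erd_depth coupling.
#' @param link_noise_sd sd of the coupling noise.
#' @param occipital_link_slope slope of the occipital gamma coupling.
#' @param gamma_base intercept of both couplings (amplitude units).
#' @param erd_range range of the uniform erd_depth spread.
#' @param layout a [channel_layout()].
#' @param plan a [session_plan()].
#' @param rate sampling rate in Hz.
#' @param rest_duration_s resting recording length in seconds.
#' @param noise_scale background amplitude for every subject.
#' @param seed cohort-level integer seed.
#' @export
cohort_config <- function(n_subjects = 10L, link_slope = 1.0,
                          link_noise_sd = 0.1, occipital_link_slope = -0.6,
                          gamma_base = 0.5, erd_range = c(0.1, 0.7),
                          layout = meg_grid_layout(152), plan = session_plan(),
                          rate = 500, rest_duration_s = 60, noise_scale = 1,
                          seed = 1L) {
  if (n_subjects < 3) stop("n_subjects must be >= 3 (correlation degenerate)")
  structure(list(n_subjects = as.integer(n_subjects), link_slope = link_slope,
                 link_noise_sd = link_noise_sd,
                 occipital_link_slope = occipital_link_slope,
                 gamma_base = gamma_base, erd_range = erd_range,
                 layout = layout, plan = plan, rate = rate,
                 rest_duration_s = rest_duration_s,
                 noise_scale = noise_scale, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw the per-subject ground-truth parameters of a cohort
#'
#' Draws `erd_depth` and the linked gamma amplitudes without synthesizing any
#' signals; [generate_cohort()] uses exactly these draws.
#'
#' @param config a [cohort_config()].
#' @return data frame with columns `subject_id`, `erd_depth`,
#'   `prefrontal_gamma_amp`, `occipital_gamma_amp`, `seed`.
#' @export
draw_cohort_params <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_subjects
  with_rng_seed(config$seed, {
    erd <- stats::runif(n, config$erd_range[1], config$erd_range[2])
    pf  <- config$gamma_base + config$link_slope * erd +
      stats::rnorm(n, 0, config$link_noise_sd)
    occ <- config$gamma_base + config$occipital_link_slope * erd +
      stats::rnorm(n, 0, config$link_noise_sd)
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               erd_depth = erd,
               prefrontal_gamma_amp = pmax(pf, 0.02),
               occipital_gamma_amp = pmax(occ, 0.02),
               seed = config$seed + 7919L * seq_len(n))
  })
}

#' Generate a synthetic cohort
#'
#' For each subject: draw ground truth via [draw_cohort_params()], then
#' synthesize one resting recording and one motor-imagery session whose
#' prefrontal/occipital gamma amplitudes and ERD depth realize that truth.
#'
#' @param config a [cohort_config()].
#' @return list of per-subject lists with elements `subject_id`, `params`
#'   ([subject_params()]), `erd_depth`, `prefrontal_gamma_amp`,
#'   `occipital_gamma_amp`, `rest` ([recording()]), `task` ([recording()]),
#'   `events` ([event_list()]). The ground-truth table is attached as
#'   attribute `"truth"` and the config as `"config"`.
#' @export
generate_cohort <- function(config) {
  truth <- draw_cohort_params(config)
  subjects <- lapply(seq_len(config$n_subjects), function(i) {
    p <- subject_params(
      erd_depth = truth$erd_depth[i],
      band_amp = default_band_amp(gamma_prefrontal = truth$prefrontal_gamma_amp[i],
                                  gamma_occipital = truth$occipital_gamma_amp[i]),
      noise_scale = config$noise_scale,
      seed = truth$seed[i])
    rest <- generate_resting(config$layout, p, config$rest_duration_s,
                             config$rate)
    ses <- generate_mi_session(config$layout, p, config$plan, config$rate)
    list(subject_id = truth$subject_id[i], params = p,
         erd_depth = truth$erd_depth[i],
         prefrontal_gamma_amp = truth$prefrontal_gamma_amp[i],
         occipital_gamma_amp = truth$occipital_gamma_amp[i],
         rest = rest, task = ses$recording, events = ses$events)
  })
  attr(subjects, "truth") <- truth
  attr(subjects, "config") <- config
  subjects
}
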