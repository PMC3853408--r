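# Shared fixtures, all built in code at test time.

# a band_amp list with every component amplitude set to zero
zero_band_amp <- function() {
  lapply(default_band_amp(), function(comps)
    lapply(comps, function(cmp) { cmp$amp <- 0; cmp }))
}

# random symmetric positive definite matrix
random_spd <- function(d) {
  A <- matrix(stats::rnorm(d * d), d)
  crossprod(A) + diag(0.1, d)
}

# Separable two-class toy epochs: class "left" has high variance on channel
# 1, class "right" on channel 2.
separable_epochs <- function(n_per_class = 20, n_ch = 4, n_samp = 50,
                             gap = 10, seed = 42) {
  n <- 2 * n_per_class
  labels <- rep(c("left", "right"), each = n_per_class)
  data <- array(0, dim = c(n, n_ch, n_samp))
  set.seed(seed)
  for (i in seq_len(n)) {
    X <- matrix(stats::rnorm(n_ch * n_samp), n_ch)
    boost <- if (labels[i] == "left") 1 else 2
    X[boost, ] <- X[boost, ] * gap
    data[i, , ] <- X
  }
  epoch_set(data, labels, 0, n_samp / 100, 100)
}

# Epochs of pure iid noise (no class information).
null_epochs <- function(n_per_class = 20, n_ch = 4, n_samp = 50, seed = 7) {
  n <- 2 * n_per_class
  set.seed(seed)
  data <- array(stats::rnorm(n * n_ch * n_samp), dim = c(n, n_ch, n_samp))
  epoch_set(data, rep(c("left", "right"), each = n_per_class), 0,
            n_samp / 100, 100)
}

# RPL-table stand-in with a prescribed gamma channel profile (other bands
# uniform); obeys the rpl_table contract well enough for correlation tests.
fake_rpl <- function(layout, gamma_profile) {
  nc <- nrow(layout)
  m <- cbind(theta = rep(1 / nc, nc), alpha = rep(1 / nc, nc),
             beta = rep(1 / nc, nc), gamma = gamma_profile / sum(gamma_profile))
  rownames(m) <- layout$label
  structure(m, layout = layout, class = c("rpl_table", "matrix"))
}

# exhaustive-search Benjamini-Hochberg oracle: reject the k smallest p values
# for the largest k with p_(k) <= k * q / m
bh_oracle <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (j in seq_len(m)) if (ps[j] <= j * q / m) k <- j
  sig <- rep(FALSE, m)
  if (k > 0) sig[o[seq_len(k)]] <- TRUE
  sig
}
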