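#' Class-wise average covariance matrices
#'
#' For each trial, the channel-by-channel sample covariance over time is
#' trace-normalized (divided by its trace) and the normalized matrices are
#' averaged within class. Normalization removes trial-to-trial global
#' amplitude differences before spatial filtering.
#'
#' @param epochs an [epoch_set()] containing exactly two classes with at
#'   least 2 trials each.
#' @return list with symmetric PSD matrices `C1`, `C2` and `classes`, the
#'   two class labels in the order used (first factor level = class 1).
#' @export
class_covariances <- function(epochs) {
  labs <- droplevels(epochs$labels)
  if (nlevels(labs) != 2)
    stop("epochs must contain exactly two classes (got ",
         nlevels(labs), ")")
  if (any(table(labs) < 2)) stop("each class needs at least 2 trials")
  covs <- trial_covariances(epochs, normalize = TRUE)
  cls <- levels(labs)
  avg <- function(idx) {
    C <- Reduce(`+`, covs[idx]) / length(idx)
    (C + t(C)) / 2
  }
  list(C1 = avg(which(labs == cls[1])), C2 = avg(which(labs == cls[2])),
       classes = cls)
}

# per-trial sample covariance matrices (list); optionally trace-normalized
trial_covariances <- function(epochs, normalize = FALSE) {
  nt <- dim(epochs$data)[1]
  lapply(seq_len(nt), function(i) {
    X <- epochs$data[i, , , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / (ncol(X) - 1)
    if (normalize) C <- C / sum(diag(C))
    C
  })
}

#' Fit common spatial patterns
#'
#' Solves the generalized eigenproblem `C1 w = lambda (C1 + C2) w` via
#' whitening of the composite covariance (numerically stable, mathematically
#' identical). Each eigenvalue `lambda` in `[0, 1]` is the fraction of
#' class-1 variance captured by its filter under composite-covariance
#' whitening; filters with `lambda` near 0 or 1 discriminate best. The
#' `n_filters/2` filters from each end of the spectrum are returned, sorted
#' by discriminability `max(lambda, 1 - lambda)` (ties broken by eigenvalue
#' index). Filters satisfy `w' (C1 + C2) w = 1`.
#'
#' @param C1,C2 symmetric positive semi-definite class covariances of equal
#'   size (see [class_covariances()]).
#' @param n_filters even number of filters to keep (default 10).
#' @return object of class `csp_model` with `filters` (n_filters x channels)
#'   and `eigenvalues`.
#' @export
fit_csp <- function(C1, C2, n_filters = 10) {
  d <- nrow(C1)
  if (!all(dim(C1) == dim(C2))) stop("C1 and C2 must have equal dimensions")
  if (max(abs(C1 - t(C1))) > 1e-8 * max(1, max(abs(C1))) ||
      max(abs(C2 - t(C2))) > 1e-8 * max(1, max(abs(C2))))
    stop("C1 and C2 must be symmetric")
  if (n_filters %% 2 != 0) stop("n_filters must be even")
  if (n_filters > d)
    stop(sprintf("n_filters (%d) cannot exceed channel count (%d)", n_filters, d))
  Cc <- C1 + C2
  ec <- eigen(Cc, symmetric = TRUE)
  if (min(ec$values) <= 1e-12 * max(ec$values))
    stop("composite covariance is singular; reduce the number of channels ",
         "(large arrays overfit spatial filters) or supply more data")
  W0 <- diag(1 / sqrt(ec$values), d) %*% t(ec$vectors)
  S <- W0 %*% C1 %*% t(W0)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)        # eigenvalues descending in [0, 1]
  W_full <- t(es$vectors) %*% W0          # rows are candidate filters
  lambda <- pmin(pmax(es$values, 0), 1)

  half <- n_filters / 2
  sel <- c(seq_len(half), seq(d - half + 1, d))
  disc <- pmax(lambda[sel], 1 - lambda[sel])
  ord <- order(-disc, sel)
  sel <- sel[ord]
  structure(list(filters = W_full[sel, , drop = FALSE],
                 eigenvalues = lambda[sel]),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d filters x %d channels; lambda: %s\n",
              nrow(x$filters), ncol(x$filters),
              paste(sprintf("%.3f", x$eigenvalues), collapse = " ")))
  invisible(x)
}

#' Variance features of spatially filtered trials
#'
#' `feature[i, j]` is the variance over time of filter `j` applied to trial
#' `i`. Plain variances are the default; set `log = TRUE` for
#' log-variances.
#'
#' @param model a [fit_csp()] model.
#' @param epochs an [epoch_set()] with matching channel count.
#' @param log take the natural log of each variance.
#' @return numeric matrix, trials x n_filters.
#' @export
csp_features <- function(model, epochs, log = FALSE) {
  W <- model$filters
  if (ncol(W) != dim(epochs$data)[2])
    stop(sprintf("model has %d channels but epochs have %d",
                 ncol(W), dim(epochs$data)[2]))
  covs <- trial_covariances(epochs)
  F <- t(vapply(covs, function(C) diag(W %*% C %*% t(W)), numeric(nrow(W))))
  if (nrow(W) == 1) F <- matrix(F, ncol = 1)
  if (log) F <- base::log(F)
  F
}
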