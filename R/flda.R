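#' Fit a Fisher linear discriminant
#'
#' Weights are proportional to `Sw^-1 (m1 - m2)` where `Sw` is the pooled
#' within-class scatter matrix and `m1`, `m2` the class means (class 1 = the
#' first factor level). The bias places the decision boundary at the midpoint
#' of the projected class means. When `Sw` is ill-conditioned (condition
#' number > 1e10) a ridge of `1e-8 * trace(Sw) / d` is added to the diagonal.
#'
#' @param features numeric matrix, samples x features.
#' @param labels two-class factor/vector, >= 2 samples per class.
#' @param ridge `"auto"` (default, conditional ridge), `"never"`, or a
#'   numeric ridge value added unconditionally.
#' @return object of class `flda_model` with `weights`, `bias` and
#'   `class_map` (`positive` score sign -> first class).
#' @export
fit_flda <- function(features, labels, ridge = "auto") {
  features <- as.matrix(features)
  labs <- droplevels(as.factor(labels))
  if (nlevels(labs) != 2) stop("labels must contain exactly two classes")
  if (any(table(labs) < 2)) stop("each class needs at least 2 samples")
  cls <- levels(labs)
  d <- ncol(features)
  X1 <- features[labs == cls[1], , drop = FALSE]
  X2 <- features[labs == cls[2], , drop = FALSE]
  m1 <- colMeans(X1); m2 <- colMeans(X2)
  scatter <- function(X, m) crossprod(sweep(X, 2, m))
  Sw <- scatter(X1, m1) + scatter(X2, m2)
  lam <- if (identical(ridge, "auto")) {
    if (d > 1 && kappa(Sw, exact = TRUE) > 1e10 || all(Sw == 0))
      1e-8 * sum(diag(Sw)) / d else 0
  } else if (identical(ridge, "never")) 0 else as.numeric(ridge)
  if (lam > 0) Sw <- Sw + diag(lam, d)
  w <- tryCatch(solve(Sw, m1 - m2), error = function(e)
    stop("within-class scatter is singular; enable the ridge fallback"))
  bias <- sum(w * (m1 + m2)) / 2
  structure(list(weights = as.numeric(w), bias = bias,
                 class_map = c(positive = cls[1], negative = cls[2])),
            class = "flda_model")
}

#' @export
print.flda_model <- function(x, ...) {
  cat(sprintf("<flda_model> %d features; score >= 0 -> %s, < 0 -> %s\n",
              length(x$weights), x$class_map["positive"],
              x$class_map["negative"]))
  invisible(x)
}

#' Classify feature rows with a fitted discriminant
#'
#' Scores `x . w - bias`; a non-negative score (including points exactly on
#' the boundary) is assigned to the positive class of `class_map`.
#'
#' @param object an [fit_flda()] model.
#' @param features numeric matrix, samples x features, width matching the
#'   model.
#' @param ... unused.
#' @return factor of predicted class labels.
#' @export
predict.flda_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != length(object$weights))
    stop(sprintf("feature width %d does not match model width %d",
                 ncol(features), length(object$weights)))
  score <- as.numeric(features %*% object$weights) - object$bias
  factor(ifelse(score >= 0, object$class_map["positive"],
                object$class_map["negative"]),
         levels = unname(object$class_map[c("positive", "negative")]))
}
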