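#' Fit z-score normalization parameters
#'
#' Per-feature arithmetic mean and standard deviation of a training score
#' table.  The population standard deviation (no Bessel correction) is the
#' default, matching the plain "mean and standard deviation" definition;
#' set `sample_sd = TRUE` for the n-1 denominator.
#'
#' @param scores Numeric matrix or data.frame, one comparison per row, one
#'   matcher per column (conventionally `sift`, `shape`, `orientation`).
#' @param sample_sd Use the sample (n-1) standard deviation.
#' @return A `score_normalization` list with `mean` and `sd` vectors.
#' @export
fit_normalization <- function(scores, sample_sd = FALSE) {
  x <- as.matrix(scores)
  if (nrow(x) < 2L) stop("need at least 2 training score vectors")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, sd)
  if (!sample_sd) sdv <- sdv * sqrt((nrow(x) - 1) / nrow(x))
  if (any(sdv <= 0))
    stop("zero variance in feature(s): ",
         paste(colnames(x)[sdv <= 0], collapse = ", "))
  structure(list(mean = mu, sd = sdv), class = "score_normalization")
}

#' Apply (or invert) z-score normalization
#'
#' @param scores Numeric vector (one score vector) or matrix/data.frame
#'   (one per row).
#' @param params A `score_normalization` from [fit_normalization()].
#' @param inverse Undo the transform.
#' @return Normalized (or restored) scores, same shape as the input.
#' @export
zscore <- function(scores, params, inverse = FALSE) {
  stopifnot(inherits(params, "score_normalization"))
  x <- if (is.null(dim(scores))) matrix(scores, 1L) else as.matrix(scores)
  if (ncol(x) != length(params$mean))
    stop("score vector length does not match the fitted parameters")
  out <- if (inverse) sweep(sweep(x, 2L, params$sd, "*"), 2L, params$mean, "+")
         else sweep(sweep(x, 2L, params$mean, "-"), 2L, params$sd, "/")
  if (is.null(dim(scores))) drop(out) else out
}

#' Weighted-sum score fusion
#'
#' Dot product of the normalized score vector with nonnegative weights
#' summing to one.  All inputs are distances, so lower fused scores mean
#' more genuine.  Default weights (sift 0.1, shape 0.7, orientation 0.2)
#' are the combined-finger operating point reported for this pipeline.
#'
#' @param z Normalized score vector (or matrix, one vector per row).
#' @param weights Nonnegative weights summing to 1.
#' @return Fused score(s).
#' @export
weighted_sum <- function(z, weights = c(sift = 0.1, shape = 0.7,
                                        orientation = 0.2)) {
  if (any(weights < 0)) stop("fusion weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-8)
    stop("fusion weights must sum to 1 (got ", sum(weights), ")")
  x <- if (is.null(dim(z))) matrix(z, 1L) else as.matrix(z)
  if (ncol(x) != length(weights))
    stop("weight vector length does not match the score vector")
  out <- drop(x %*% weights)
  unname(out)
}

#' Train an RBF-kernel C-SVC score fuser
#'
#' Soft-margin support-vector classification on labeled normalized score
#' vectors (+1 genuine, -1 imposter), solved by sequential minimal
#' optimization; the RBF kernel is `exp(-gamma * |x - x'|^2)`.  Defaults
#' `gamma = 0.006`, `cost = 1.2` are the empirically tuned fusion settings
#' for z-scored vein matcher triplets.
#'
#' @param x Numeric matrix of normalized score vectors (rows).
#' @param labels Vector in `{1, -1}` (or logical, `TRUE` = genuine).
#' @param gamma RBF kernel width parameter.
#' @param cost Soft-margin cost C.
#' @return A `fusion_model` of kind `"svm"`.
#' @export
fit_svm <- function(x, labels, gamma = 0.006, cost = 1.2) {
  x <- as.matrix(x)
  if (is.logical(labels)) labels <- ifelse(labels, 1, -1)
  labels <- as.numeric(labels)
  if (!all(labels %in% c(-1, 1))) stop("labels must be +1/-1 (or logical)")
  if (length(unique(labels)) < 2L)
    stop("training set must contain both classes")
  if (nrow(x) != length(labels)) stop("row/label count mismatch")
  fit <- .svm_smo_cpp(x, labels, cost, gamma)
  keep <- fit$alpha > 1e-8
  structure(list(kind = "svm", sv = x[keep, , drop = FALSE],
                 alpha_y = fit$alpha[keep] * labels[keep], b = fit$b,
                 gamma = gamma, cost = cost),
            class = "fusion_model")
}

#' Weighted-sum fusion model object
#'
#' @param weights See [weighted_sum()].
#' @return A `fusion_model` of kind `"weighted_sum"`.
#' @export
weighted_model <- function(weights = c(sift = 0.1, shape = 0.7,
                                       orientation = 0.2)) {
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("weights must be nonnegative and sum to 1")
  structure(list(kind = "weighted_sum", weights = weights),
            class = "fusion_model")
}

#' SVM decision values
#'
#' Signed distance-like decision value `sum(alpha_i c_i K(x_i, x)) + b`;
#' positive means the genuine side.
#'
#' @param model A `fusion_model` of kind `"svm"`.
#' @param x Score vector or matrix of vectors (rows).
#' @return Numeric decision value(s).
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "fusion_model"), model$kind == "svm")
  x <- if (is.null(dim(x))) matrix(x, 1L) else as.matrix(x)
  d2 <- outer(rowSums(x^2), rowSums(model$sv^2), "+") -
    2 * tcrossprod(x, model$sv)
  drop(exp(-model$gamma * pmax(d2, 0)) %*% model$alpha_y + model$b)
}

#' Fuse a normalized score vector
#'
#' Weighted-sum models return the weighted sum; SVM models return the
#' negated decision value so that, as for every matcher in this package,
#' lower fused scores mean more genuine.
#'
#' @param z Normalized score vector or matrix (rows).
#' @param model A `fusion_model`.
#' @return Fused score(s), lower = genuine.
#' @export
fuse <- function(z, model) {
  if (!inherits(model, "fusion_model")) stop("model is not a fitted fuser")
  switch(model$kind,
    weighted_sum = weighted_sum(z, model$weights),
    svm = -svm_decision(model, z),
    stop("unknown fusion model kind: ", model$kind)
  )
}

#' @export
print.fusion_model <- function(x, ...) {
  if (x$kind == "weighted_sum") {
    cat("fusion_model (weighted sum):",
        paste(sprintf("%s=%.3g", names(x$weights), x$weights),
              collapse = ", "), "\n")
  } else {
    cat("fusion_model (RBF C-SVC):", nrow(x$sv), "support vectors, gamma =",
        x$gamma, ", cost =", x$cost, "\n")
  }
  invisible(x)
}
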