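#' Detect scale-invariant keypoints and 128-element descriptors
#'
#' Standard difference-of-Gaussian keypoint detection on the (smoothed,
#' cropped) grayscale image: scale-space extremum detection, sub-pixel
#' localization with contrast and edge rejection, gradient-orientation
#' assignment, and the 4 x 4 x 8 = 128-element descriptor, L2-normalized
#' with the usual 0.2 clipping.  Deterministic for a fixed image.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param n_layers DoG layers per octave.
#' @param contrast_thresh Minimum interpolated DoG contrast (on the `[0, 1]`
#'   intensity scale).
#' @param edge_thresh Principal-curvature ratio bound for edge rejection.
#' @param upsample Double the image before building the pyramid (detects
#'   smaller structures; the default).
#' @return A `sift_features` list: `keypoints`, a data.frame with columns
#'   `x`, `y` (1-based pixel coordinates), `scale`, `angle`, `response`; and
#'   `descriptors`, a numeric matrix with one 128-element unit-norm row per
#'   keypoint.  Zero keypoints (e.g. a constant image) gives empty
#'   components, not an error.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3))
#' f <- detect_keypoints(gaussian_smooth(ph$image))
#' nrow(f$keypoints)
detect_keypoints <- function(img, n_layers = 3L, contrast_thresh = 0.04,
                             edge_thresh = 10, upsample = TRUE) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (min(dim(img)) < 8L) {
    res <- list(keypoints = matrix(numeric(0), 0, 5),
                descriptors = matrix(numeric(0), 0, 128))
  } else {
    res <- .sift_cpp(img, n_layers, contrast_thresh, edge_thresh, upsample)
  }
  kp <- as.data.frame(res$keypoints)
  names(kp) <- c("x", "y", "scale", "angle", "response")
  structure(list(keypoints = kp, descriptors = res$descriptors),
            class = "sift_features")
}

#' @export
print.sift_features <- function(x, ...) {
  cat("sift_features:", nrow(x$keypoints), "keypoints\n")
  invisible(x)
}

#' Match every gallery keypoint to its nearest probe descriptor
#'
#' For each gallery keypoint the Euclidean-closest probe descriptor is
#' selected, yielding `m =` number of gallery keypoints candidate pairs with
#' their descriptor and geometric (image-plane Euclidean) distances.
#'
#' @param gallery,probe `sift_features` from [detect_keypoints()].
#' @return A data.frame with one row per gallery keypoint: `gallery`,
#'   `probe` (indices), `desc_dist`, `second_dist` (distance to the
#'   second-closest probe descriptor, `NA` if the probe has a single
#'   keypoint), `gx`, `gy`, `px`, `py`, `geom_dist`.
#' @export
nearest_neighbor_match <- function(gallery, probe) {
  stopifnot(inherits(gallery, "sift_features"), inherits(probe, "sift_features"))
  m <- nrow(gallery$descriptors)
  n <- nrow(probe$descriptors)
  if (m == 0L) stop("gallery has no keypoints: no-match condition")
  if (n == 0L) stop("probe has no keypoints: no-match condition")
  g <- gallery$descriptors
  q <- probe$descriptors
  d2 <- outer(rowSums(g^2), rowSums(q^2), "+") - 2 * tcrossprod(g, q)
  d2[d2 < 0] <- 0
  d <- sqrt(d2)
  best <- max.col(-d, ties.method = "first")
  desc_dist <- d[cbind(seq_len(m), best)]
  second <- if (n >= 2L) {
    vapply(seq_len(m), function(i) min(d[i, -best[i]]), numeric(1))
  } else rep(NA_real_, m)
  gxy <- gallery$keypoints[, c("x", "y")]
  pxy <- probe$keypoints[best, c("x", "y")]
  data.frame(gallery = seq_len(m), probe = best, desc_dist = desc_dist,
             second_dist = second, gx = gxy$x, gy = gxy$y,
             px = pxy$x, py = pxy$y,
             geom_dist = sqrt((gxy$x - pxy$x)^2 + (gxy$y - pxy$y)^2))
}

#' Ratio-test filter on candidate matches
#'
#' Retains pairs whose closest descriptor distance is at most `c` times the
#' second-closest.  Provided as the conventional baseline; on smooth vein
#' images the geometric filter ([geometric_filter()]) replaces it.
#'
#' @param pairs Data.frame from [nearest_neighbor_match()].
#' @param c Ratio constant in `(0, 1]` (conventionally 0.8; not prescribed
#'   for vein images).
#' @return The retained subset of `pairs`.
#' @export
lowe_ratio_filter <- function(pairs, c = 0.8) {
  if (!is.numeric(c) || length(c) != 1L || c <= 0)
    stop("ratio constant c must be positive")
  if (any(is.na(pairs$second_dist)))
    stop("ratio test needs at least two probe keypoints")
  pairs[pairs$desc_dist <= c * pairs$second_dist, , drop = FALSE]
}

#' Geometric-distance mismatch removal
#'
#' Sorts candidate pairs by the image-plane distance between the matched
#' keypoints and keeps the `k = min(T, m)` smallest; the rest are discarded
#' as mismatches.  Ties at the cut are broken by smaller descriptor
#' distance, then input order, for determinism.
#'
#' @param pairs Data.frame from [nearest_neighbor_match()].
#' @param T Retention threshold (default 20).
#' @return A `match_set` list: `pairs` (the retained rows, sorted by
#'   `geom_dist`), `k`, `T`, `m`.
#' @export
geometric_filter <- function(pairs, T = 20L) {
  m <- nrow(pairs)
  if (is.null(m) || m == 0L) stop("no candidate pairs: no-match condition")
  ord <- order(pairs$geom_dist, pairs$desc_dist, seq_len(m))
  k <- min(as.integer(T), m)
  structure(list(pairs = pairs[ord[seq_len(k)], , drop = FALSE],
                 k = k, T = as.integer(T), m = m),
            class = "match_set")
}

#' @export
print.match_set <- function(x, ...) {
  cat("match_set: k =", x$k, "of m =", x$m, "candidate pairs (T =", x$T, ")\n")
  invisible(x)
}

#' Keypoint matching score
#'
#' The arithmetic mean of the retained descriptor distances; lower means
#' more similar.
#'
#' @param ms A `match_set` from [geometric_filter()].
#' @return A single nonnegative score.
#' @export
sift_score <- function(ms) {
  stopifnot(inherits(ms, "match_set"))
  if (ms$k < 1L) stop("empty match set: no-match condition")
  mean(ms$pairs$desc_dist)
}
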