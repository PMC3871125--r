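#' Sub-region sizes for template matching
#'
#' Default sizes follow the vein-verification convention: shape templates
#' use 120 x 60 (gallery) vs 110 x 50 (probe) sub-regions, orientation
#' templates 60 x 40 vs 50 x 30.  The gallery window must strictly contain
#' the probe window so the translation search of [subregion_score()] has
#' room to move.
#'
#' @param gallery,probe Integer `c(width, height)` in pixels.
#' @return A `subregion_spec` list.
#' @export
subregion_spec <- function(gallery = c(120L, 60L), probe = c(110L, 50L)) {
  gallery <- as.integer(gallery); probe <- as.integer(probe)
  stopifnot(length(gallery) == 2L, length(probe) == 2L)
  if (any(gallery <= probe))
    stop("gallery sub-region must be strictly larger than the probe ",
         "sub-region in both dimensions")
  structure(list(gallery = gallery, probe = probe), class = "subregion_spec")
}

#' Extract keypoint-centered sub-regions from a template
#'
#' One fixed-size window per center, anchored so the keypoint sits at
#' 0-based index `floor(size / 2)` of the window; windows extending past the
#' template border are zero-padded (code 0 = background), so edge keypoints
#' still yield full-size sub-regions.  Regions may overlap.
#'
#' @param template Integer matrix (vein mask or orientation codes).
#' @param centers Matrix or data.frame with columns `x`, `y` (1-based pixel
#'   positions); one sub-region per row.
#' @param size Integer `c(width, height)` of the window.
#' @return List of `height x width` integer matrices, each with attribute
#'   `"center"`.
#' @export
extract_subregions <- function(template, centers, size) {
  stopifnot(is.matrix(template), length(size) == 2L)
  size <- as.integer(size)
  if (size[1] > ncol(template) || size[2] > nrow(template))
    stop("sub-region size exceeds the template dimensions")
  centers <- as.data.frame(centers)
  if (nrow(centers) < 1L) stop("need at least one sub-region center")
  w <- size[1]; h <- size[2]
  lapply(seq_len(nrow(centers)), function(i) {
    cx <- as.integer(round(centers$x[i])) - 1L # 0-based
    cy <- as.integer(round(centers$y[i])) - 1L
    x0 <- cx - w %/% 2L
    y0 <- cy - h %/% 2L
    out <- matrix(0L, h, w)
    xlo <- max(0L, x0); xhi <- min(ncol(template) - 1L, x0 + w - 1L)
    ylo <- max(0L, y0); yhi <- min(nrow(template) - 1L, y0 + h - 1L)
    if (xlo <= xhi && ylo <= yhi) {
      xs <- xlo:xhi; ys <- ylo:yhi
      out[ys - y0 + 1L, xs - x0 + 1L] <- template[ys + 1L, xs + 1L]
    }
    attr(out, "center") <- c(x = centers$x[i], y = centers$y[i])
    out
  })
}

#' Pixel mismatch indicator for binary shape templates
#'
#' `1` when `|P1 - P2| = 1` (one pixel is vein, the other background),
#' else `0`.
#'
#' @param p1,p2 Values in `{0, 1}` (vectorized).
#' @return Integer vector of 0/1 mismatch indicators.
#' @export
phi_shape <- function(p1, p2) {
  if (!all(p1 %in% c(0L, 1L)) || !all(p2 %in% c(0L, 1L)))
    stop("shape template values must be binary 0/1")
  as.integer(abs(p1 - p2) == 1)
}

#' Pixel mismatch indicator for orientation templates
#'
#' `1` when the two codes differ, else `0`; two background pixels (code 0)
#' agree.
#'
#' @param p1,p2 Orientation codes in `{0, ..., 8}` (vectorized).
#' @return Integer vector of 0/1 mismatch indicators.
#' @export
phi_orientation <- function(p1, p2) {
  if (!all(p1 %in% 0:8) || !all(p2 %in% 0:8))
    stop("orientation codes must lie in 0..8")
  as.integer(p1 != p2)
}

#' Translation-search mismatch score between two sub-regions
#'
#' Slides the probe window over every non-negative integer offset inside
#' the larger gallery window and returns the minimum fraction of
#' mismatching pixels (by [phi_shape()] or [phi_orientation()]), a value in
#' `[0, 1]`; 0 means the probe matches some placement exactly.
#'
#' @param a Gallery sub-region (integer matrix).
#' @param b Probe sub-region, no larger than `a` in either dimension.
#' @param phi `"shape"` or `"orientation"`.
#' @param exclude_background Orientation only: drop pixel pairs where both
#'   codes are 0 from the denominator instead of counting them as
#'   agreement (a window with only background then scores 0).
#' @return The minimum mismatch fraction, with attribute `"offset"` giving
#'   the arg-min `c(x, y)` translation.
#' @export
subregion_score <- function(a, b, phi = c("shape", "orientation"),
                            exclude_background = FALSE) {
  phi <- match.arg(phi)
  stopifnot(is.matrix(a), is.matrix(b))
  if (ncol(b) > ncol(a) || nrow(b) > nrow(a))
    stop("probe sub-region larger than gallery sub-region")
  if (phi == "shape") {
    if (!all(a %in% c(0L, 1L)) || !all(b %in% c(0L, 1L)))
      stop("shape template values must be binary 0/1")
  } else {
    if (!all(a %in% 0:8) || !all(b %in% 0:8))
      stop("orientation codes must lie in 0..8")
  }
  res <- .psi_min_cpp(matrix(as.integer(a), nrow(a), ncol(a)),
                      matrix(as.integer(b), nrow(b), ncol(b)),
                      if (phi == "shape") 0L else 1L, exclude_background)
  structure(res$psi, offset = c(x = res$x, y = res$y))
}

#' Template matching score over aligned sub-region lists
#'
#' The mean of the per-region mismatch fractions `Psi_i` between
#' corresponding gallery/probe sub-regions.
#'
#' @param gallery_regions,probe_regions Equal-length lists from
#'   [extract_subregions()].
#' @param phi `"shape"` or `"orientation"`.
#' @param exclude_background See [subregion_score()].
#' @return A `match_score` list: `per_region` (vector of `Psi_i` in
#'   `[0, 1]`), `total` (their mean), `offsets` (k x 2 matrix of arg-min
#'   translations).
#' @export
template_score <- function(gallery_regions, probe_regions,
                           phi = c("shape", "orientation"),
                           exclude_background = FALSE) {
  phi <- match.arg(phi)
  k <- length(gallery_regions)
  if (k == 0L || k != length(probe_regions))
    stop("gallery and probe region lists must be non-empty and equal length")
  psi <- numeric(k)
  offs <- matrix(0L, k, 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(k)) {
    s <- subregion_score(gallery_regions[[i]], probe_regions[[i]], phi,
                         exclude_background)
    psi[i] <- as.numeric(s)
    offs[i, ] <- attr(s, "offset")
  }
  structure(list(per_region = psi, total = mean(psi), offsets = offs),
            class = "match_score")
}

#' @export
print.match_score <- function(x, ...) {
  cat("match_score: total =", format(x$total, digits = 4),
      "over", length(x$per_region), "sub-regions\n")
  invisible(x)
}
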