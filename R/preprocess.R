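#' Gaussian smoothing with a truncated, normalized kernel
#'
#' Convolves the image with a `size x size` Gaussian kernel of standard
#' deviation `sigma`, normalized to unit sum after truncation.  The default
#' 5 x 5, sigma = 3 kernel is the standard preprocessing step for vein
#' images; note that truncating sigma = 3 at a 5 x 5 window makes the
#' effective smoothing much milder than an untruncated sigma = 3 Gaussian.
#' Borders use reflect padding so no dark frame is introduced that could
#' masquerade as a vessel.
#'
#' @param img Numeric matrix.
#' @param size Odd kernel side length in pixels.
#' @param sigma Kernel standard deviation in pixels.
#' @return Smoothed matrix of identical dimensions.
#' @export
gaussian_smooth <- function(img, size = 5L, sigma = 3) {
  stopifnot(is.matrix(img), is.numeric(img), sigma > 0)
  size <- as.integer(size)
  if (size < 1L || size %% 2L == 0L)
    stop("kernel size must be an odd positive integer, got ", size)
  if (size == 1L) return(img)
  r <- size %/% 2L
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k) # the 2-D truncated kernel is the outer product -> separable
  h <- nrow(img); w <- ncol(img)
  ridx <- reflect_index(seq_len(h + 2L * r) - r, h)
  cidx <- reflect_index(seq_len(w + 2L * r) - r, w)
  pad <- img[ridx, cidx, drop = FALSE]
  out <- matrix(0, h + 2L * r, w + 2L * r)
  for (i in -r:r) # convolve rows
    out[(1L + r):(h + r), ] <- out[(1L + r):(h + r), ] +
      k[i + r + 1L] * pad[(1L + r + i):(h + r + i), ]
  res <- matrix(0, h, w)
  for (i in -r:r) # convolve columns
    res <- res + k[i + r + 1L] * out[(1L + r):(h + r), (1L + r + i):(w + r + i)]
  res
}

# map 1-based indices (possibly out of range) into [1, n] by reflection
# about the edge pixels (symmetric half-sample-free reflection)
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * (n - 1L)
  i <- (i - 1L) %% period
  ifelse(i < n, i + 1L, period - i + 1L)
}

#' Crop a sub-grid from an image
#'
#' @param img Numeric matrix.
#' @param box Integer vector `c(x, y, width, height)`: 1-based top-left
#'   corner and extent.
#' @return The `height x width` sub-matrix, with the original offset recorded
#'   in attribute `"offset"` (`c(x, y)`).
#' @export
crop <- function(img, box) {
  stopifnot(is.matrix(img), length(box) == 4L)
  box <- as.integer(box)
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  if (w < 1L || h < 1L) stop("crop box must have positive width and height")
  if (x < 1L || y < 1L || x + w - 1L > ncol(img) || y + h - 1L > nrow(img))
    stop("crop box [", x, ",", y, ",", w, ",", h, "] out of image bounds ",
         ncol(img), "x", nrow(img))
  out <- img[y:(y + h - 1L), x:(x + w - 1L), drop = FALSE]
  attr(out, "offset") <- c(x = x, y = y)
  out
}

#' Centered crop box of a given size
#'
#' Convenience for the fixed-size crops used on vein databases (e.g. a
#' 352 x 288 capture cropped to its central 221 x 83 region).
#'
#' @param img Numeric matrix to crop from.
#' @param width,height Crop extent in pixels.
#' @return A `c(x, y, width, height)` box for [crop()].
#' @export
center_box <- function(img, width, height) {
  c(floor((ncol(img) - width) / 2) + 1L, floor((nrow(img) - height) / 2) + 1L,
    width, height)
}
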