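#' Specification of a synthetic finger-vein phantom
#'
#' The phantom emulates a cropped near-infrared finger image: a bright,
#' smoothly lit background crossed lengthwise by a few dark curvilinear
#' vessels of varying width, plus sensor noise.  Defaults describe a typical
#' cropped finger-vein frame: a 221 x 83 canvas, three vessels of 5-10 px
#' width, vessel contrast 0.25 below a 0.6 background, Gaussian noise with
#' sd 0.02 and a mild 0.1 left-to-right illumination gradient.  A vessel's
#' nominal width is the full width at half maximum (FWHM) of its Gaussian
#' intensity dip, so the ground-truth mask (pixels within half-width of the
#' centerline) delimits exactly the region where the dip exceeds half its
#' depth.
#'
#' @param width,height Canvas size in pixels.
#' @param n_vessels Number of vessels (>= 0).
#' @param width_range Numeric `c(min, max)` full vessel width in pixels.
#' @param contrast Intensity depth below the background of a reference
#'   vessel of 10 px nominal width, in `[0, 1]` units.  Actual depth scales
#'   linearly with each vessel's width (Beer-Lambert absorption is
#'   proportional to the optical path length, i.e. the vessel diameter), so
#'   thin vessels are shallower than wide ones.
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param illum_gradient Total left-to-right background intensity change.
#' @param background Background intensity level.
#' @param seed Integer seed; fixed seed gives bit-identical phantoms.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(width = 221L, height = 83L, n_vessels = 3L,
                         width_range = c(5, 10), contrast = 0.25,
                         noise_sd = 0.02, illum_gradient = 0.1,
                         background = 0.6, seed = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  n_vessels <- as.integer(n_vessels)
  if (width < 1L || height < 1L) stop("phantom canvas must be non-empty")
  if (n_vessels < 0L) stop("n_vessels must be >= 0")
  if (length(width_range) != 2L || width_range[1] > width_range[2] ||
      width_range[1] <= 0)
    stop("width_range must be positive c(min, max) with min <= max")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(width = width, height = height, n_vessels = n_vessels,
                 width_range = as.numeric(width_range), contrast = contrast,
                 noise_sd = noise_sd, illum_gradient = illum_gradient,
                 background = background, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic finger-vein phantom
#'
#' Vessel centerlines are random cubic splines spanning the canvas
#' lengthwise (finger veins extend along the finger, giving a clear
#' orientation field); each vessel dips the intensity with a Gaussian cross
#' profile whose FWHM equals the vessel's nominal width
#' (sd = width / (2 sqrt(2 ln 2))).  Ground truth: `vessel_mask` marks pixels
#' within half-width of a centerline, and `tangent_angle` holds the
#' centerline tangent (radians in `[0, pi)`) of the nearest centerline
#' point, `NA` off the mask.
#'
#' @param spec A [phantom_spec()].
#' @param centerlines Optional list of data.frames with columns `x`, `y`
#'   giving explicit centerline control points (1-based pixel coordinates)
#'   for each vessel, overriding the random splines; the number of vessels
#'   is then `length(centerlines)`.  Two control points give a straight
#'   vessel.  Mainly for controlled experiments.
#' @return A `vein_phantom` list with elements `image` (noisy), `clean`
#'   (noise-free), `vessel_mask` (0/1 integer matrix), `tangent_angle`,
#'   `spec` and `noise_seed`.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' mean(ph$vessel_mask)
generate_phantom <- function(spec, centerlines = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$height; w <- spec$width
  n_vessels <- if (is.null(centerlines)) spec$n_vessels
               else length(centerlines)
  dip <- matrix(0, h, w)
  best_dist <- matrix(Inf, h, w)
  angle <- matrix(NA_real_, h, w)
  mask <- matrix(0L, h, w)
  withr::with_seed(spec$seed, {
    for (v in seq_len(n_vessels)) {
      vw <- runif(1, spec$width_range[1], spec$width_range[2])
      cl <- vessel_centerline(w, h, knots = centerlines[[v]])
      sigma <- vw / (2 * sqrt(2 * log(2))) # FWHM = nominal width
      st <- .stamp_vessel_cpp(h, w, cl$x, cl$y, cl$tangent,
                              max(vw / 2, 3 * sigma) + 1)
      depth <- spec$contrast * vw / 10 # Beer-Lambert: depth ~ diameter
      dip <- dip + depth * exp(-st$dist^2 / (2 * sigma^2))
      mask[st$dist <= vw / 2] <- 1L
      upd <- st$dist < best_dist
      angle[upd] <- st$angle[upd]
      best_dist[upd] <- st$dist[upd]
    }
  })
  angle[mask == 0L] <- NA_real_
  illum <- matrix(rep(spec$illum_gradient *
                        ((seq_len(w) - 1) / max(w - 1, 1) - 0.5), each = h),
                  h, w)
  clean <- pmin(pmax(spec$background + illum - dip, 0), 1)
  noise_seed <- spec$seed
  img <- add_noise(clean, spec$noise_sd, noise_seed)
  structure(list(image = img, clean = clean, vessel_mask = mask,
                 tangent_angle = angle, spec = spec, noise_seed = noise_seed),
            class = "vein_phantom")
}

# smooth centerline spanning the canvas lengthwise; returns dense samples
# (~2 per pixel along x) with 1-based coords and tangent angles in [0, pi).
# Random natural-spline knots by default, explicit knots when given.
vessel_centerline <- function(w, h, knots = NULL) {
  if (is.null(knots)) {
    kx <- seq(1, w, length.out = 4L)
    ky <- runif(4L, 0.15 * h, 0.85 * h)
  } else {
    kx <- knots$x
    ky <- knots$y
  }
  if (length(unique(ky)) == 1L) # spline() needs >= 2 distinct y for stats
    return(list(x = seq(1, w, length.out = 2L * w),
                y = rep(ky[1], 2L * w),
                tangent = rep(0, 2L * w)))
  s <- spline(kx, ky, n = 2L * w, method = "natural")
  dx <- diff(s$x); dy <- diff(s$y)
  tang <- atan2(c(dy, dy[length(dy)]), c(dx, dx[length(dx)])) %% pi
  list(x = s$x, y = s$y, tangent = tang)
}

add_noise <- function(clean, noise_sd, noise_seed) {
  if (noise_sd <= 0) return(clean)
  noise <- withr::with_seed(noise_seed,
    matrix(rnorm(length(clean), 0, noise_sd), nrow(clean), ncol(clean)))
  pmin(pmax(clean + noise, 0), 1)
}

#' Geometric transform relating two genuine acquisitions
#'
#' Describes the nuisance variation between two images of the same finger:
#' a global translation and rotation plus a smooth local elastic warp.  The
#' default rotation bound is pi/8, the largest rotation an 8-level
#' orientation code can absorb.
#'
#' @param dx,dy Translation in pixels (applied to the output, i.e. the warped
#'   content moves by `+dx, +dy`).
#' @param rotation Rotation about the canvas center, radians.
#' @param elastic_amplitude Peak local displacement in pixels (0 disables).
#' @param elastic_scale Correlation length of the elastic field, pixels.
#' @param noise_seed Seed for the fresh sensor noise of the new acquisition
#'   (and the elastic field); `NULL` lets [make_genuine_pair()] derive one.
#' @param max_rotation Validation bound on `|rotation|`.
#' @return A `pair_transform` list.
#' @export
pair_transform <- function(dx = 0, dy = 0, rotation = 0,
                           elastic_amplitude = 0, elastic_scale = 8,
                           noise_seed = NULL, max_rotation = pi / 8) {
  if (abs(rotation) > max_rotation)
    stop("|rotation| exceeds the stated bound of ", signif(max_rotation, 3),
         " radians")
  if (elastic_scale <= 0) stop("elastic_scale must be positive")
  structure(list(dx = dx, dy = dy, rotation = rotation,
                 elastic_amplitude = elastic_amplitude,
                 elastic_scale = elastic_scale, noise_seed = noise_seed),
            class = "pair_transform")
}

#' Warp a phantom into a second genuine acquisition
#'
#' Applies the rigid + elastic transform of `t` to the phantom's clean image,
#' mask and tangent field (tangents are shifted by the rotation, reduced mod
#' pi), then adds fresh sensor noise.  The identity transform with
#' `noise_seed` equal to the phantom's own noise seed reproduces the phantom
#' exactly.
#'
#' @param phantom A `vein_phantom`.
#' @param t A [pair_transform()].
#' @return A new `vein_phantom`.
#' @export
make_genuine_pair <- function(phantom, t) {
  stopifnot(inherits(phantom, "vein_phantom"), inherits(t, "pair_transform"))
  h <- nrow(phantom$clean); w <- ncol(phantom$clean)
  noise_seed <- if (is.null(t$noise_seed)) phantom$noise_seed + 1L
                else as.integer(t$noise_seed)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  gx <- matrix(rep(seq_len(w), each = h), h, w)
  gy <- matrix(rep(seq_len(h), times = w), h, w)
  # inverse rigid map: undo translation, then rotation about the center
  ux <- gx - t$dx - cx
  uy <- gy - t$dy - cy
  co <- cos(-t$rotation); si <- sin(-t$rotation)
  sx <- co * ux - si * uy + cx
  sy <- si * ux + co * uy + cy
  if (t$elastic_amplitude > 0) {
    ex <- elastic_field(h, w, t$elastic_scale, t$elastic_amplitude,
                        noise_seed + 101L)
    ey <- elastic_field(h, w, t$elastic_scale, t$elastic_amplitude,
                        noise_seed + 211L)
    sx <- sx + ex
    sy <- sy + ey
  }
  clean <- matrix(.bilinear_sample_cpp(phantom$clean, as.vector(sx) - 1,
                                       as.vector(sy) - 1, 1L), h, w)
  maskv <- .nearest_sample_cpp(matrix(as.numeric(phantom$vessel_mask), h, w),
                               as.vector(sx) - 1, as.vector(sy) - 1, 0)
  mask <- matrix(as.integer(maskv > 0.5), h, w)
  angv <- .nearest_sample_cpp(phantom$tangent_angle, as.vector(sx) - 1,
                              as.vector(sy) - 1, NA_real_)
  angle <- matrix((angv + t$rotation) %% pi, h, w)
  angle[mask == 0L] <- NA_real_
  if (sum(phantom$vessel_mask) > 0L && sum(mask) == 0L)
    stop("transform pushed all vessels out of frame")
  img <- add_noise(clean, phantom$spec$noise_sd, noise_seed)
  structure(list(image = img, clean = clean, vessel_mask = mask,
                 tangent_angle = angle, spec = phantom$spec,
                 noise_seed = noise_seed),
            class = "vein_phantom")
}

# smooth zero-mean random field, peak magnitude = amplitude
elastic_field <- function(h, w, scale, amplitude, seed) {
  raw <- withr::with_seed(seed, matrix(rnorm(h * w), h, w))
  sm <- gaussian_smooth(raw, size = 2L * ceiling(2 * scale) + 1L,
                        sigma = scale)
  amplitude * sm / max(abs(sm))
}

#' Generate a labelled multi-class phantom dataset
#'
#' Emulates an acquisition campaign: each class (finger) is a freshly drawn
#' phantom, and its repeated samples are genuine-pair warps of the class
#' phantom with small random translations (+-4 px), rotations (+-0.05 rad)
#' and a 1.5 px elastic warp -- the within-finger nuisance variation of a
#' vein capture session.
#'
#' @param n_classes Number of distinct fingers.
#' @param samples_per_class Acquisitions per finger.
#' @param seed Master seed.
#' @param spec Template [phantom_spec()]; its seed field is overridden
#'   per class.
#' @return A list with `phantoms` (list of `vein_phantom`), and parallel
#'   integer vectors `class` and `sample`.
#' @export
phantom_dataset <- function(n_classes, samples_per_class, seed = 1L,
                            spec = phantom_spec()) {
  stopifnot(n_classes >= 1L, samples_per_class >= 1L)
  phantoms <- vector("list", n_classes * samples_per_class)
  cls <- smp <- integer(length(phantoms))
  idx <- 0L
  for (ci in seq_len(n_classes)) {
    cspec <- spec
    cspec$seed <- as.integer((seed + 7919L * ci) %% .Machine$integer.max)
    base <- generate_phantom(cspec)
    draws <- withr::with_seed(cspec$seed + 13L, list(
      dx = runif(samples_per_class, -4, 4),
      dy = runif(samples_per_class, -4, 4),
      rot = runif(samples_per_class, -0.05, 0.05)
    ))
    for (si in seq_len(samples_per_class)) {
      idx <- idx + 1L
      phantoms[[idx]] <- if (si == 1L) base else
        make_genuine_pair(base, pair_transform(
          dx = draws$dx[si], dy = draws$dy[si], rotation = draws$rot[si],
          elastic_amplitude = 1.5, elastic_scale = 10,
          noise_seed = cspec$seed + 1000L + si))
      cls[idx] <- ci
      smp[idx] <- si
    }
  }
  list(phantoms = phantoms, class = cls, sample = smp)
}
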