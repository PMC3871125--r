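#' Default pipeline configuration
#'
#' Collects every tunable parameter of the verification pipeline with its
#' conventional value: 5 x 5 / sigma 3 Gaussian smoothing, profile halfwidth
#' r = 4, Otsu binarization, keypoint retention threshold T = 20, shape
#' sub-regions 120 x 60 (gallery) vs 110 x 50 (probe), orientation
#' sub-regions 60 x 40 vs 50 x 30, weighted-sum weights
#' (sift 0.1, shape 0.7, orientation 0.2) and RBF C-SVC fusion with
#' gamma = 0.006, cost = 1.2.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return A `vein_config` list.
#' @export
#' @examples
#' cfg <- vein_config(curvature = list(r = 5))
#' cfg$curvature$r
vein_config <- function(...) {
  cfg <- list(
    smooth = list(size = 5L, sigma = 3),
    curvature = list(r = 4L, threshold = "otsu"),
    # vein images are smooth and low-contrast: the DoG contrast gate must sit
    # far below the 0.04 used for natural photographs or almost no keypoints
    # survive
    sift = list(n_layers = 3L, contrast_thresh = 0.005, edge_thresh = 10,
                upsample = TRUE),
    match = list(T = 20L),
    subregion = list(
      shape = subregion_spec(c(120L, 60L), c(110L, 50L)),
      orientation = subregion_spec(c(60L, 40L), c(50L, 30L)),
      exclude_background = FALSE),
    fusion = list(weights = c(sift = 0.1, shape = 0.7, orientation = 0.2),
                  gamma = 0.006, cost = 1.2),
    protocol = list(n_repeats = 20L, far_target = 0.01)
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("configuration overrides must be named")
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(overrides)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(overrides[[nm]]))
        modifyList(cfg[[nm]], overrides[[nm]]) else overrides[[nm]]
    }
  }
  structure(cfg, class = "vein_config")
}

#' Extract all per-image features
#'
#' Runs the full feature-extraction front end on one grayscale image:
#' Gaussian smoothing, difference-curvature enhancement, binarization into
#' the vein shape template, orientation coding on the shape support, and
#' keypoint detection on the smoothed grayscale image (not the binarized
#' template).
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param config A [vein_config()].
#' @return A `vein_features` list: `shape` (0/1 matrix), `orientation`
#'   (codes 0..8), `keypoints` (`sift_features`), `dmax`, and the smoothed
#'   image `smoothed`.
#' @export
extract_features <- function(img, config = vein_config()) {
  stopifnot(is.matrix(img))
  sm <- gaussian_smooth(img, config$smooth$size, config$smooth$sigma)
  dmax <- difference_curvature_map(sm, config$curvature$r)
  shape <- binarize(dmax, config$curvature$threshold)
  orient <- orientation_encode(sm, config$curvature$r, support = shape)
  kp <- detect_keypoints(sm, config$sift$n_layers,
                         config$sift$contrast_thresh,
                         config$sift$edge_thresh, config$sift$upsample)
  structure(list(shape = shape, orientation = orient, keypoints = kp,
                 dmax = dmax, smoothed = sm),
            class = "vein_features")
}

#' @export
print.vein_features <- function(x, ...) {
  cat("vein_features:", nrow(x$shape), "x", ncol(x$shape), "template,",
      round(100 * mean(x$shape), 1), "% vein pixels,",
      nrow(x$keypoints$keypoints), "keypoints\n")
  invisible(x)
}

#' Score a gallery/probe comparison
#'
#' Computes the three matcher distances between two feature sets: the mean
#' retained descriptor distance (after nearest-neighbor matching and
#' geometric mismatch removal), and the shape and orientation sub-region
#' matching scores, with sub-regions centered on the retained gallery
#' keypoints (gallery template) and their matched probe keypoints (probe
#' template).
#'
#' @param gallery,probe `vein_features` from [extract_features()].
#' @param config A [vein_config()].
#' @return A named numeric vector `c(sift, shape, orientation)`; lower
#'   values mean more similar.  If either image yields no keypoints the
#'   comparison is a no-match: all three scores are `NA`.
#' @export
score_pair <- function(gallery, probe, config = vein_config()) {
  stopifnot(inherits(gallery, "vein_features"),
            inherits(probe, "vein_features"))
  if (nrow(gallery$keypoints$keypoints) == 0L ||
      nrow(probe$keypoints$keypoints) == 0L)
    return(c(sift = NA_real_, shape = NA_real_, orientation = NA_real_))
  pairs <- nearest_neighbor_match(gallery$keypoints, probe$keypoints)
  ms <- geometric_filter(pairs, config$match$T)
  s_sift <- sift_score(ms)
  g_centers <- data.frame(x = ms$pairs$gx, y = ms$pairs$gy)
  p_centers <- data.frame(x = ms$pairs$px, y = ms$pairs$py)
  score_one <- function(feature) {
    spec <- config$subregion[[feature]]
    ga <- extract_subregions(gallery[[feature]], g_centers, spec$gallery)
    pr <- extract_subregions(probe[[feature]], p_centers, spec$probe)
    template_score(ga, pr,
                   phi = if (feature == "shape") "shape" else "orientation",
                   exclude_background = config$subregion$exclude_background
                   )$total
  }
  c(sift = s_sift, shape = score_one("shape"),
    orientation = score_one("orientation"))
}

#' Score every comparison of a verification protocol
#'
#' @param features List of `vein_features`, one per image.
#' @param class,sample Integer vectors labelling each feature set.
#' @param protocol A protocol from [enumerate_protocol()].
#' @param config A [vein_config()].
#' @return A score table: data.frame with `gallery`, `probe` (image
#'   indices), logical `genuine`, and columns `sift`, `shape`,
#'   `orientation`.
#' @export
score_protocol <- function(features, class, sample, protocol,
                           config = vein_config()) {
  idx <- function(cl, sm) which(class == cl & sample == sm)[1]
  g <- protocol$genuine
  im <- protocol$imposter
  ga <- c(mapply(idx, g$class, g$i), mapply(idx, im$class_a, im$sample_a))
  pr <- c(mapply(idx, g$class, g$j), mapply(idx, im$class_b, im$sample_b))
  genuine <- c(rep(TRUE, nrow(g)), rep(FALSE, nrow(im)))
  sc <- vapply(seq_along(ga), function(r)
    score_pair(features[[ga[r]]], features[[pr[r]]], config), numeric(3))
  data.frame(gallery = ga, probe = pr, genuine = genuine,
             sift = sc[1, ], shape = sc[2, ], orientation = sc[3, ])
}

#' End-to-end phantom verification experiment
#'
#' Generates a labelled phantom dataset, extracts features from every
#' image, scores all genuine and imposter comparisons of the protocol
#' (imposters restricted to a designated subset of samples per class), and
#' runs the repeated-split fusion evaluation.  Also reports the
#' segmentation Dice coefficient of each binarized shape template against
#' the phantom ground truth.
#'
#' @param n_classes,samples_per_class Dataset shape.
#' @param seed Master seed for phantom generation and splits.
#' @param imposter_samples Designated imposter subset (default: the last
#'   half of the samples, mirroring a train/test split of acquisitions).
#' @param spec Template [phantom_spec()].
#' @param config A [vein_config()].
#' @param fusion Fusion rules to evaluate.
#' @return A list: `report` (from [run_experiment()]), `scores` (the score
#'   table), `dice` (per-image Dice coefficients), `protocol`.
#' @export
run_phantom_experiment <- function(n_classes = 20L, samples_per_class = 6L,
                                   seed = 1L,
                                   imposter_samples = NULL,
                                   spec = phantom_spec(),
                                   config = vein_config(),
                                   fusion = c("weighted_sum", "svm")) {
  if (is.null(imposter_samples))
    imposter_samples <-
      seq_len(samples_per_class)[-seq_len(samples_per_class %/% 2L)]
  ds <- phantom_dataset(n_classes, samples_per_class, seed = seed,
                        spec = spec)
  features <- lapply(ds$phantoms, function(p)
    extract_features(p$image, config))
  dice <- vapply(seq_along(features), function(i)
    dice_coefficient(features[[i]]$shape, ds$phantoms[[i]]$vessel_mask),
    numeric(1))
  protocol <- enumerate_protocol(n_classes, samples_per_class,
                                 imposter_samples = imposter_samples)
  scores <- score_protocol(features, ds$class, ds$sample, protocol, config)
  report <- run_experiment(scores, fusion = fusion,
                           weights = config$fusion$weights,
                           gamma = config$fusion$gamma,
                           cost = config$fusion$cost,
                           n_repeats = config$protocol$n_repeats,
                           far_target = config$protocol$far_target,
                           seed = seed)
  list(report = report, scores = scores, dice = dice, protocol = protocol)
}

#' Dice overlap coefficient between two binary masks
#'
#' @param a,b 0/1 matrices of equal dimensions.
#' @return `2|A intersect B| / (|A| + |B|)`; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a == 1L); sb <- sum(b == 1L)
  if (sa + sb == 0L) return(1)
  2 * sum(a == 1L & b == 1L) / (sa + sb)
}
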