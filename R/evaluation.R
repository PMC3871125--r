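#' Enumerate genuine and imposter comparisons
#'
#' Verification protocol: genuine scores compare all unordered sample pairs
#' within each class (`n * choose(m, 2)` comparisons); imposter scores
#' compare, for every unordered class pair, all ordered sample products
#' over a designated subset of `s` samples per class (`choose(n, 2) * s^2`
#' comparisons).  The asymmetry (all samples genuine, subset imposter)
#' mirrors the usual vein-database protocol where only the test half of
#' each class enters the imposter set.
#'
#' @param n_classes Number of classes (fingers).
#' @param samples_per_class Samples per class.
#' @param imposter_samples Indices of the designated imposter subset within
#'   each class (default: all samples).
#' @return A `protocol` list: `genuine` (data.frame `class`, `i`, `j`),
#'   `imposter` (data.frame `class_a`, `sample_a`, `class_b`, `sample_b`),
#'   and `counts` with the two closed-form totals.
#' @export
#' @examples
#' enumerate_protocol(142, 10, imposter_samples = 6:10)$counts
enumerate_protocol <- function(n_classes, samples_per_class,
                               imposter_samples = seq_len(samples_per_class)) {
  n_classes <- as.integer(n_classes)
  samples_per_class <- as.integer(samples_per_class)
  if (n_classes < 2L) stop("need at least 2 classes for imposter pairs")
  if (samples_per_class < 1L) stop("need at least 1 sample per class")
  imposter_samples <- as.integer(imposter_samples)
  if (length(imposter_samples) < 1L ||
      any(imposter_samples < 1L | imposter_samples > samples_per_class))
    stop("imposter_samples must index into 1..samples_per_class")
  s <- length(imposter_samples)
  genuine <- if (samples_per_class >= 2L) {
    ij <- utils::combn(samples_per_class, 2L)
    data.frame(class = rep(seq_len(n_classes), each = ncol(ij)),
               i = rep(ij[1, ], n_classes), j = rep(ij[2, ], n_classes))
  } else data.frame(class = integer(0), i = integer(0), j = integer(0))
  ab <- utils::combn(n_classes, 2L)
  grid <- expand.grid(sample_a = imposter_samples,
                      sample_b = imposter_samples)
  imposter <- data.frame(
    class_a = rep(ab[1, ], each = nrow(grid)),
    sample_a = rep(grid$sample_a, ncol(ab)),
    class_b = rep(ab[2, ], each = nrow(grid)),
    sample_b = rep(grid$sample_b, ncol(ab)))
  counts <- c(genuine = n_classes * choose(samples_per_class, 2L),
              imposter = choose(n_classes, 2L) * s^2)
  stopifnot(nrow(genuine) == counts["genuine"],
            nrow(imposter) == counts["imposter"])
  list(genuine = genuine, imposter = imposter, counts = counts)
}

#' FAR/FRR/ROC curves and the equal error rate
#'
#' Scores follow the "lower = genuine" convention: a comparison is accepted
#' iff its score is <= the threshold.  The sweep visits every observed
#' score (plus sentinels), making FAR/FRR step functions exact and the
#' resulting EER invariant under strictly monotone transforms of all
#' scores.  The EER is found by linear interpolation between the two
#' consecutive thresholds bracketing the FAR = FRR crossing.
#'
#' @param genuine,imposter Numeric score vectors (non-empty).
#' @param n_thresholds Optional: evaluate on an equally spaced grid of this
#'   size over the pooled score range instead of at every observed score.
#' @return A `roc_result` list: `roc` (data.frame `threshold`, `far`,
#'   `frr`, `gar`) and `eer`.
#' @export
#' @examples
#' compute_roc(c(0.1, 0.2), c(0.8, 0.9))$eer
compute_roc <- function(genuine, imposter, n_thresholds = NULL) {
  if (length(genuine) == 0L || length(imposter) == 0L)
    stop("both genuine and imposter score sets must be non-empty")
  if (anyNA(genuine) || anyNA(imposter)) stop("scores contain NA")
  pool <- c(genuine, imposter)
  thr <- if (is.null(n_thresholds)) {
    sort(unique(pool))
  } else {
    seq(min(pool), max(pool), length.out = max(2L, as.integer(n_thresholds)))
  }
  thr <- c(min(pool) - 1, thr) # sentinel: reject everything
  far <- vapply(thr, function(t) mean(imposter <= t), numeric(1))
  frr <- vapply(thr, function(t) mean(genuine > t), numeric(1))
  roc <- data.frame(threshold = thr, far = far, frr = frr, gar = 1 - frr)
  diffs <- far - frr
  cross <- which(diffs >= 0)[1] # far starts 0 (<= frr side), ends 1
  eer <- if (is.na(cross)) {
    NA_real_
  } else if (cross == 1L || diffs[cross] == 0) {
    # exact tie at the crossing threshold
    (far[cross] + frr[cross]) / 2
  } else {
    i0 <- cross - 1L; i1 <- cross
    denom <- (diffs[i1] - diffs[i0])
    alpha <- if (denom == 0) 0.5 else -diffs[i0] / denom
    far[i0] + alpha * (far[i1] - far[i0])
  }
  structure(list(roc = roc, eer = eer), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: EER =", format(x$eer, digits = 4), "over",
      nrow(x$roc), "thresholds\n")
  invisible(x)
}

#' Genuine accept rate at a target false accept rate
#'
#' @param roc A `roc_result`.
#' @param far_target Largest admissible FAR.
#' @return The maximum GAR among operating points with FAR <= `far_target`.
#' @export
gar_at_far <- function(roc, far_target = 0.01) {
  stopifnot(inherits(roc, "roc_result"))
  ok <- roc$roc$far <= far_target
  if (!any(ok)) return(0)
  max(roc$roc$gar[ok])
}

#' Repeated-split fusion experiment on a score table
#'
#' Randomly splits genuine and imposter scores in half (training /
#' testing), fits z-score normalization and the fusion model on the
#' training half only, evaluates EER and GAR on the testing half, and
#' repeats.  Reported per fusion rule and per single feature (single
#' features are evaluated on the same test halves, without training).
#'
#' @param score_table Data.frame with a logical `genuine` column and one
#'   numeric column per matcher (`sift`, `shape`, `orientation`).
#' @param fusion Character vector of rules to fit: `"weighted_sum"`,
#'   `"svm"`.
#' @param weights Weighted-sum weights.
#' @param gamma,cost SVM parameters.
#' @param n_repeats Number of random splits.
#' @param far_target FAR at which GAR is reported.
#' @param seed Master seed; repeat `r` uses seed `seed + r`.
#' @return An `experiment_report` list: `summary` (data.frame with mean/sd
#'   EER and GAR per method), `per_repeat` (long data.frame), and the call
#'   parameters.
#' @export
run_experiment <- function(score_table,
                           fusion = c("weighted_sum", "svm"),
                           weights = c(sift = 0.1, shape = 0.7,
                                       orientation = 0.2),
                           gamma = 0.006, cost = 1.2, n_repeats = 20L,
                           far_target = 0.01, seed = 1L) {
  fusion <- match.arg(fusion, several.ok = TRUE)
  stopifnot(is.data.frame(score_table), "genuine" %in% names(score_table))
  feat_cols <- setdiff(names(score_table), c("genuine", "gallery", "probe"))
  gi <- which(score_table$genuine)
  ii <- which(!score_table$genuine)
  if (length(gi) < 4L || length(ii) < 4L)
    stop("insufficient scores for split evaluation")
  methods <- c(feat_cols, fusion)
  rows <- list()
  for (r in seq_len(n_repeats)) {
    split <- withr::with_seed(as.integer(seed) + r, list(
      g = sample(gi, length(gi) %/% 2L),
      i = sample(ii, length(ii) %/% 2L)))
    train <- c(split$g, split$i)
    test <- setdiff(c(gi, ii), train)
    train_tab <- score_table[train, , drop = FALSE]
    test_tab <- score_table[test, , drop = FALSE]
    norm <- fit_normalization(train_tab[, feat_cols, drop = FALSE])
    ztrain <- zscore(train_tab[, feat_cols, drop = FALSE], norm)
    ztest <- zscore(test_tab[, feat_cols, drop = FALSE], norm)
    for (mname in methods) {
      sc <- if (mname %in% feat_cols) {
        test_tab[[mname]]
      } else if (mname == "weighted_sum") {
        fuse(ztest, weighted_model(weights))
      } else {
        model <- fit_svm(ztrain, train_tab$genuine, gamma = gamma,
                         cost = cost)
        fuse(ztest, model)
      }
      roc <- compute_roc(sc[test_tab$genuine], sc[!test_tab$genuine])
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, method = mname, eer = roc$eer,
        gar = gar_at_far(roc, far_target))
    }
  }
  per_repeat <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_repeat, per_repeat$method),
    function(d) data.frame(method = d$method[1],
                           eer_mean = mean(d$eer), eer_sd = sd(d$eer),
                           gar_mean = mean(d$gar), gar_sd = sd(d$gar))))
  summary <- summary[match(methods, summary$method), , drop = FALSE]
  rownames(summary) <- NULL
  structure(list(summary = summary, per_repeat = per_repeat,
                 n_repeats = n_repeats, far_target = far_target,
                 seed = seed),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report:", x$n_repeats, "random half splits, GAR at FAR <=",
      x$far_target, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}
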