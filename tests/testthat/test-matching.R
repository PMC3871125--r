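random_features <- function(n, seed, spread = 1) {
  withr::with_seed(seed, {
    desc <- matrix(abs(rnorm(n * 128, sd = spread)), n, 128)
    desc <- desc / sqrt(rowSums(desc^2))
    xy <- cbind(runif(n, 1, 200), runif(n, 1, 80))
    make_features(xy, desc)
  })
}

test_that("nearest-neighbor matching equals the exhaustive oracle", {
  g <- random_features(20, 1)
  p <- random_features(30, 2)
  pairs <- nearest_neighbor_match(g, p)
  expect_identical(nrow(pairs), 20L) # one pair per gallery keypoint
  oracle <- oracle_nn(g$descriptors, p$descriptors)
  expect_equal(pairs$probe, as.integer(oracle[, 1]))
  expect_equal(pairs$desc_dist, oracle[, 2], tolerance = 1e-12)
  # geometric distances match the coordinate formula
  expect_equal(pairs$geom_dist,
               sqrt((pairs$gx - pairs$px)^2 + (pairs$gy - pairs$py)^2))
})

test_that("matching a set against itself is the identity with distance 0", {
  g <- random_features(15, 3)
  pairs <- nearest_neighbor_match(g, g)
  expect_equal(pairs$probe, seq_len(15))
  expect_equal(pairs$desc_dist, rep(0, 15), tolerance = 1e-6)
  # a single gallery point picks the closer of two probe descriptors
  g1 <- make_features(cbind(5, 5), g$descriptors[1, , drop = FALSE])
  p2 <- make_features(cbind(c(1, 2), c(1, 2)), g$descriptors[c(2, 1), ])
  pr <- nearest_neighbor_match(g1, p2)
  expect_identical(pr$probe, 2L)
  expect_equal(pr$desc_dist, 0, tolerance = 1e-6)
  expect_error(nearest_neighbor_match(g, make_features(cbind(1, 1)[0, , drop = FALSE],
                                                       matrix(0, 0, 128))),
               "no-match")
})

test_that("the ratio test keeps pairs per the closest/second-closest rule", {
  g <- random_features(12, 4)
  p <- random_features(12, 5)
  pairs <- nearest_neighbor_match(g, p)
  # c = 1 retains everything: closest <= second-closest by construction
  expect_identical(nrow(lowe_ratio_filter(pairs, c = 1)), nrow(pairs))
  # c -> 0 retains only exact duplicates
  pdup <- make_features(rbind(cbind(1, 1), cbind(2, 2)),
                        rbind(g$descriptors[1, ], random_features(1, 6)$descriptors))
  prs <- nearest_neighbor_match(g, pdup)
  kept <- lowe_ratio_filter(prs, c = 1e-9)
  expect_true(all(kept$desc_dist < 1e-12))
  expect_error(lowe_ratio_filter(pairs, c = 0), "positive")
  # hand-computed 3-point case: probe descriptors at known distances
  e1 <- c(1, rep(0, 127)); e2 <- c(0, 1, rep(0, 126))
  gal <- make_features(cbind(1, 1), matrix(e1, 1))
  prb <- make_features(cbind(1:3, 1), rbind(e1 * 0.9 + e2 * sqrt(1 - 0.81),
                                            e2, c(0, 0, 1, rep(0, 125))))
  # distances: sqrt(2 - 1.8) = 0.4472, sqrt(2), sqrt(2)
  pp <- nearest_neighbor_match(gal, prb)
  expect_equal(pp$desc_dist, sqrt(2 - 1.8), tolerance = 1e-9)
  expect_equal(pp$second_dist, sqrt(2), tolerance = 1e-9)
  expect_identical(nrow(lowe_ratio_filter(pp, c = 0.5)), 1L)  # 0.447 <= 0.707
  expect_identical(nrow(lowe_ratio_filter(pp, c = 0.3)), 0L)  # 0.447 >  0.424
})

test_that("the geometric filter keeps the k = min(T, m) closest pairs", {
  g <- random_features(30, 7)
  p <- random_features(40, 8)
  pairs <- nearest_neighbor_match(g, p)
  ms <- geometric_filter(pairs, T = 20)
  expect_identical(ms$k, 20L)
  expect_identical(ms$m, 30L)
  # sort-based oracle: the retained geometric distances are the 20 smallest
  expect_equal(sort(ms$pairs$geom_dist),
               sort(pairs$geom_dist)[1:20], tolerance = 1e-12)
  # every retained distance <= every discarded distance
  discarded <- setdiff(pairs$gallery, ms$pairs$gallery)
  expect_lte(max(ms$pairs$geom_dist),
             min(pairs$geom_dist[pairs$gallery %in% discarded]))
  # m < T keeps everything
  small <- nearest_neighbor_match(random_features(12, 9), p)
  expect_identical(geometric_filter(small, T = 20)$k, 12L)
  expect_error(geometric_filter(small$pairs[0, ]), "no-match")
})

test_that("the keypoint score is the mean retained descriptor distance", {
  g <- random_features(25, 10)
  p <- random_features(25, 11)
  ms <- geometric_filter(nearest_neighbor_match(g, p), T = 20)
  expect_equal(sift_score(ms), sum(ms$pairs$desc_dist) / ms$k,
               tolerance = 1e-12)
  # permutation invariance and linear scaling
  ms2 <- ms
  perm <- sample(ms$k)
  ms2$pairs <- ms$pairs[perm, ]
  expect_equal(sift_score(ms2), sift_score(ms))
  ms3 <- ms
  ms3$pairs$desc_dist <- 3 * ms$pairs$desc_dist
  expect_equal(sift_score(ms3), 3 * sift_score(ms))
  # self-comparison scores 0
  self <- geometric_filter(nearest_neighbor_match(g, g), T = 20)
  expect_equal(sift_score(self), 0, tolerance = 1e-6)
  # k = 1 returns the single distance
  one <- ms
  one$pairs <- ms$pairs[1, ]
  one$k <- 1L
  expect_equal(sift_score(one), ms$pairs$desc_dist[1])
})

test_that("genuine pairs sit geometrically closer than imposter pairs", {
  cfg <- fix_config()
  mean_geo <- function(fa, fb) {
    ms <- geometric_filter(nearest_neighbor_match(fa$keypoints, fb$keypoints),
                           T = 20)
    mean(ms$pairs$geom_dist)
  }
  set.seed(14)
  gg <- numeric(0); ii <- numeric(0)
  for (s in 1:6) {
    base <- generate_phantom(phantom_spec(seed = 600L + s))
    fa <- extract_features(base$image, cfg)
    genuine <- make_genuine_pair(base, pair_transform(
      dx = runif(1, -3, 3), dy = runif(1, -3, 3),
      rotation = runif(1, -0.04, 0.04), noise_seed = 900L + s))
    other <- generate_phantom(phantom_spec(seed = 700L + s))
    gg <- c(gg, mean_geo(fa, extract_features(genuine$image, cfg)))
    ii <- c(ii, mean_geo(fa, extract_features(other$image, cfg)))
  }
  expect_lt(mean(gg), mean(ii))
})
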