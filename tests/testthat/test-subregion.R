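test_that("sub-region specs demand a strictly larger gallery window", {
  s <- subregion_spec()
  expect_identical(s$gallery, c(120L, 60L))
  expect_identical(s$probe, c(110L, 50L))
  expect_error(subregion_spec(c(50, 30), c(50, 30)), "strictly larger")
  expect_error(subregion_spec(c(40, 60), c(50, 30)), "strictly larger")
})

test_that("sub-regions are keypoint-anchored, zero-padded, fixed-size", {
  tpl <- matrix(sample(0:1, 200 * 100, replace = TRUE), 100, 200)
  ctr <- data.frame(x = 100, y = 50)
  rg <- extract_subregions(tpl, ctr, size = c(120L, 60L))[[1]]
  expect_equal(dim(rg), c(60L, 120L))
  # anchor: the keypoint (0-based (99, 49)) sits at 0-based index
  # floor(size/2) of the window
  x0 <- 99 - 120 %/% 2  # 0-based left edge = 39
  y0 <- 49 - 60 %/% 2   # 0-based top edge = 19
  expect_equal(rg, matrix(tpl[(y0 + 1):(y0 + 60), (x0 + 1):(x0 + 120)],
                          60, 120), ignore_attr = TRUE)
  expect_identical(rg[60 %/% 2 + 1, 120 %/% 2 + 1], tpl[50, 100])
  # corner keypoint: out-of-template area is zero-padded
  corner <- extract_subregions(tpl, data.frame(x = 1, y = 1),
                               size = c(10L, 8L))[[1]]
  expect_true(all(corner[1:(8 %/% 2), ] == 0L) || 8 %/% 2 == 0)
  expect_identical(corner[8 %/% 2 + 1, 10 %/% 2 + 1], tpl[1, 1])
  # duplicate centers give identical regions
  two <- extract_subregions(tpl, data.frame(x = c(30, 30), y = c(40, 40)),
                            size = c(20L, 12L))
  expect_equal(two[[1]], two[[2]], ignore_attr = TRUE)
  expect_error(extract_subregions(matrix(0L, 5, 5), ctr, c(10L, 10L)),
               "exceeds")
})

test_that("the pixel mismatch indicators implement their truth tables", {
  expect_identical(phi_shape(0L, 1L), 1L)
  expect_identical(phi_shape(1L, 0L), 1L)
  expect_identical(phi_shape(1L, 1L), 0L)
  expect_identical(phi_shape(0L, 0L), 0L)
  expect_error(phi_shape(2L, 0L), "binary")
  expect_identical(phi_orientation(3L, 5L), 1L)
  expect_identical(phi_orientation(4L, 4L), 0L)
  expect_identical(phi_orientation(0L, 0L), 0L) # background agreement
  expect_error(phi_orientation(9L, 0L), "0..8")
})

test_that("the translation search equals the exhaustive offset oracle", {
  withr::with_seed(31, {
    for (rep in 1:4) {
      a <- matrix(sample(0:1, 12 * 8, replace = TRUE), 8, 12)
      b <- matrix(sample(0:1, 8 * 6, replace = TRUE), 6, 8)
      expect_equal(as.numeric(subregion_score(a, b, "shape")),
                   oracle_psi(a, b, phi_shape))
      ao <- matrix(sample(0:8, 12 * 8, replace = TRUE), 8, 12)
      bo <- matrix(sample(0:8, 8 * 6, replace = TRUE), 6, 8)
      expect_equal(as.numeric(subregion_score(ao, bo, "orientation")),
                   oracle_psi(ao, bo, phi_orientation))
      expect_equal(as.numeric(subregion_score(ao, bo, "orientation",
                                              exclude_background = TRUE)),
                   oracle_psi(ao, bo, phi_orientation,
                              exclude_background = TRUE))
    }
  })
})

test_that("perfect containment scores 0 and total mismatch scores 1", {
  withr::with_seed(32, {
    a <- matrix(sample(0:1, 30 * 16, replace = TRUE), 16, 30)
    b <- a[3:12, 5:24] # a true sub-window
    s <- subregion_score(a, b, "shape")
    expect_equal(as.numeric(s), 0)
    expect_equal(attr(s, "offset"), c(x = 4, y = 2))
  })
  ones <- matrix(1L, 10, 14)
  zeros <- matrix(0L, 8, 10)
  expect_equal(as.numeric(subregion_score(ones, zeros, "shape")), 1)
  expect_error(subregion_score(zeros, ones, "shape"), "larger")
  expect_error(subregion_score(matrix(2L, 4, 4), matrix(0L, 2, 2), "shape"),
               "binary")
})

test_that("translated templates score 0 within the search margins", {
  withr::with_seed(33, {
    tpl <- matrix(sample(0:1, 221 * 83, replace = TRUE, prob = c(0.8, 0.2)),
                  83, 221)
    dx <- 4L; dy <- 3L
    shifted <- matrix(0L, 83, 221)
    shifted[(1 + dy):83, (1 + dx):221] <- tpl[1:(83 - dy), 1:(221 - dx)]
    ctr <- data.frame(x = 110, y = 40)
    ga <- extract_subregions(tpl, ctr, c(120L, 60L))
    pr <- extract_subregions(shifted, data.frame(x = 110 + dx, y = 40 + dy),
                             c(110L, 50L))
    expect_equal(as.numeric(subregion_score(ga[[1]], pr[[1]], "shape")), 0)
  })
})

test_that("widening the gallery search margin never raises the score", {
  withr::with_seed(34, {
    tpl <- matrix(sample(0:1, 40 * 60, replace = TRUE), 40, 60)
    prb <- matrix(sample(0:1, 10 * 16, replace = TRUE), 10, 16)
    ctr <- data.frame(x = 30, y = 20)
    sizes <- list(c(18L, 12L), c(20L, 14L), c(24L, 18L), c(30L, 24L))
    psis <- vapply(sizes, function(sz) {
      g <- extract_subregions(tpl, ctr, sz)[[1]]
      as.numeric(subregion_score(g, prb, "shape"))
    }, numeric(1))
    expect_true(all(diff(psis) <= 1e-12))
  })
})

test_that("the template score is the mean and degenerates to global matching", {
  a1 <- matrix(0L, 6, 8); b1 <- matrix(0L, 4, 6)
  a2 <- matrix(1L, 6, 8); b2 <- matrix(0L, 4, 6)
  ts <- template_score(list(a1, a2), list(b1, b2), "shape")
  expect_equal(ts$per_region, c(0, 1))
  expect_equal(ts$total, 0.5)
  expect_error(template_score(list(), list(), "shape"), "non-empty")
  # k = 1 with the full templates as the two regions reproduces the plain
  # whole-image translation-search score
  withr::with_seed(35, {
    A <- matrix(sample(0:1, 30 * 20, replace = TRUE), 20, 30)
    B <- matrix(sample(0:1, 26 * 16, replace = TRUE), 16, 26)
    expect_equal(template_score(list(A), list(B), "shape")$total,
                 as.numeric(subregion_score(A, B, "shape")))
  })
})
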