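# Shared fixtures and independent oracles.  Fixtures are generated in code
# (no files) and memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures, inherits = FALSE))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures, inherits = FALSE)
}

# default-world phantom and its features
fix_phantom <- function() fixture("phantom", generate_phantom(phantom_spec(seed = 42L)))
fix_features <- function() fixture("features", extract_features(fix_phantom()$image, fix_config()))
fix_config <- function() vein_config()

# noiseless single straight horizontal vessel through the canvas middle
fix_straight <- function() fixture("straight", {
  spec <- phantom_spec(n_vessels = 1L, noise_sd = 0, illum_gradient = 0,
                       width_range = c(8, 8), seed = 5L)
  generate_phantom(spec, centerlines = list(data.frame(x = c(1, 221), y = 42)))
})

# clean vertical dark stripe (vessel along y): column profile is a Gaussian
# dip in x, constant in y
fix_vstripe <- function() fixture("vstripe", {
  w <- 61L; h <- 61L
  x <- matrix(rep(seq_len(w), each = h), h, w)
  0.6 - 0.25 * exp(-(x - 31)^2 / (2 * 2.5^2))
})

# rotate a matrix 90 degrees counter-clockwise (row y, col x convention)
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# exhaustive double-loop oracle for the sub-region translation search
oracle_psi <- function(a, b, phi_fun, exclude_background = FALSE) {
  wa <- ncol(a); ha <- nrow(a); wb <- ncol(b); hb <- nrow(b)
  best <- Inf
  for (x in 0:(wa - wb)) {
    for (y in 0:(ha - hb)) {
      win <- a[(y + 1):(y + hb), (x + 1):(x + wb), drop = FALSE]
      mism <- phi_fun(as.vector(win), as.vector(b))
      if (exclude_background) {
        keep <- !(as.vector(win) == 0 & as.vector(b) == 0)
        frac <- if (any(keep)) sum(mism[keep]) / sum(keep) else 0
      } else {
        frac <- sum(mism) / (wb * hb)
      }
      best <- min(best, frac)
    }
  }
  best
}

# brute-force nearest-neighbor descriptor matching
oracle_nn <- function(g, p) {
  t(vapply(seq_len(nrow(g)), function(i) {
    d <- sqrt(colSums((t(p) - g[i, ])^2))
    j <- which.min(d)
    c(j, d[j])
  }, numeric(2)))
}

# per-threshold counting oracle for FAR/FRR at a given threshold
oracle_rates <- function(genuine, imposter, thr) {
  c(far = mean(imposter <= thr), frr = mean(genuine > thr))
}

# synthetic sift_features object from a coordinate/descriptor matrix
make_features <- function(xy, desc) {
  n <- nrow(xy)
  kp <- data.frame(x = xy[, 1], y = xy[, 2], scale = rep(1, n),
                   angle = rep(0, n), response = rep(1, n))
  structure(list(keypoints = kp, descriptors = desc),
            class = "sift_features")
}

# the acceptance-scale end-to-end experiment, computed once
acceptance_run <- function() fixture("acceptance_run",
  run_phantom_experiment(n_classes = 20L, samples_per_class = 6L,
                         seed = 101L))
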