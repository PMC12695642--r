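# phantom, deformation, spiral and score-array generators

test_that("phantom generation is seeded, labelled and synapse-consistent", {
  ph <- make_phantom(48, rng_seed = 42, n_synapses = 20)
  ph2 <- make_phantom(48, rng_seed = 42, n_synapses = 20)
  expect_identical(ph$density, ph2$density)
  expect_identical(ph$labels, ph2$labels)
  expect_identical(dim(ph$density), dim(ph$labels))
  expect_true(all(ph$density >= 0))

  # exactly the requested synapse count, every point on label-4 support
  expect_equal(nrow(ph$synapses), 20)
  vox <- cbind(round(ph$synapses$z_nm / ph$voxel_size) + 1,
               round(ph$synapses$y_nm / ph$voxel_size) + 1,
               round(ph$synapses$x_nm / ph$voxel_size) + 1)
  expect_true(all(vox >= 1) && all(vox <= 48))
  expect_true(all(ph$labels[vox] == 4L))

  # all-zero densities: uniform empty volume, no synapses
  ph0 <- make_phantom(32, feature_densities = c(background = 0, neurite = 0,
                                                mitochondrion = 0,
                                                nucleus = 0, synapse = 0),
                      rng_seed = 1)
  expect_true(all(ph0$density == 0))
  expect_equal(nrow(ph0$synapses), 0)

  expect_error(make_phantom(16), "size")
})

test_that("phantom density has one mode per material present", {
  ph <- make_phantom(48, rng_seed = 3, texture_sd = 0)
  lut <- c(0.1, 0.5, 0.8, 0.65, 1.0)
  present <- sort(unique(as.vector(ph$labels)))
  expected_modes <- unique(c(0, lut[present + 1L]))  # 0 = outside pillar
  expect_setequal(round(unique(as.vector(ph$density)), 10),
                  round(expected_modes, 10))
})

test_that("deformation model honors amplitude, zero start and smoothness", {
  d <- c(32, 32, 32)
  dm0 <- make_deformation(d, amplitude = 0, rng_seed = 1)
  for (f in dm0$control_fields)
    expect_true(all(f$uz == 0 & f$uy == 0 & f$ux == 0))

  dm <- make_deformation(d, amplitude = 3, smoothness = 12, rng_seed = 5)
  expect_true(all(dm$control_fields[[1]]$uz == 0))
  peak <- max(vapply(dm$control_fields,
                     function(f) max(pxctsim:::.field_norms(f)), numeric(1)))
  expect_gt(peak, 2.97)
  expect_lte(peak, 3.0 + 1e-9)

  # empirical autocorrelation length of the field ~ smoothness (1/e lag);
  # needs a grid a few correlation lengths wide to be estimable
  dm64 <- make_deformation(c(64, 64, 64), amplitude = 3, smoothness = 12,
                           rng_seed = 5)
  f <- dm64$control_fields[[length(dm64$control_fields)]]$ux
  v <- f - mean(f)
  ac <- sapply(0:31, function(lag) {
    a <- v[, , 1:(64 - lag)]; b <- v[, , (1 + lag):64]
    cor(as.vector(a), as.vector(b))
  })
  l_e <- approx(ac, 0:31, xout = exp(-1))$y
  expect_gt(l_e, 12 * 0.8)
  expect_lt(l_e, 12 * 1.2)

  expect_error(make_deformation(d, control_times = c(0, 0.5, 0.3)),
               "increasing")
  expect_error(make_deformation(d, control_times = c(0.1, 0.5)), "start")
})

test_that("deformation fields do not fold for amplitude <= smoothness/2", {
  d <- c(32, 32, 32)
  dm <- make_deformation(d, amplitude = 6, smoothness = 12, rng_seed = 9)
  f <- dm$control_fields[[length(dm$control_fields)]]
  grad <- function(v, ax) {
    g <- array(0, d)
    if (ax == 1) g[2:31, , ] <- (v[3:32, , ] - v[1:30, , ]) / 2
    if (ax == 2) g[, 2:31, ] <- (v[, 3:32, ] - v[, 1:30, ]) / 2
    if (ax == 3) g[, , 2:31] <- (v[, , 3:32] - v[, , 1:30]) / 2
    g
  }
  a11 <- 1 + grad(f$uz, 1); a12 <- grad(f$uz, 2); a13 <- grad(f$uz, 3)
  a21 <- grad(f$uy, 1); a22 <- 1 + grad(f$uy, 2); a23 <- grad(f$uy, 3)
  a31 <- grad(f$ux, 1); a32 <- grad(f$ux, 2); a33 <- 1 + grad(f$ux, 3)
  detJ <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  expect_true(all(detJ > 0))
})

test_that("deformation_at interpolates control fields linearly and clamps", {
  dm <- make_deformation(c(16, 16, 16), control_times = c(0, 0.5, 1),
                         amplitude = 2, smoothness = 8, rng_seed = 2)
  mid <- deformation_at(dm, 0.75)
  avg <- (dm$control_fields[[2]]$ux + dm$control_fields[[3]]$ux) / 2
  expect_equal(mid$ux, avg, tolerance = 1e-12)
  expect_identical(deformation_at(dm, 2)$ux, dm$control_fields[[3]]$ux)
  expect_identical(deformation_at(dm, -1)$ux, dm$control_fields[[1]]$ux)
})

test_that("fermat spiral has calibrated spacing and distinct points", {
  expect_equal(fermat_spiral(1, 1), cbind(y = 0, x = 0))
  for (n in c(50, 200)) {
    pts <- fermat_spiral(n, 1.0)
    dm <- as.matrix(dist(pts))
    diag(dm) <- Inf
    expect_gt(min(dm), 0)                      # no coincident points
    nn <- mean(apply(dm, 1, min))
    expect_gt(nn, 0.8)
    expect_lt(nn, 1.2)
  }
  expect_error(fermat_spiral(0, 1))
  expect_error(fermat_spiral(10, 0))
})

test_that("score arrays reflect configured rates and dropouts", {
  flags <- rep(c(TRUE, FALSE), length.out = 250)
  sa <- make_score_array(250, 3, true_flags = flags, sensitivity = 1,
                         specificity = 1, dropout_rate = 0, rng_seed = 1)
  expect_identical(dim(sa$scores), c(250L, 3L, 2L))
  expect_true(all(sa$scores %in% 1:4))
  # perfect rates: binarized scores reproduce the truth exactly
  for (m in 1:2) for (a in 1:3)
    expect_identical(sa$scores[, a, m] >= 3, flags)

  sa0 <- make_score_array(50, 3, dropout_rate = 1, rng_seed = 1)
  expect_true(all(sa0$scores == 0))

  expect_error(make_score_array(10, 3, sensitivity = 1.2), "rates")
})
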