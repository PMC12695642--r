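# tomography: FBP, alignment, subtomogram splitting, optical flow,
# flow interpolation, nonrigid reconstruction

test_that("FBP recovers a delta voxel and a full phantom", {
  vol <- array(0, c(32, 32, 32))
  vol[16, 20, 12] <- 1
  ps <- static_projection_set(vol, seq(0, 179, by = 1))
  tg <- fbp(ps, "ramlak")
  am <- arrayInd(which.max(tg$volume), dim(tg$volume))
  expect_equal(as.vector(am), c(16, 20, 12))

  ph <- make_phantom(64, rng_seed = 3)
  plan <- acquisition_plan(n_angles = 180, n_subtomos = 1)
  psf <- acquire_series(ph, NULL, plan)
  tgf <- fbp(psf, "hann")
  expect_gt(cor(as.vector(tgf$volume), as.vector(ph$density)), 0.95)
  expect_error(fbp(psf, "shepp"))
})

test_that("hann suppresses high frequencies relative to ramlak", {
  ph <- make_phantom(32, rng_seed = 6)
  ps <- static_projection_set(ph$density, seq(0, 179, length.out = 60))
  vh <- fbp(ps, "hann")$volume
  vr <- fbp(ps, "ramlak")$volume
  hi_power <- function(v) {
    F2 <- Mod(fft(v))^2
    sh <- pxctsim:::.shell_index(dim(v))
    hi <- sh > 0.35 * 32          # shells above 0.35 Nyquist band
    sum(F2[hi]) / sum(F2)
  }
  expect_lt(hi_power(vh), hi_power(vr))
})

test_that("projection alignment recovers injected shifts", {
  ph <- make_phantom(48, rng_seed = 12)
  # z-compact object: vertical shifts must not clip mass off the detector,
  # or the center-of-mass consistency argument does not apply
  vol <- ph$density
  vol[c(1:8, 41:48), , ] <- 0
  ps <- static_projection_set(vol, seq(0, 179, length.out = 40))
  al0 <- align_projections(ps)
  expect_lt(max(abs(as.matrix(al0$alignment_shifts))), 0.1)

  set.seed(77)
  shifts <- cbind(dz = runif(40, -3, 3), dt = runif(40, -3, 3))
  shifted <- ps
  for (i in 1:40)
    shifted$projections[[i]] <-
      pxctsim:::.shift_image(ps$projections[[i]], shifts[i, 1], shifts[i, 2])
  al <- align_projections(shifted)
  err_z <- abs(al$alignment_shifts$dz - shifts[, "dz"])
  # horizontal shifts are identifiable only up to the sinusoid fit; compare
  # projections directly instead
  expect_lt(max(err_z), 0.5)
  rec0 <- fbp(ps, "hann")$volume
  rec_sh <- fbp(shifted, "hann")$volume
  rec_al <- fbp(al, "hann")$volume
  err <- function(v) sqrt(mean((v - rec0)^2))
  expect_lt(err(rec_al), err(rec_sh))
  bad <- ps
  bad$projections <- lapply(bad$projections, function(p) p * 0)
  expect_error(align_projections(bad), "degenerate")
})

test_that("subtomogram split is an interlaced partition", {
  ph <- make_phantom(32, rng_seed = 2)
  ps <- static_projection_set(ph$density, seq(0, 180, length.out = 17)[1:16])
  s1 <- split_subtomograms(ps, 1)
  expect_equal(s1[[1]]$angles, ps$angles)

  s4 <- split_subtomograms(ps, 4)
  all_angles <- sort(unlist(lapply(s4, `[[`, "angles")))
  expect_equal(all_angles, sort(ps$angles))                  # union = input
  expect_equal(sum(lengths(lapply(s4, `[[`, "angles"))), 16) # disjoint
  for (j in 1:4) {
    a <- sort(s4[[j]]$angles)
    expect_length(a, 4)
    expect_equal(diff(a), rep(45, 3), tolerance = 1e-9)      # uniform 45 deg
  }
  expect_error(split_subtomograms(ps, 0), "k")
})

test_that("optical flow recovers known displacements", {
  vol <- textured_volume(c(48, 48, 48), seed = 2)
  d <- dim(vol)
  fl0 <- estimate_flow(vol, vol)
  expect_lt(max(abs(c(fl0$uz, fl0$uy, fl0$ux))), 0.05)

  m <- 6
  sub <- function(a) a[m:(d[1] - m), m:(d[2] - m), m:(d[3] - m)]

  b <- warp_volume(vol, list(uz = array(0, d), uy = array(-2, d),
                             ux = array(0, d)))
  fl <- estimate_flow(vol, b)   # b(x + u) ~ a: recovered uy ~ +2
  epe <- sqrt((sub(fl$uy) - 2)^2 + sub(fl$uz)^2 + sub(fl$ux)^2)
  expect_lt(mean(epe), 0.25)

  g <- arrayInd(seq_along(vol), d)
  uy_true <- array(3 * sin(2 * pi * g[, 3] / 32), d)
  b2 <- warp_volume(vol, list(uz = array(0, d), uy = uy_true,
                              ux = array(0, d)))
  fl2 <- estimate_flow(vol, b2)  # recovers approximately -uy_true
  epe2 <- sqrt(sub(fl2$uy + uy_true)^2 + sub(fl2$uz)^2 + sub(fl2$ux)^2)
  expect_lt(mean(epe2), 0.5)

  expect_error(estimate_flow(vol, vol[1:20, , ]), "mismatch")
})

test_that("flow interpolation is exact at nodes, linear between, clamped", {
  d <- c(8, 8, 8)
  f1 <- list(uz = array(1, d), uy = array(0, d), ux = array(-1, d))
  f2 <- list(uz = array(3, d), uy = array(2, d), ux = array(1, d))
  out <- interpolate_flows(list(f1, f2), c(0.2, 0.8),
                           c(0.2, 0.5, 0.8, 1.5, 0.0))
  expect_identical(out[[1]], f1)
  expect_identical(out[[3]], f2)
  expect_equal(out[[2]]$uz, (f1$uz + f2$uz) / 2)
  expect_identical(out[[4]], f2)   # clamped above
  expect_identical(out[[5]], f1)   # clamped below
  expect_error(interpolate_flows(list(f1), c(0, 1), 0.5), "lengths")
  one <- interpolate_flows(list(f1), 0.3, c(0, 1))
  expect_identical(one[[1]], f1)
})

test_that("field inversion composes to identity", {
  set.seed(3)
  d <- c(24, 24, 24)
  u <- list(uz = pxctsim:::.gaussian_smooth3(array(rnorm(prod(d)), d), 4),
            uy = pxctsim:::.gaussian_smooth3(array(rnorm(prod(d)), d), 4),
            ux = pxctsim:::.gaussian_smooth3(array(rnorm(prod(d)), d), 4))
  sc <- 2 / max(pxctsim:::.field_norms(u))
  u <- lapply(u, `*`, sc)
  v <- invert_displacement_field(u, iters = 10, tol = 1e-4)
  # composition residual: v(x) + u(x + v(x)) ~ 0 (identity displacement)
  idx <- arrayInd(seq_along(u$uz), d)
  res <- sqrt(
    (v$uz + trilinear_gather(u$uz, idx[, 1] + as.vector(v$uz),
                             idx[, 2] + as.vector(v$uy),
                             idx[, 3] + as.vector(v$ux)))^2 +
    (v$uy + trilinear_gather(u$uy, idx[, 1] + as.vector(v$uz),
                             idx[, 2] + as.vector(v$uy),
                             idx[, 3] + as.vector(v$ux)))^2 +
    (v$ux + trilinear_gather(u$ux, idx[, 1] + as.vector(v$uz),
                             idx[, 2] + as.vector(v$uy),
                             idx[, 3] + as.vector(v$ux)))^2)
  core <- array(res, d)[5:20, 5:20, 5:20]
  expect_lt(mean(core), 0.05)
})

test_that("nonrigid reconstruction: degenerate case matches rigid FBP", {
  fx <- deforming_fixture(seed = 1, size = 48, n_angles = 48, amplitude = 0,
                          noise_sd = 0)
  rigid <- fbp(fx$ps, "hann")$volume
  rng <- diff(range(rigid))
  # amplitude 0: the true flows are zero fields; warp-accumulate must agree
  # with rigid FBP to interpolation tolerance
  zf <- lapply(1:4, function(j) pxctsim:::.zero_field(dim(rigid)))
  nr0 <- nonrigid_reconstruct(fx$ps, filter = "hann", flows = zf,
                              node_times = c(0.125, 0.375, 0.625,
                                             0.875))$volume
  expect_lt(sqrt(mean((nr0 - rigid)^2)) / rng, 0.01)
  # with flows estimated from the static data the residual spurious flow
  # adds a little extra resampling error; bound it at 2%
  nr <- nonrigid_reconstruct(fx$ps, filter = "hann")$volume
  expect_lt(sqrt(mean((nr - rigid)^2)) / rng, 0.02)
})

test_that("true deformation fields do at least as well as estimated ones", {
  fx <- deforming_fixture(seed = 2, size = 48, n_angles = 48, amplitude = 2,
                          noise_sd = 0)
  ph <- fx$phantom
  est <- estimate_subtomo_flows(fx$ps, filter = "hann")
  rec_est <- nonrigid_reconstruct(fx$ps, filter = "hann",
                                  flows = est$flows,
                                  node_times = est$node_times)$volume
  # oracle: true gather fields from the simulator (invert the forward warp)
  # sample_t(x) = phantom(x + d_t(x)); mapping the state at t back onto the
  # reference state at t0 needs u ~ d_t0 - d_t (first order, smooth fields)
  true_flows <- lapply(est$node_times, function(t) {
    fwd <- deformation_at(fx$deformation, t)
    ref <- deformation_at(fx$deformation, est$node_times[1])
    list(uz = ref$uz - fwd$uz, uy = ref$uy - fwd$uy, ux = ref$ux - fwd$ux)
  })
  rec_true <- nonrigid_reconstruct(fx$ps, filter = "hann",
                                   flows = true_flows,
                                   node_times = est$node_times)$volume
  rigid <- fbp(fx$ps, "hann")$volume
  err <- function(v) sqrt(mean((v - ph$density)^2))
  expect_lte(err(rec_true), err(rec_est) * 1.02)
  expect_lt(err(rec_true), err(rigid))
})
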