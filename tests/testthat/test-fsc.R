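# FRC/FSC, bit thresholds, split-half workflow, power-law fit

test_that("bit thresholds encode the stated SNR conventions", {
  t1 <- bit_threshold(1, 100, normalization = "per_half")
  expect_equal(t1$snr, 0.5)
  th <- bit_threshold(0.5, 100, normalization = "full")
  expect_equal(round(th$snr, 1), 0.4)
  expect_equal(th$snr, 2^0.5 - 1, tolerance = 1e-12)
  # asymptote: threshold -> SNR/(SNR+1) as n -> Inf
  big <- bit_threshold(1, 1e12, normalization = "per_half")
  expect_equal(big$threshold, 0.5 / 1.5, tolerance = 1e-5)
  # monotone: decreasing in n, increasing in bits
  ns <- c(4, 16, 64, 256)
  thr <- bit_threshold(0.5, ns)$threshold
  expect_false(is.unsorted(rev(thr)))
  expect_true(all(bit_threshold(1, ns)$threshold >
                    bit_threshold(0.5, ns)$threshold))
  expect_error(bit_threshold(0, 10), "bits")
  expect_error(bit_threshold(1, 0), "counts")
})

test_that("FRC of an image with itself is 1; white noise decorrelates", {
  set.seed(1)
  img <- matrix(rnorm(64 * 64), 64, 64)
  cv <- frc(img, img)
  expect_true(all(abs(cv$correlation - 1) < 1e-10))

  # independent white noise: per-shell correlation ~ 0 within 3/sqrt(n)
  ms <- replicate(20, {
    a <- matrix(rnorm(64 * 64), 64, 64)
    b <- matrix(rnorm(64 * 64), 64, 64)
    cvn <- frc(a, b, mask = FALSE)
    mean(cvn$correlation[-(1:2)])
  })
  n_min <- min(frc(img, img, mask = FALSE)$n_per_shell[-(1:2)])
  expect_lt(abs(mean(ms)), 3 / sqrt(n_min))
  expect_error(frc(img, img[1:32, ]), "shapes")
})

test_that("FRC tracks SNR/(SNR+1) for signal plus independent noise", {
  set.seed(2)
  sig <- matrix(rnorm(64 * 64), 64, 64)   # white signal: flat spectrum
  snr <- 2
  reps <- replicate(30, {
    a <- sig + matrix(rnorm(64 * 64, sd = 1 / sqrt(snr)), 64, 64)
    b <- sig + matrix(rnorm(64 * 64, sd = 1 / sqrt(snr)), 64, 64)
    mean(frc(a, b, mask = FALSE)$correlation[-(1:2)])
  })
  expect_equal(mean(reps), snr / (snr + 1), tolerance = 0.03)
})

test_that("FSC is symmetric and scale invariant", {
  v1 <- textured_volume(c(32, 32, 32), seed = 4)
  v2 <- textured_volume(c(32, 32, 32), seed = 4) +
    0.3 * textured_volume(c(32, 32, 32), seed = 5)
  c12 <- fsc(v1, v2)
  c21 <- fsc(v2, v1)
  expect_equal(c12$correlation, c21$correlation, tolerance = 1e-12)
  c_scaled <- fsc(v1 * 7.3, v2)
  expect_equal(c_scaled$resolution_nm, c12$resolution_nm, tolerance = 1e-9)
})

test_that("split-half FSC: duplicated halves hit the band limit and noise
           moves the crossing", {
  ph <- make_phantom(48, rng_seed = 5)
  ps <- static_projection_set(ph$density, seq(0, 179.9, length.out = 48),
                              pixel_size = 40)
  cv <- fsc_split_half(ps, mode = "rigid")
  # noiseless static data: halves agree to the band edge
  expect_false(cv$crossed)
  expect_equal(cv$resolution_nm, 2 * 40)
  expect_error(fsc_split_half(
    structure(list(projections = ps$projections[1:4], angles = ps$angles[1:4],
                   times = ps$times[1:4], pixel_size = 40, k_phase = 1),
              class = "phase_projection_set")), ">= 8")
})

test_that("resolution improves when photons increase 16x (dose ladder)", {
  res <- sapply(1:3, function(s) {
    ph <- make_phantom(48, rng_seed = 30 + s, texture_sd = 0.08)
    plan <- acquisition_plan(n_angles = 48, n_subtomos = 4)
    sapply(c(1, 16), function(scale) {
      # Gaussian phase noise ~ 1/sqrt(photons): 16x photons = 1/4 noise
      ps <- acquire_series(ph, NULL, plan, rng_seed = 40 + s,
                           noise_sd_rad = 0.6 / sqrt(scale))
      fsc_split_half(ps, mode = "rigid")$resolution_nm
    })
  })
  expect_lt(mean(res[2, ]), mean(res[1, ]))
})

test_that("power-law fit: exact recovery, unbiasedness, coverage", {
  dose <- 10^seq(6, 9, length.out = 12)
  res <- 100 / dose^0.25
  fit <- fit_dose_resolution(dose, res)
  expect_equal(fit$a, 100, tolerance = 1e-9)
  pred <- fit$predict(c(1e7, 1e8))
  expect_true(all(diff(pred$fit) < 0))        # decreasing in dose

  # Monte-Carlo: lognormal noise sigma = 0.1, n = 50: a-hat unbiased to 2%
  set.seed(11)
  doses <- 10^runif(50, 6, 9)
  ahat <- replicate(500, {
    r <- 100 / doses^0.25 * rlnorm(50, 0, 0.1)
    fit_dose_resolution(doses, r)$a
  })
  expect_lt(abs(mean(ahat) / 100 - 1), 0.02)

  # prediction-interval coverage 93-97% over 1,000 fresh draws
  set.seed(12)
  cover <- replicate(1000, {
    r <- 100 / doses^0.25 * rlnorm(50, 0, 0.1)
    f <- fit_dose_resolution(doses, r)
    d_new <- 10^runif(1, 6, 9)
    r_new <- 100 / d_new^0.25 * rlnorm(1, 0, 0.1)
    p <- f$predict(d_new)
    r_new >= p$lower && r_new <= p$upper
  })
  expect_gte(mean(cover), 0.93)
  expect_lte(mean(cover), 0.97)

  expect_error(fit_dose_resolution(c(1e7, 1e7), c(50, 60)), "distinct")
  expect_error(fit_dose_resolution(c(1e7, 1e8), c(-1, 60)), "positive")
})
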