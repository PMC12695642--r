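# Shared fixtures and independent oracles. Everything is generated in code
# at test time; oracles deliberately use different algorithms than the
# implementation they check.

# smooth random textured volume (flow / FSC fixture)
textured_volume <- function(d = c(48, 48, 48), sigma = 2, seed = 1) {
  set.seed(seed)
  v <- array(rnorm(prod(d)), d)
  v <- pxctsim:::.gaussian_smooth3(v, sigma)
  v / sd(v)
}

# brute-force projection oracle: nearest-neighbour rotation then sum,
# independent of the bilinear resampling in project()
oracle_project_nn <- function(vol, angle_deg) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  th <- angle_deg * pi / 180
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  out <- matrix(0, nz, ny)
  for (y in seq_len(ny)) for (x in seq_len(nx)) {
    # forward map: voxel (y, x) lands at detector t = rotated y coordinate
    t <- (y - cy) * cos(th) + (x - cx) * sin(th) + cy
    ti <- round(t)
    if (ti >= 1 && ti <= ny) out[, ti] <- out[, ti] + vol[, y, x]
  }
  out
}

# brute-force single-link clustering oracle: BFS over the pairwise
# distance graph (implementation uses hclust)
oracle_single_link <- function(pos, radius) {
  n <- nrow(pos)
  if (n == 0) return(integer(0))
  adj <- as.matrix(dist(pos)) <= radius
  lab <- rep(0L, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v] > 0) next
      lab[v] <- cur
      queue <- c(queue, which(adj[v, ] & lab == 0L))
    }
  }
  lab
}

# ramp-aligned phase comparison: fits est - truth to a plane on `sel` and
# returns the correlation after removing it
phase_corr_aligned <- function(est, truth, sel) {
  dphi <- est - truth
  Y <- row(dphi); X <- col(dphi)
  fit <- lm(d ~ Y + X, data = data.frame(d = dphi[sel], Y = Y[sel],
                                         X = X[sel]))
  aligned <- est - (coef(fit)[1] + coef(fit)[2] * Y + coef(fit)[3] * X)
  cor(aligned[sel], truth[sel])
}

# small ptycho fixture: 64x64 phase object scanned with a 32 px disk probe
make_ptycho_fixture <- function(photons = Inf, n_pos = 40, step = 5,
                                seed = 7) {
  set.seed(seed)
  os <- 64; np <- 32
  g <- expand.grid(y = 1:os, x = 1:os)
  phase_obj <- matrix(0.5 * sin(2 * pi * g$y / 11) * cos(2 * pi * g$x / 7),
                      os, os) +
    matrix(exp(-((g$y - 30)^2 + (g$x - 40)^2) / 60), os, os)
  pts <- fermat_spiral(n_pos, step)
  pos <- round(pts) + 17
  pos[, 1] <- pmin(pmax(pos[, 1], 1), os - np + 1)
  pos[, 2] <- pmin(pmax(pos[, 2], 1), os - np + 1)
  probe <- disk_probe(np)
  scan <- simulate_ptycho_scan(phase_obj, probe, as.matrix(pos),
                               photons_per_exposure = photons,
                               rng_seed = seed)
  illum <- matrix(0, os, os)
  for (j in seq_len(nrow(pos))) {
    ii <- pos[j, 1]:(pos[j, 1] + np - 1)
    jj <- pos[j, 2]:(pos[j, 2] + np - 1)
    illum[ii, jj] <- illum[ii, jj] + Mod(probe)^2
  }
  list(scan = scan, phase = phase_obj, probe = probe,
       sel = illum > 0.3 * max(illum))
}

# bare projection set from a static volume (voxel units, k_phase = 1)
static_projection_set <- function(vol, angles, pixel_size = 1) {
  n <- length(angles)
  structure(list(
    projections = lapply(angles, function(a)
      project(vol, a, voxel_size_nm = pixel_size, k_phase = 1)),
    angles = angles, times = seq_len(n) / n, subtomo = rep(1L, n),
    pixel_size = pixel_size, per_projection_dose = rep(0, n), k_phase = 1),
    class = "phase_projection_set")
}

# standard deforming-acquisition world used by the nonrigid tests:
# 20 nm voxels, sub-100 nm (4 voxel) drift deformation, phase noise such
# that the split-half FSC is noise-limited mid-band (see methods vignette)
deforming_fixture <- function(seed, size = 64, n_angles = 96, k = 4,
                              amplitude = 4, noise_sd = 0.08,
                              voxel_nm = 20) {
  ph <- make_phantom(size, voxel_size_nm = voxel_nm,
                     rng_seed = seed * 10 + 1, texture_sd = 0.08)
  dmod <- make_deformation(dim(ph$density), amplitude = amplitude,
                           smoothness = 16, mode = "drift",
                           rng_seed = seed * 10 + 2)
  plan <- acquisition_plan(n_angles = n_angles, n_subtomos = k)
  ps <- acquire_series(ph, dmod, plan, rng_seed = seed * 10 + 3,
                       noise_sd_rad = noise_sd)
  list(phantom = ph, deformation = dmod, plan = plan, ps = ps)
}
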