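# Forward model: parallel-beam phase projection of a (possibly deforming)
# phantom, ptychographic scan simulation with Poisson noise, and the
# absorbed-dose model.
#
# Projection geometry: rotation axis z (vertical). At angle theta the
# projection p(z, t) integrates the volume along the beam direction
# (-sin theta, cos theta) in the (y, x) plane, with detector axis
# (cos theta, sin theta); theta = 0 integrates along +x and the detector
# coordinate is y.

#' Phase projection of a phantom at one angle
#'
#' Optionally warps the phantom density by a displacement field (pull-back,
#' see [warp_volume()]), rotates about z and integrates along the beam. The
#' phase is `sum(density) * voxel_size_nm * k_phase` per ray: proportional to
#' projected electron density.
#'
#' @param phantom a `tissue_phantom`, or a bare 3D array.
#' @param angle_deg projection angle in degrees, in `[0, 180)`.
#' @param deformation displacement field (`uz`,`uy`,`ux`) or NULL.
#' @param k_phase density-to-phase constant, radians per (density unit * nm)
#'   (default 1e-3).
#' @param voxel_size_nm voxel pitch; taken from the phantom when available.
#' @return 2D phase image, dim `(nz, n_detector)`, radians.
#' @export
project <- function(phantom, angle_deg, deformation = NULL,
                    k_phase = 1e-3, voxel_size_nm = NULL) {
  vol <- if (inherits(phantom, "tissue_phantom")) phantom$density else phantom
  if (is.null(voxel_size_nm))
    voxel_size_nm <- if (inherits(phantom, "tissue_phantom"))
      phantom$voxel_size else 1
  if (!is.null(deformation)) {
    if (!identical(dim(deformation$uz), dim(vol)))
      stop("deformation field shape does not match phantom")
    vol <- warp_volume(vol, deformation)
  }
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  th <- angle_deg * pi / 180
  cy <- .grid_center(ny); cx <- .grid_center(nx)
  nt <- ny            # detector bins along the rotated y axis
  ns <- nx            # integration samples along the beam
  g <- expand.grid(t = seq_len(nt), s = seq_len(ns))
  ys <- cy + (g$t - cy) * cos(th) - (g$s - cx) * sin(th)
  xs <- cx + (g$t - cy) * sin(th) + (g$s - cx) * cos(th)
  sampled <- .sample_yx_slices(vol, ys, xs)        # nz x (nt*ns), t fastest
  proj <- matrix(rowSums(matrix(sampled, nz * nt, ns)), nz, nt)
  proj * voxel_size_nm * k_phase
}

#' Absorbed dose in gray
#'
#' Total energy absorbed by the sample divided by its total mass:
#' `dose = flux * exposure_total * fraction_absorbed * E_photon /
#' (electron_moles * molar_mass_per_electron * 1e-3)`, in J/kg = Gy. The
#' sample mass comes from the electron count via the mean molar mass per
#' electron of the resin/stain mixture (default 1.9 g/mol).
#'
#' @param flux photons per second.
#' @param exposure_total total exposure time, s.
#' @param fraction_absorbed fraction of incident photons absorbed, `[0, 1]`.
#' @param photon_energy_keV photon energy, keV (default 6.2).
#' @param electron_moles sample electron content, mol.
#' @param molar_mass_per_electron g per mol of electrons (default 1.9).
#' @return dose in Gy.
#' @export
absorbed_dose <- function(flux, exposure_total, fraction_absorbed,
                          photon_energy_keV = 6.2, electron_moles,
                          molar_mass_per_electron = 1.9) {
  vals <- c(flux, exposure_total, fraction_absorbed, photon_energy_keV,
            electron_moles, molar_mass_per_electron)
  if (any(vals < 0)) stop("all dose inputs must be >= 0")
  if (fraction_absorbed > 1) stop("fraction_absorbed must be <= 1")
  mass_kg <- electron_moles * molar_mass_per_electron * 1e-3
  if (mass_kg == 0) stop("sample mass is zero")
  e_j <- photon_energy_keV * 1.602176634e-16   # J per keV photon
  flux * exposure_total * fraction_absorbed * e_j / mass_kg
}

#' Electron content of a phantom, in moles
#'
#' Interprets the density grid as electrons per voxel in units of
#' `electrons_per_density_unit`, so the dose model can derive the sample
#' mass. A convenience for the simulator only.
#'
#' @param phantom a `tissue_phantom`.
#' @param electrons_per_density_unit electrons per voxel per density unit
#'   (default 1e9, giving ~ug-scale masses for desk phantoms).
#' @return mol of electrons.
#' @export
phantom_electron_moles <- function(phantom, electrons_per_density_unit = 1e9) {
  sum(phantom$density) * electrons_per_density_unit / 6.02214076e23
}

#' Acquire a projection series of a deforming phantom
#'
#' Projects the phantom at every angle of the plan, in acquisition order
#' (subtomogram-interlaced: each subtomogram's angles are acquired in one
#' contiguous dose window). The deformation is evaluated at the cumulative
#' dose fraction midpoint of each exposure. Per-projection dose is uniform
#' and sums to the total absorbed dose implied by the plan.
#'
#' @param phantom a `tissue_phantom`.
#' @param deformation_model a `deformation_model` or NULL (static sample).
#' @param plan an `acquisition_plan`.
#' @param k_phase density-to-phase constant (see [project()]).
#' @param fraction_absorbed absorbed fraction for the dose model
#'   (default 0.01).
#' @param noise_sd_rad optional Gaussian phase noise s.d. added per
#'   projection, radians (default 0 = noiseless).
#' @param rng_seed seed for the noise draw.
#' @return object of class `phase_projection_set`: list `projections` (list
#'   of matrices in acquisition order), `angles`, `times` (dose fraction at
#'   completion of each exposure, non-decreasing, ending at 1), `subtomo`,
#'   `pixel_size` (nm), `per_projection_dose` (Gy), `k_phase`.
#' @export
acquire_series <- function(phantom, deformation_model = NULL, plan,
                           k_phase = 1e-3, fraction_absorbed = 0.01,
                           noise_sd_rad = 0, rng_seed = 1L) {
  stopifnot(inherits(plan, "acquisition_plan"))
  n <- length(plan$angles)
  ord <- plan$acq_order
  angles_acq <- plan$angles[ord]
  subtomo_acq <- plan$subtomo_of[ord]
  times <- seq_len(n) / n
  n_pts <- nrow(plan$scan_positions)
  exposure_total <- plan$exposure * n_pts * n
  total_dose <- absorbed_dose(plan$flux, exposure_total, fraction_absorbed,
                              plan$photon_energy,
                              phantom_electron_moles(phantom))
  set.seed(as.integer(rng_seed))
  projections <- vector("list", n)
  for (i in seq_len(n)) {
    t_mid <- (i - 0.5) / n
    field <- if (is.null(deformation_model)) NULL else
      deformation_at(deformation_model, t_mid)
    p <- project(phantom, angles_acq[i], deformation = field,
                 k_phase = k_phase)
    if (noise_sd_rad > 0)
      p <- p + matrix(stats::rnorm(length(p), sd = noise_sd_rad),
                      nrow(p), ncol(p))
    projections[[i]] <- p
  }
  structure(list(projections = projections, angles = angles_acq,
                 times = times, subtomo = subtomo_acq,
                 pixel_size = phantom$voxel_size,
                 per_projection_dose = rep(total_dose / n, n),
                 total_dose = total_dose, k_phase = k_phase),
            class = "phase_projection_set")
}

#' @export
print.phase_projection_set <- function(x, ...) {
  cat("<phase_projection_set> ", length(x$projections), " projections, ",
      paste(dim(x$projections[[1]]), collapse = " x "), " px @ ",
      x$pixel_size, " nm; total dose ",
      format(sum(x$per_projection_dose), digits = 3), " Gy\n", sep = "")
  invisible(x)
}

#' Simulate a ptychographic scan
#'
#' For each scan position the exit wave is `probe * object patch`; the
#' far-field pattern is `|FFT(exit)|^2`, scaled so a pure-phase object
#' yields `photons_per_exposure` expected photons per pattern, then
#' Poisson-sampled (use `photons_per_exposure = Inf` for noiseless).
#'
#' @param object_phase real 2D phase image, radians (object is
#'   `exp(1i * phase)`).
#' @param probe complex 2D illumination (any overall power; normalized
#'   internally).
#' @param positions integer matrix, columns `y`, `x`: top-left corner (1-based)
#'   of the probe patch in the object plane.
#' @param photons_per_exposure expected photons per diffraction pattern.
#' @param rng_seed seed for the Poisson draw.
#' @return object of class `diffraction_scan`: `patterns` (list of
#'   non-negative matrices), `positions`, `probe_truth`, `object_truth_phase`,
#'   `photons_per_exposure`, `detector_pixels`.
#' @export
simulate_ptycho_scan <- function(object_phase, probe, positions,
                                 photons_per_exposure = 1e5, rng_seed = 1L) {
  np <- nrow(probe)
  if (np > nrow(object_phase) || ncol(probe) > ncol(object_phase))
    stop("probe must be smaller than the object")
  if (any(positions < 1) ||
      any(positions[, 1] + np - 1 > nrow(object_phase)) ||
      any(positions[, 2] + ncol(probe) - 1 > ncol(object_phase)))
    stop("scan positions out of object bounds")
  ov <- .mean_linear_overlap(positions, np)
  if (!is.na(ov) && ov < 0.6)
    warning(sprintf("mean linear probe overlap %.0f%% is below 60%%",
                    100 * ov))
  probe <- probe / sqrt(sum(Mod(probe)^2))    # unit power
  obj <- exp(1i * object_phase)
  N <- length(probe)
  set.seed(as.integer(rng_seed))
  patterns <- vector("list", nrow(positions))
  for (j in seq_len(nrow(positions))) {
    iy <- positions[j, 1]; ix <- positions[j, 2]
    patch <- obj[iy:(iy + np - 1), ix:(ix + ncol(probe) - 1)]
    I <- Mod(fft(probe * patch))^2 / N    # sums to patch-transmitted power
    if (is.finite(photons_per_exposure)) {
      I <- I * photons_per_exposure
      patterns[[j]] <- matrix(stats::rpois(length(I), I), nrow(I), ncol(I))
    } else {
      patterns[[j]] <- I   # noiseless: unit photon budget, no sampling
    }
  }
  structure(list(patterns = patterns, positions = positions,
                 probe_truth = probe, object_truth_phase = object_phase,
                 photons_per_exposure = photons_per_exposure,
                 detector_pixels = np),
            class = "diffraction_scan")
}

# mean pairwise nearest-neighbour linear overlap fraction of probe patches
.mean_linear_overlap <- function(positions, probe_px) {
  if (nrow(positions) < 2) return(NA_real_)
  dm <- as.matrix(stats::dist(positions))
  diag(dm) <- Inf
  nn <- apply(dm, 1, min)
  mean(pmax(0, 1 - nn / probe_px))
}

#' Disk probe initialization
#'
#' Circular-aperture probe: a filled disk, softly apodized and normalized to
#' unit power. A plain stand-in for structured zone-plate illumination.
#'
#' @param n probe array size in pixels.
#' @param radius_frac disk radius as a fraction of `n/2` (default 0.6).
#' @return complex `n x n` matrix.
#' @export
disk_probe <- function(n, radius_frac = 0.6) {
  c0 <- .grid_center(n)
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  r <- sqrt((g$y - c0)^2 + (g$x - c0)^2) / (n / 2)
  amp <- matrix(pmin(1, pmax(0, (radius_frac - r) / 0.1 + 0.5)), n, n)
  p <- amp * exp(1i * 0)
  p / sqrt(sum(Mod(p)^2))
}
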