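# Seeded synthetic-data generators: tissue phantom, deformation model,
# Fermat-spiral scan trajectory, acquisition plan and annotator score arrays.

#' Generate a synthetic stained-tissue phantom
#'
#' Builds a voxelized phantom emulating heavy-metal-stained neural tissue:
#' neurites as persistent-random-walk tubes, mitochondria as small ellipsoids
#' inside neurites, a nucleus as a large ellipsoid, and synapses as
#' high-density ellipsoidal puncta apposed to neurite surfaces. Densities are
#' in arbitrary electron-density units; the label grid uses
#' 0 = background/resin, 1 = neurite, 2 = mitochondrion, 3 = nucleus,
#' 4 = synapse.
#'
#' @param size_voxels edge length of the cubic grid (>= 32).
#' @param voxel_size_nm isotropic voxel pitch in nm (default 40).
#' @param feature_densities named numeric vector with entries `background`,
#'   `neurite`, `mitochondrion`, `nucleus`, `synapse` (non-negative).
#' @param n_neurites number of neurite tubes (default 6).
#' @param n_mitochondria number of mitochondria (default 6).
#' @param n_synapses number of synaptic puncta (default 12).
#' @param nucleus logical: include a nucleus (default TRUE).
#' @param neurite_radius tube radius in voxels (default 2.5).
#' @param texture_sd s.d. of smooth intra-material density texture relative
#'   to the material density step (default 0.05); texture gives the optical
#'   flow something to grip inside otherwise flat materials.
#' @param rng_seed integer seed; regeneration is bit-identical per seed.
#' @return object of class `tissue_phantom`: list with `density`, `labels`
#'   (3D arrays, axis order z,y,x), `synapses` (data.frame z_nm, y_nm, x_nm,
#'   id), `voxel_size`, `rng_seed`, `params`.
#' @export
make_phantom <- function(size_voxels = 64,
                         voxel_size_nm = 40,
                         feature_densities = c(background = 0.1,
                                               neurite = 0.5,
                                               mitochondrion = 0.8,
                                               nucleus = 0.65,
                                               synapse = 1.0),
                         n_neurites = 6,
                         n_mitochondria = 6,
                         n_synapses = 12,
                         nucleus = TRUE,
                         neurite_radius = 2.5,
                         texture_sd = 0.05,
                         rng_seed = 1L) {
  n <- as.integer(size_voxels)
  if (n < 32) stop("phantom size must be >= 32 voxels per edge")
  fd <- feature_densities
  need <- c("background", "neurite", "mitochondrion", "nucleus", "synapse")
  if (!all(need %in% names(fd))) stop("feature_densities must name: ",
                                      paste(need, collapse = ", "))
  if (any(fd < 0)) stop("feature densities must be non-negative")
  empty <- all(fd == 0)

  d <- c(n, n, n)
  labels <- array(0L, d)
  set.seed(as.integer(rng_seed))

  idx_grid <- NULL
  paint_ball <- function(center, radii, value) {
    # mark voxels inside an axis-aligned ellipsoid; cheap local bounding box
    lo <- pmax(floor(center - radii), 1)
    hi <- pmin(ceiling(center + radii), n)
    zz <- lo[1]:hi[1]; yy <- lo[2]:hi[2]; xx <- lo[3]:hi[3]
    g <- expand.grid(z = zz, y = yy, x = xx)
    r2 <- ((g$z - center[1]) / radii[1])^2 + ((g$y - center[2]) / radii[2])^2 +
      ((g$x - center[3]) / radii[3])^2
    sel <- g[r2 <= 1, , drop = FALSE]
    if (nrow(sel)) {
      lin <- ((sel$x - 1) * n + (sel$y - 1)) * n + sel$z
      labels[lin] <<- value
    }
    invisible(NULL)
  }

  active <- !empty && (fd["neurite"] > 0 || n_synapses > 0)
  if (active && n_neurites > 0) {
    for (t in seq_len(n_neurites)) {
      # persistent random walk entering from a random face
      pos <- runif(3, 4, n - 3)
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      steps <- 3L * n
      for (s in seq_len(steps)) {
        paint_ball(pos, rep(neurite_radius, 3), 1L)
        dir <- dir + stats::rnorm(3, sd = 0.15)
        dir <- dir / sqrt(sum(dir^2))
        pos <- pos + dir
        if (any(pos < 2) || any(pos > n - 1)) break
      }
    }
  }

  if (!empty && nucleus && fd["nucleus"] > 0) {
    ctr <- runif(3, n * 0.25, n * 0.75)
    paint_ball(ctr, runif(3, n * 0.12, n * 0.18), 3L)
  }

  if (!empty && n_mitochondria > 0 && fd["mitochondrion"] > 0) {
    inside <- which(labels == 1L)
    if (length(inside)) {
      picks <- sample(inside, min(n_mitochondria, length(inside)))
      ctrs <- arrayInd(picks, d)
      for (i in seq_len(nrow(ctrs))) {
        paint_ball(ctrs[i, ], runif(3, 1.2, 2.2), 2L)
      }
    }
  }

  synapses <- data.frame(z_nm = numeric(0), y_nm = numeric(0),
                         x_nm = numeric(0), id = integer(0))
  if (!empty && n_synapses > 0) {
    # synapse puncta sit on neurite surfaces: neurite voxels with a
    # background 6-neighbour
    lab1 <- which(labels == 1L)
    if (!length(lab1)) stop("phantom too small/empty to place synapses: ",
                            "no neurite support")
    ai <- arrayInd(lab1, d)
    c0 <- .grid_center(n)
    interior <- ai[, 1] > 2 & ai[, 1] < n - 1 & ai[, 2] > 2 & ai[, 2] < n - 1 &
      ai[, 3] > 2 & ai[, 3] < n - 1 &
      (ai[, 2] - c0)^2 + (ai[, 3] - c0)^2 <= (n / 2 - 4)^2  # inside pillar
    ai <- ai[interior, , drop = FALSE]
    nb_bg <- function(m, dz, dy, dx) {
      lin <- ((m[, 3] + dx - 1) * n + (m[, 2] + dy - 1)) * n + (m[, 1] + dz)
      labels[lin] == 0L
    }
    surf <- nb_bg(ai, 1, 0, 0) | nb_bg(ai, -1, 0, 0) | nb_bg(ai, 0, 1, 0) |
      nb_bg(ai, 0, -1, 0) | nb_bg(ai, 0, 0, 1) | nb_bg(ai, 0, 0, -1)
    cand <- ai[surf, , drop = FALSE]
    if (nrow(cand) < n_synapses) stop("phantom too small for ", n_synapses,
                                      " synapses (", nrow(cand),
                                      " surface sites)")
    # greedy min-separation picks so puncta do not merge
    ord <- sample(nrow(cand))
    chosen <- matrix(NA_real_, 0, 3)
    for (i in ord) {
      p <- cand[i, ]
      if (nrow(chosen) == 0 ||
          min(rowSums((chosen - matrix(p, nrow(chosen), 3,
                                       byrow = TRUE))^2)) > (3 * 1.6)^2) {
        chosen <- rbind(chosen, p)
      }
      if (nrow(chosen) == n_synapses) break
    }
    if (nrow(chosen) < n_synapses) stop("phantom too crowded to separate ",
                                        n_synapses, " synapses")
    for (i in seq_len(nrow(chosen))) {
      paint_ball(chosen[i, ], c(1.4, 1.4, 1.4), 4L)
    }
    synapses <- data.frame(z_nm = (chosen[, 1] - 1) * voxel_size_nm,
                           y_nm = (chosen[, 2] - 1) * voxel_size_nm,
                           x_nm = (chosen[, 3] - 1) * voxel_size_nm,
                           id = seq_len(nrow(chosen)))
  }

  dens_lut <- c(fd["background"], fd["neurite"], fd["mitochondrion"],
                fd["nucleus"], fd["synapse"])
  density <- array(dens_lut[labels + 1L], d)
  if (!empty && texture_sd > 0) {
    tex <- .gaussian_smooth3(array(stats::rnorm(prod(d)), d), 1.5)
    tex <- tex / stats::sd(tex) * texture_sd * max(diff(sort(unique(dens_lut))), 0)
    density <- pmax(density + tex * (labels > 0L), 0)
  }
  if (!empty) {
    # cylindrical pillar support about the rotation axis, as for a
    # FIB-milled sample: keeps all mass inside the reconstruction circle
    c0 <- .grid_center(n)
    r2 <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
    pillar <- r2 <= (n / 2 - 2)^2
    mask <- aperm(array(pillar, c(n, n, n)), c(3, 1, 2)) # (y,x) -> (z,y,x)
    density <- density * mask
    labels <- labels * mask
  }

  structure(list(density = density, labels = labels, synapses = synapses,
                 voxel_size = voxel_size_nm, rng_seed = as.integer(rng_seed),
                 params = list(size_voxels = n, feature_densities = fd,
                               n_neurites = n_neurites,
                               n_mitochondria = n_mitochondria,
                               n_synapses = n_synapses,
                               neurite_radius = neurite_radius,
                               texture_sd = texture_sd)),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  d <- dim(x$density)
  cat("<tissue_phantom> ", paste(d, collapse = " x "), " voxels @ ",
      x$voxel_size, " nm; ", nrow(x$synapses), " synapses; seed ",
      x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Generate a smooth dose-indexed deformation model
#'
#' Simulates progressive radiation-induced sample deformation: a smooth
#' random displacement field that grows as dose accumulates. Control fields
#' are a random walk in field space (each control time adds an independent
#' smooth increment), globally rescaled so the maximum displacement norm over
#' all control fields equals `amplitude`. The field at `control_times[1] = 0`
#' is identically zero (reference state).
#'
#' @param dim_voxels grid dim, length-3 integer `(z, y, x)` (or scalar cube).
#' @param control_times increasing dose fractions in `[0, 1]`, first = 0.
#' @param amplitude peak displacement in voxels (>= 0).
#' @param smoothness spatial correlation length in voxels: lag at which the
#'   field autocorrelation drops to 1/e (Gaussian kernel sigma =
#'   smoothness / 2).
#' @param mode `"drift"` (default): one smooth random field scaled linearly
#'   with dose — the coherent creep of a softening resin; `"walk"`: an
#'   independent smooth increment per control interval (less coherent,
#'   partially self-cancelling motion).
#' @param rng_seed integer seed.
#' @return object of class `deformation_model`: list `control_fields` (each a
#'   list uz, uy, ux), `control_times`, `amplitude`, `smoothness`, `rng_seed`.
#' @export
make_deformation <- function(dim_voxels,
                             control_times = c(0, 0.25, 0.5, 0.75, 1),
                             amplitude = 2,
                             smoothness = 16,
                             mode = c("drift", "walk"),
                             rng_seed = 1L) {
  mode <- match.arg(mode)
  if (length(dim_voxels) == 1) dim_voxels <- rep(dim_voxels, 3)
  d <- as.integer(dim_voxels)
  if (control_times[1] != 0) stop("control_times must start at 0")
  if (is.unsorted(control_times, strictly = TRUE))
    stop("control_times must be strictly increasing")
  if (amplitude < 0) stop("amplitude must be >= 0")
  set.seed(as.integer(rng_seed))
  nt <- length(control_times)
  sigma <- smoothness / 2
  fields <- vector("list", nt)
  fields[[1]] <- .zero_field(d)
  if (amplitude == 0 || nt == 1) {
    for (i in seq_len(nt)) fields[[i]] <- .zero_field(d)
  } else {
    smooth_field <- function() list(
      uz = .gaussian_smooth3(array(stats::rnorm(prod(d)), d), sigma),
      uy = .gaussian_smooth3(array(stats::rnorm(prod(d)), d), sigma),
      ux = .gaussian_smooth3(array(stats::rnorm(prod(d)), d), sigma))
    if (mode == "drift") {
      U <- smooth_field()
      for (i in 2:nt) {
        w <- control_times[i]
        fields[[i]] <- list(uz = w * U$uz, uy = w * U$uy, ux = w * U$ux)
      }
    } else {
      cur <- .zero_field(d)
      for (i in 2:nt) {
        inc <- smooth_field()
        w <- control_times[i] - control_times[i - 1]
        cur <- list(uz = cur$uz + w * inc$uz, uy = cur$uy + w * inc$uy,
                    ux = cur$ux + w * inc$ux)
        fields[[i]] <- cur
      }
    }
    peak <- max(vapply(fields, function(f) max(.field_norms(f)), numeric(1)))
    sc <- amplitude / peak
    for (i in 2:nt) {
      fields[[i]] <- list(uz = fields[[i]]$uz * sc, uy = fields[[i]]$uy * sc,
                          ux = fields[[i]]$ux * sc)
    }
  }
  structure(list(control_fields = fields, control_times = control_times,
                 amplitude = amplitude, smoothness = smoothness,
                 rng_seed = as.integer(rng_seed), dim = d),
            class = "deformation_model")
}

#' Evaluate a deformation model at a dose fraction
#'
#' Piecewise-linear interpolation of the control fields in time; queries
#' outside the control range are clamped.
#'
#' @param model a `deformation_model`.
#' @param t dose fraction.
#' @return displacement field (list `uz`, `uy`, `ux`).
#' @export
deformation_at <- function(model, t) {
  ct <- model$control_times
  if (t <= ct[1]) return(model$control_fields[[1]])
  if (t >= ct[length(ct)]) return(model$control_fields[[length(ct)]])
  i <- findInterval(t, ct)
  w <- (t - ct[i]) / (ct[i + 1] - ct[i])
  a <- model$control_fields[[i]]; b <- model$control_fields[[i + 1]]
  list(uz = (1 - w) * a$uz + w * b$uz,
       uy = (1 - w) * a$uy + w * b$uy,
       ux = (1 - w) * a$ux + w * b$ux)
}

#' Fermat-spiral scan trajectory
#'
#' Point `k` (k = 0, ..., n-1) sits at radius `c * sqrt(k)` and azimuth
#' `k * golden_angle`. The scaling constant is calibrated numerically so the
#' mean nearest-neighbour spacing matches `step`.
#'
#' @param n_points number of scan points (>= 1).
#' @param step target mean nearest-neighbour spacing (same units as output).
#' @return matrix with columns `y`, `x` (point 1 at the origin).
#' @export
fermat_spiral <- function(n_points, step) {
  if (n_points < 1) stop("n_points must be >= 1")
  if (step <= 0) stop("step must be > 0")
  k <- 0:(n_points - 1)
  gamma <- pi * (3 - sqrt(5))
  r <- sqrt(k)
  pts <- cbind(y = r * sin(k * gamma), x = r * cos(k * gamma))
  if (n_points >= 2) {
    dm <- as.matrix(stats::dist(pts))
    diag(dm) <- Inf
    mean_nn <- mean(apply(dm, 1, min))
    pts <- pts * (step / mean_nn)
  }
  pts
}

#' Build an acquisition plan
#'
#' Equally spaced projection angles over `[0, 180)` with a subtomogram
#' interlace: the sorted angle list is partitioned into `n_subtomos`
#' interlaced subsets (rank mod k), and acquisition proceeds subtomogram by
#' subtomogram so each subset occupies a contiguous dose window while still
#' spanning the whole angular range.
#'
#' @param n_angles total number of projections.
#' @param n_subtomos number of interlaced subtomograms (>= 1).
#' @param scan_step scan step in um (default 1.0; paper-scale knob 2.0-0.5).
#' @param exposure s per scan point (default 0.1; knob 0.025-0.1).
#' @param flux photons/s (default 7e8).
#' @param photon_energy keV (default 6.2).
#' @param n_scan_points Fermat-spiral points per projection (default 120).
#' @param fov_um field of view in um used for the spiral extent (default 10).
#' @return object of class `acquisition_plan` with `angles` (sorted),
#'   `acq_order` (indices into `angles` in acquisition/time order),
#'   `subtomo_of` (subtomogram id per sorted angle), scan geometry and beam
#'   parameters, and `scan_positions` (one spiral shared by all projections).
#' @export
acquisition_plan <- function(n_angles = 96, n_subtomos = 4,
                             scan_step = 1.0, exposure = 0.1,
                             flux = 7e8, photon_energy = 6.2,
                             n_scan_points = 120, fov_um = 10) {
  if (n_subtomos < 1) stop("n_subtomos must be >= 1")
  angles <- seq(0, 180, length.out = n_angles + 1)[seq_len(n_angles)]
  subtomo_of <- as.integer((seq_len(n_angles) - 1L) %% n_subtomos) + 1L
  acq_order <- order(subtomo_of, angles)
  structure(list(angles = angles, n_subtomos = as.integer(n_subtomos),
                 subtomo_of = subtomo_of, acq_order = acq_order,
                 scan_step = scan_step, exposure = exposure, flux = flux,
                 photon_energy = photon_energy,
                 scan_positions = fermat_spiral(n_scan_points, scan_step),
                 fov_um = fov_um),
            class = "acquisition_plan")
}

#' Simulate an annotator confidence-score array
#'
#' Emulates the randomized ROI ("captcha") task: `n_regions` regions scored
#' by `n_annotators` annotators in two imaging modalities (1 = EM reference,
#' 2 = PXCT) with confidence 1 (clearly no synapse) to 4 (clearly a synapse);
#' unanswered regions are coded 0. Regions that truly contain a synapse draw
#' a high score (3-4) with probability `sensitivity`; regions without draw a
#' low score (1-2) with probability `specificity`.
#'
#' @param n_regions number of ROIs.
#' @param n_annotators number of annotators.
#' @param true_flags logical vector length `n_regions`; if NULL, drawn
#'   Bernoulli(0.5).
#' @param sensitivity,specificity per-modality rates in `[0,1]`; scalars are
#'   recycled to (EM, PXCT).
#' @param dropout_rate probability an entry is 0 (missing).
#' @param rng_seed integer seed.
#' @return object of class `score_array`: list with integer array `scores`
#'   `(region x annotator x modality)` and `region_meta` data.frame
#'   (center_z/y/x nm, true_synapse).
#' @export
make_score_array <- function(n_regions = 250, n_annotators = 3,
                             true_flags = NULL,
                             sensitivity = c(0.95, 0.75),
                             specificity = c(0.95, 0.85),
                             dropout_rate = 0.02,
                             rng_seed = 1L) {
  sensitivity <- rep(sensitivity, length.out = 2)
  specificity <- rep(specificity, length.out = 2)
  if (any(c(sensitivity, specificity, dropout_rate) < 0) ||
      any(c(sensitivity, specificity, dropout_rate) > 1))
    stop("rates must lie in [0, 1]")
  set.seed(as.integer(rng_seed))
  if (is.null(true_flags)) true_flags <- stats::runif(n_regions) < 0.5
  stopifnot(length(true_flags) == n_regions)
  scores <- array(0L, c(n_regions, n_annotators, 2))
  for (m in 1:2) {
    for (a in seq_len(n_annotators)) {
      hit <- stats::runif(n_regions) <
        ifelse(true_flags, sensitivity[m], 1 - specificity[m])
      # hit = "scored as synapse" (3 or 4); otherwise 1 or 2
      hi <- sample(3:4, n_regions, replace = TRUE)
      lo <- sample(1:2, n_regions, replace = TRUE)
      scores[, a, m] <- ifelse(hit, hi, lo)
    }
  }
  if (dropout_rate > 0) {
    drop <- stats::runif(length(scores)) < dropout_rate
    scores[drop] <- 0L
  }
  structure(list(scores = scores,
                 region_meta = data.frame(
                   center_z_nm = stats::runif(n_regions, 0, 2e4),
                   center_y_nm = stats::runif(n_regions, 0, 2e4),
                   center_x_nm = stats::runif(n_regions, 0, 2e4),
                   true_synapse = true_flags)),
            class = "score_array")
}
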