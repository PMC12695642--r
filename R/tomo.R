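# Tomographic reconstruction: projection alignment, filtered back projection
# (Hann / Ram-Lak), interlaced subtomogram splitting, multiresolution 3D
# optical flow, temporal flow interpolation, and deformation-compensated
# (nonrigid) reconstruction by warp-accumulate.

# ramp filter applied along the detector (t) axis of a (nz x nt) projection;
# zero-padded to 2x next power of two to suppress circular wrap.
.filter_projection <- function(proj, filter = c("ramlak", "hann")) {
  filter <- match.arg(filter)
  nt <- ncol(proj)
  npad <- 2^ceiling(log2(2 * nt))
  f <- c(0:(npad / 2), -(npad / 2 - 1):-1) / npad   # cycles/pixel
  H <- abs(f)
  if (filter == "hann") {
    w <- 0.5 * (1 + cos(pi * f / 0.5))   # Hann window closing at Nyquist
    H <- H * w
  }
  P <- matrix(0, nrow(proj), npad)
  P[, seq_len(nt)] <- proj
  Ff <- t(mvfft(t(P)))
  Ff <- Ff * rep(H, each = nrow(proj))
  out <- Re(t(mvfft(t(Ff), inverse = TRUE))) / npad
  out[, seq_len(nt), drop = FALSE]
}

# back-project one filtered (nz x nt) projection at angle theta into a
# (nz x ny x nx) volume increment (as nz x ny*nx matrix).
.backproject_one <- function(pf, theta_deg, ny, nx) {
  th <- theta_deg * pi / 180
  cy <- .grid_center(ny); cx <- .grid_center(nx)
  ct <- .grid_center(ncol(pf))
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  tpos <- ct + (g$y - cy) * cos(th) + (g$x - cx) * sin(th)
  .sample_cols(pf, tpos)
}

#' Filtered back projection
#'
#' Windowed-ramp FBP over the half circle: projections are ramp-filtered
#' along the detector axis (Ram-Lak, or Hann-windowed ramp) and
#' back-projected, scaled by `pi / n_angles` so values approximate the
#' density-line-integral inverse divided by the phase scaling.
#'
#' @param projection_set a `phase_projection_set`.
#' @param filter `"hann"` or `"ramlak"`.
#' @return object of class `tomogram`: `volume` (z, y, x), `voxel_size`,
#'   `provenance`.
#' @export
fbp <- function(projection_set, filter = c("hann", "ramlak")) {
  filter <- match.arg(filter)
  ps <- projection_set
  n <- length(ps$projections)
  if (n == 0) stop("no projections")
  nz <- nrow(ps$projections[[1]]); nt <- ncol(ps$projections[[1]])
  ny <- nt; nx <- nt
  acc <- matrix(0, nz, ny * nx)
  for (i in seq_len(n)) {
    pf <- .filter_projection(ps$projections[[i]], filter)
    acc <- acc + .backproject_one(pf, ps$angles[i], ny, nx)
  }
  vol <- array(acc, c(nz, ny, nx)) * pi / n
  # undo the phase scaling so the tomogram is in density units
  sc <- ps$k_phase * ps$pixel_size
  if (is.numeric(sc) && sc > 0) vol <- vol / sc
  structure(list(volume = vol, voxel_size = ps$pixel_size,
                 provenance = list(n_angles = n, filter = filter,
                                   mode = "rigid")),
            class = "tomogram")
}

#' @export
print.tomogram <- function(x, ...) {
  cat("<tomogram> ", paste(dim(x$volume), collapse = " x "), " voxels @ ",
      x$voxel_size, " nm (", x$provenance$mode, ", ",
      x$provenance$filter, ", ", x$provenance$n_angles, " angles)\n",
      sep = "")
  invisible(x)
}

#' Align projections by center-of-mass consistency
#'
#' Estimates per-projection 2D shifts without external references: the
#' vertical (z) mass center must be invariant under rotation about z, and
#' the horizontal mass center of each projection must follow a sinusoid
#' `A cos(theta) + B sin(theta) + C` across angles. Residuals from those
#' models are removed by subpixel resampling.
#'
#' @param projection_set a `phase_projection_set` (>= 3 projections).
#' @return the projection set with shifted projections and an added
#'   `alignment_shifts` data.frame (dz, dt per projection).
#' @export
align_projections <- function(projection_set) {
  ps <- projection_set
  n <- length(ps$projections)
  if (n < 3) stop("need >= 3 projections to align")
  mass <- vapply(ps$projections, sum, numeric(1))
  if (any(mass == 0)) stop("degenerate all-zero projection")
  nz <- nrow(ps$projections[[1]]); nt <- ncol(ps$projections[[1]])
  comz <- vapply(ps$projections, function(p)
    sum(rowSums(p) * seq_len(nz)) / sum(p), numeric(1))
  comt <- vapply(ps$projections, function(p)
    sum(colSums(p) * seq_len(nt)) / sum(p), numeric(1))
  dz <- comz - mean(comz)
  th <- ps$angles * pi / 180
  fit <- stats::lm(comt ~ cos(th) + sin(th))
  dt <- comt - stats::fitted(fit)
  out <- ps
  for (i in seq_len(n)) {
    out$projections[[i]] <- .shift_image(ps$projections[[i]], -dz[i], -dt[i])
  }
  out$alignment_shifts <- data.frame(dz = dz, dt = dt)
  out
}

#' Split a projection set into interlaced subtomograms
#'
#' Subtomogram `j` receives the angles whose rank in sorted-angle order is
#' congruent to `j` (mod k): each subset spans the whole 0-180 degree range
#' with k-fold sparser, still uniform, spacing. When the series was acquired
#' with the matching interlaced plan each subset also occupies one
#' contiguous dose window.
#'
#' @param projection_set a `phase_projection_set`.
#' @param k number of subtomograms (>= 1).
#' @return list of `k` projection sets (projections kept in original order).
#' @export
split_subtomograms <- function(projection_set, k) {
  if (k < 1) stop("k must be >= 1")
  ps <- projection_set
  rank_of <- rank(ps$angles, ties.method = "first")
  grp <- ((rank_of - 1L) %% k) + 1L
  lapply(seq_len(k), function(j) .subset_ps(ps, which(grp == j)))
}

# subset a phase_projection_set by projection index, keeping metadata aligned
.subset_ps <- function(ps, sel) {
  out <- ps
  out$projections <- ps$projections[sel]
  out$angles <- ps$angles[sel]
  out$times <- ps$times[sel]
  if (!is.null(ps$subtomo)) out$subtomo <- ps$subtomo[sel]
  if (!is.null(ps$per_projection_dose))
    out$per_projection_dose <- ps$per_projection_dose[sel]
  out
}

# Horn-Schunck iterations at one pyramid level; a and b are intensity
# volumes, f the current flow (gather convention: b(x + f) ~ a). `w` is an
# optional data-term weight in [0,1]: where w = 0 the flow is driven purely
# by the smoothness term (used to ignore out-of-support artifacts).
.hs_level <- function(a, b, f, alpha = 0.5, n_iter = 60, n_warp = 2,
                      w = NULL) {
  d <- dim(a)
  nb_mean <- function(v) {
    s <- array(0, d)
    s[-1, , ] <- s[-1, , ] + v[-d[1], , ]; s[1, , ] <- s[1, , ] + v[1, , ]
    s[-d[1], , ] <- s[-d[1], , ] + v[-1, , ]; s[d[1], , ] <- s[d[1], , ] + v[d[1], , ]
    s[, -1, ] <- s[, -1, ] + v[, -d[2], ]; s[, 1, ] <- s[, 1, ] + v[, 1, ]
    s[, -d[2], ] <- s[, -d[2], ] + v[, -1, ]; s[, d[2], ] <- s[, d[2], ] + v[, d[2], ]
    s[, , -1] <- s[, , -1] + v[, , -d[3]]; s[, , 1] <- s[, , 1] + v[, , 1]
    s[, , -d[3]] <- s[, , -d[3]] + v[, , -1]; s[, , d[3]] <- s[, , d[3]] + v[, , d[3]]
    s / 6
  }
  cdiff <- function(v, axis) {
    g <- array(0, d)
    if (axis == 1) {
      g[2:(d[1] - 1), , ] <- (v[3:d[1], , ] - v[1:(d[1] - 2), , ]) / 2
    } else if (axis == 2) {
      g[, 2:(d[2] - 1), ] <- (v[, 3:d[2], ] - v[, 1:(d[2] - 2), ]) / 2
    } else {
      g[, , 2:(d[3] - 1)] <- (v[, , 3:d[3]] - v[, , 1:(d[3] - 2)]) / 2
    }
    g
  }
  for (wi in seq_len(n_warp)) {
    bw <- warp_volume(b, f, fill = 0)
    Iz <- cdiff(bw, 1); Iy <- cdiff(bw, 2); Ix <- cdiff(bw, 3)
    It <- bw - a
    if (!is.null(w)) {
      Iz <- Iz * w; Iy <- Iy * w; Ix <- Ix * w; It <- It * w
    }
    denom <- alpha^2 + Iz^2 + Iy^2 + Ix^2
    dz <- array(0, d); dy <- array(0, d); dx <- array(0, d)
    for (i in seq_len(n_iter)) {
      mz <- nb_mean(dz); my <- nb_mean(dy); mx <- nb_mean(dx)
      t1 <- (Iz * mz + Iy * my + Ix * mx + It) / denom
      dz <- mz - Iz * t1
      dy <- my - Iy * t1
      dx <- mx - Ix * t1
    }
    f <- list(uz = f$uz + dz, uy = f$uy + dy, ux = f$ux + dx)
  }
  f
}

#' Estimate 3D optical flow between two volumes
#'
#' Multiresolution variational (Horn-Schunck) optical flow under brightness
#' constancy with a smoothness penalty. Returns the displacement `u` (in
#' voxels) such that `warp_volume(volume_b, u)` approximates `volume_a`
#' (gather convention). A boundary margin of the field is forced to zero.
#'
#' @param volume_a reference volume.
#' @param volume_b moving volume (same dim).
#' @param pyramid_levels number of resolution levels (default 3).
#' @param regularization Horn-Schunck smoothness weight alpha (default 1.0,
#'   on intensity-normalized volumes).
#' @param boundary_margin voxels of zero flow at each face (default 2).
#' @param n_iter relaxation iterations per warp (default 60).
#' @param mask optional data-term weight array in `[0, 1]` (same dim as the
#'   volumes): where 0, the flow is extrapolated by smoothness alone.
#' @return object of class `flow_field`: `uz`, `uy`, `ux` arrays plus
#'   `pyramid_levels`.
#' @export
estimate_flow <- function(volume_a, volume_b, pyramid_levels = 3,
                          regularization = 1.0, boundary_margin = 2,
                          n_iter = 60, mask = NULL) {
  if (!identical(dim(volume_a), dim(volume_b))) stop("shape mismatch")
  s <- stats::sd(volume_a)
  if (s == 0) s <- 1
  a <- (volume_a - mean(volume_a)) / s
  b <- (volume_b - mean(volume_a)) / s
  pyr_a <- list(a); pyr_b <- list(b)
  pyr_w <- if (is.null(mask)) NULL else list(mask)
  for (l in seq_len(pyramid_levels - 1)) {
    if (min(dim(pyr_a[[l]])) < 12) break
    pyr_a[[l + 1]] <- .downsample2(pyr_a[[l]])
    pyr_b[[l + 1]] <- .downsample2(pyr_b[[l]])
    if (!is.null(pyr_w)) pyr_w[[l + 1]] <- .downsample2(pyr_w[[l]])
  }
  L <- length(pyr_a)
  f <- .zero_field(dim(pyr_a[[L]]))
  for (l in L:1) {
    if (l < L) {
      dnew <- dim(pyr_a[[l]])
      f <- list(uz = .upsample_to(f$uz, dnew) * 2,
                uy = .upsample_to(f$uy, dnew) * 2,
                ux = .upsample_to(f$ux, dnew) * 2)
    }
    f <- .hs_level(pyr_a[[l]], pyr_b[[l]], f, alpha = regularization,
                   n_iter = n_iter,
                   w = if (is.null(pyr_w)) NULL else pyr_w[[l]])
  }
  if (boundary_margin > 0) {
    d <- dim(f$uz)
    m <- boundary_margin
    mask <- array(0, d)
    mask[(m + 1):(d[1] - m), (m + 1):(d[2] - m), (m + 1):(d[3] - m)] <- 1
    f <- list(uz = f$uz * mask, uy = f$uy * mask, ux = f$ux * mask)
  }
  structure(list(uz = f$uz, uy = f$uy, ux = f$ux,
                 pyramid_levels = pyramid_levels),
            class = c("flow_field", "list"))
}

#' Interpolate flow fields in time
#'
#' Componentwise piecewise-linear interpolation between flow nodes; queries
#' outside the node range are clamped to the nearest node.
#'
#' @param flow_nodes list of flow fields (lists with `uz`, `uy`, `ux`).
#' @param node_times increasing times of the nodes.
#' @param query_times times at which fields are wanted.
#' @return list of flow fields, one per query time.
#' @export
interpolate_flows <- function(flow_nodes, node_times, query_times) {
  if (length(flow_nodes) != length(node_times))
    stop("flow_nodes and node_times lengths differ")
  if (is.unsorted(node_times, strictly = TRUE))
    stop("node_times must be strictly increasing")
  if (length(flow_nodes) < 1) stop("need at least one flow node")
  lapply(query_times, function(t) {
    if (length(flow_nodes) == 1 || t <= node_times[1])
      return(flow_nodes[[1]])
    nt <- length(node_times)
    if (t >= node_times[nt]) return(flow_nodes[[nt]])
    i <- findInterval(t, node_times)
    w <- (t - node_times[i]) / (node_times[i + 1] - node_times[i])
    a <- flow_nodes[[i]]; b <- flow_nodes[[i + 1]]
    list(uz = (1 - w) * a$uz + w * b$uz,
         uy = (1 - w) * a$uy + w * b$uy,
         ux = (1 - w) * a$ux + w * b$ux)
  })
}

#' Estimate per-subtomogram deformation flows for a projection series
#'
#' FBP-reconstructs each subtomogram (dose-window snapshot), picks the
#' lowest-dose one as the reference state, and estimates the 3D optical flow
#' from the reference to every other subtomogram. The returned flows are in
#' the gather convention: warping subtomogram j's volume by `flows[[j]]`
#' approximates the reference.
#'
#' @param projection_set a `phase_projection_set`.
#' @param k_subtomos number of dose windows; defaults to the set's own
#'   `subtomo` labels when present.
#' @param filter FBP filter.
#' @param pre_smooth_sigma Gaussian sigma (voxels) applied to the subtomogram
#'   volumes before flow estimation (default 2). Sample deformations are
#'   smooth on the scale of tens of voxels while few-angle subtomogram FBPs
#'   are noisy and streaky; without the low-pass the flow estimator fits
#'   reconstruction noise, and because those noise-fit fields are shared by
#'   both FSC half-reconstructions they would inject spurious half-to-half
#'   correlation.
#' @param flow_smooth_sigma Gaussian sigma (voxels) applied to the estimated
#'   flow components (default 6): physical deformations have correlation
#'   lengths of tens of voxels, so this rejects residual noise-fit structure
#'   while passing the real field.
#' @param flow_args arguments passed to [estimate_flow()].
#' @return list: `flows` (time-ordered), `node_times`, `volumes`
#'   (subtomogram FBPs, time-ordered), `reference` (index into the ordered
#'   lists, always 1).
#' @export
estimate_subtomo_flows <- function(projection_set, k_subtomos = NULL,
                                   filter = c("hann", "ramlak"),
                                   pre_smooth_sigma = 2,
                                   flow_smooth_sigma = 6,
                                   flow_args = list()) {
  filter <- match.arg(filter)
  ps <- projection_set
  if (!is.null(ps$subtomo) && length(unique(ps$subtomo)) >= 2 &&
      is.null(k_subtomos)) {
    ids <- sort(unique(ps$subtomo))
    subs <- lapply(ids, function(j) .subset_ps(ps, which(ps$subtomo == j)))
  } else {
    if (is.null(k_subtomos)) k_subtomos <- 4L
    if (k_subtomos < 2) stop("need k >= 2 subtomograms")
    subs <- split_subtomograms(ps, k_subtomos)
  }
  node_times <- vapply(subs, function(s) mean(s$times), numeric(1))
  ord <- order(node_times)
  subs <- subs[ord]; node_times <- node_times[ord]
  vols <- lapply(subs, function(s) fbp(s, filter = filter)$volume)
  sm <- if (pre_smooth_sigma > 0)
    lapply(vols, function(v) .gaussian_smooth3(v, pre_smooth_sigma))
  else vols
  ref <- sm[[1]]
  d <- dim(ref)
  # restrict the flow data term to the reconstruction cylinder: outside it
  # few-angle FBPs contain only streak artifacts specific to each angle
  # subset, which the flow estimator would otherwise chase
  cy <- .grid_center(d[2]); cx <- .grid_center(d[3])
  r2 <- outer((seq_len(d[2]) - cy)^2, (seq_len(d[3]) - cx)^2, `+`)
  cyl <- aperm(array(r2 <= (min(d[2], d[3]) / 2 - 2)^2, c(d[2], d[3], d[1])),
               c(3, 1, 2)) * 1
  fa <- utils::modifyList(list(regularization = 2, mask = cyl), flow_args)
  flows <- vector("list", length(vols))
  flows[[1]] <- .zero_field(d)
  for (j in seq_along(vols)[-1]) {
    fj <- do.call(estimate_flow, c(list(ref, sm[[j]]), fa))
    if (flow_smooth_sigma > 0) {
      # physical deformations are smooth on the scale of tens of voxels;
      # low-passing the field keeps them and rejects noise-fit wiggles
      fj$uz <- .gaussian_smooth3(fj$uz, flow_smooth_sigma)
      fj$uy <- .gaussian_smooth3(fj$uy, flow_smooth_sigma)
      fj$ux <- .gaussian_smooth3(fj$ux, flow_smooth_sigma)
    }
    flows[[j]] <- fj
  }
  list(flows = flows, node_times = node_times, volumes = vols,
       reference = 1L)
}

#' Nonrigid (deformation-compensated) tomographic reconstruction
#'
#' Pipeline: (1) FBP each interlaced subtomogram; (2) estimate 3D optical
#' flow from every subtomogram to the reference (first, lowest-dose)
#' subtomogram; (3) interpolate the flows to every projection's acquisition
#' time; (4) warp-accumulate — back-project each filtered projection alone,
#' warp that partial volume onto the reference state with its interpolated
#' flow, and accumulate. Optionally iterate flow re-estimation against the
#' running reconstruction.
#'
#' @param projection_set a `phase_projection_set`.
#' @param k_subtomos number of subtomograms (>= 2); defaults to the set's
#'   own dose-window labels when present.
#' @param filter FBP filter.
#' @param n_outer_iters extra flow re-estimation passes against the running
#'   reconstruction (default 0).
#' @param flows optional precomputed flow fields (time-ordered, reference
#'   first, gather convention) to use instead of estimating; requires
#'   `node_times`.
#' @param node_times times of the supplied flow nodes.
#' @param flow_args list of arguments passed to [estimate_flow()].
#' @return a `tomogram` with `provenance$mode = "nonrigid"`.
#' @export
nonrigid_reconstruct <- function(projection_set, k_subtomos = NULL,
                                 filter = c("hann", "ramlak"),
                                 n_outer_iters = 0, flows = NULL,
                                 node_times = NULL, flow_args = list()) {
  filter <- match.arg(filter)
  ps <- projection_set
  if (is.null(flows)) {
    est <- estimate_subtomo_flows(ps, k_subtomos, filter = filter,
                                  flow_args = flow_args)
    flows <- est$flows
    node_times <- est$node_times
  } else if (is.null(node_times)) {
    stop("node_times must accompany supplied flows")
  }
  recon <- .warp_accumulate(ps, flows, node_times, filter)
  iter <- 0
  while (iter < n_outer_iters) {
    iter <- iter + 1
    est <- estimate_subtomo_flows(ps, k_subtomos, filter = filter,
                                  flow_args = flow_args)
    # re-estimate against the sharper running reconstruction as reference
    for (j in seq_along(est$volumes)[-1]) {
      flows[[j]] <- do.call(estimate_flow,
                            c(list(recon, est$volumes[[j]]), flow_args))
    }
    recon <- .warp_accumulate(ps, flows, node_times, filter)
  }
  structure(list(volume = recon, voxel_size = ps$pixel_size,
                 provenance = list(n_angles = length(ps$projections),
                                   filter = filter, mode = "nonrigid",
                                   k_subtomos = length(flows))),
            class = "tomogram")
}

# warp-accumulate core: per projection, back-project, warp onto the
# reference state with its time-interpolated flow, accumulate.
.warp_accumulate <- function(ps, node_flows, node_times, filter) {
  n <- length(ps$projections)
  nz <- nrow(ps$projections[[1]]); nt <- ncol(ps$projections[[1]])
  ny <- nt; nx <- nt
  qflows <- interpolate_flows(node_flows, node_times, ps$times)
  acc <- array(0, c(nz, ny, nx))
  for (i in seq_len(n)) {
    pf <- .filter_projection(ps$projections[[i]], filter)
    part <- array(.backproject_one(pf, ps$angles[i], ny, nx), c(nz, ny, nx))
    f <- qflows[[i]]
    if (max(abs(f$uz), abs(f$uy), abs(f$ux)) > 1e-6) {
      part <- warp_volume(part, f)
    }
    acc <- acc + part
  }
  vol <- acc * pi / n
  sc <- ps$k_phase * ps$pixel_size
  if (is.numeric(sc) && sc > 0) vol <- vol / sc
  vol
}
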