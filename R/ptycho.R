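# Ptychographic phase retrieval: difference map with alternating object /
# probe overlap updates, followed by conjugate-gradient maximum-likelihood
# refinement (Poisson or Gaussian-amplitude metric) with >= 1 probe modes,
# and the constant/linear phase-ramp removal applied before tomography.
#
# Fourier convention: the unitary transform U(x) = fft(x)/sqrt(N). Measured
# patterns are photon counts with expectation |U(exit)|^2 * photons, so the
# amplitude targets are A = sqrt(counts / photons).

# per-scan amplitude targets in unitary-FFT units
.amp_targets <- function(scan) {
  sc <- if (is.finite(scan$photons_per_exposure))
    scan$photons_per_exposure else 1
  lapply(scan$patterns, function(p) sqrt(pmax(p, 0) / sc))
}

.patch_idx <- function(pos, np) {
  list(y = pos[1]:(pos[1] + np - 1), x = pos[2]:(pos[2] + np - 1))
}

# normalized Fourier-amplitude data error: ||  |U(P O_j)| - A_j ||able / ||A||
.ptycho_data_error <- function(object, probes, scan, amps) {
  np <- nrow(probes[[1]])
  num <- 0; den <- 0
  for (j in seq_along(scan$patterns)) {
    ii <- .patch_idx(scan$positions[j, ], np)
    oj <- object[ii$y, ii$x]
    I <- 0
    for (P in probes) I <- I + Mod(fft(P * oj) / sqrt(length(P)))^2
    num <- num + sum((sqrt(I) - amps[[j]])^2)
    den <- den + sum(amps[[j]]^2)
  }
  sqrt(num / den)
}

#' Difference-map ptychographic reconstruction
#'
#' Classic two-projection difference map (relaxation 1) on the exit waves:
#' `psi <- psi + P_F(2 P_O(psi) - psi) - P_O(psi)`, where `P_O` is the
#' overlap projection (least-squares object/probe factorization) and `P_F`
#' replaces Fourier moduli with the measured amplitudes. The probe is held
#' fixed for the first `probe_delay` iterations.
#'
#' @param scan a `diffraction_scan`.
#' @param probe_init complex matrix or NULL (disk probe).
#' @param object_init complex matrix or NULL (free-space object).
#' @param n_iter difference-map iterations (>= 0).
#' @param probe_delay iterations before probe updates begin (default 5).
#' @return object of class `ptycho_result`: `object_estimate`,
#'   `probe_estimates` (list, one mode here), `iterations_run`,
#'   `data_error` (per-iteration history).
#' @export
difference_map <- function(scan, probe_init = NULL, object_init = NULL,
                           n_iter = 200, probe_delay = 5) {
  if (!length(scan$patterns)) stop("empty scan")
  if (n_iter < 0) stop("n_iter must be >= 0")
  np <- scan$detector_pixels
  os <- dim(scan$object_truth_phase)
  P <- if (is.null(probe_init)) disk_probe(np) else probe_init
  O <- if (is.null(object_init))
    matrix(1 + 0i, os[1], os[2]) else object_init
  amps <- .amp_targets(scan)
  nj <- length(scan$patterns)
  ov <- .mean_linear_overlap(scan$positions, np)
  if (!is.na(ov) && ov < 0.6)
    warning("probe overlap below 60%; retrieval may stagnate")

  psi <- vector("list", nj)
  for (j in seq_len(nj)) {
    ii <- .patch_idx(scan$positions[j, ], np)
    psi[[j]] <- P * O[ii$y, ii$x]
  }
  err <- numeric(0)
  if (n_iter == 0) {
    return(structure(list(object_estimate = O, probe_estimates = list(P),
                          iterations_run = c(dm = 0L),
                          data_error = err), class = "ptycho_result"))
  }
  eps <- 1e-8
  for (it in seq_len(n_iter)) {
    # -- overlap projection: refactor psi into object and probe
    num <- matrix(0 + 0i, os[1], os[2]); den <- matrix(eps, os[1], os[2])
    for (j in seq_len(nj)) {
      ii <- .patch_idx(scan$positions[j, ], np)
      num[ii$y, ii$x] <- num[ii$y, ii$x] + Conj(P) * psi[[j]]
      den[ii$y, ii$x] <- den[ii$y, ii$x] + Mod(P)^2
    }
    O <- num / den
    if (it > probe_delay) {
      pn <- matrix(0 + 0i, np, np); pd <- matrix(eps, np, np)
      for (j in seq_len(nj)) {
        ii <- .patch_idx(scan$positions[j, ], np)
        oj <- O[ii$y, ii$x]
        pn <- pn + Conj(oj) * psi[[j]]
        pd <- pd + Mod(oj)^2
      }
      P <- pn / pd
    }
    # -- difference-map update with Fourier magnitude projection
    e2 <- 0; eden <- 0
    for (j in seq_len(nj)) {
      ii <- .patch_idx(scan$positions[j, ], np)
      phi <- P * O[ii$y, ii$x]
      Fv <- fft(2 * phi - psi[[j]]) / sqrt(length(phi))
      Fc <- amps[[j]] * Fv / (Mod(Fv) + 1e-12)
      pf <- fft(Fc, inverse = TRUE) / sqrt(length(phi))
      psi[[j]] <- psi[[j]] + pf - phi
      Fphi <- Mod(fft(phi) / sqrt(length(phi)))
      e2 <- e2 + sum((Fphi - amps[[j]])^2)
      eden <- eden + sum(amps[[j]]^2)
    }
    err <- c(err, sqrt(e2 / eden))
  }
  structure(list(object_estimate = O, probe_estimates = list(P),
                 iterations_run = c(dm = as.integer(n_iter)),
                 data_error = err),
            class = "ptycho_result")
}

#' @export
print.ptycho_result <- function(x, ...) {
  cat("<ptycho_result> object ", paste(dim(x$object_estimate),
                                       collapse = " x "),
      ", ", length(x$probe_estimates), " probe mode(s); final data error ",
      if (length(x$data_error)) format(tail(x$data_error, 1), digits = 4)
      else "NA", "\n", sep = "")
  invisible(x)
}

#' Maximum-likelihood refinement of a ptychographic reconstruction
#'
#' Conjugate-gradient (Polak-Ribiere) minimization of the negative
#' log-likelihood over object and probe modes with a backtracking (Armijo)
#' line search. The default `metric = "poisson"` minimizes the Poisson NLL
#' `sum (I - c log I)` of the measured counts, which is what distinguishes
#' the refinement from the difference map's amplitude projections on
#' photon-limited data; `metric = "amplitude"` uses the Gaussian amplitude
#' approximation `sum (sqrt(I) - A)^2`. Steps are accepted only if the
#' objective decreases, so the recorded history is non-increasing.
#' Additional probe modes are seeded from the warm-start probe with small
#' random perturbations at 1% power.
#'
#' @param scan a `diffraction_scan`.
#' @param warm_start a `ptycho_result` (e.g. from [difference_map()]).
#' @param n_iter CG iterations.
#' @param n_probe_modes number of probe modes (>= 1).
#' @param metric `"poisson"` (default) or `"amplitude"`.
#' @param rng_seed seed for extra-mode initialization.
#' @return a `ptycho_result` with `probe_estimates` of length
#'   `n_probe_modes`; `data_error` continues the warm start's history with
#'   the normalized amplitude data error per accepted iteration.
#' @export
ml_refine <- function(scan, warm_start, n_iter = 100, n_probe_modes = 1,
                      metric = c("poisson", "amplitude"), rng_seed = 1L) {
  metric <- match.arg(metric)
  if (is.null(warm_start)) stop("warm_start required")
  if (n_probe_modes < 1) stop("n_probe_modes must be >= 1")
  np <- scan$detector_pixels
  nj <- length(scan$patterns)
  amps <- .amp_targets(scan)
  O <- warm_start$object_estimate
  probes <- warm_start$probe_estimates
  set.seed(as.integer(rng_seed))
  while (length(probes) < n_probe_modes) {
    base <- probes[[1]]
    pert <- matrix(complex(real = stats::rnorm(length(base)),
                           imaginary = stats::rnorm(length(base))),
                   np, np)
    pert <- pert * sqrt(0.01 * sum(Mod(base)^2) / sum(Mod(pert)^2))
    probes <- c(probes, list(pert))
  }
  sN <- sqrt(np * np)

  eps <- 1e-10
  loss_grad <- function(O, probes, want_grad = TRUE) {
    L <- 0
    gO <- if (want_grad) matrix(0 + 0i, nrow(O), ncol(O)) else NULL
    gP <- if (want_grad) lapply(probes, function(p) matrix(0 + 0i, np, np))
    for (j in seq_len(nj)) {
      ii <- .patch_idx(scan$positions[j, ], np)
      oj <- O[ii$y, ii$x]
      Fm <- lapply(probes, function(P) fft(P * oj) / sN)
      I <- Reduce(`+`, lapply(Fm, function(f) Mod(f)^2))
      Aj <- amps[[j]]
      if (metric == "poisson") {
        cj <- Aj^2                      # scaled counts
        L <- L + sum(I - cj * log(I + eps))
        fac <- if (want_grad) (1 - cj / (I + eps)) else NULL
      } else {
        r <- sqrt(I + 1e-12)
        L <- L + sum((r - Aj)^2)
        fac <- if (want_grad) (1 - Aj / r) else NULL
      }
      if (want_grad) {
        for (m in seq_along(probes)) {
          chiF <- fac * Fm[[m]]
          chi <- fft(chiF, inverse = TRUE) / sN
          gO[ii$y, ii$x] <- gO[ii$y, ii$x] + Conj(probes[[m]]) * chi
          gP[[m]] <- gP[[m]] + Conj(oj) * chi
        }
      }
    }
    list(L = L, gO = gO, gP = gP)
  }

  flat <- function(O, probes) c(as.vector(O),
                                unlist(lapply(probes, as.vector)))
  unflat <- function(v) {
    nO <- length(O)
    Ov <- matrix(v[seq_len(nO)], nrow(O), ncol(O))
    ps <- vector("list", length(probes))
    off <- nO
    for (m in seq_along(probes)) {
      ps[[m]] <- matrix(v[off + seq_len(np * np)], np, np)
      off <- off + np * np
    }
    list(O = Ov, probes = ps)
  }

  n_meas <- nj * np * np
  record <- function(L) {
    if (metric == "poisson") L / n_meas       # mean NLL (monotone history)
    else sqrt(L / sum(unlist(amps)^2))
  }
  cur <- loss_grad(O, probes)
  err <- numeric(0)
  g_old <- NULL; dir <- NULL
  step <- 1
  for (it in seq_len(n_iter)) {
    g <- flat(cur$gO, cur$gP)
    if (is.null(dir)) {
      dir <- -g
    } else {
      beta <- max(0, Re(sum(Conj(g) * (g - g_old))) / sum(Mod(g_old)^2))
      dir <- -g + beta * dir
      if (Re(sum(Conj(g) * dir)) > 0) dir <- -g   # reset on non-descent
    }
    g_old <- g
    # backtracking Armijo line search
    x0 <- flat(O, probes)
    gd <- Re(sum(Conj(g) * dir))
    alpha <- step
    ok <- FALSE
    for (ls in 1:12) {
      cand <- unflat(x0 + alpha * dir)
      Lc <- loss_grad(cand$O, cand$probes, want_grad = FALSE)$L
      if (Lc <= cur$L + 1e-4 * alpha * gd) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) { err <- c(err, record(cur$L)); next }
    step <- alpha * 2
    O <- cand$O; probes <- cand$probes
    cur <- loss_grad(O, probes)
    err <- c(err, record(cur$L))
  }
  structure(list(object_estimate = O, probe_estimates = probes,
                 iterations_run = c(warm_start$iterations_run,
                                    ml = as.integer(n_iter)),
                 data_error = c(warm_start$data_error, err)),
            class = "ptycho_result")
}

#' Remove constant and linear phase components
#'
#' Subtracts the least-squares best-fit plane `a + b x + c y` from a phase
#' image: the output has zero mean and zero first moments in x and y. These
#' components are gauge freedoms of ptychographic reconstructions and are
#' removed before tomography.
#'
#' @param phase_image real 2D matrix (radians).
#' @return matrix of the same dim.
#' @export
remove_phase_ramp <- function(phase_image) {
  if (!all(is.finite(phase_image))) stop("phase image must be finite")
  ny <- nrow(phase_image); nx <- ncol(phase_image)
  y <- rep(seq_len(ny), nx) - .grid_center(ny)
  x <- rep(seq_len(nx), each = ny) - .grid_center(nx)
  v <- as.vector(phase_image)
  # centered coordinates: normal equations are diagonal
  a <- mean(v)
  b <- sum(v * x) / sum(x * x)
  c <- sum(v * y) / sum(y * y)
  matrix(v - a - b * x - c * y, ny, nx)
}

#' Fraction of total probe power in each mode
#'
#' @param result a `ptycho_result`.
#' @return numeric vector summing to 1.
#' @export
probe_mode_power <- function(result) {
  p <- vapply(result$probe_estimates, function(P) sum(Mod(P)^2), numeric(1))
  p / sum(p)
}
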