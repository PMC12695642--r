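# Fourier ring/shell correlation, information-bit thresholds, split-half
# resolution estimation, and the dose-resolution power-law fit.
#
# Resolution convention: frequencies are in cycles/voxel (Nyquist = 0.5);
# the reported resolution is the half-pitch at the first downward threshold
# crossing, resolution_nm = voxel_size / (2 * f_cross). A curve that never
# crosses reports the band-limit sentinel 2 * voxel_size with
# `crossed = FALSE` (deliberately pessimistic so an uncrossed curve never
# beats a crossed one near Nyquist).

# shell/ring index per Fourier voxel for an array of dim d (any rank),
# frequencies per axis in cycles/sample. Bin width 1 Fourier voxel.
.shell_index <- function(d) {
  fr <- lapply(d, function(n) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    if (n %% 2 == 0) f <- c(0:(n / 2 - 1), -(n / 2):-1) / n
    f
  })
  r2 <- 0
  for (ax in seq_along(d)) {
    shp <- rep(1, length(d)); shp[ax] <- d[ax]
    f <- array(fr[[ax]], dim = shp)
    r2 <- r2 + as.vector(outer_expand(f, d, ax))^2
  }
  r <- sqrt(r2) * min(d)        # radius in Fourier voxels of smallest axis
  pmin(round(r), floor(min(d) / 2))
}

# broadcast a per-axis vector into the full array shape (helper for
# .shell_index)
outer_expand <- function(f, d, axis) {
  perm <- seq_along(d)
  v <- f
  reps_before <- prod(d[seq_len(axis - 1)])
  reps_after <- prod(d[seq_along(d) > axis])
  array(rep(rep(as.vector(v), each = reps_before), times = reps_after), d)
}

# soft spherical/circular mask with cosine edge (edge width as a fraction of
# the radius) to suppress wraparound before FSC
.soft_mask <- function(d, edge = 0.05) {
  ctrs <- (d + 1) / 2
  r2 <- 0
  for (ax in seq_along(d)) {
    shp <- rep(1, length(d)); shp[ax] <- d[ax]
    x <- (seq_len(d[ax]) - ctrs[ax]) / (d[ax] / 2)
    r2 <- r2 + as.vector(outer_expand(array(x, shp), d, ax))^2
  }
  r <- sqrt(r2)
  inner <- 1 - edge
  m <- ifelse(r <= inner, 1,
              ifelse(r >= 1, 0, 0.5 * (1 + cos(pi * (r - inner) / edge))))
  array(m, d)
}

#' Information-bit FRC/FSC threshold curve
#'
#' Computes per-shell thresholds from an information criterion of `bits`
#' bits per Fourier voxel (van Heel & Schatz form):
#' `T = (SNR + 2 sqrt(SNR)/sqrt(n) + 1/sqrt(n)) /
#'      (SNR + 2 sqrt(SNR)/sqrt(n) + 1)`.
#' The total-dataset SNR implied by the criterion is `2^bits - 1`; the
#' `normalization` flag selects whether the per-half-dataset SNR
#' (`(2^bits - 1)/2`, the convention of the canonical 1-bit and half-bit
#' curves) or the full-dataset SNR enters the formula and is reported.
#'
#' @param bits information bits (> 0); 1 for the 1-bit criterion, 0.5 for
#'   the half-bit criterion.
#' @param n_per_shell voxel counts per shell (>= 1).
#' @param normalization `"per_half"` or `"full"`.
#' @return list with `snr` (the selected SNR) and `threshold` (vector like
#'   `n_per_shell`).
#' @export
bit_threshold <- function(bits, n_per_shell = 1,
                          normalization = c("per_half", "full")) {
  normalization <- match.arg(normalization)
  if (bits <= 0) stop("bits must be > 0")
  if (any(n_per_shell < 1)) stop("shell counts must be >= 1")
  snr_full <- 2^bits - 1
  snr <- if (normalization == "per_half") snr_full / 2 else snr_full
  rn <- 1 / sqrt(n_per_shell)
  thr <- (snr + 2 * sqrt(snr) * rn + rn) / (snr + 2 * sqrt(snr) * rn + 1)
  list(snr = snr, threshold = thr)
}

# shared FRC/FSC core for 2D or 3D arrays
.fourier_correlation <- function(a, b, criterion, voxel_size, mask = TRUE) {
  if (!identical(dim(a), dim(b))) stop("mismatched shapes")
  d <- dim(a)
  if (mask) {
    m <- .soft_mask(d)
    a <- a * m; b <- b * m
  }
  Fa <- fft(a); Fb <- fft(b)
  sh <- .shell_index(d)
  ns <- max(sh)
  idx <- factor(sh, levels = 0:ns)
  num <- vapply(split(as.vector(Fa * Conj(Fb)), idx), sum, complex(1))
  pa <- vapply(split(as.vector(Mod(Fa)^2), idx), sum, numeric(1))
  pb <- vapply(split(as.vector(Mod(Fb)^2), idx), sum, numeric(1))
  n_per_shell <- as.vector(table(idx))
  corr <- Re(num) / sqrt(pmax(pa * pb, 1e-300))
  freqs <- (0:ns) / min(d)                 # cycles/voxel at bin centers
  bits <- switch(criterion, one_bit = 1, half_bit = 0.5,
                 stop("unknown criterion: ", criterion))
  thr <- bit_threshold(bits, pmax(n_per_shell, 1),
                       normalization = "per_half")$threshold
  # first downward crossing, DC shell excluded, linear interpolation
  diffc <- corr - thr
  crossed <- FALSE
  f_cross <- 0.5
  for (s in 2:(ns)) {
    if (diffc[s] >= 0 && diffc[s + 1] < 0) {
      w <- diffc[s] / (diffc[s] - diffc[s + 1])
      f_cross <- freqs[s] + w * (freqs[s + 1] - freqs[s])
      crossed <- TRUE
      break
    }
    if (s == 2 && diffc[s] < 0) {      # already below at first shell
      f_cross <- freqs[s]
      crossed <- TRUE
      break
    }
  }
  # no crossing: report the band limit (2 * voxel size) with crossed = FALSE
  resolution_nm <- if (crossed) voxel_size / (2 * f_cross) else 2 * voxel_size
  structure(list(shell_freqs = freqs, correlation = corr,
                 n_per_shell = n_per_shell, threshold = thr,
                 criterion = criterion, crossed = crossed,
                 resolution_nm = resolution_nm, voxel_size = voxel_size),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat("<fsc_curve> ", length(x$shell_freqs), " shells (", x$criterion,
      "); resolution ", format(x$resolution_nm, digits = 4), " nm",
      if (!x$crossed) " [no crossing: band limit]", "\n", sep = "")
  invisible(x)
}

#' Fourier ring correlation between two images
#'
#' Per-ring normalized cross-correlation of the 2D Fourier transforms,
#' compared against the information-bit threshold; resolution is the
#' half-pitch at the first downward crossing.
#'
#' @param image_a,image_b real matrices of identical dim.
#' @param criterion `"one_bit"` (default for 2D projections) or `"half_bit"`.
#' @param pixel_size_nm pixel pitch in nm (default 1).
#' @param mask apply a soft circular mask before the FFT (default TRUE).
#' @return an `fsc_curve`.
#' @export
frc <- function(image_a, image_b, criterion = "one_bit", pixel_size_nm = 1,
                mask = TRUE) {
  .fourier_correlation(as.matrix(image_a), as.matrix(image_b), criterion,
                       pixel_size_nm, mask = mask)
}

#' Fourier shell correlation between two volumes
#'
#' @param vol_a,vol_b 3D arrays of identical dim.
#' @param criterion `"half_bit"` (default for split-half tomograms) or
#'   `"one_bit"`.
#' @param voxel_size_nm voxel pitch in nm (default 1).
#' @param mask apply a soft spherical mask (default TRUE).
#' @return an `fsc_curve`.
#' @export
fsc <- function(vol_a, vol_b, criterion = "half_bit", voxel_size_nm = 1,
                mask = TRUE) {
  .fourier_correlation(vol_a, vol_b, criterion, voxel_size_nm, mask = mask)
}

#' Split-half FSC resolution of a projection series
#'
#' Splits the projections into odd/even angular halves, reconstructs each
#' half independently (rigid FBP or nonrigid), and computes the 3D FSC with
#' the half-bit criterion (each half has double angular sampling, so the
#' pair is an independently acquired dataset pair). In nonrigid mode the
#' deformation flows are estimated once from the full series' subtomograms
#' and both halves are deformation-corrected onto the same (lowest-dose)
#' reference state; estimating flows per half would register the halves to
#' different deformation states and bias the FSC down.
#'
#' @param projection_set a `phase_projection_set` (>= 8 projections).
#' @param mode `"rigid"` or `"nonrigid"`.
#' @param filter FBP filter.
#' @param criterion threshold criterion (default `"half_bit"`).
#' @param flows,node_times optional precomputed flows (see
#'   [nonrigid_reconstruct()]).
#' @param flow_args arguments for [estimate_flow()].
#' @return an `fsc_curve` (with the two half-volumes attached as
#'   `half_volumes`).
#' @export
fsc_split_half <- function(projection_set, mode = c("rigid", "nonrigid"),
                           filter = c("hann", "ramlak"),
                           criterion = "half_bit", flows = NULL,
                           node_times = NULL, flow_args = list()) {
  mode <- match.arg(mode)
  filter <- match.arg(filter)
  ps <- projection_set
  if (length(ps$projections) < 8) stop("need >= 8 projections for split-half FSC")
  if (mode == "nonrigid" && is.null(flows)) {
    est <- estimate_subtomo_flows(ps, filter = filter, flow_args = flow_args)
    flows <- est$flows
    node_times <- est$node_times
  }
  rank_of <- rank(ps$angles, ties.method = "first")
  halves <- lapply(1:2, function(h) .subset_ps(ps, which(rank_of %% 2 == h %% 2)))
  vols <- lapply(halves, function(h) {
    if (mode == "rigid") fbp(h, filter = filter)$volume
    else nonrigid_reconstruct(h, filter = filter, flows = flows,
                              node_times = node_times)$volume
  })
  out <- fsc(vols[[1]], vols[[2]], criterion = criterion,
             voxel_size_nm = ps$pixel_size)
  out$half_volumes <- vols
  out$mode <- mode
  out
}

#' Fit the dose-resolution power law
#'
#' Fits `resolution = a / dose^(1/4)` with the exponent fixed at 1/4:
#' least squares on `log(res) = log(a) - 0.25 log(dose)`, i.e. `log(a)` is
#' the mean of `log(res) + 0.25 log(dose)`. The 95% prediction band uses
#' nonsimultaneous observational bounds on the log-residuals
#' (`t_{0.975, n-1} * s * sqrt(1 + 1/n)`).
#'
#' @param dose vector of doses, Gy (> 0).
#' @param resolution vector of resolutions, nm (> 0).
#' @param level prediction level (default 0.95).
#' @return object of class `powerlaw_fit`: `a`, `exponent` (0.25),
#'   `log_sigma`, `n`, `predict(dose)` closure returning a data.frame with
#'   fit, lower, upper.
#' @export
fit_dose_resolution <- function(dose, resolution, level = 0.95) {
  if (length(dose) != length(resolution)) stop("length mismatch")
  if (length(unique(dose)) < 2) stop("need >= 2 points with distinct doses")
  if (any(dose <= 0) || any(resolution <= 0))
    stop("dose and resolution must be positive")
  ylog <- log(resolution) + 0.25 * log(dose)
  n <- length(ylog)
  la <- mean(ylog)
  s <- stats::sd(ylog)
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  half <- if (n > 1 && is.finite(s)) tq * s * sqrt(1 + 1 / n) else 0
  a <- exp(la)
  structure(list(
    a = a, exponent = 0.25, log_sigma = s, n = n, level = level,
    predict = function(d) {
      mu <- la - 0.25 * log(d)
      data.frame(dose = d, fit = exp(mu), lower = exp(mu - half),
                 upper = exp(mu + half))
    }),
    class = "powerlaw_fit")
}

#' Write a power-law fit as JSON
#'
#' @param fit a `powerlaw_fit`.
#' @param path output path.
#' @export
save_powerlaw_json <- function(fit, path) {
  jsonlite::write_json(list(a = fit$a, exponent = fit$exponent,
                            log_sigma = fit$log_sigma, n = fit$n,
                            level = fit$level),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Log-log dose-resolution chart
#'
#' Plots dose-resolution points with the fitted `a / dose^(1/4)` curve and
#' its 95% prediction band on log-log axes (base graphics).
#'
#' @param x a `powerlaw_fit`.
#' @param dose,resolution the fitted points.
#' @param ... passed to [plot()].
#' @export
plot.powerlaw_fit <- function(x, dose = NULL, resolution = NULL, ...) {
  rng <- if (is.null(dose)) c(1e6, 1e10) else range(dose) * c(0.5, 2)
  dd <- 10^seq(log10(rng[1]), log10(rng[2]), length.out = 100)
  p <- x$predict(dd)
  graphics::plot(dd, p$fit, type = "l", log = "xy",
                 xlab = "dose (Gy)", ylab = "resolution (nm)",
                 ylim = range(c(p$lower, p$upper, resolution)), ...)
  graphics::lines(dd, p$lower, lty = 2)
  graphics::lines(dd, p$upper, lty = 2)
  if (!is.null(dose)) graphics::points(dose, resolution, pch = 19)
  invisible(x)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat("<powerlaw_fit> resolution = ", format(x$a, digits = 5),
      " / dose^(1/4)  (n = ", x$n, ", log-sigma = ",
      format(x$log_sigma, digits = 3), ")\n", sep = "")
  invisible(x)
}
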