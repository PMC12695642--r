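# Experiment runner and plain-text I/O. Units policy at the I/O boundary:
# positions and resolutions in nm, dose in Gy, angles in degrees.

#' Default experiment configuration
#'
#' A single declarative configuration covering phantom, deformation, plan,
#' reconstruction and metric parameters with explicit seeds. Values are
#' plain lists so the configuration serializes losslessly to JSON.
#'
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(...) {
  base <- list(
    phantom = list(size_voxels = 64, voxel_size_nm = 40, n_neurites = 6,
                   n_mitochondria = 6, n_synapses = 12),
    deformation = list(amplitude = 2, smoothness = 16,
                       control_times = c(0, 0.25, 0.5, 0.75, 1)),
    plan = list(n_angles = 96, n_subtomos = 4, scan_step = 1.0,
                exposure = 0.1, flux = 7e8, photon_energy = 6.2),
    recon = list(filter = "hann", mode = "rigid", outer_iters = 0),
    metrics = list(criterion = "half_bit", mask = TRUE),
    dose_ladder = list(photon_budgets = c(1e3, 1.6e4),
                       noise_ref_photons = 1e3, noise_ref_sd = 0.2),
    captcha = list(n_regions = 250, n_annotators = 3,
                   sensitivity = c(0.95, 0.75), specificity = c(0.95, 0.85),
                   dropout_rate = 0.02, min_xcorr = 0.4, cut = 2.5,
                   beta = 2, n_boot = 1000),
    seeds = list(phantom = 1L, deformation = 2L, noise = 3L, captcha = 4L),
    output_dir = NULL)
  ov <- list(...)
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  structure(merge_rec(base, ov), class = "experiment_config")
}

#' Save / load an experiment configuration (JSON round trip)
#'
#' @param config an `experiment_config`.
#' @param path file path.
#' @return `load_config` returns the `experiment_config`.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "experiment_config")
}

#' Run a dose-ladder experiment
#'
#' For each photon-budget rung: simulate an acquisition of the (optionally
#' deforming) phantom with phase noise scaled as `1/sqrt(photons)` relative
#' to the calibration rung, compute the absorbed dose (proportional to the
#' budget), reconstruct both rigidly and nonrigidly, and measure the
#' split-half FSC resolution of each. Fits the `a / dose^(1/4)` power law
#' to the nonrigid points when >= 2 rungs are present.
#'
#' @param config an `experiment_config`; `config$dose_ladder$photon_budgets`
#'   sets the rungs.
#' @param deformation logical: deform the sample with accumulating dose
#'   (default TRUE).
#' @return list: `table` (data.frame dose_Gy, resolution_rigid_nm,
#'   resolution_nonrigid_nm, photons), `fit` (a `powerlaw_fit` or NULL).
#' @export
run_dose_ladder <- function(config = experiment_config(),
                            deformation = TRUE) {
  rungs <- config$dose_ladder$photon_budgets
  if (length(rungs) < 2) stop("need >= 2 dose rungs")
  ph <- do.call(make_phantom,
                c(config$phantom, list(rng_seed = config$seeds$phantom)))
  plan <- do.call(acquisition_plan, config$plan)
  dm <- if (deformation)
    do.call(make_deformation,
            c(list(dim_voxels = dim(ph$density)), config$deformation,
              list(rng_seed = config$seeds$deformation))) else NULL
  ref_ph <- config$dose_ladder$noise_ref_photons
  ref_sd <- config$dose_ladder$noise_ref_sd
  rows <- lapply(seq_along(rungs), function(i) {
    photons <- rungs[i]
    noise_sd <- ref_sd * sqrt(ref_ph / photons)
    # dose scales linearly with the per-point photon budget
    exposure_eff <- config$plan$exposure * photons / ref_ph
    plan_i <- plan
    plan_i$exposure <- exposure_eff
    ps <- acquire_series(ph, dm, plan_i, noise_sd_rad = noise_sd,
                         rng_seed = config$seeds$noise + i)
    res_r <- fsc_split_half(ps, mode = "rigid",
                            filter = config$recon$filter)$resolution_nm
    res_n <- fsc_split_half(ps, mode = "nonrigid",
                            filter = config$recon$filter)$resolution_nm
    data.frame(photons = photons, dose_Gy = ps$total_dose,
               resolution_rigid_nm = res_r, resolution_nonrigid_nm = res_n)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fit <- if (nrow(tab) >= 2 && length(unique(tab$dose_Gy)) >= 2)
    fit_dose_resolution(tab$dose_Gy, tab$resolution_nonrigid_nm) else NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(tab, file.path(config$output_dir, "dose_ladder.csv"),
              row.names = FALSE)
    if (!is.null(fit))
      save_powerlaw_json(fit, file.path(config$output_dir,
                                        "dose_ladder_fit.json"))
    .write_manifest(config, "dose_ladder",
                    file.path(config$output_dir, "manifest.json"))
  }
  list(table = tab, fit = fit)
}

#' Run a simulated captcha experiment
#'
#' Generates a synthetic annotator score array, applies the QC cleaning,
#' computes the confusion metrics, and attaches bootstrap confidence
#' intervals (resampling regions).
#'
#' @param config an `experiment_config`.
#' @return list: `summary` (a `confusion_summary`), `tables`, `boot_ci`
#'   (2.5/97.5% quantiles for P, R, F1, F_beta), `cleaning` (QC record).
#' @export
run_captcha_sim <- function(config = experiment_config()) {
  cc <- config$captcha
  sa <- make_score_array(n_regions = cc$n_regions,
                         n_annotators = cc$n_annotators,
                         sensitivity = cc$sensitivity,
                         specificity = cc$specificity,
                         dropout_rate = cc$dropout_rate,
                         rng_seed = config$seeds$captcha)
  cleaned <- clean_scores(sa, min_xcorr = cc$min_xcorr)
  res <- captcha_confusion(cleaned$scores, cut = cc$cut, beta = cc$beta)
  nr <- dim(cleaned$scores)[1]
  set.seed(config$seeds$captcha + 1L)
  boot <- replicate(cc$n_boot, {
    idx <- sample.int(nr, nr, replace = TRUE)
    s <- captcha_confusion(cleaned$scores[idx, , , drop = FALSE],
                           cut = cc$cut, beta = cc$beta)$summary
    c(precision = s$precision, recall = s$recall, f1 = s$f1,
      f_beta = s$f_beta)
  })
  ci <- apply(boot, 1, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    .write_manifest(config, "captcha_sim",
                    file.path(config$output_dir, "manifest.json"))
  }
  list(summary = res$summary, tables = res[c("table_2x2", "table_4x4")],
       boot_ci = ci, cleaning = cleaned[c("kept_annotators",
                                          "dropped_annotators",
                                          "kept_regions",
                                          "dropped_regions")])
}

# experiment manifest: config (hashable content), seeds and versions,
# sufficient to re-run deterministic stages bit-identically
.write_manifest <- function(config, stage, path) {
  payload <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA)
  manifest <- list(stage = stage,
                   config = unclass(config),
                   config_hash = sprintf("%08x",
                                         sum(utf8ToInt(payload) *
                                               seq_along(utf8ToInt(payload))) %%
                                           .Machine$integer.max),
                   seeds = config$seeds,
                   r_version = as.character(getRversion()),
                   package_version =
                     as.character(utils::packageVersion("pxctsim")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# ---------------------------------------------------------------- I/O ----

#' Save / load a volume as a plain-text stack
#'
#' Writes the z-slices of a 3D array as one TSV block per slice (blank-line
#' separated) plus a JSON sidecar carrying dim, voxel size and free
#' metadata. Round trips are bit-identical for doubles written with
#' full precision.
#'
#' @param vol 3D array.
#' @param path base path; `<path>.tsv` and `<path>.json` are written.
#' @param voxel_size_nm voxel pitch recorded in the sidecar.
#' @param meta extra metadata list for the sidecar.
#' @return `load_volume` returns a list `volume`, `voxel_size_nm`, `meta`.
#' @export
save_volume <- function(vol, path, voxel_size_nm = 1, meta = list()) {
  d <- dim(vol)
  con <- file(paste0(path, ".tsv"), "w")
  on.exit(close(con))
  for (z in seq_len(d[1])) {
    write.table(format(vol[z, , ], digits = 17),
                con, sep = "\t", row.names = FALSE, col.names = FALSE,
                quote = FALSE)
    if (z < d[1]) writeLines("", con)
  }
  jsonlite::write_json(list(dim = d, voxel_size_nm = voxel_size_nm,
                            meta = meta),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_volume
#' @export
load_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  d <- as.integer(info$dim)
  lines <- readLines(paste0(path, ".tsv"))
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- blocks[lengths(blocks) > 0]
  if (length(blocks) != d[1])
    stop("corrupt volume stack: expected ", d[1], " slices, found ",
         length(blocks))
  vol <- array(0, d)
  for (z in seq_along(blocks)) {
    rows <- strsplit(blocks[[z]], "\t")
    if (length(rows) != d[2] || any(lengths(rows) != d[3]))
      stop("corrupt volume stack at slice ", z, ": ragged rows")
    vol[z, , ] <- matrix(as.numeric(unlist(rows)), d[2], d[3], byrow = TRUE)
  }
  list(volume = vol, voxel_size_nm = info$voxel_size_nm, meta = info$meta)
}

#' Read annotation nodes from CSV, normalizing units to nm
#'
#' Accepts coordinate columns named `z_nm`/`y_nm`/`x_nm` or `z_um`/`y_um`/
#' `x_um` (converted to nm); other columns (`pass_index`, `annotator_id`,
#' `modality`, `dendrite_id`) pass through.
#'
#' @param path CSV path.
#' @return data.frame with `z_nm`, `y_nm`, `x_nm` columns.
#' @export
read_annotations <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (ax in c("z", "y", "x")) {
    nm <- paste0(ax, "_nm"); um <- paste0(ax, "_um")
    if (!nm %in% names(df)) {
      if (um %in% names(df)) {
        df[[nm]] <- df[[um]] * 1000
        df[[um]] <- NULL
      } else {
        stop("annotation file lacks column ", nm, " (or ", um, ")")
      }
    }
  }
  df
}

#' Write an FSC curve as CSV
#'
#' @param curve an `fsc_curve`.
#' @param path CSV path.
#' @export
write_fsc_csv <- function(curve, path) {
  write.csv(data.frame(freq = curve$shell_freqs,
                       correlation = curve$correlation,
                       threshold = curve$threshold,
                       n = curve$n_per_shell),
            path, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------- CLI ----

#' Command-line entry point
#'
#' Verb dispatcher for `Rscript -e 'pxctsim::pxct_main()' <verb> ...` or the
#' wrapper script in `inst/cli/pxct.R`. Verbs: `phantom`, `acquire`,
#' `tomo`, `fsc`, `captcha-sim`, `dose-ladder`. Arguments are `--key value`
#' pairs; `--seed` seeds every stochastic stage.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @return invisibly, the verb's result.
#' @export
pxct_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: pxct <phantom|acquire|tomo|fsc|captcha-sim|dose-ladder>",
        "[--key value ...]\n")
    return(invisible(NULL))
  }
  verb <- args[1]
  kv <- .parse_cli_args(args[-1])
  seed <- as.integer(kv$seed %||% 1)
  out <- kv$out %||% "pxct_out"
  res <- switch(
    verb,
    "phantom" = {
      ph <- make_phantom(size_voxels = as.integer(kv$size %||% 64),
                         rng_seed = seed)
      save_volume(ph$density, out, ph$voxel_size,
                  meta = list(seed = seed))
      write.csv(ph$synapses, paste0(out, "_synapses.csv"),
                row.names = FALSE)
      ph
    },
    "acquire" = {
      ph <- make_phantom(size_voxels = as.integer(kv$size %||% 64),
                         rng_seed = seed)
      plan <- acquisition_plan(n_angles = as.integer(kv$angles %||% 96),
                               n_subtomos = as.integer(kv$subtomos %||% 4))
      dm <- if (!is.null(kv$amplitude) && as.numeric(kv$amplitude) > 0)
        make_deformation(dim(ph$density),
                         amplitude = as.numeric(kv$amplitude),
                         rng_seed = seed + 1L) else NULL
      ps <- acquire_series(ph, dm, plan, rng_seed = seed + 2L)
      .save_projection_set(ps, out)
      ps
    },
    "tomo" = {
      ps <- .load_projection_set(kv$`in` %||% stop("--in required"))
      mode <- kv$mode %||% "rigid"
      tg <- if (mode == "nonrigid")
        nonrigid_reconstruct(ps, filter = kv$filter %||% "hann")
      else fbp(ps, filter = kv$filter %||% "hann")
      save_volume(tg$volume, out, tg$voxel_size, meta = tg$provenance)
      tg
    },
    "fsc" = {
      ps <- .load_projection_set(kv$`in` %||% stop("--in required"))
      cv <- fsc_split_half(ps, mode = kv$mode %||% "rigid",
                           filter = kv$filter %||% "hann")
      write_fsc_csv(cv, paste0(out, "_fsc.csv"))
      cat("resolution_nm:", cv$resolution_nm, "\n")
      cv
    },
    "captcha-sim" = {
      cfg <- experiment_config(seeds = list(captcha = seed))
      r <- run_captcha_sim(cfg)
      jsonlite::write_json(list(
        precision = r$summary$precision, recall = r$summary$recall,
        f1 = r$summary$f1, f_beta = r$summary$f_beta),
        paste0(out, "_captcha.json"), auto_unbox = TRUE, digits = NA)
      r
    },
    "dose-ladder" = {
      cfg <- experiment_config(seeds = list(phantom = seed,
                                            deformation = seed + 1L,
                                            noise = seed + 2L))
      r <- run_dose_ladder(cfg)
      write.csv(r$table, paste0(out, "_ladder.csv"), row.names = FALSE)
      r
    },
    stop("unknown verb: ", verb))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_cli_args <- function(args) {
  kv <- list()
  i <- 1
  while (i <= length(args)) {
    if (startsWith(args[i], "--")) {
      key <- sub("^--", "", args[i])
      kv[[key]] <- if (i + 1 <= length(args)) args[i + 1] else TRUE
      i <- i + 2
    } else i <- i + 1
  }
  kv
}

.save_projection_set <- function(ps, path) {
  d <- c(length(ps$projections), dim(ps$projections[[1]]))
  stack <- array(0, d)
  for (i in seq_len(d[1])) stack[i, , ] <- ps$projections[[i]]
  save_volume(stack, path, ps$pixel_size,
              meta = list(angles = ps$angles, times = ps$times,
                          subtomo = ps$subtomo,
                          per_projection_dose = ps$per_projection_dose,
                          k_phase = ps$k_phase))
  invisible(path)
}

.load_projection_set <- function(path) {
  x <- load_volume(path)
  d <- dim(x$volume)
  structure(list(
    projections = lapply(seq_len(d[1]), function(i) x$volume[i, , ]),
    angles = as.numeric(x$meta$angles),
    times = as.numeric(x$meta$times),
    subtomo = as.integer(x$meta$subtomo),
    pixel_size = x$voxel_size_nm,
    per_projection_dose = as.numeric(x$meta$per_projection_dose),
    k_phase = as.numeric(x$meta$k_phase)),
    class = "phase_projection_set")
}
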