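#' Benchmark run configuration
#'
#' Bundles geometry, sampling, simulation and solver settings for an
#' end-to-end synthetic benchmark. All random stages draw from seeds
#' derived deterministically from `seed`, so a configuration reproduces a
#' run exactly. The default geometry is the package's desk-scale study:
#' a 64 x 64 x 12 slab, 8 coils, 12 shots, Ry = 3, noiseless, with
#' 2-radian shot phases.
#'
#' @param seed master seed.
#' @param Nx,Ny,Nkz image/grid size (`Nz == Nkz` for a single slab).
#' @param Ncoil,Nshot,Ry,pf,dmax acquisition settings; `dmax` defaults to
#'   6 grid units, the 64-line equivalent of the published 15-line bound
#'   on a 180-line grid.
#' @param amplitude peak shot phase (radians).
#' @param sigma complex noise standard deviation per channel.
#' @param sens_support coil map k-space support size (odd).
#' @param admm an [admm_params()].
#' @param lambda4 slab-reconstruction SPIRiT weight; the benchmark default
#'   is 1 (the weight also conditions the normal equations of the fixed
#'   CG budget; see the methods vignette).
#' @param recon_cg_iters CG iterations of the slab reconstruction.
#' @param filter_window Hamming window width for phase-map filtering
#'   before the slab reconstruction; defaults to the published absolute
#'   width 32 (capped at the grid size).
#' @param use_estimated_sens estimate sensitivities from calibration
#'   instead of using the generating maps.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, Nx = 64L, Ny = 64L, Nkz = 12L,
                       Ncoil = 8L, Nshot = 12L, Ry = 3L, pf = 1,
                       dmax = 6, amplitude = 2, sigma = 0,
                       sens_support = 5L, admm = admm_params(),
                       lambda4 = 1, recon_cg_iters = 30L,
                       filter_window = NULL,
                       use_estimated_sens = FALSE) {
  seed <- as.integer(seed)
  if (is.null(filter_window)) filter_window <- min(32L, Nx, Ny)
  admm$seed <- seed + 4000L
  structure(list(
    seed = seed, Nx = as.integer(Nx), Ny = as.integer(Ny),
    Nkz = as.integer(Nkz), Ncoil = as.integer(Ncoil),
    Nshot = as.integer(Nshot), Ry = as.integer(Ry), pf = pf, dmax = dmax,
    amplitude = amplitude, sigma = sigma,
    sens_support = as.integer(sens_support), admm = admm,
    lambda4 = lambda4, recon_cg_iters = as.integer(recon_cg_iters),
    filter_window = as.integer(filter_window),
    use_estimated_sens = isTRUE(use_estimated_sens),
    seeds = list(phantom = seed, sens = seed + 1000L,
                 phases = seed + 2000L, noise = seed + 3000L)
  ), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$admm <- unclass(x$admm)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  admm <- do.call(admm_params, x$admm[setdiff(names(x$admm), "seed")])
  admm$seed <- as.integer(x$admm$seed)
  cfg <- do.call(run_config, c(
    x[c("seed", "Nx", "Ny", "Nkz", "Ncoil", "Nshot", "Ry", "pf", "dmax",
        "amplitude", "sigma", "sens_support", "lambda4", "recon_cg_iters",
        "filter_window", "use_estimated_sens")],
    list(admm = admm)))
  cfg
}

#' Simulate a complete synthetic study
#'
#' Runs the generative half of the benchmark: greedy sampling design,
#' phantom, coil maps, shot phases, encoding, calibration, SPIRiT kernel
#' training, self-navigation extraction and the magnitude reference.
#'
#' @param config a [run_config()].
#' @return a `selfnav_study` list holding all inputs, ground truth and
#'   calibrated operators for the reconstruction stages.
#' @export
simulate_study <- function(config) {
  scfg <- sampling_config(config$Ny, config$Nkz, config$Nshot, config$Ry,
                          config$pf, config$dmax)
  patterns <- greedy_optimize(scfg)
  phantom <- make_phantom(config$Nx, config$Ny, config$Nkz,
                          seed = config$seeds$phantom)
  sens <- make_sensitivities(config$Ncoil, config$Nx, config$Ny,
                             s = config$sens_support,
                             seed = config$seeds$sens)
  phases <- make_shot_phases(config$Nshot, config$Nx, config$Ny,
                             amplitude = config$amplitude,
                             seed = config$seeds$phases)
  kspace <- encode(phantom, sens, phases, patterns,
                   noise_spec(config$sigma, config$seeds$noise))
  calib <- make_calibration(phantom, sens)
  ckz0 <- calib_kz0(calib)
  G_kz0 <- calibrate_kernel(ckz0)
  G_slab <- calibrate_slab_kernels(calib)
  sens_use <- if (config$use_estimated_sens) {
    unclass(estimate_sensitivities(ckz0))
  } else {
    # SOS-normalize the generating maps (the estimated-map convention)
    sos <- sqrt(apply(abs(unclass(sens))^2, c(1, 2), sum))
    unclass(sens) / array(rep(pmax(sos, 1e-12), config$Ncoil), dim(sens))
  }
  selfnav <- extract_selfnav(kspace)
  mref <- magnitude_reference(selfnav, G_kz0,
                              lambda1 = config$admm$lambda1)
  # ground-truth kz0-plane image: z-projection of the object
  proj <- apply(phantom, c(1, 2), sum) / sqrt(config$Nkz)
  support <- abs(proj) > 0.1 * max(abs(proj))
  # coil-weighted ground-truth magnitude volume (what SOS reconstructs)
  sos2d <- sqrt(apply(abs(unclass(sens))^2, c(1, 2), sum))
  truth_sos <- abs(phantom) *
    array(rep(sos2d, config$Nkz), dim(phantom))
  structure(list(
    config = config, sampling = scfg, patterns = patterns,
    phantom = phantom, sens = sens, sens_use = sens_use,
    phases = phases, kspace = kspace, calib = calib, ckz0 = ckz0,
    G_kz0 = G_kz0, G_slab = G_slab, selfnav = selfnav, mref = mref,
    proj = proj, support = support, truth_sos = truth_sos
  ), class = "selfnav_study")
}

#' @export
print.selfnav_study <- function(x, ...) {
  cat(sprintf("<selfnav_study> %d x %d x %d, %d coils, %d shots (seed %d)\n",
              x$config$Nx, x$config$Ny, x$config$Nkz, x$config$Ncoil,
              x$config$Nshot, x$config$seed))
  invisible(x)
}

subset_selfnav <- function(selfnav, shots) {
  trav <- selfnav$traversal
  list(y = selfnav$y[, , , shots, drop = FALSE],
       sel = selfnav$sel[, shots, drop = FALSE],
       traversal = if (!is.na(trav) && trav %in% shots)
         match(trav, shots) else NA_integer_)
}

#' Estimate per-shot phase maps of a study
#'
#' Runs the structured low-rank ADMM on (a subset of) the study's shots
#' and extracts unit-magnitude phase maps, with the circular MAE against
#' the generating phases evaluated inside the object support after
#' referencing both to the first retained shot. `mae` is computed on the
#' unfiltered maps (phase-map accuracy is reported before smoothing);
#' `phi` carries the Hamming-filtered maps used by the slab
#' reconstruction, whose MAE is reported as `mae_filtered`.
#'
#' @param study a [simulate_study()] result.
#' @param mode Hankel redundancy: `"full"`, `"shots"` or `"coils"`.
#' @param shots integer subset of shots (default: all).
#' @param params override the study's [admm_params()].
#' @param use_magnitude include the traversal-shot magnitude constraint
#'   (automatically off when the traversal shot is excluded).
#' @return a `phase_estimate` list: `fit` (the `admm_result`), `phi`
#'   (filtered maps), `phi_raw`, `mae` (raw maps), `mae_filtered`,
#'   `shots`.
#' @export
phase_estimate <- function(study, mode = "full", shots = NULL,
                           params = NULL, use_magnitude = TRUE) {
  cfg <- study$config
  if (is.null(params)) params <- cfg$admm
  if (is.null(shots)) shots <- seq_len(cfg$Nshot)
  sn <- subset_selfnav(study$selfnav, shots)
  mref <- if (use_magnitude && !is.na(sn$traversal)) study$mref else NULL
  fit <- admm_solve(sn, study$G_kz0, mref, study$sens_use,
                    params = params, mode = mode)
  phi_raw <- extract_phase(fit$xhat, study$sens_use)
  phi <- extract_phase(fit$xhat, study$sens_use,
                       filter_window = cfg$filter_window)
  truth <- exp(1i * study$phases[, , shots, drop = FALSE])
  mae <- phase_mae(reference_to_shot1(phi_raw),
                   reference_to_shot1(truth), study$support)
  mae_filtered <- phase_mae(reference_to_shot1(phi),
                            reference_to_shot1(truth), study$support)
  structure(list(fit = fit, phi = phi, phi_raw = phi_raw, mae = mae,
                 mae_filtered = mae_filtered, shots = shots, mode = mode),
            class = "phase_estimate")
}

#' Reconstruct the slab of a study with given phase maps
#'
#' @param study a [simulate_study()] result.
#' @param phi unit-magnitude phase maps `[Nx, Ny, Nshot]`, or `NULL` for
#'   an uncorrected reconstruction, or `"truth"` for the generating
#'   phases.
#' @param shots shot subset used in the reconstruction (default: all).
#' @return list with `Xhat` (corrected k-space), `sos` (magnitude volume)
#'   and `nrmse` against the coil-weighted ground-truth magnitude.
#' @export
reconstruct_study <- function(study, phi = NULL, shots = NULL) {
  cfg <- study$config
  if (is.null(shots)) shots <- seq_len(cfg$Nshot)
  if (is.null(phi)) {
    phi <- array(1 + 0i, c(cfg$Nx, cfg$Ny, length(shots)))
  } else if (identical(phi, "truth")) {
    phi <- exp(1i * study$phases[, , shots, drop = FALSE])
  }
  ks <- study$kspace
  ks$y <- ks$y[, , , , shots, drop = FALSE]
  ks$mask <- ks$mask[, , shots, drop = FALSE]
  ks$patterns <- ks$patterns[shots]
  X <- reconstruct_slab(ks, phi, study$G_slab, lambda4 = cfg$lambda4,
                        cg_iters = cfg$recon_cg_iters)
  sos <- sos_combine(X)
  list(Xhat = X, sos = sos, nrmse = nrmse(sos, study$truth_sos))
}

#' Run the full synthetic benchmark
#'
#' Simulates a study, estimates phase maps (full shot+coil structured
#' low-rank, plus optional shots-only and coils-only ablations), performs
#' uncorrected, true-phase and SLR-phase reconstructions, and collects all
#' metrics. Deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @param ablations also run the shots-only and coils-only Hankel
#'   variants.
#' @param study optionally a pre-computed [simulate_study()] result for
#'   this configuration.
#' @return a `benchmark_report`: tibbles `recon` (per-method NRMSE),
#'   `phase` (per-variant MAE), `sampling` (per-shot o/g/d metrics),
#'   objective traces, and the elapsed time per stage.
#' @export
run_benchmark <- function(config = run_config(), ablations = FALSE,
                          study = NULL) {
  t0 <- proc.time()[3]
  if (is.null(study)) study <- simulate_study(config)
  t_sim <- proc.time()[3] - t0
  est <- list(full = phase_estimate(study, mode = "full"))
  if (ablations) {
    est$shots <- phase_estimate(study, mode = "shots")
    est$coils <- phase_estimate(study, mode = "coils")
  }
  t_phase <- proc.time()[3] - t0 - t_sim
  recons <- list(
    uncorrected = reconstruct_study(study, NULL),
    truth = reconstruct_study(study, "truth"),
    slr = reconstruct_study(study, est$full$phi)
  )
  t_recon <- proc.time()[3] - t0 - t_sim - t_phase
  recon_tbl <- tibble::tibble(
    method = names(recons),
    nrmse = vapply(recons, `[[`, numeric(1), "nrmse")
  )
  phase_tbl <- tibble::tibble(
    variant = names(est),
    mae = vapply(est, `[[`, numeric(1), "mae"),
    mae_filtered = vapply(est, `[[`, numeric(1), "mae_filtered")
  )
  structure(list(
    config = config, study = study, estimates = est, recons = recons,
    recon = recon_tbl, phase = phase_tbl,
    sampling = attr(study$patterns, "metrics"),
    trace = est$full$fit$log,
    runtime = tibble::tibble(stage = c("simulate", "phase", "recon"),
                             seconds = c(t_sim, t_phase, t_recon))
  ), class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("<benchmark_report>\nreconstruction NRMSE:\n")
  print(x$recon)
  cat("phase-map MAE (rad):\n")
  print(x$phase)
  invisible(x)
}

#' Objective trace plot of an ADMM fit
#'
#' @param result an `admm_result`.
#' @return a ggplot of the logged objective components per iteration.
#' @export
plot_objective_trace <- function(result) {
  lg <- result$log
  df <- tibble::tibble(
    iter = rep(lg$iter, 3),
    component = rep(c("data", "spirit", "retained singular mass"),
                    each = nrow(lg)),
    value = c(lg$data, lg$spirit, lg$nuclear_kept)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = iter, y = value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "ADMM iteration", y = "objective component") +
    ggplot2::theme_minimal()
}

# ---------------------------------------------------------------- containers

kspace_container_schema <- c("kspace", "mask", "calib", "sens_truth",
                             "phase_truth", "phantom", "config")

#' Read and write study containers
#'
#' Serialises the simulated k-space study (k-space, masks, calibration,
#' ground truth and configuration) as a single-file container with a
#' validated schema; complex arrays round-trip exactly.
#'
#' @param study a `selfnav_study`.
#' @param path file path (`.rds`).
#' @return `write_study_container`: the path, invisibly;
#'   `read_study_container`: the container list.
#' @export
write_study_container <- function(study, path) {
  obj <- list(kspace = study$kspace$y, mask = study$kspace$mask,
              calib = study$calib, sens_truth = unclass(study$sens),
              phase_truth = study$phases, phantom = study$phantom,
              config = study$config,
              container = "selfnav3d-study", version = 1L)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_study_container
#' @export
read_study_container <- function(path) {
  obj <- readRDS(path)
  missing <- setdiff(kspace_container_schema, names(obj))
  if (length(missing))
    stop("container is missing dataset(s): ",
         paste(missing, collapse = ", "))
  obj
}

#' Export a sampling pattern
#'
#' Writes the per-shot parameters, binary masks and combined count mask as
#' a container, or the `(shot, ky, kz)` line triplets as CSV.
#'
#' @param patterns list of `shot_pattern`s.
#' @param config the [sampling_config()].
#' @param path output path (`.rds` for the container, `.csv` for lines).
#' @export
write_pattern_container <- function(patterns, config, path) {
  masks <- sampling_masks(patterns, config)
  params <- t(vapply(patterns, function(p)
    c(p$params$s_ky, p$params$s_kz, p$params$s_p), integer(3)))
  colnames(params) <- c("s_ky", "s_kz", "s_p")
  saveRDS(list(params = params, masks = masks$per_shot,
               combined = masks$combined,
               metrics = attr(patterns, "metrics"),
               container = "selfnav3d-pattern", version = 1L), path)
  invisible(path)
}

#' @rdname write_pattern_container
#' @export
export_pattern_csv <- function(patterns, path) {
  utils::write.csv(shot_lines(patterns), path, row.names = FALSE)
  invisible(path)
}

#' Write a magnitude volume as NIfTI
#'
#' @param vol real 3D array.
#' @param path output `.nii` / `.nii.gz` path.
#' @param voxel_size numeric length-3 voxel dimensions in mm.
#' @export
write_volume_nifti <- function(vol, path, voxel_size = c(1, 1, 1)) {
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}
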