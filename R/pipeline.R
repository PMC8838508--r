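# Composable end-to-end pipeline: io -> superpose -> {rmsf, rmsd, dccm}
# -> ddccm -> features; io -> acf -> spectrum -> peaks. Configuration is
# a plain named list (or JSON file); every stage parameter serializes
# losslessly, all randomness flows from config seeds, and the manifest
# records inputs, parameters and content hashes of every output.

.pd_default_config <- list(
  selection = "CA",        # analysis subset
  timestep = 5,            # fs between analysis snapshots
  temperature = 300,       # K, for the quantum correction
  cutoff = 0.25,           # |C| / |dC| display & feature threshold
  max_lag_frac = 0.25,     # ACF lag fraction of the series span
  zero_pad = 4L,
  seed = 1L
)

#' Load (and validate) a pipeline configuration
#'
#' @param config named list, or path to a JSON file with the same
#'   fields. Recognized fields: `top` (PDB path), `traj` (XYZ path),
#'   `wt_traj` (optional second XYZ for a difference map), `dipole`
#'   (optional CSV path), `band` (optional numeric(2), cm^-1),
#'   `selection`, `timestep` (fs), `temperature` (K), `cutoff`,
#'   `max_lag_frac`, `zero_pad`, `seed`, `outdir`. Defaults mirror the
#'   analysis conventions: 5 fs snapshot spacing, 0.25 cutoff, 300 K.
#' @return Validated config list of class `run_config`.
#' @export
load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.pd_default_config, config)
  if (is.null(cfg$outdir)) stop("config error: 'outdir' is required")
  if (!is.null(cfg$traj)) {
    if (is.null(cfg$timestep) || !is.numeric(cfg$timestep) || cfg$timestep <= 0) {
      stop("config error: trajectory given but 'timestep' (fs) is missing or invalid")
    }
    if (is.null(cfg$top)) stop("config error: 'traj' requires a 'top' reference PDB")
  }
  for (p in c("top", "traj", "wt_traj", "dipole")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop(sprintf("config error: input '%s' not found: %s", p, cfg[[p]]))
    }
  }
  if (cfg$cutoff < 0) stop("config error: 'cutoff' must be >= 0")
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Save a pipeline configuration as JSON
#' @param config a config list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

.stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline from a configuration
#'
#' Stages execute in dependency order; any stage failure aborts with the
#' stage name. With `top` + `traj` the structural branch runs
#' (superposition, `rmsd.csv`, `rmsf.csv`, `dccm.csv`; plus `ddccm.csv`
#' and `features.json` when `wt_traj` is given, difference convention
#' modified - WT with `traj` as the modified system). With `dipole` the
#' spectroscopic branch runs (`acf.csv`, `spectrum.csv`, and
#' `peaks.json` when `band` is given). The manifest lists inputs,
#' parameters, seeds, and the MD5 content hash of every artifact; the
#' same config always yields hash-identical outputs.
#'
#' @param config a list or JSON path accepted by [load_config()].
#' @return The manifest (named list), invisibly written as
#'   `manifest.json` in `outdir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  add_output <- function(path) outputs <<- c(outputs, path)

  run_structural <- function(traj_path, tag = "") {
    ref <- read_pdb(cfg$top)
    traj <- read_xyz_trajectory(traj_path, dt = cfg$timestep)
    sel <- select_atoms(ref, cfg$selection)
    .stage_log("superpose", "%d frames on %d selected atoms%s",
               n_frames(traj), length(sel),
               if (tag == "") "" else " (wild type)")
    sup <- superpose_trajectory(traj, ref, sel)
    rmsd <- compute_rmsd_series(traj, ref, sel)
    rmsf <- compute_rmsf(sup, sel, reference_label = cfg$top)
    dccm <- compute_dccm(sup, sel)
    if (tag == "") {
      p <- file.path(cfg$outdir, "rmsd.csv")
      write.csv(rmsd, p, row.names = FALSE); add_output(p)
      p <- file.path(cfg$outdir, "rmsf.csv")
      write.csv(data.frame(residue = rmsf$resno, rmsf_A = rmsf$rmsf),
                p, row.names = FALSE); add_output(p)
    }
    p <- file.path(cfg$outdir, if (tag == "") "dccm.csv" else paste0("dccm", tag, ".csv"))
    write_correlation_csv(dccm, p); add_output(p)
    dccm
  }

  if (!is.null(cfg$traj)) {
    dccm_mod <- tryCatch(run_structural(cfg$traj),
                         error = function(e) stop("pipeline stage 'dccm' failed: ",
                                                  conditionMessage(e), call. = FALSE))
    if (!is.null(cfg$wt_traj)) {
      dccm_wt <- tryCatch(run_structural(cfg$wt_traj, tag = "_wt"),
                          error = function(e) stop("pipeline stage 'dccm_wt' failed: ",
                                                   conditionMessage(e), call. = FALSE))
      delta <- compute_delta_dccm(dccm_mod, dccm_wt)
      p <- file.path(cfg$outdir, "ddccm.csv")
      write_correlation_csv(delta, p); add_output(p)
      feats <- extract_feature_blocks(delta, cutoff = cfg$cutoff)
      .stage_log("features", "%d feature block(s) above |dC| > %g",
                 nrow(feats), cfg$cutoff)
      p <- file.path(cfg$outdir, "features.json")
      jsonlite::write_json(as.data.frame(feats), p, digits = NA, pretty = TRUE)
      add_output(p)
    }
  }

  if (!is.null(cfg$dipole)) {
    series <- read_dipole_csv(cfg$dipole)
    span <- (nrow(series$values) - 1) * series$dt
    acf <- dipole_acf(series, max_lag = cfg$max_lag_frac * span)
    spec <- ir_spectrum(acf, temperature = cfg$temperature,
                        zero_pad = cfg$zero_pad)
    .stage_log("spectrum", "%d bins, resolution %.4g cm^-1",
               nrow(spec), attr(spec, "resolution"))
    p <- file.path(cfg$outdir, "acf.csv")
    write.csv(data.frame(lag_fs = acf$lags, acf = acf$values), p,
              row.names = FALSE); add_output(p)
    p <- file.path(cfg$outdir, "spectrum.csv")
    write_spectrum_csv(spec, p); add_output(p)
    if (!is.null(cfg$band)) {
      peaks <- peak_metrics(spec, cfg$band)
      p <- file.path(cfg$outdir, "peaks.json")
      jsonlite::write_json(peaks, p, auto_unbox = TRUE, digits = NA)
      add_output(p)
    }
  }

  manifest <- list(
    inputs = Filter(Negate(is.null),
                    list(top = cfg$top, traj = cfg$traj,
                         wt_traj = cfg$wt_traj, dipole = cfg$dipole)),
    parameters = unclass(cfg)[setdiff(names(cfg),
                                      c("top", "traj", "wt_traj", "dipole", "outdir"))],
    outputs = as.list(tools::md5sum(outputs))
  )
  names(manifest$outputs) <- basename(outputs)
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
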