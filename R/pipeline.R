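check_keys <- function(x, allowed, what) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop(sprintf("unknown %s key(s): %s", what, paste(bad, collapse = ", ")))
  x
}

#' End-to-end run configuration
#'
#' Bundles every sub-configuration of the virtual scanner with a global seed.
#' Unknown keys in any sub-list are rejected.
#'
#' @param phantom overrides for [make_phantom].
#' @param trace overrides for [trace_params], plus optional `duration_s`.
#' @param protocol overrides for [scan_protocol] (applied on top of the
#'   scenario preset).
#' @param geometry overrides for [scan_geometry].
#' @param predictor overrides for [predictor_config].
#' @param recon list with `grid_shape`, `grid_spacing_mm` and `reg`
#'   (overrides for [reg_config]).
#' @param noise `NULL`, or overrides for [noise_model].
#' @param seed global integer seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = list(), trace = list(), protocol = list(),
                       geometry = list(), predictor = list(),
                       recon = list(), noise = NULL, seed = 1L) {
  check_keys(trace, c(names(formals(trace_params)), "duration_s"), "trace")
  check_keys(protocol, setdiff(names(formals(scan_protocol)), "n_proj"),
             "protocol")
  check_keys(geometry, names(formals(scan_geometry)), "geometry")
  check_keys(predictor, names(formals(predictor_config)), "predictor")
  check_keys(recon, c("grid_shape", "grid_spacing_mm", "reg"), "recon")
  if (!is.null(recon$reg))
    check_keys(recon$reg, names(formals(reg_config)), "recon$reg")
  if (!is.null(noise)) check_keys(noise, names(formals(noise_model)), "noise")
  check_keys(phantom, c("body", "lungs", "tumor", "diaphragm"), "phantom")
  structure(list(phantom = phantom, trace = trace, protocol = protocol,
                 geometry = geometry, predictor = predictor, recon = recon,
                 noise = noise, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  do.call(run_config, y)
}

scenario_protocol <- function(scenario, overrides = list()) {
  base <- switch(scenario,
    conventional = list(n_proj = 1320L, mode = "conventional"),
    STO600 = list(n_proj = 600L, mode = "STO"),
    STO200 = list(n_proj = 200L, mode = "STO"))
  do.call(scan_protocol, modifyList(base, overrides))
}

## displacement at the center of bin j (ground-truth motion law)
bin_displacement <- function(params, j, n_bins) {
  1 - breath_waveform((j - 0.5) / n_bins, params$dwell_power)
}

default_probes <- function(model, u) {
  tc <- model$tumor$center + u * model$tumor$amplitude
  dome_top <- model$diaphragm$center[3] + model$diaphragm$radius +
    u * model$diaphragm$amplitude[3]
  list(
    ## the tumor probe must stay shorter than the tumor diameter so the run
    ## crosses a single edge rather than the whole sphere
    tumor = list(center = c(tc[1], tc[2], tc[3] + model$tumor$radius),
                 direction = c(0, 0, 1), n_along = 13L, n_across = 5L,
                 step_mm = 2, cross_step_mm = 2),
    diaphragm = list(center = c(model$diaphragm$center[1],
                                model$diaphragm$center[2], dome_top),
                     direction = c(0, 0, 1), n_along = 21L, n_across = 5L,
                     step_mm = 2, cross_step_mm = 2)
  )
}

#' Run a full virtual trial arm
#'
#' Generates the breathing trace, runs the (closed-loop or conventional)
#' scan simulation, reconstructs, and computes the schedule and image-quality
#' metrics. Scenarios mirror the clinical study arms: `conventional` (1320 projections
#' over 240 s, phase-resolved FDK reconstruction), `STO600` (600 projections,
#' phase-resolved FDK) and `STO200` (200 projections, motion-compensated
#' adaptive reconstruction; the raw phase-resolved frames are retained too).
#' All artifacts (trace and schedule CSV, projections, volumes, displacement
#' fields, metrics report, run log) are written under `out_dir` when given.
#'
#' @param config a [run_config].
#' @param scenario `"conventional"`, `"STO600"` or `"STO200"`.
#' @param out_dir output directory, or `NULL` to skip writing.
#' @return list with `report` (metrics), `schedule`, `recon` (image4d used
#'   for metrics), and `sim` (the raw simulation output).
#' @export
run_pipeline <- function(config, scenario = c("conventional", "STO600",
                                              "STO200"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  scenario <- match.arg(scenario)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  protocol <- stage("protocol", scenario_protocol(scenario, config$protocol))
  geometry <- stage("geometry", do.call(scan_geometry, config$geometry))
  model <- stage("phantom", make_phantom(config$phantom))
  pcfg <- stage("predictor", do.call(predictor_config, config$predictor))

  tr_args <- config$trace
  duration <- tr_args$duration_s
  tr_args$duration_s <- NULL
  tparams <- stage("trace", do.call(trace_params, tr_args))
  if (is.null(duration)) {
    breaths <- protocol$n_proj / protocol$n_bins
    duration <- if (protocol$mode == "conventional")
      protocol$duration_s + 10 else
        (1.3 * breaths + 10) * tparams$period_s + 30  # slack for missed bins
  }
  trace <- stage("trace",
                 generate_breathing_trace(tparams, duration, config$seed))

  gs <- config$recon$grid_shape %||% 64L
  gsp <- config$recon$grid_spacing_mm %||% 4
  grid <- grid_spec(gs, gsp)
  rcfg <- do.call(reg_config, config$recon$reg %||% list())
  noise <- if (!is.null(config$noise))
    do.call(noise_model, modifyList(config$noise,
                                    list(seed = config$seed + 1L)))

  sim <- stage("scan", simulate_scan(model, trace, protocol, geometry, pcfg,
                                     grid, noise = noise))
  if (sim$aborted)
    stop("[scan] scan aborted (gantry-speed constraint); partial schedule only",
         call. = FALSE)

  nb <- protocol$n_bins
  recon_kind <- if (scenario == "STO200") "adaptive" else "4dfdk"
  rec <- stage("recon", {
    if (recon_kind == "adaptive")
      adaptive_reconstruct(sim$projections, nb, rcfg, grid)
    else list(fdk4d = reconstruct_4dfdk(sim$projections, nb, grid))
  })
  frames <- if (recon_kind == "adaptive") rec$adaptive else rec$fdk4d

  report <- stage("metrics", {
    mae <- if (protocol$mode == "STO")
      schedule_mae(sim$schedule, sim$ideal) else NA_real_
    gaps <- interbin_separation(sim$schedule)
    lung_roi <- roi_sphere(grid, c(-60, 0, 20), 15)
    dia_roi <- roi_sphere(grid, c(60, 0, -80), 10)
    cnr_f <- vapply(frames$frames, cnr, 0, lung_roi, dia_roi)
    tiw_t <- tiw_d <- rep(NA_real_, nb)
    for (j in seq_len(nb)) {
      u <- bin_displacement(tparams, j, nb)
      pr <- default_probes(model, u)
      tiw_t[j] <- tryCatch(as.numeric(tiw(frames$frames[[j]], pr$tumor)),
                           error = function(e) NA_real_)
      tiw_d[j] <- tryCatch(as.numeric(tiw(frames$frames[[j]], pr$diaphragm)),
                           error = function(e) NA_real_)
    }
    list(scenario = scenario, reconstruction = recon_kind,
         n_proj = nrow(sim$schedule),
         scan_time_s = diff(range(sim$schedule$t_s)),
         mae_deg = mae,
         interbin_mean_deg = mean(unlist(gaps)),
         interbin_max_deg = max(unlist(gaps)),
         dose_reduction_percent = dose_reduction(nrow(sim$schedule), 1320),
         cnr = cnr_f, cnr_median = median(cnr_f),
         tiw_t_mm = tiw_t, tiw_t_median_mm = median(tiw_t, na.rm = TRUE),
         tiw_d_mm = tiw_d, tiw_d_median_mm = median(tiw_d, na.rm = TRUE),
         aborted = sim$aborted)
  })

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_trace(trace, file.path(out_dir, "trace.csv"))
      write_schedule(sim$schedule, file.path(out_dir, "schedule.csv"))
      write_projections(sim$projections, file.path(out_dir, "projections"))
      for (j in seq_len(nb))
        write_volume(frames$frames[[j]],
                     file.path(out_dir, sprintf("frame_%02d.nii.gz", j)))
      if (recon_kind == "adaptive") {
        write_volume(rec$fdk, file.path(out_dir, "fdk3d.nii.gz"))
        for (j in seq_len(nb)) {
          V <- rec$dvfs[[j]]
          con <- file(file.path(out_dir, sprintf("dvf_%02d.raw", j)), "wb")
          writeBin(as.numeric(V$disp), con, size = 4, endian = "little")
          close(con)
        }
      }
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      jsonlite::write_json(
        list(scenario = scenario, seed = config$seed,
             package_version = as.character(utils::packageVersion("stocbct")),
             r_version = R.version.string,
             frames = sprintf("frame_%02d.nii.gz", seq_len(nb)),
             n_proj = nrow(sim$schedule)),
        file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA)
    })
  }
  list(report = report, schedule = sim$schedule, recon = frames, sim = sim)
}
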