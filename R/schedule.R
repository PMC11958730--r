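#' Scan protocol
#'
#' Acquisition protocol and hardware constraint set for the virtual scanner.
#' Defaults mirror a clinical linac 4D-CBCT: 200 degree arc, 5.5 Hz projection
#' trigger, 6 deg/s maximum gantry speed, 0.3 deg/s abort threshold and
#' 2 deg/s^2 acceleration limit. In `conventional` mode the gantry sweeps at
#' constant speed for `duration_s` seconds acquiring every trigger; in `STO`
#' mode the controller modulates speed and gates triggers so that projection
#' `k` lands at angle `k * arc/N_p` in respiratory bin `((k-1) mod N_b) + 1`.
#'
#' @param n_proj total projections N_p.
#' @param n_bins respiratory bins N_b (default 10).
#' @param arc_deg gantry arc (degrees, default 200).
#' @param duration_s scan duration for conventional mode (s, default 240).
#' @param trigger_hz projection trigger rate (Hz, default 5.5).
#' @param v_max maximum gantry speed (deg/s, default 6).
#' @param v_abort abort threshold speed (deg/s, default 0.3).
#' @param a_max maximum gantry acceleration (deg/s^2, default 2).
#' @param mode `"STO"` or `"conventional"`.
#' @return list of class `scan_protocol`.
#' @export
scan_protocol <- function(n_proj, n_bins = 10, arc_deg = 200,
                          duration_s = 240, trigger_hz = 5.5,
                          v_max = 6, v_abort = 0.3, a_max = 2,
                          mode = c("STO", "conventional")) {
  mode <- match.arg(mode)
  n_proj <- as.integer(n_proj); n_bins <- as.integer(n_bins)
  if (n_proj < 1L) stop("n_proj must be positive")
  if (arc_deg / n_proj <= 0) stop("angular step must be positive")
  if (v_abort >= v_max) stop("v_abort must be below v_max")
  if (mode == "STO" && n_proj %% n_bins != 0L)
    stop("in STO mode n_proj must be divisible by n_bins")
  structure(list(n_proj = n_proj, n_bins = n_bins, arc_deg = arc_deg,
                 duration_s = duration_s, trigger_hz = trigger_hz,
                 v_max = v_max, v_abort = v_abort, a_max = a_max,
                 mode = mode),
            class = "scan_protocol")
}

new_schedule <- function(k, t_s, angle_deg, bin, acquired, provenance,
                         protocol = NULL, aborted = FALSE) {
  df <- data.frame(k = as.integer(k), t_s = t_s, angle_deg = angle_deg,
                   bin = as.integer(bin), acquired = as.logical(acquired))
  structure(df, class = c("acquisition_schedule", "data.frame"),
            provenance = provenance, protocol = protocol, aborted = aborted)
}

#' Ideal spatiotemporally optimized schedule
#'
#' The target data structure: projection k at angle `k * arc/N_p`, in bin
#' `((k-1) mod N_b) + 1`, so consecutive projections step through the
#' respiratory cycle and projections of the same bin are spread exactly
#' `N_b * arc / N_p` degrees apart. Times are unbound (they depend on the
#' patient's breathing when realized).
#'
#' @param protocol a [scan_protocol] in STO mode.
#' @return An `acquisition_schedule` data frame (columns `k, t_s, angle_deg,
#'   bin, acquired`) with provenance `"ideal"`.
#' @export
ideal_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (protocol$mode != "STO") stop("ideal_schedule requires STO mode")
  k <- seq_len(protocol$n_proj)
  new_schedule(k, t_s = NA_real_,
               angle_deg = k * protocol$arc_deg / protocol$n_proj,
               bin = ((k - 1L) %% protocol$n_bins) + 1L,
               acquired = FALSE, provenance = "ideal", protocol = protocol)
}

#' Conventional evenly spaced schedule
#'
#' Even separation in angle and time with no reference to the patient state:
#' angular step `arc/N_p` and time step `duration/N_p`. Bins are unassigned
#' (NA) until a breathing trace provides the retrospective sorting.
#'
#' @param protocol a [scan_protocol].
#' @return An `acquisition_schedule` with provenance `"conventional"`.
#' @export
conventional_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "scan_protocol"))
  k <- seq_len(protocol$n_proj)
  new_schedule(k, t_s = k * protocol$duration_s / protocol$n_proj,
               angle_deg = k * protocol$arc_deg / protocol$n_proj,
               bin = NA_integer_, acquired = FALSE,
               provenance = "conventional", protocol = protocol)
}

#' One receding-horizon control step
#'
#' Greedy single-projection lookahead replacing a full mixed-integer solve:
#' given the gantry state, the bin predicted for the upcoming trigger, and the
#' estimated acquisition time of the next ideal projection `k*`, command the
#' speed that places the gantry at `S_ideal(k*) = k* arc/N_p` exactly when the
#' projection will be triggered (the absolute-angular-deviation objective),
#' clamped to `[0, v_max]`. The gate opens only when the predicted bin equals
#' the bin the ideal sequence requires next. Acceleration limiting toward the
#' setpoint is enforced by the gantry plant model in the simulator.
#'
#' @param state list with `time` (s), `angle` (deg), `speed` (deg/s).
#' @param predicted_bin bin predicted at the next trigger time (latency
#'   compensated).
#' @param progress index `k*` of the next ideal projection to acquire.
#' @param protocol a [scan_protocol] in STO mode.
#' @param t_acquire estimated time (s) at which projection `k*` will be
#'   triggered; `NA` when the predictor has no confident estimate.
#' @param dt control tick length (s).
#' @return list of class `control_command`: `time`, `speed_setpoint`,
#'   `gate_open`, plus `saturated` (TRUE when the required speed exceeded
#'   `v_max`, an unavoidable schedule-error event).
#' @export
control_step <- function(state, predicted_bin, progress, protocol,
                         t_acquire = NA_real_, dt = 1 / 30) {
  stopifnot(inherits(protocol, "scan_protocol"))
  j_star <- ((progress - 1L) %% protocol$n_bins) + 1L
  s_target <- progress * protocol$arc_deg / protocol$n_proj
  gate <- isTRUE(predicted_bin == j_star)
  if (is.na(t_acquire)) {
    ## no confident entry-time estimate: hold current speed, keep gate shut
    return(structure(list(time = state$time, speed_setpoint = state$speed,
                          gate_open = FALSE, saturated = FALSE),
                     class = "control_command"))
  }
  h <- max(t_acquire - state$time, dt)
  D <- s_target - state$angle
  a <- protocol$a_max
  v <- state$speed
  ## deadbeat setpoint for the rate-limited plant: ramp at a_max toward the
  ## setpoint, then hold; choose the setpoint that lands on the target angle
  ## exactly at the trigger
  if (D > v * h + 1e-12) {
    disc <- (v + a * h)^2 - v^2 - 2 * a * D
    v_req <- if (disc >= 0) (v + a * h) - sqrt(disc) else Inf
  } else if (D < v * h - 1e-12) {
    disc <- (v - a * h)^2 - v^2 + 2 * a * D
    v_req <- if (disc >= 0) (v - a * h) + sqrt(disc) else 0
  } else v_req <- v
  sat <- v_req > protocol$v_max
  ## never command a sustained speed below the abort threshold mid-scan:
  ## crawling (with a small angular overshoot) is preferred to an abort
  v_req <- max(v_req, 1.05 * protocol$v_abort)
  structure(list(time = state$time,
                 speed_setpoint = min(max(v_req, 0), protocol$v_max),
                 gate_open = gate, saturated = sat),
            class = "control_command")
}

#' Check a gantry trajectory against the hardware constraint set
#'
#' Verifies (1) unidirectional rotation, (2) speed within `[0, v_max]`,
#' (3) the sustained-slow abort condition, (4) acceleration within `a_max`,
#' and (5) acquired projection times on the trigger grid. An empty report
#' means the trajectory is compliant.
#'
#' @param trajectory data frame with columns `time`, `angle`, `speed` sampled
#'   at the control tick.
#' @param protocol a [scan_protocol].
#' @param schedule optional realized `acquisition_schedule` whose acquired
#'   times are checked against the `trigger_hz` grid (tolerance 1e-6 s).
#' @param abort_dwell_s dwell (s) below `v_abort` that triggers the abort
#'   condition.
#' @return data frame with columns `type`, `time`, `detail`; zero rows when
#'   compliant.
#' @export
validate_constraints <- function(trajectory, protocol, schedule = NULL,
                                 abort_dwell_s = 5) {
  stopifnot(nrow(trajectory) > 0)
  tol <- 1e-9
  rep_rows <- list()
  add <- function(type, time, detail)
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(type = type, time = time,
                                                     detail = detail)
  dA <- diff(trajectory$angle)
  bad <- which(dA < -1e-9)
  for (i in bad) add("reversal", trajectory$time[i + 1L],
                     sprintf("angle step %.3g deg", dA[i]))
  bad <- which(trajectory$speed > protocol$v_max + 1e-9 |
                 trajectory$speed < -tol)
  for (i in bad) add("speed", trajectory$time[i],
                     sprintf("speed %.3g deg/s", trajectory$speed[i]))
  dt <- diff(trajectory$time)
  acc <- diff(trajectory$speed) / dt
  bad <- which(abs(acc) > protocol$a_max + 1e-6)
  for (i in bad) add("acceleration", trajectory$time[i + 1L],
                     sprintf("acceleration %.3g deg/s^2", acc[i]))
  ## sustained sub-abort speed
  slow <- trajectory$speed < protocol$v_abort
  r <- rle(slow)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    dur <- trajectory$time[ends[i]] - trajectory$time[starts[i]]
    if (dur > abort_dwell_s)
      add("abort", trajectory$time[starts[i]],
          sprintf("speed < %g deg/s for %.1f s", protocol$v_abort, dur))
  }
  if (!is.null(schedule)) {
    tk <- schedule$t_s[schedule$acquired]
    if (length(tk)) {
      grid_err <- abs(tk * protocol$trigger_hz -
                        round(tk * protocol$trigger_hz)) / protocol$trigger_hz
      bad <- which(grid_err > 1e-6)
      for (i in bad) add("trigger_grid", tk[i],
                         sprintf("off trigger grid by %.3g s", grid_err[i]))
    }
  }
  if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(type = character(0), time = numeric(0), detail = character(0))
}

#' Same-phase angular separations of a schedule
#'
#' For each respiratory bin, the sorted consecutive differences between the
#' gantry angles of that bin's projections.
#'
#' @param schedule an `acquisition_schedule`.
#' @return named list (one element per bin) of angular gap vectors (degrees).
#' @export
interbin_separation <- function(schedule) {
  bins <- sort(unique(schedule$bin[!is.na(schedule$bin)]))
  out <- lapply(bins, function(b) {
    a <- sort(schedule$angle_deg[!is.na(schedule$bin) & schedule$bin == b])
    if (length(a) >= 2) diff(a) else numeric(0)
  })
  names(out) <- paste0("bin", bins)
  out
}
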