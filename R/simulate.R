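#' Photon (Poisson) noise model for projections
#'
#' @param i0 incident photons per detector element.
#' @param enabled logical; `FALSE` makes [apply_noise] the identity.
#' @param seed integer seed.
#' @return list of class `noise_model`.
#' @export
noise_model <- function(i0 = 1e4, enabled = TRUE, seed = 1L) {
  if (i0 <= 0) stop("i0 must be positive")
  structure(list(i0 = i0, enabled = enabled, seed = as.integer(seed)),
            class = "noise_model")
}

#' Apply photon counting noise to line integrals
#'
#' Converts line integrals p to expected counts `I0 * exp(-p)`, draws Poisson
#' counts, clamps zero counts to 0.5, and converts back with
#' `-log(counts / I0)`. Seeded and reproducible.
#'
#' @param projections a [projection_set].
#' @param noise a [noise_model].
#' @return the noisy [projection_set].
#' @export
apply_noise <- function(projections, noise = noise_model()) {
  stopifnot(inherits(noise, "noise_model"))
  if (!noise$enabled) return(projections)
  set.seed(noise$seed)
  counts <- rpois(length(projections$stack),
                  noise$i0 * exp(-projections$stack))
  counts[counts == 0] <- 0.5
  out <- projections
  out$stack <- array(-log(counts / noise$i0), dim(projections$stack))
  out
}

## render-and-project with a displacement cache (u quantized to 0.005, i.e.
## 0.075 mm of tumor motion at the default 15 mm amplitude)
project_at_displacements <- function(model, u, angles_deg, geometry, grid) {
  uq <- round(u * 200) / 200
  stack <- array(0, c(geometry$det_cols, geometry$det_rows, length(u)))
  for (uu in unique(uq)) {
    idx <- which(uq == uu)
    vol <- phantom_volume(model, uu, grid)
    ps <- forward_project(vol, geometry, angles_deg[idx])
    stack[, , idx] <- ps$stack
  }
  stack
}

#' Simulate a full scan (closed loop for STO, fixed pace for conventional)
#'
#' The measurement model: runs the acquisition against the breathing phantom
#' with predictor latency, first-order gantry speed dynamics saturated at the
#' acceleration limit, and the fixed projection trigger clock. In STO mode
#' the controller modulates gantry speed and gates triggers using the
#' ellipse predictor (fed strictly causally); in conventional mode every
#' trigger is acquired at constant speed. Acquired projections render the
#' phantom at the trace's ground-truth displacement and record the
#' ground-truth respiratory bin, so prediction errors surface as
#' data-structure (angle placement) errors rather than label errors.
#'
#' @param model a [make_phantom] phantom.
#' @param trace a [generate_breathing_trace] trace (long enough to cover the
#'   scan; an abort is a legal outcome otherwise).
#' @param protocol a [scan_protocol].
#' @param geometry a [scan_geometry].
#' @param predictor_cfg a [predictor_config] (STO mode).
#' @param grid rendering [grid_spec].
#' @param noise optional [noise_model].
#' @param project logical; `FALSE` skips projection rendering (schedule only).
#' @return list with `schedule` (acquisition_schedule), `projections`
#'   ([projection_set] or NULL), `trajectory` (tick-sampled gantry state),
#'   `aborted`, and `ideal` (the matched ideal schedule in STO mode).
#' @export
simulate_scan <- function(model, trace, protocol, geometry,
                          predictor_cfg = predictor_config(),
                          grid = grid_spec(64, 4), noise = NULL,
                          project = TRUE) {
  stopifnot(inherits(protocol, "scan_protocol"))
  if (protocol$mode == "conventional") {
    n <- protocol$n_proj
    k <- seq_len(n)
    tk <- k * protocol$duration_s / n
    if (max(tk) > max(trace$times))
      stop("trace shorter than the conventional scan duration")
    st <- trace_state_at(trace, tk)
    sched <- new_schedule(k, tk, k * protocol$arc_deg / n, st$bin,
                          acquired = TRUE, provenance = "simulated",
                          protocol = protocol)
    v <- protocol$arc_deg / protocol$duration_s
    traj <- data.frame(time = tk, angle = k * protocol$arc_deg / n,
                       speed = v)
    proj <- NULL
    if (project) {
      stack <- project_at_displacements(model, st$u,
                                        k * protocol$arc_deg / n,
                                        geometry, grid)
      proj <- projection_set(stack, k * protocol$arc_deg / n, geometry,
                             times_s = tk, bins = st$bin)
      if (!is.null(noise)) proj <- apply_noise(proj, noise)
    }
    return(list(schedule = sched, projections = proj, trajectory = traj,
                aborted = FALSE, ideal = NULL))
  }

  ## ---- closed-loop STO ----
  np <- protocol$n_proj; nb <- protocol$n_bins
  ideal <- ideal_schedule(protocol)
  f_tr <- protocol$trigger_hz
  dt <- 1 / 30
  pred <- phase_predictor(predictor_cfg)
  t_end <- max(trace$times)
  amp_at <- function(t) approx(trace$times, trace$amplitude, t, rule = 2)$y

  ## causal warm-up: observe until the predictor locks on (>= 3 peak-inhale
  ## crossings), then wait for a bin-1 entry at least `lead` ahead
  lead <- 1.0
  t <- 0; i_samp <- 1L
  locked_at <- NA_real_
  while (t < t_end && is.na(locked_at)) {
    pred$feed(trace$times[i_samp], trace$amplitude[i_samp])
    t <- trace$times[i_samp]; i_samp <- i_samp + 1L
    if (t >= predictor_cfg$window_s &&
        length(pred$state()$crossings) >= 3) locked_at <- t
  }
  if (is.na(locked_at)) stop("trace too short for predictor lock-on")
  epoch <- pred$next_bin_entry(1L, after = locked_at + lead)
  if (!is.finite(epoch)) stop("no confident bin-1 entry estimate")
  scan_t0 <- epoch - lead

  state <- list(time = t, angle = 0, speed = 0)
  k_star <- 1L
  next_tr <- ceiling(scan_t0 * f_tr) / f_tr
  gate_decided <- FALSE; gate_open <- FALSE
  slow_since <- NA_real_
  aborted <- FALSE
  acq_t <- acq_ang <- numeric(0)
  traj_t <- traj_a <- traj_v <- numeric(0)
  binw_guess <- function() {
    Tp <- pred$period()
    if (is.finite(Tp)) Tp / nb else 0.4
  }

  while (k_star <= np && i_samp <= length(trace$times)) {
    ## feed the next surrogate sample (strictly causal)
    pred$feed(trace$times[i_samp], trace$amplitude[i_samp])
    t_next <- trace$times[i_samp]
    i_samp <- i_samp + 1L

    j_star <- ((k_star - 1L) %% nb) + 1L
    ## estimated occupancy window of bin j* (covering the current bin too);
    ## the gate opens a small guard after the predicted entry to protect
    ## against entry-time jitter, and the speed controller targets the exact
    ## trigger at which that gate will first open
    guard <- 0.03
    bw <- binw_guess()
    entry <- pred$next_bin_entry(j_star, after = state$time - bw)
    t_acq <- NA_real_
    if (is.finite(entry)) {
      first_tr <- max(ceiling((entry + guard) * f_tr) / f_tr, next_tr)
      if (first_tr >= entry + bw) {  # window missed: same bin, next breath
        Tp <- pred$period()
        if (is.finite(Tp)) {
          entry <- entry + Tp
          first_tr <- ceiling((entry + guard) * f_tr) / f_tr
        }
      }
      ## among the triggers inside the occupancy window, target the one
      ## whose required mean speed is closest to the current speed (the
      ## relay can block any individual trigger)
      cand <- seq(first_tr, entry + bw - 1e-9, by = 1 / f_tr)
      cand <- cand[cand > state$time]
      if (length(cand)) {
        v_need <- (k_star * protocol$arc_deg / np - state$angle) /
          pmax(cand - state$time, dt)
        ok_v <- v_need <= protocol$v_max & v_need >= 0
        if (any(ok_v)) { cand <- cand[ok_v]; v_need <- v_need[ok_v] }
        t_acq <- cand[which.min(abs(v_need - state$speed))]
      } else t_acq <- first_tr
    }
    if (!gate_decided && next_tr - state$time <= predictor_cfg$tau) {
      in_window <- is.finite(entry) && next_tr >= entry + guard &&
        next_tr < entry + bw
      ## prefer the targeted trigger, but never skip the last chance in the
      ## window (entry-time jitter would otherwise cost a whole breath)
      last_chance <- in_window && next_tr + 1 / f_tr >= entry + bw
      gate_open <- state$time >= scan_t0 && in_window &&
        (last_chance || (is.finite(t_acq) && next_tr >= t_acq - 1e-6))
      gate_decided <- TRUE
    }
    pb_now <- if (gate_decided && gate_open) j_star else NA_integer_
    cmd <- control_step(state, pb_now, k_star, protocol, t_acq, dt)
    setp <- if (state$time < scan_t0) 0 else cmd$speed_setpoint

    ## abort bookkeeping: commanded speed below v_abort for > 5 s mid-scan
    if (state$time >= epoch && k_star <= np) {
      if (setp < protocol$v_abort) {
        if (is.na(slow_since)) slow_since <- state$time
        if (state$time - slow_since > 5) { aborted <- TRUE; break }
      } else slow_since <- NA_real_
    }

    ## integrate plant to t_next, firing any trigger inside the interval
    step_to <- function(tt) {
      h <- tt - state$time
      if (h <= 0) return(invisible())
      dv <- max(min(setp - state$speed, protocol$a_max * h),
                -protocol$a_max * h)
      v_new <- min(max(state$speed + dv, 0), protocol$v_max)
      state$angle <<- state$angle + (state$speed + v_new) / 2 * h
      state$speed <<- v_new
      state$time <<- tt
    }
    while (next_tr <= t_next && k_star <= np) {
      step_to(next_tr)
      if (!gate_decided) {  # latency window shorter than a tick: decide now
        in_window <- is.finite(entry) && next_tr >= entry + guard &&
          next_tr < entry + bw
        last_chance <- in_window && next_tr + 1 / f_tr >= entry + bw
        gate_open <- state$time >= scan_t0 && in_window &&
          (last_chance || (is.finite(t_acq) && next_tr >= t_acq - 1e-6))
      }
      if (gate_open) {
        acq_t <- c(acq_t, next_tr)
        acq_ang <- c(acq_ang, state$angle)
        k_star <- k_star + 1L
      }
      next_tr <- next_tr + 1 / f_tr
      gate_decided <- FALSE; gate_open <- FALSE
    }
    step_to(t_next)
    traj_t <- c(traj_t, state$time)
    traj_a <- c(traj_a, state$angle)
    traj_v <- c(traj_v, state$speed)
  }
  if (k_star <= np && !aborted) aborted <- TRUE  # trace exhausted

  n_acq <- length(acq_t)
  st <- trace_state_at(trace, acq_t)
  sched <- new_schedule(seq_len(n_acq), acq_t, acq_ang, st$bin,
                        acquired = TRUE, provenance = "simulated",
                        protocol = protocol, aborted = aborted)
  traj <- data.frame(time = traj_t, angle = traj_a, speed = traj_v)
  proj <- NULL
  if (project && n_acq > 0) {
    stack <- project_at_displacements(model, st$u, acq_ang, geometry, grid)
    proj <- projection_set(stack, acq_ang, geometry, times_s = acq_t,
                           bins = st$bin)
    if (!is.null(noise)) proj <- apply_noise(proj, noise)
  }
  list(schedule = sched, projections = proj, trajectory = traj,
       aborted = aborted, ideal = ideal)
}
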