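## Event-driven simulation loop: dichotomic time search for the threshold
## crossing of the circle minimum, on-circle minimization, noise injection,
## concomitant initiations, Gamma ramp.

## field mode code for the C++ backend: class-ii fields enter the
## initiation criterion; class-iii does not (it only shifts ages).
field_mode_code <- function(sec) {
  switch(sec$mode, redundant = 1L, synergetic = 2L, 0L)
}

## low-level minimum of the (possibly combined) inhibition on the circle
min_on_circle <- function(t, state, cfg, R_circle, d0) {
  sec <- cfg$secondary
  cpp_min_on_circle(t, state$azimuth, state$birth_time, state$r0_birth,
                    cfg$V0, R_circle, cfg$geom$unroll_factor,
                    d0, cfg$field$steepness_s, kernel_code(cfg$field),
                    field_mode_code(sec), sec$range_d1, sec$delay_tau,
                    sec$weight_beta, cfg$prune_eps,
                    cfg$n_grid, cfg$angle_precision)
}

#' Minimum of the inhibition on the competent circle
#'
#' Locates the global minimizer of the total inhibition over azimuth at time
#' `t`, by a coarse scan over `cfg$n_grid` equispaced azimuths followed by
#' golden-section refinement to `cfg$angle_precision`.  When a class-ii
#' secondary field is configured, the minimized quantity is the combined
#' inhibition (redundant sum or synergetic product).
#'
#' @param t Evaluation time.
#' @param p A [primordia()] set (at least one organ).
#' @param cfg A [simulation_config()].
#' @param R_circle Competent-circle radius (default `cfg$R0_mean`).
#' @return A list with elements `theta` (the minimizing azimuth, radians in
#'   `[0, 2*pi)`) and `E` (the minimum inhibition).
#' @export
min_inhibition_on_circle <- function(t, p, cfg, R_circle = cfg$R0_mean) {
  stopifnot(inherits(p, "primordia"), inherits(cfg, "phyllo_config"))
  if (length(p$azimuth) == 0L)
    stop("degenerate state: seed the simulation with at least one organ")
  min_on_circle(t, p, cfg, R_circle, cfg$field$range_d0)
}

#' Draw the initiation threshold for the next event
#'
#' Gaussian with mean `threshold_mean` and SD `noise_sd_threshold`,
#' truncated below at `0.05 * threshold_mean` by redrawing; used for the
#' next initiation only.
#'
#' @param cfg A [simulation_config()] with `noise_mode = "threshold"`.
#' @return A positive threshold value.
#' @export
draw_threshold <- function(cfg) {
  if (cfg$noise_sd_threshold == 0) return(cfg$threshold_mean)
  repeat {
    x <- rnorm(1L, cfg$threshold_mean, cfg$noise_sd_threshold)
    if (x > 0.05 * cfg$threshold_mean) return(x)
  }
}

#' Draw the competent-circle radius for the next event
#'
#' Gaussian with mean `R0_mean` and SD `noise_sd_radius`, truncated below
#' at `0.1 * R0_mean` by redrawing; sets the circle radius until the next
#' initiation.
#'
#' @param cfg A [simulation_config()] with `noise_mode = "size"`.
#' @return A positive radius.
#' @export
draw_radius <- function(cfg) {
  if (cfg$noise_sd_radius == 0) return(cfg$R0_mean)
  repeat {
    x <- rnorm(1L, cfg$R0_mean, cfg$noise_sd_radius)
    if (x > 0.1 * cfg$R0_mean) return(x)
  }
}

## Solve for the next initiation: earliest t* >= t_cur at which the circle
## minimum falls to `thr`.  Bracket by geometric time-stepping (factor 1.5)
## then bisect to eps_t.  Returns list(t, theta, E).
solve_next_event <- function(state, t_cur, thr, R_circle, d0, cfg, eps_t,
                             plast_est) {
  e0 <- min_on_circle(t_cur, state, cfg, R_circle, d0)
  if (e0$E <= thr) return(list(t = t_cur, theta = e0$theta, E = e0$E))
  dt <- 0.25 * plast_est
  horizon <- 100 * plast_est
  lo <- t_cur
  repeat {
    hi <- lo + dt
    if (hi - t_cur > horizon)
      stop(sprintf(paste0("stalled simulation: circle minimum never reached ",
                          "the threshold %.4g within %g time units"),
                   thr, horizon))
    emin <- min_on_circle(hi, state, cfg, R_circle, d0)
    if (emin$E <= thr) break
    lo <- hi
    dt <- dt * 1.5
  }
  while (hi - lo > eps_t) {
    mid <- 0.5 * (lo + hi)
    if (min_on_circle(mid, state, cfg, R_circle, d0)$E > thr) lo <- mid
    else hi <- mid
  }
  es <- min_on_circle(hi, state, cfg, R_circle, d0)
  list(t = hi, theta = es$theta, E = es$E)
}

## append one organ to a primordia state (in place semantics via return)
state_add <- function(state, azimuth, birth_time, r0_birth, age_shift = 0) {
  state$azimuth <- c(state$azimuth, azimuth %% (2 * pi))
  state$birth_time <- c(state$birth_time, birth_time)
  state$r0_birth <- c(state$r0_birth, r0_birth)
  state$age_shift <- c(state$age_shift, age_shift)
  state
}

## fixture cache (memory always; optional disk via
## options(phyllonoise.fixture_cache = <dir>))
.fixture_cache <- new.env(parent = emptyenv())

fixture_key <- function(cfg, handedness) {
  paste("eq", handedness, cfg$field$kernel_form,
        format(c(cfg$R0_mean, cfg$V0, cfg$threshold_mean,
                 cfg$field$range_d0, cfg$field$steepness_s,
                 cfg$geom$unroll_factor, cfg$angle_precision, cfg$n_grid,
                 cfg$prune_eps, cfg$fixture_keep), digits = 15),
        collapse = "_")
}

#' Deterministic equilibrium state
#'
#' Runs the noise-free model from an asymmetric two-organ seed until the
#' divergence angle is constant to within 0.01 degrees over 20 consecutive
#' events, and returns the converged primordium set, re-timed so that the
#' newest organ was born at `t = 0`.  The default seed yields a spiral of
#' positive divergence ("left" by the package's convention); mirroring the
#' azimuths flips the handedness.  Results are cached in memory (and on disk
#' under `getOption("phyllonoise.fixture_cache")` if set), keyed by the
#' relevant parameters.
#'
#' @param cfg A [simulation_config()]; its noise settings are ignored (the
#'   equilibrium is a property of the deterministic model).
#' @param handedness `"left"` or `"right"` (default `cfg$handedness`).
#' @param max_events Error if no convergence within this many events.
#' @return A [primordia()] set with attributes `mean_plastochron`,
#'   `eq_divergence_deg` (signed, degrees), `n_events_to_converge` and
#'   `handedness`.
#' @export
make_equilibrium_state <- function(cfg, handedness = cfg$handedness,
                                   max_events = 1000L) {
  stopifnot(inherits(cfg, "phyllo_config"))
  key <- fixture_key(cfg, handedness)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  disk <- getOption("phyllonoise.fixture_cache", NULL)
  if (!is.null(disk)) {
    f <- file.path(disk, paste0("phyllonoise_", substr(make.names(key), 1, 120),
                                ".rds"))
    if (file.exists(f)) {
      st <- readRDS(f)
      .fixture_cache[[key]] <- st
      return(st)
    }
  }

  d0 <- if (!is.null(cfg$gamma_schedule))
    gamma_at(0L, cfg$gamma_schedule) * cfg$R0_mean else cfg$field$range_d0
  base <- cfg
  base$secondary <- secondary_field_params("off")  # equilibrium of primary field
  R0 <- cfg$R0_mean
  ## asymmetric two-organ seed: sets the handedness, breaks the distichous
  ## symmetry
  state <- primordia(azimuth = c(0, 150 * pi / 180),
                     birth_time = c(-1, 0), r0_birth = c(R0, R0))
  t_cur <- 0
  az <- state$azimuth
  tv <- state$birth_time
  plast <- 1
  div_deg <- numeric(0)
  converged <- FALSE
  for (i in seq_len(max_events)) {
    eps_t <- 1e-4 * max(plast, 1e-3)
    ev <- solve_next_event(state, t_cur, cfg$threshold_mean, R0, d0, base,
                           eps_t, plast)
    if (ev$t - t_cur > 1e-9) plast <- ev$t - t_cur
    state <- state_add(state, ev$theta, ev$t, R0)
    az <- c(az, ev$theta)
    tv <- c(tv, ev$t)
    div_deg <- c(div_deg, wrap_deg((ev$theta - az[length(az) - 1L]) * 180 / pi))
    t_cur <- ev$t
    if (i >= 21L) {
      last20 <- div_deg[(length(div_deg) - 19L):length(div_deg)]
      if (max(last20) - min(last20) < 0.01) { converged <- TRUE; break }
    }
  }
  if (!converged)
    stop(sprintf(paste0("equilibrium not reached within %d events for ",
                        "R0 = %g, V0 = %g, E* = %g, d0 = %g, s = %g"),
                 max_events, R0, cfg$V0, cfg$threshold_mean, d0,
                 cfg$field$steepness_s))
  n <- length(state$azimuth)
  keep <- seq.int(max(1L, n - cfg$fixture_keep + 1L), n)
  mean_pl <- mean(diff(tv[(length(tv) - 20L):length(tv)]))
  eq_div <- mean(div_deg[(length(div_deg) - 19L):length(div_deg)])
  st <- primordia(azimuth = state$azimuth[keep],
                  birth_time = state$birth_time[keep] - t_cur,
                  r0_birth = state$r0_birth[keep])
  if (handedness == "right") st <- mirror_state(st)
  attr(st, "mean_plastochron") <- mean_pl
  attr(st, "eq_divergence_deg") <- if (handedness == "right") -eq_div else eq_div
  attr(st, "n_events_to_converge") <- i
  attr(st, "handedness") <- handedness
  .fixture_cache[[key]] <- st
  if (!is.null(disk)) {
    dir.create(disk, recursive = TRUE, showWarnings = FALSE)
    saveRDS(st, f)
  }
  st
}

#' Mirror a primordium state
#'
#' Reflects all azimuths (`theta -> -theta`), flipping the handedness of the
#' pattern while leaving all distances unchanged.
#'
#' @param p A [primordia()] set.
#' @return The mirrored [primordia()] set.
#' @export
mirror_state <- function(p) {
  stopifnot(inherits(p, "primordia"))
  p$azimuth <- (-p$azimuth) %% (2 * pi)
  p
}

wrap_deg <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

#' Run the stochastic inhibitory-field simulation
#'
#' Builds (or loads from cache) the deterministic equilibrium fixture, turns
#' on the configured noise, and simulates `n_events` initiations (after
#' `warmup_events` unrecorded ones).  Each event records the time, azimuth,
#' the threshold and circle radius in force, the concomitance group and the
#' class-iii age shift.  Initia whose times differ by less than the time
#' precision form one concomitance group; their recorded order is drawn at
#' random (or, under a class-iii secondary field, by decreasing corrected
#' age with random tie-breaks).  The run is fully seeded: identical
#' configuration and seed reproduce the event stream exactly.
#'
#' @param cfg A [simulation_config()].
#' @param state Optional initial [primordia()] state; default is the
#'   equilibrium fixture for `cfg`.
#' @return An object of class `event_sequence`: a list with `events` (a
#'   data frame with columns `rank`, `time`, `azimuth_rad`, `radius_used`,
#'   `threshold_used`, `concomitance_group`, `age_shift`), `config`,
#'   `time_precision`, `mean_plastochron` (of the deterministic
#'   equilibrium), `eq_divergence_deg`, and `final_state` (the primordium
#'   set at the end of the run).
#' @export
run_simulation <- function(cfg, state = NULL) {
  stopifnot(inherits(cfg, "phyllo_config"))
  if (is.null(state)) {
    state <- make_equilibrium_state(cfg)
    mean_pl <- attr(state, "mean_plastochron")
    eq_div <- attr(state, "eq_divergence_deg")
  } else {
    stopifnot(inherits(state, "primordia"))
    if (is.null(state$age_shift)) state$age_shift <- numeric(length(state$azimuth))
    mean_pl <- attr(state, "mean_plastochron") %||% 1
    eq_div <- attr(state, "eq_divergence_deg") %||% NA_real_
  }
  eps_t <- cfg$time_precision %||% (1e-4 * mean_pl)
  sec <- cfg$secondary
  n_total <- cfg$n_events + cfg$warmup_events

  with_local_seed(cfg$seed, {
    thr <- if (cfg$noise_mode == "threshold") draw_threshold(cfg) else cfg$threshold_mean
    Rcur <- if (cfg$noise_mode == "size") draw_radius(cfg) else cfg$R0_mean
    t_cur <- max(state$birth_time)
    cap <- n_total + 8L
    ev_t <- numeric(cap); ev_th <- numeric(cap); ev_R <- numeric(cap)
    ev_E <- numeric(cap); ev_grp <- integer(cap); ev_da <- numeric(cap)
    n_ev <- 0L
    grp <- 0L
    plast_est <- mean_pl
    while (n_ev < n_total) {
      d0 <- if (!is.null(cfg$gamma_schedule))
        gamma_at(n_ev, cfg$gamma_schedule) * cfg$R0_mean else cfg$field$range_d0
      ev <- solve_next_event(state, t_cur, thr, Rcur, d0, cfg, eps_t,
                             plast_est)
      ## place the first initium of this crossing, then re-scan the circle at
      ## the same solver time for additional minima still below threshold
      ## (one concomitance group, cap 4)
      group_theta <- ev$theta
      group_E <- ev$E
      repeat {
        if (length(group_theta) >= 4L) {
          warning("more than 4 concomitant initia at one solver time; capped")
          break
        }
        st_tmp <- state
        for (j in seq_along(group_theta))
          st_tmp <- state_add(st_tmp, group_theta[j], ev$t, Rcur)
        more <- cpp_minima_below(ev$t, st_tmp$azimuth, st_tmp$birth_time,
                                 st_tmp$r0_birth, cfg$V0, Rcur,
                                 cfg$geom$unroll_factor, d0,
                                 cfg$field$steepness_s, kernel_code(cfg$field),
                                 field_mode_code(sec), sec$range_d1,
                                 sec$delay_tau, sec$weight_beta,
                                 cfg$prune_eps, cfg$n_grid,
                                 cfg$angle_precision, thr,
                                 100 * cfg$angle_precision, group_theta)
        if (length(more$theta) == 0L) break
        group_theta <- c(group_theta, more$theta[1L])
        group_E <- c(group_E, more$E[1L])
      }
      ## class-iii: age shift sensed from the pre-existing primordia
      shifts <- numeric(length(group_theta))
      if (sec$mode == "age_shift") {
        for (j in seq_along(group_theta)) {
          act <- step_field_active(group_theta[j], ev$t, state, sec,
                                   cfg$geom, Rcur, cfg$V0)
          shifts[j] <- if (act) sec$age_shift_delta else 0
        }
      }
      if (n_ev > 0L && ev$t - ev_t[n_ev] >= eps_t) grp <- grp + 1L
      for (j in seq_along(group_theta)) {
        state <- state_add(state, group_theta[j], ev$t, Rcur, shifts[j])
        n_ev <- n_ev + 1L
        ev_t[n_ev] <- ev$t; ev_th[n_ev] <- group_theta[j]
        ev_R[n_ev] <- Rcur; ev_E[n_ev] <- thr
        ev_grp[n_ev] <- grp; ev_da[n_ev] <- shifts[j]
      }
      if (ev$t > t_cur) plast_est <- max(0.2 * mean_pl, ev$t - t_cur)
      t_cur <- ev$t
      ## one noise redraw per accepted initiation event (a multi-initium
      ## group from a single crossing counts as one redraw)
      if (cfg$noise_mode == "threshold") thr <- draw_threshold(cfg)
      if (cfg$noise_mode == "size") Rcur <- draw_radius(cfg)
    }
    len <- n_ev
    ev_t <- ev_t[1:len]; ev_th <- ev_th[1:len]; ev_R <- ev_R[1:len]
    ev_E <- ev_E[1:len]; ev_grp <- ev_grp[1:len]; ev_da <- ev_da[1:len]
    ## recorded order within each concomitance group: decreasing corrected
    ## age, exact ties in random order
    ord <- seq_len(len)
    for (g in unique(ev_grp)) {
      idx <- which(ev_grp == g)
      if (length(idx) > 1L) {
        ## randomize only exact time ties so the stream stays time-sorted
        for (tt in unique(ev_t[idx])) {
          sub <- idx[ev_t[idx] == tt]
          if (length(sub) > 1L)
            ord[sub] <- sub[rank_by_corrected_age(ev_da[sub])]
        }
      }
    }
    ev_t <- ev_t[ord]; ev_th <- ev_th[ord]; ev_R <- ev_R[ord]
    ev_E <- ev_E[ord]; ev_grp <- ev_grp[ord]; ev_da <- ev_da[ord]

    keep <- seq.int(cfg$warmup_events + 1L, len)
    events <- data.frame(
      rank = seq_along(keep) - 1L,
      time = ev_t[keep],
      azimuth_rad = ev_th[keep],
      radius_used = ev_R[keep],
      threshold_used = ev_E[keep],
      concomitance_group = match(ev_grp[keep], unique(ev_grp[keep])) - 1L,
      age_shift = ev_da[keep])
    structure(list(events = events, config = cfg, time_precision = eps_t,
                   mean_plastochron = mean_pl, eq_divergence_deg = eq_div,
                   final_state = state),
              class = "event_sequence")
  })
}

#' @export
print.event_sequence <- function(x, ...) {
  n <- nrow(x$events)
  ng <- length(unique(x$events$concomitance_group))
  cat(sprintf("<event_sequence> %d events, %d concomitance groups\n", n, ng))
  cat(sprintf("  noise = %s (strength %.3g), seed = %d\n",
              x$config$noise_mode, noise_strength(x$config), x$config$seed))
  cat(sprintf("  time span [%.4g, %.4g], mean equilibrium plastochron %.4g\n",
              min(x$events$time), max(x$events$time), x$mean_plastochron))
  invisible(x)
}

#' Mirror an event sequence
#'
#' Reflects every azimuth, producing the sequence of the opposite
#' handedness; divergence angles of the mirrored sequence are the negated
#' originals.
#'
#' @param seq An `event_sequence`.
#' @return The mirrored `event_sequence`.
#' @export
mirror_sequence <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  seq$events$azimuth_rad <- (-seq$events$azimuth_rad) %% (2 * pi)
  if (!is.null(seq$final_state)) seq$final_state <- mirror_state(seq$final_state)
  seq
}
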