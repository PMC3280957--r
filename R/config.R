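## Simulation configuration, Gamma ramp, secondary-field settings, YAML I/O.

#' Time-varying Gamma protocol
#'
#' Imposes a piecewise-linear variation of `Gamma = range_d0 / R0` with the
#' initium rank: `Gamma` interpolates linearly from `gamma_start` at rank 0
#' to `gamma_end` at rank `ramp_steps`, and is constant outside the ramp
#' window.  The ramp rescales the inhibition range `d0` (the circle radius
#' stays fixed) before each initiation.  The reference slow/fast protocols
#' use 350 and 140 initiation events.
#'
#' @param gamma_start,gamma_end Dimensionless `Gamma` endpoints.
#' @param ramp_steps Number of initiation events over which `Gamma` varies.
#' @return An object of class `gamma_ramp`.
#' @export
gamma_ramp <- function(gamma_start, gamma_end, ramp_steps) {
  stopifnot(gamma_start > 0, gamma_end > 0, ramp_steps >= 1)
  structure(list(gamma_start = gamma_start, gamma_end = gamma_end,
                 ramp_steps = as.integer(ramp_steps)), class = "gamma_ramp")
}

#' Gamma value at a given initium rank
#'
#' @param event_rank Integer rank (0-based) of the next initium.
#' @param ramp A [gamma_ramp()].
#' @return The dimensionless `Gamma` to use for that initiation.
#' @export
gamma_at <- function(event_rank, ramp) {
  stopifnot(inherits(ramp, "gamma_ramp"))
  f <- pmin(pmax(event_rank / ramp$ramp_steps, 0), 1)
  ramp$gamma_start + f * (ramp$gamma_end - ramp$gamma_start)
}

#' Secondary-field settings
#'
#' Two classes of secondary fields can be layered on top of the primary
#' inhibitory field.  Class (ii) acts *during* initiation: primordia older
#' than `delay_tau` are sources of a second inhibition of range `range_d1`
#' (same power-law form and steepness as the primary field), and initiation
#' compares either the redundant sum `E1 + beta*E2` (`mode = "redundant"`)
#' or the synergetic product `E1*E2` (`mode = "synergetic"`) to the
#' threshold.  Class (iii) (`mode = "age_shift"`) acts *after* initiation:
#' primordia older than `delay_tau` are step-like sources (active strictly
#' within `range_d1`, nothing at or beyond), and a new initium sensing the
#' field has its physiological age shifted once, permanently, by
#' `age_shift_delta` (negative = made "younger"); concomitant initia are
#' then ranked by corrected age.
#'
#' @param mode One of `"off"`, `"redundant"`, `"synergetic"`, `"age_shift"`.
#' @param range_d1 Range of the secondary field (length units; report it
#'   relative to the primary range `d0` when comparing runs).
#' @param delay_tau Delay after initiation before an organ becomes a
#'   secondary source (time units, same order as the plastochron).
#' @param weight_beta Weight of the second field (redundant mode only).
#' @param age_shift_delta Age increment applied to overlapped initia
#'   (class iii; may be negative).
#' @return An object of class `secondary_field_params`.
#' @export
secondary_field_params <- function(mode = c("off", "redundant", "synergetic",
                                            "age_shift"),
                                   range_d1 = 3.3, delay_tau = 2,
                                   weight_beta = 1, age_shift_delta = 0) {
  mode <- match.arg(mode)
  if (mode != "off") stopifnot(range_d1 > 0, delay_tau >= 0)
  structure(list(mode = mode, range_d1 = range_d1, delay_tau = delay_tau,
                 weight_beta = weight_beta,
                 age_shift_delta = age_shift_delta),
            class = "secondary_field_params")
}

#' Full simulation configuration
#'
#' Collects every parameter of the stochastic inhibitory-field model.  The
#' defaults are the typical values of the reference parameter set: competent
#' circle of radius 2 (arbitrary units), radial velocity 1, initiation
#' threshold 1, inhibition range 3 and steepness 2, i.e. `Gamma = 1.5`,
#' which yields a 3-5 parastichy spiral.
#'
#' Noise modes redraw, following each initiation, either the threshold
#' (Gaussian, mean `threshold_mean`, SD `noise_sd_threshold`, redrawn if
#' below `0.05 * threshold_mean`) or the competent-circle radius (Gaussian,
#' mean `R0_mean`, SD `noise_sd_radius`, redrawn if below `0.1 * R0_mean`).
#' Noise strengths are reported as the dimensionless ratios
#' `noise_sd_threshold / threshold_mean` and `noise_sd_radius / R0_mean`.
#'
#' @param R0_mean Mean competent-circle radius.
#' @param V0 Radial velocity of primordia.
#' @param threshold_mean Mean initiation threshold `E*`.
#' @param field [field_params()] of the primary inhibitory field.
#' @param geom [cone_geometry()].
#' @param noise_mode `"none"`, `"threshold"` or `"size"`.
#' @param noise_sd_threshold SD of the threshold noise (inhibition units).
#' @param noise_sd_radius SD of the size noise (length units).
#' @param time_precision Solver precision on event times; `NULL` (default)
#'   resolves to `1e-4` times the equilibrium mean plastochron.
#' @param angle_precision Solver precision on azimuths, radians.
#' @param seed Integer RNG seed; identical config + seed replay bit-for-bit.
#' @param n_events Number of initiation events to record.
#' @param warmup_events Events simulated (with noise on) but not recorded.
#' @param gamma_schedule Optional [gamma_ramp()].
#' @param secondary Optional [secondary_field_params()].
#' @param handedness Handedness of the equilibrium starting state,
#'   `"left"` (default) or `"right"`; the sign convention for divergence
#'   angles is positive = the handedness of the fixture.
#' @param n_grid Number of azimuths in the coarse circle scan (must be fine
#'   enough to isolate every basin of the inhibition profile).
#' @param prune_eps Per-source pruning floor for field sums.
#' @param fixture_keep Number of most recent equilibrium organs retained as
#'   the initial state (older organs contribute a nearly uniform background).
#' @return An object of class `phyllo_config`.
#' @export
simulation_config <- function(R0_mean = 2, V0 = 1, threshold_mean = 1,
                              field = field_params(),
                              geom = cone_geometry(),
                              noise_mode = c("none", "threshold", "size"),
                              noise_sd_threshold = 0, noise_sd_radius = 0,
                              time_precision = NULL, angle_precision = 1e-4,
                              seed = 1L, n_events = 100L, warmup_events = 0L,
                              gamma_schedule = NULL, secondary = NULL,
                              handedness = c("left", "right"),
                              n_grid = 360L, prune_eps = 1e-9,
                              fixture_keep = 250L) {
  noise_mode <- match.arg(noise_mode)
  handedness <- match.arg(handedness)
  stopifnot(R0_mean > 0, V0 > 0, threshold_mean > 0,
            inherits(field, "field_params"), inherits(geom, "cone_geometry"),
            noise_sd_threshold >= 0, noise_sd_radius >= 0,
            angle_precision > 0, n_events >= 1, warmup_events >= 0,
            n_grid >= 16)
  if (!is.null(gamma_schedule)) stopifnot(inherits(gamma_schedule, "gamma_ramp"))
  if (!is.null(secondary))
    stopifnot(inherits(secondary, "secondary_field_params"))
  cfg <- structure(list(
    R0_mean = R0_mean, V0 = V0, threshold_mean = threshold_mean,
    field = field, geom = geom, noise_mode = noise_mode,
    noise_sd_threshold = noise_sd_threshold,
    noise_sd_radius = noise_sd_radius,
    time_precision = time_precision, angle_precision = angle_precision,
    seed = as.integer(seed), n_events = as.integer(n_events),
    warmup_events = as.integer(warmup_events),
    gamma_schedule = gamma_schedule,
    secondary = secondary %||% secondary_field_params("off"),
    handedness = handedness, n_grid = as.integer(n_grid),
    prune_eps = prune_eps, fixture_keep = as.integer(fixture_keep)),
    class = "phyllo_config")
  if (gamma_of(cfg) <= 1)
    warning("Gamma = range_d0 / R0_mean <= 1: outside the spiral regimes")
  cfg
}

#' Ratio of inhibition range to competent-circle radius
#'
#' `Gamma = range_d0 / R0_mean`, the main control parameter of the
#' phyllotactic mode.
#'
#' @param cfg A [simulation_config()].
#' @return Dimensionless `Gamma`.
#' @export
gamma_of <- function(cfg) {
  stopifnot(inherits(cfg, "phyllo_config"))
  cfg$field$range_d0 / cfg$R0_mean
}

#' Dimensionless noise strength of a configuration
#'
#' @param cfg A [simulation_config()].
#' @return `noise_sd_threshold / threshold_mean` for threshold noise,
#'   `noise_sd_radius / R0_mean` for size noise, 0 otherwise.
#' @export
noise_strength <- function(cfg) {
  stopifnot(inherits(cfg, "phyllo_config"))
  switch(cfg$noise_mode,
         threshold = cfg$noise_sd_threshold / cfg$threshold_mean,
         size = cfg$noise_sd_radius / cfg$R0_mean,
         0)
}

#' @export
print.phyllo_config <- function(x, ...) {
  cat("<phyllo_config>\n")
  cat(sprintf("  R0 = %g, V0 = %g, E* = %g, d0 = %g, s = %g (Gamma = %g)\n",
              x$R0_mean, x$V0, x$threshold_mean, x$field$range_d0,
              x$field$steepness_s, gamma_of(x)))
  cat(sprintf("  cone unroll = %g; noise = %s (strength %.3g)\n",
              x$geom$unroll_factor, x$noise_mode, noise_strength(x)))
  cat(sprintf("  events = %d (+%d warmup), seed = %d, handedness = %s\n",
              x$n_events, x$warmup_events, x$seed, x$handedness))
  if (!is.null(x$gamma_schedule))
    cat(sprintf("  Gamma ramp: %g -> %g over %d events\n",
                x$gamma_schedule$gamma_start, x$gamma_schedule$gamma_end,
                x$gamma_schedule$ramp_steps))
  if (x$secondary$mode != "off")
    cat(sprintf("  secondary field: %s (d1 = %g, tau = %g, beta = %g, da = %g)\n",
                x$secondary$mode, x$secondary$range_d1, x$secondary$delay_tau,
                x$secondary$weight_beta, x$secondary$age_shift_delta))
  invisible(x)
}

## ---- configuration file I/O (YAML, flat keys in sections) ----------------

#' Serialize a configuration to YAML
#'
#' The file has flat key-value sections `model:`, `noise:`, `solver:`,
#' `run:`, plus optional `gamma_ramp:` and `secondary:` blocks.  The
#' `secondary:` block uses the relative keys `d1_rel` (`d1/d0`), `tau`,
#' `beta` and `delta_a` (absolute time units).
#'
#' @param cfg A [simulation_config()].
#' @param path File path; if `NULL`, the YAML text is returned.
#' @return `path` invisibly, or the YAML string.
#' @export
write_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "phyllo_config"))
  lst <- list(
    model = list(R0_mean = cfg$R0_mean, V0 = cfg$V0,
                 threshold_mean = cfg$threshold_mean,
                 range_d0 = cfg$field$range_d0,
                 steepness_s = cfg$field$steepness_s,
                 kernel_form = cfg$field$kernel_form,
                 unroll_factor = cfg$geom$unroll_factor),
    noise = list(mode = cfg$noise_mode,
                 sd_threshold = cfg$noise_sd_threshold,
                 sd_radius = cfg$noise_sd_radius),
    solver = list(time_precision = cfg$time_precision,
                  angle_precision = cfg$angle_precision,
                  n_grid = cfg$n_grid, prune_eps = cfg$prune_eps,
                  fixture_keep = cfg$fixture_keep),
    run = list(seed = cfg$seed, n_events = cfg$n_events,
               warmup_events = cfg$warmup_events,
               handedness = cfg$handedness))
  if (!is.null(cfg$gamma_schedule))
    lst$gamma_ramp <- unclass(cfg$gamma_schedule)
  if (cfg$secondary$mode != "off")
    lst$secondary <- list(mode = cfg$secondary$mode,
                          d1_rel = cfg$secondary$range_d1 / cfg$field$range_d0,
                          tau = cfg$secondary$delay_tau,
                          beta = cfg$secondary$weight_beta,
                          delta_a = cfg$secondary$age_shift_delta)
  txt <- yaml::as.yaml(lst)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Inverse of [write_config()]: `read_config(write_config(cfg))` restores an
#' identical configuration.
#'
#' @param path File path, or a YAML string.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  lst <- if (file.exists(path)) yaml::read_yaml(path)
         else yaml::yaml.load(path)
  m <- lst$model; no <- lst$noise; so <- lst$solver; ru <- lst$run
  sec <- NULL
  if (!is.null(lst$secondary))
    sec <- secondary_field_params(
      mode = lst$secondary$mode,
      range_d1 = lst$secondary$d1_rel * m$range_d0,
      delay_tau = lst$secondary$tau,
      weight_beta = lst$secondary$beta %||% 1,
      age_shift_delta = lst$secondary$delta_a %||% 0)
  ramp <- NULL
  if (!is.null(lst$gamma_ramp))
    ramp <- gamma_ramp(lst$gamma_ramp$gamma_start, lst$gamma_ramp$gamma_end,
                       lst$gamma_ramp$ramp_steps)
  simulation_config(
    R0_mean = m$R0_mean, V0 = m$V0, threshold_mean = m$threshold_mean,
    field = field_params(m$range_d0, m$steepness_s,
                         m$kernel_form %||% "exponential"),
    geom = cone_geometry(m$unroll_factor),
    noise_mode = no$mode, noise_sd_threshold = no$sd_threshold,
    noise_sd_radius = no$sd_radius,
    time_precision = so$time_precision,
    angle_precision = so$angle_precision,
    seed = ru$seed, n_events = ru$n_events,
    warmup_events = ru$warmup_events,
    gamma_schedule = ramp, secondary = sec,
    handedness = ru$handedness, n_grid = so$n_grid,
    prune_eps = so$prune_eps, fixture_keep = so$fixture_keep)
}
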