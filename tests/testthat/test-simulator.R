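cfg0 <- simulation_config()

test_that("circle minimization finds the symmetry point and the global min", {
  ## a single primordium just outside the circle: the minimum is opposite
  p1 <- primordia(0, 0, 2.5)
  m <- min_inhibition_on_circle(0, p1, cfg0)
  expect_equal(m$theta, pi, tolerance = 1e-3)
  ## two opposite primordia of equal age: two equal minima at +/- pi/2
  p2 <- primordia(c(0, pi), c(0, 0), c(2.5, 2.5))
  m2 <- min_inhibition_on_circle(0, p2, cfg0)
  expect_true(min(abs(m2$theta - c(pi / 2, 3 * pi / 2))) < 1e-3)
  E_q <- total_inhibition(c(pi / 2, 3 * pi / 2), 0, p2, cfg0$field, cfg0$geom, 2)
  expect_equal(E_q[1], E_q[2], tolerance = 1e-9)
  ## multi-organ spiral state: matches a dense-grid brute-force scan
  st <- recent_state(make_equilibrium_state(cfg0), 25)
  grid <- seq(0, 2 * pi, length.out = 1e5 + 1)[-(1e5 + 1)]
  E <- bf_total_inhibition(grid, 0.5, st, 3, 2, "exponential", 0.95, 2, 1)
  m3 <- min_inhibition_on_circle(0.5, st, cfg0)
  dth <- abs(m3$theta - grid[which.min(E)])
  expect_lt(min(dth, 2 * pi - dth), max(cfg0$angle_precision, 2 * pi / 1e5) * 2)
  expect_equal(m3$E, min(E), tolerance = 1e-9)
  expect_error(min_inhibition_on_circle(0, primordia(numeric(0), numeric(0),
                                                     numeric(0)), cfg0),
               "degenerate")
})

test_that("noise draws follow the stated truncated Gaussians", {
  ## degenerate limits
  expect_identical(draw_threshold(cfg0), 1)
  expect_identical(draw_radius(cfg0), 2)
  set.seed(99)
  cfgT <- simulation_config(noise_mode = "threshold", noise_sd_threshold = 0.3)
  x <- replicate(1e5, draw_threshold(cfgT))
  expect_lt(abs(mean(x) - 1), 0.01)
  expect_lt(abs(sd(x) - 0.3) / 0.3, 0.03)
  expect_true(all(x > 0.05))
  ## strongly noisy draws stay strictly positive (truncation by redraw)
  cfgW <- simulation_config(noise_mode = "threshold", noise_sd_threshold = 3)
  expect_true(all(replicate(2000, draw_threshold(cfgW)) > 0))
  ## size noise at 16% strength: empirical strength within 0.5 points
  cfgR <- simulation_config(noise_mode = "size", noise_sd_radius = 0.16 * 2)
  r <- replicate(1e5, draw_radius(cfgR))
  expect_lt(abs(sd(r) / 2 - 0.16), 0.005)
  expect_true(all(r > 0.2))
})

test_that("the Gamma ramp is piecewise linear in event rank", {
  ramp <- gamma_ramp(2, 1.2, 140)
  expect_equal(gamma_at(0, ramp), 2)
  expect_equal(gamma_at(140, ramp), 1.2)
  expect_equal(gamma_at(500, ramp), 1.2)
  expect_equal(gamma_at(70, ramp), 1.6)
})

test_that("the deterministic equilibrium converges and sets handedness", {
  st <- make_equilibrium_state(cfg0)
  ## regression snapshot of the reference equilibrium
  expect_equal(attr(st, "mean_plastochron"), 1.3063, tolerance = 1e-3)
  expect_equal(attr(st, "eq_divergence_deg"), 139.74, tolerance = 1e-3)
  ## continuing the run, the divergence angle stays constant to < 0.01 deg
  r <- run_simulation(simulation_config(n_events = 21))
  ang <- divergence_angles(r)$angles_deg
  expect_lt(max(abs(diff(ang))), 0.01)
  ## mirrored fixture: angles equal in magnitude, opposite in sign
  rl <- run_simulation(simulation_config(n_events = 30, handedness = "left"))
  rr <- run_simulation(simulation_config(n_events = 30, handedness = "right"))
  expect_equal(divergence_angles(rr)$angles_deg,
               -divergence_angles(rl)$angles_deg, tolerance = 1e-6)
  ## the equilibrium is insensitive to the two-organ seed azimuths
  plast <- sapply(c(120, 150, 170), function(off) {
    st0 <- primordia(c(0, off * pi / 180), c(-1, 0), c(2, 2))
    r <- run_simulation(simulation_config(n_events = 150), state = st0)
    mean(tail(plastochrons(r), 30))
  })
  expect_lt(max(plast) - min(plast), 1e-3 * mean(plast))
})

test_that("runs are replayable and the zero-noise limit is deterministic", {
  cfg <- simulation_config(n_events = 60, seed = 5)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$events, r2$events)
  ## sd = 0 noise modes reproduce the deterministic model exactly
  cfgT0 <- simulation_config(n_events = 60, seed = 5,
                             noise_mode = "threshold", noise_sd_threshold = 0)
  expect_equal(run_simulation(cfgT0)$events$time, r1$events$time,
               tolerance = 1e-12)
  ## steady state: successive plastochrons constant within 2 * eps_t
  pl <- plastochrons(r1)
  expect_lt(max(abs(diff(pl))), 2 * r1$time_precision)
  ## different seeds with noise give different streams
  cfgA <- simulation_config(n_events = 60, seed = 1, noise_mode = "threshold",
                            noise_sd_threshold = 0.3)
  cfgB <- simulation_config(n_events = 60, seed = 2, noise_mode = "threshold",
                            noise_sd_threshold = 0.3)
  expect_false(identical(run_simulation(cfgA)$events,
                         run_simulation(cfgB)$events))
})

test_that("the dichotomic solver matches the brute-force grid solver", {
  ## 30 deterministic events from the equilibrium state, at coarsened
  ## precisions so the uniform-grid oracle is tractable; agreement within
  ## 2 * eps_t in time and twice the azimuth resolution in angle
  st <- make_equilibrium_state(cfg0)
  T <- attr(st, "mean_plastochron")
  eps_t <- 0.04 * T
  n_grid_bf <- 720
  cfg <- simulation_config(n_events = 30, time_precision = eps_t,
                           angle_precision = 1e-3)
  r <- run_simulation(cfg, state = st)
  p <- st
  t_cur <- 0
  for (i in seq_len(30)) {
    ev <- bf_next_event(p, t_cur, 1, 3, 2, "exponential", 0.95, 2, 1,
                        eps_t, n_grid = n_grid_bf)
    expect_lt(abs(ev$t - r$events$time[i]), 2 * eps_t)
    dth <- abs(ev$theta - r$events$azimuth_rad[i])
    expect_lt(min(dth, 2 * pi - dth), 2 * (2 * pi / n_grid_bf))
    p <- primordia(c(p$azimuth, r$events$azimuth_rad[i]),
                   c(p$birth_time, r$events$time[i]),
                   c(p$r0_birth, 2))
    t_cur <- r$events$time[i]
  }
})

test_that("halving the solver precisions leaves divergence angles unchanged", {
  cfg1 <- simulation_config(n_events = 100)
  T <- attr(make_equilibrium_state(cfg1), "mean_plastochron")
  cfg1$time_precision <- 1e-4 * T
  cfg2 <- simulation_config(n_events = 100, time_precision = 0.5e-4 * T,
                            angle_precision = 0.5e-4)
  a1 <- divergence_angles(run_simulation(cfg1))$angles_deg
  a2 <- divergence_angles(run_simulation(cfg2))$angles_deg
  expect_lt(max(abs(a1 - a2)), 0.1)
})

test_that("concomitant initiations appear under strong threshold noise", {
  cfg <- simulation_config(noise_mode = "threshold", noise_sd_threshold = 0.35,
                           n_events = 400, seed = 3)
  r <- run_simulation(cfg)
  cc <- detect_concomitant(r)
  expect_gt(cc$n_groups_ge2, 0)
  ## group members share a solver time and the group id
  ev <- r$events
  for (g in unique(ev$concomitance_group)) {
    idx <- which(ev$concomitance_group == g)
    if (length(idx) > 1)
      expect_lt(max(ev$time[idx]) - min(ev$time[idx]), r$time_precision)
  }
})
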