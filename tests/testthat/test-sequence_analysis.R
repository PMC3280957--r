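phi_g <- golden_angle()

test_that("divergence angles are wrapped consecutive azimuth differences", {
  s <- fake_sequence(c(0, 137.5, 275))
  expect_equal(divergence_angles(s)$angles_deg, c(137.5, 137.5))
  expect_equal(divergence_angles(fake_sequence(c(0, 200)))$angles_deg, -160)
  ## mirroring negates every angle
  set.seed(3)
  az <- cumsum(runif(30, -180, 180))
  s <- fake_sequence(az)
  m <- s
  m$events$azimuth_rad <- (-m$events$azimuth_rad) %% (2 * pi)
  expect_equal(divergence_angles(m)$angles_deg,
               wrap180(-divergence_angles(s)$angles_deg))
  expect_error(divergence_angles(fake_sequence(10)), "at least 2")
})

test_that("plastochrons telescope and vanish within concomitance groups", {
  s <- fake_sequence(c(0, 10, 20, 30), times = c(0, 1, 1, 2))
  expect_equal(plastochrons(s), c(1, 0, 1))
  expect_equal(sum(plastochrons(s)), max(s$events$time) - min(s$events$time))
})

test_that("concomitance grouping is transitive under the time precision", {
  eps <- 1e-3
  s <- fake_sequence(1:5 * 10, times = c(0, 1, 2, 3, 4), eps_t = eps)
  cc <- detect_concomitant(s)
  expect_equal(cc$n_groups_ge2, 0L)
  expect_equal(cc$proportion, 0)
  s2 <- fake_sequence(1:4 * 10, times = c(0, 1, 1, 2), eps_t = eps)
  cc2 <- detect_concomitant(s2)
  expect_equal(cc2$n_groups_ge2, 1L)
  expect_equal(sort(table(cc2$group), decreasing = TRUE)[[1]], 2L)
  ## chaining: gaps eps/2 each, total above eps, still one group of 3
  s3 <- fake_sequence(1:4 * 10, times = c(0, 5, 5 + eps / 2, 5 + eps),
                      eps_t = eps)
  cc3 <- detect_concomitant(s3)
  expect_equal(max(cc3$group_sizes), 3L)
})

test_that("the M-shape detector is exact on permuted golden sequences", {
  ## ideal sequence: no flags
  az <- make_golden_azimuths(40)
  ideal <- wrap180(diff(az))
  expect_equal(detect_m_shapes(ideal)$n, 0L)
  ## the canonical single-transposition example
  ex <- c(137.5, 137.5, -85.0, -137.5, -85.0, 137.5)
  det <- detect_m_shapes(ex, phi_hat = 137.5)
  expect_equal(det$triple_starts, 3L)
  expect_equal(det$n, 1L)
  expect_equal(which(det$flags), 3:5)
  ## a transposition of organs k, k+1 creates exactly one M-triple at k-1
  for (k in c(3, 10, 25)) {
    ang <- wrap180(diff(transpose_organs(az, k)))
    det <- detect_m_shapes(ang)
    expect_equal(det$triple_starts, k - 1L)
  }
  ## property: k non-overlapping transpositions yield exactly k triples
  set.seed(11)
  for (rep in 1:20) {
    n <- 80
    az2 <- make_golden_azimuths(n)
    pos <- sort(sample(seq(3, n - 3, by = 4), sample(1:5, 1)))
    for (k in pos) az2 <- transpose_organs(az2, k)
    det <- detect_m_shapes(wrap180(diff(az2)))
    expect_equal(det$triple_starts, pos - 1L)
    ## swap-back equivalence: undoing the permutations restores regularity
    az3 <- az2
    for (k in pos) az3 <- transpose_organs(az3, k)
    expect_true(all(abs(wrap180(diff(az3)) - phi_g) < 1e-9))
  }
})

test_that("distichous flags use a closed band below 180 degrees", {
  expect_true(detect_distichous(179))
  expect_true(detect_distichous(160.0))
  expect_true(detect_distichous(-170))
  expect_false(detect_distichous(137.5))
  expect_false(detect_distichous(159.99))
})

test_that("reversal segments are long opposite-handedness runs", {
  phi <- 138
  r1 <- detect_reversals(c(phi, phi, phi, -phi, -phi, -phi), phi_hat = phi)
  expect_equal(r1$n_switches, 1L)
  expect_equal(which(r1$flags), 4:6)
  expect_equal(detect_reversals(rep(phi, 8), phi_hat = phi)$n_switches, 0L)
  ## a single opposite angle is below min_run: not a reversal
  r2 <- detect_reversals(c(phi, phi, phi, -phi, phi, phi, phi),
                         phi_hat = phi)
  expect_equal(r2$n_switches, 0L)
  expect_false(any(r2$flags))
  ## masked angles (e.g. M members) cannot join runs
  r3 <- detect_reversals(c(phi, -phi, -phi, -phi, phi), phi_hat = phi,
                         mask = c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(r3$n_switches, 0L)
})

test_that("angle dispersion is the normalized SD of the symmetrised set", {
  expect_equal(angle_dispersion(rep(137.5, 10), m_flags = rep(FALSE, 10)), 0)
  expect_equal(angle_dispersion(c(140, -140), m_flags = c(FALSE, FALSE)), 0)
  x <- c(130, 140, 150, -135, 137, -142)
  got <- angle_dispersion(x, m_flags = rep(FALSE, 6))
  want <- sd(abs(x)) / mean(abs(x))
  expect_equal(got, want, tolerance = 1e-12)
  ## M-flagged angles are excluded before symmetrisation
  y <- c(137, 137, -85, -137, -85, 137, 137)
  fl <- detect_m_shapes(y, phi_hat = 137)$flags
  expect_equal(angle_dispersion(y, fl),
               sd(abs(y[!fl])) / mean(abs(y[!fl])), tolerance = 1e-12)
  expect_error(angle_dispersion(c(1, 2), m_flags = c(TRUE, TRUE)), "undefined")
})

test_that("contact parastichies are read off synthetic lattices", {
  ## self-similar golden-angle lattice: the exhaustive audit finds contact
  ## offsets {3, 5}, and the estimator agrees
  lat <- make_lattice(40, 137.507764, growth_q = 1.15)
  aud <- audit_contact_offsets(lat, at_time = max(lat$birth_time))
  expect_setequal(as.integer(names(aud)[1:2]), c(3L, 5L))
  expect_equal(estimate_parastichies(lat, n_recent = 40L,
                                     geom = cone_geometry(0.95)), c(3L, 5L))
  ## alternating distichous lattice on a narrow cone: successive organs
  ## dominate the audited contacts, and the estimator matches the audit
  dis <- make_lattice(20, 180, growth_q = 1.3, r0 = 5)
  aud_d <- audit_contact_offsets(dis, at_time = max(dis$birth_time),
                                 unroll = 0.05)
  expect_equal(as.integer(names(aud_d)[1]), 1L)
  est_d <- estimate_parastichies(dis, n_recent = 20L,
                                 geom = cone_geometry(0.05))
  expect_equal(est_d, sort(as.integer(names(aud_d)[1:2])))
  expect_error(estimate_parastichies(make_lattice(10, 137.5, 1.15)),
               "too few")
})

test_that("defect summaries pool events with event weighting", {
  ## zero-noise run: no defects of any class
  r0 <- run_simulation(simulation_config(n_events = 60))
  s0 <- defect_summary(list(r0), 0)
  expect_equal(s0$prop_concomitant, 0)
  expect_equal(s0$prop_m_shape, 0)
  expect_equal(s0$prop_distichous, 0)
  expect_equal(s0$prop_reversal, 0)
  ## pooling two identical runs leaves every proportion unchanged
  s2 <- defect_summary(list(r0, r0), c(0, 0))
  cols <- c("prop_concomitant", "prop_m_shape", "prop_distichous",
            "prop_reversal", "m_per_event")
  expect_equal(s2[, cols], s0[, cols], tolerance = 1e-12)
  expect_equal(s2$n_events, 2 * s0$n_events)
  ## hand-built fixture with known counts
  phi <- 139
  m1 <- wrap180(2 * phi)
  ang <- c(rep(phi, 8), m1, -phi, m1, rep(phi, 4), 170, phi, -175, phi, phi)
  az <- cumsum(c(0, ang))
  times <- cumsum(c(0, rep(1, 20)))
  times[4] <- times[3]                      # one concomitant pair
  fx <- fake_sequence(az, times = times, eps_t = 1e-4)
  s <- defect_summary(list(fx), 1)
  expect_equal(s$prop_concomitant, 2 / 21)
  expect_equal(s$prop_m_shape, 3 / 20)
  expect_equal(s$prop_distichous, 2 / 20)
  expect_equal(s$prop_reversal, 0)
  expect_equal(s$m_per_event, 1 / 21)
})
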