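## Independent reference implementations used as oracles.  These
## deliberately share no code with the package internals: distances are
## computed with their own trigonometry, field sums with plain R loops, and
## the brute-force event solver steps time on a uniform grid.

## planar/unrolled-cone distance written from the law of cosines
bf_cone_distance <- function(ra, ta, rb, tb, unroll = 1) {
  dth <- abs(ta - tb) %% (2 * pi)
  dth <- pmin(dth, 2 * pi - dth)
  al <- unroll * dth
  ifelse(al >= pi, ra + rb,
         sqrt(pmax(ra^2 + rb^2 - 2 * ra * rb * cos(al), 0)))
}

## element-by-element field sum at probe azimuths `theta` on a circle
bf_total_inhibition <- function(theta, t, p, d0, s, form = "exponential",
                                unroll = 0.95, Rc = 2, V0 = 1) {
  rho <- p$r0_birth + V0 * (t - p$birth_time)
  vapply(theta, function(th) {
    d <- bf_cone_distance(Rc, th, rho, p$azimuth, unroll)
    if (form == "power") sum((d0 / d)^s) else sum(exp(s * (1 - d / d0)))
  }, 0)
}

## brute-force next-event solver: uniform time stepping (eps_t / 4) with a
## dense azimuth grid; returns the first grid time at which the minimum
## falls to the threshold, and the minimizing azimuth
bf_next_event <- function(p, t_cur, thr, d0, s, form, unroll, Rc, V0,
                          eps_t, n_grid = 720, max_t = 50) {
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  dt <- eps_t / 4
  t <- t_cur
  repeat {
    E <- bf_total_inhibition(grid, t, p, d0, s, form, unroll, Rc, V0)
    if (min(E) <= thr)
      return(list(t = t, theta = grid[which.min(E)], E = min(E)))
    t <- t + dt
    if (t - t_cur > max_t) stop("brute-force solver found no crossing")
  }
}

## ideal golden-spiral azimuth series (degrees) and organ transpositions
make_golden_azimuths <- function(n, div_deg = golden_angle()) {
  cumsum(c(0, rep(div_deg, n - 1)))
}

transpose_organs <- function(az, i) {
  az[c(i, i + 1)] <- az[c(i + 1, i)]
  az
}

## wrap degrees to (-180, 180]
wrap180 <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

## build a fake event sequence from azimuths (degrees) and times
fake_sequence <- function(az_deg, times = seq_along(az_deg),
                          eps_t = 1e-4, radius = 2) {
  ev <- data.frame(rank = seq_along(az_deg) - 1L, time = times,
                   azimuth_rad = (az_deg * pi / 180) %% (2 * pi),
                   radius_used = radius, threshold_used = 1,
                   concomitance_group = cumsum(c(1, diff(times) >= eps_t)) - 1L,
                   age_shift = 0)
  structure(list(events = ev, config = NULL, time_precision = eps_t,
                 mean_plastochron = stats::median(diff(times)),
                 eq_divergence_deg = NA_real_, final_state = NULL),
            class = "event_sequence")
}

## self-similar spiral lattice (geometric radii) as a primordia set; the
## tiny birth-time increments only set the rank order
make_lattice <- function(n, div_deg, growth_q, r0 = 2) {
  primordia(azimuth = (seq_len(n) - 1) * div_deg * pi / 180,
            birth_time = (seq_len(n) - 1) * 1e-9,
            r0_birth = r0 * growth_q^(seq_len(n) - 1))
}

## subset of a primordia state keeping the most recent k organs
recent_state <- function(p, k) {
  n <- length(p$azimuth)
  idx <- order(p$birth_time)
  idx <- idx[seq.int(max(1L, n - k + 1L), n)]
  primordia(p$azimuth[idx], p$birth_time[idx], p$r0_birth[idx])
}

## exhaustive audit of contact rank-offsets in an organ set (independent of
## estimate_parastichies): nearest-neighbour cut at 1.5 x median NN
audit_contact_offsets <- function(p, at_time, unroll = 0.95, V0 = 1) {
  n <- length(p$azimuth)
  rho <- p$r0_birth + V0 * (at_time - p$birth_time)
  D <- matrix(Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    D[i, j] <- bf_cone_distance(rho[i], p$azimuth[i], rho[j], p$azimuth[j],
                                unroll)
  nn <- apply(D, 1, min)
  cut <- 1.5 * median(nn)
  offs <- integer(0)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n))
    if (D[i, j] <= cut) offs <- c(offs, j - i)
  sort(table(offs), decreasing = TRUE)
}
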