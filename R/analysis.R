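## Divergence-angle / plastochron extraction and the defect taxonomy:
## concomitant initiations, M-shaped permutation motifs, transient
## distichous angles, handedness reversals, dispersion statistics,
## contact-parastichy estimation.

#' The golden angle (degrees)
#'
#' `360 * (1 - 1/phi) = 360 / phi^2`, about 137.5077 degrees: the
#' divergence angle of ideal spiral phyllotaxis.  Used only as a bracketing
#' prior when estimating a sequence's own regular angle.
#'
#' @return The golden angle in degrees.
#' @export
golden_angle <- function() 137.50776405003785

wrap_180 <- function(a) {
  a <- a %% 360
  a[a > 180] <- a[a > 180] - 360
  a
}

## circular difference in degrees, in (-180, 180]
circ_diff <- function(a, b) wrap_180(a - b)

as_events <- function(x) {
  if (inherits(x, "event_sequence")) return(x$events)
  if (is.data.frame(x)) return(x)
  stop("expected an event_sequence or a data frame of events")
}

#' Divergence-angle sequence
#'
#' The divergence angle is the azimuthal angle (viewed from the apex)
#' between two consecutively recorded organs: angle `i` is
#' `azimuth(i+1) - azimuth(i)` in event-rank order, wrapped to
#' `(-180, 180]` degrees.  Positive angles follow the handedness of the
#' initial fixture.
#'
#' @param x An `event_sequence` or events data frame (`>= 2` events).
#' @return An object of class `angle_sequence`: a list with `angles_deg`,
#'   `source_ranks` (the rank of the first organ of each pair) and
#'   `golden_angle_ref`.
#' @export
divergence_angles <- function(x) {
  ev <- as_events(x)
  if (nrow(ev) < 2L) stop("need at least 2 events for divergence angles")
  az <- ev$azimuth_rad * 180 / pi
  structure(list(angles_deg = wrap_180(diff(az)),
                 source_ranks = ev$rank[-nrow(ev)],
                 golden_angle_ref = golden_angle()),
            class = "angle_sequence")
}

#' Construct an angle sequence from bare angles
#'
#' @param angles_deg Signed divergence angles in degrees.
#' @param source_ranks Optional event ranks (default `0:(n-1)`).
#' @return An `angle_sequence`.
#' @export
angle_sequence <- function(angles_deg, source_ranks = seq_along(angles_deg) - 1L) {
  structure(list(angles_deg = wrap_180(as.numeric(angles_deg)),
                 source_ranks = source_ranks,
                 golden_angle_ref = golden_angle()),
            class = "angle_sequence")
}

as_angles <- function(x) {
  if (inherits(x, "angle_sequence")) return(x$angles_deg)
  if (inherits(x, "event_sequence")) return(divergence_angles(x)$angles_deg)
  as.numeric(x)
}

#' @export
print.angle_sequence <- function(x, ...) {
  cat(sprintf("<angle_sequence> %d angles, median |angle| = %.2f deg\n",
              length(x$angles_deg), median(abs(x$angles_deg))))
  invisible(x)
}

#' Plastochron sequence
#'
#' Time delays between consecutive initiations, in event-rank order.
#' Non-negative; zero within a concomitance group.
#'
#' @param x An `event_sequence` or events data frame (`>= 2` events).
#' @return Numeric vector of length `n - 1`.
#' @export
plastochrons <- function(x) {
  ev <- as_events(x)
  if (nrow(ev) < 2L) stop("need at least 2 events for plastochrons")
  diff(ev$time)
}

#' Detect concomitant initiations
#'
#' Initia are concomitant when the plastochron separating them is smaller
#' than the time precision of the simulation.  Grouping is transitive:
#' maximal runs of events with inter-event delays `< eps_t` form one group.
#'
#' @param x An `event_sequence` or events data frame.
#' @param eps_t Time precision; defaults to the sequence's own
#'   `time_precision`.
#' @return A list with `group` (integer id per event), `group_sizes`,
#'   `proportion` (events in groups of size `>= 2` over all events) and
#'   `n_groups_ge2`.
#' @export
detect_concomitant <- function(x, eps_t = NULL) {
  ev <- as_events(x)
  if (is.null(eps_t)) {
    if (inherits(x, "event_sequence")) eps_t <- x$time_precision
    else stop("`eps_t` must be given for a bare events table")
  }
  n <- nrow(ev)
  if (n == 0L)
    return(list(group = integer(0), group_sizes = integer(0),
                proportion = 0, n_groups_ge2 = 0L))
  grp <- cumsum(c(1L, as.integer(diff(ev$time) >= eps_t)))
  sizes <- as.integer(table(grp))
  in_big <- sizes[grp] >= 2L
  list(group = grp, group_sizes = sizes,
       proportion = mean(in_big),
       n_groups_ge2 = sum(sizes >= 2L))
}

#' Estimate the sequence's own regular divergence angle
#'
#' The deterministic equilibrium angle depends on `Gamma`, so the reference
#' regular angle `phi_hat` is estimated from the data: the median of the
#' angles lying within `band` degrees of plus or minus the golden angle,
#' signed by the majority handedness of those angles.  The golden-angle
#' constant is only the bracketing prior.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees.
#' @param band Half-width of the bracketing band (degrees).
#' @return Signed `phi_hat` in degrees.
#' @export
estimate_regular_angle <- function(angles, band = 30) {
  a <- as_angles(angles)
  g <- golden_angle()
  cand <- a[abs(abs(a) - g) <= band]
  if (length(cand) == 0L)
    stop("no angles within the golden-angle bracketing band")
  s <- if (sum(sign(cand)) >= 0) 1 else -1
  same <- cand[sign(cand) == s]
  s * median(abs(same))
}

#' Detect M-shaped divergence-angle motifs
#'
#' A concomitant pair recorded in permuted order turns three consecutive
#' regular angles `(phi, phi, phi)` into the motif
#' `(2*phi, -phi, 2*phi)` (angles wrapped to `(-180, 180]`).  Each index
#' triple `(i, i+1, i+2)` matching the motif around the sequence's own
#' regular angle `phi_hat` within `tol_deg` is flagged; un-transposing the
#' permuted organ pair restores three near-`phi_hat` angles.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees
#'   (`>= 3` angles).
#' @param tol_deg Matching tolerance in degrees (default 25).
#' @param phi_hat Optional regular angle; estimated from the data when
#'   `NULL`.
#' @return A list with `triple_starts` (1-based indices `i` of matched
#'   triples), `flags` (logical per angle: member of any matched triple),
#'   `n` (number of M-shapes) and `phi_hat`.
#' @export
detect_m_shapes <- function(angles, tol_deg = 25, phi_hat = NULL) {
  a <- as_angles(angles)
  n <- length(a)
  if (n < 3L)
    return(list(triple_starts = integer(0), flags = logical(n), n = 0L,
                phi_hat = phi_hat %||% NA_real_))
  if (is.null(phi_hat)) phi_hat <- estimate_regular_angle(a)
  m1 <- wrap_180(2 * phi_hat)
  m2 <- -phi_hat
  ok <- abs(circ_diff(a, m1)) <= tol_deg
  ok2 <- abs(circ_diff(a, m2)) <= tol_deg
  starts <- which(ok[seq_len(n - 2L)] &
                  ok2[seq.int(2L, n - 1L)] &
                  ok[seq.int(3L, n)])
  flags <- logical(n)
  for (i in starts) flags[i:(i + 2L)] <- TRUE
  list(triple_starts = starts, flags = flags, n = length(starts),
       phi_hat = phi_hat)
}

#' Detect transient distichous angles
#'
#' Flags divergence angles whose magnitude lies in
#' `[180 - tol_deg, 180]` (closed interval), the signature of a transient
#' distichous phyllotaxis.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees.
#' @param tol_deg Band half-width below 180 degrees (default 20).
#' @return Logical vector of flags.
#' @export
detect_distichous <- function(angles, tol_deg = 20) {
  a <- abs(as_angles(angles))
  a >= (180 - tol_deg) & a <= 180
}

#' Detect handedness reversals
#'
#' Classifies each unmasked angle as regular of the fixture handedness
#' (within `tol_deg` of `phi_hat`), regular of the opposite handedness
#' (within `tol_deg` of `-phi_hat`), or neither.  Runs of at least
#' `min_run` consecutive same-sign regular angles form regular segments; a
#' reversal is counted at each handedness switch between successive
#' regular segments, and the opposite-handedness segments are the reversal
#' segments.  Short opposite-sign excursions (below `min_run`) are not
#' reversals -- they are M-shape member candidates instead.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees.
#' @param min_run Minimum regular-run length (default 3).
#' @param tol_deg Regular-angle tolerance (default 30).
#' @param phi_hat Optional regular angle; estimated when `NULL`.
#' @param mask Logical vector of angles to exclude (e.g. M-shape or
#'   distichous flags); masked angles belong to no run.
#' @return A list with `n_switches` (the reversal count), `segments` (a
#'   data frame of opposite-handedness runs: `start`, `end` original
#'   indices), `flags` (logical: angle belongs to a reversal segment) and
#'   `phi_hat`.
#' @export
detect_reversals <- function(angles, min_run = 3L, tol_deg = 30,
                             phi_hat = NULL, mask = NULL) {
  a <- as_angles(angles)
  n <- length(a)
  if (is.null(mask)) mask <- logical(n)
  if (is.null(phi_hat) && n) phi_hat <- tryCatch(estimate_regular_angle(a),
                                                 error = function(e) NA_real_)
  empty <- list(n_switches = 0L,
                segments = data.frame(start = integer(0), end = integer(0)),
                flags = logical(n), phi_hat = phi_hat)
  if (n == 0L || is.na(phi_hat)) return(empty)
  lab <- integer(n)  # +1 fixture hand, -1 opposite, 0 neither/masked
  lab[abs(circ_diff(a, phi_hat)) <= tol_deg] <- 1L
  lab[abs(circ_diff(a, -phi_hat)) <= tol_deg] <- -1L
  lab[mask] <- 0L
  ## runs over the subsequence of regular angles only
  reg_idx <- which(lab != 0L)
  if (length(reg_idx) == 0L) return(empty)
  rl <- rle(lab[reg_idx])
  keep <- rl$lengths >= min_run
  run_end <- cumsum(rl$lengths)
  run_start <- run_end - rl$lengths + 1L
  kept_vals <- rl$values[keep]
  n_switch <- if (length(kept_vals) >= 2L) sum(diff(kept_vals) != 0L) else 0L
  opp <- which(keep & rl$values == -1L)
  segments <- data.frame(start = reg_idx[run_start[opp]],
                         end = reg_idx[run_end[opp]])
  flags <- logical(n)
  for (k in seq_len(nrow(segments))) {
    span <- segments$start[k]:segments$end[k]
    flags[span[lab[span] == -1L]] <- TRUE
  }
  list(n_switches = n_switch, segments = segments, flags = flags,
       phi_hat = phi_hat)
}

#' Normalized dispersion of divergence angles
#'
#' M-shaped patterns reflect a recording permutation, not angular noise, so
#' they are excluded; the remaining angles are symmetrised to their
#' magnitudes in `(0, 180)` and the statistic is their standard deviation
#' divided by their mean.
#'
#' @param angles An `angle_sequence` or numeric vector of degrees.
#' @param m_flags Logical flags of M-shape members (from
#'   [detect_m_shapes()]); `NULL` detects them internally.
#' @return `sd / mean` of the symmetrised unflagged angles.
#' @export
angle_dispersion <- function(angles, m_flags = NULL) {
  a <- as_angles(angles)
  if (is.null(m_flags)) m_flags <- detect_m_shapes(a)$flags
  x <- abs(a[!m_flags])
  if (length(x) < 2L)
    stop("undefined statistic: fewer than 2 unflagged angles")
  sd(x) / mean(x)
}

#' Estimate contact-parastichy counts
#'
#' Takes the organ positions at a fixed time, finds each organ's contact
#' neighbours (pairs closer than 1.5 times the median nearest-neighbour
#' geodesic distance), and reads the two dominant rank offsets among
#' contact pairs: these are the numbers of conspicuous spirals of each
#' handedness.
#'
#' @param x An `event_sequence`, or a [primordia()] set.
#' @param at_time Snapshot time (default: latest birth time).
#' @param n_recent Number of most recent organs used (default 30).
#' @param geom,V0 Geometry and radial velocity; taken from the sequence's
#'   configuration when `x` is an `event_sequence`.
#' @return Integer vector `c(m, n)`, sorted ascending.
#' @export
estimate_parastichies <- function(x, at_time = NULL, n_recent = 30L,
                                  geom = cone_geometry(), V0 = 1) {
  if (inherits(x, "event_sequence")) {
    geom <- x$config$geom
    V0 <- x$config$V0
    ev <- x$events
    p <- primordia(ev$azimuth_rad, ev$time, ev$radius_used)
  } else if (inherits(x, "primordia")) {
    p <- x
  } else stop("expected an event_sequence or primordia")
  n <- length(p$azimuth)
  if (n < 15L) stop("too few organs to estimate parastichies (need >= 15)")
  if (is.null(at_time)) at_time <- max(p$birth_time)
  keep <- order(p$birth_time)
  keep <- keep[seq.int(max(1L, n - n_recent + 1L), n)]
  th <- p$azimuth[keep]
  rho <- p$r0_birth[keep] + V0 * (at_time - p$birth_time[keep])
  m <- length(keep)
  ## pairwise geodesic distances
  ia <- rep(seq_len(m), each = m)
  ib <- rep(seq_len(m), times = m)
  D <- matrix(cpp_cone_distance(rho[ia], th[ia], rho[ib], th[ib],
                                geom$unroll_factor), m, m, byrow = TRUE)
  diag(D) <- Inf
  nn <- apply(D, 1L, min)
  cut <- 1.5 * median(nn)
  offs <- integer(0)
  for (a in seq_len(m - 1L)) {
    b <- which(D[a, ] <= cut)
    b <- b[b > a]
    offs <- c(offs, b - a)
  }
  if (length(offs) == 0L) stop("no contact pairs found")
  tab <- sort(table(offs), decreasing = TRUE)
  top <- as.integer(names(tab))
  if (length(top) == 1L) return(c(top, top))
  sort(top[1:2])
}

#' Annotate a sequence with the full defect taxonomy
#'
#' Applies the detectors with their precedence: concomitance from event
#' times; M-shapes from the angles; distichous and reversal detection on
#' the M-masked sequence.  Labels are mutually exclusive except
#' `concomitant_member`, which may co-occur with `m_shape`.
#'
#' @param seq An `event_sequence`.
#' @param tol_m,tol_distichous,tol_reversal Detector tolerances (degrees).
#' @param min_run Minimum regular-run length for reversals.
#' @param eps_t Optional override of the concomitance time precision (for
#'   sequences read from files).
#' @return An object of class `defect_annotation`: a list with `labels`
#'   (character per angle), `concomitant` (per-event group info),
#'   `m_shapes`, `reversals`, `phi_hat`, and `proportions` (named numeric:
#'   `concomitant`, `m_shape`, `distichous`, `reversal`, and the
#'   normalized dispersions `sd_angle_norm`, `sd_plastochron_norm`).
#' @export
annotate_defects <- function(seq, tol_m = 25, tol_distichous = 20,
                             tol_reversal = 30, min_run = 3L, eps_t = NULL) {
  stopifnot(inherits(seq, "event_sequence"))
  ang <- divergence_angles(seq)
  a <- ang$angles_deg
  conc <- detect_concomitant(seq, eps_t = eps_t)
  ms <- detect_m_shapes(a, tol_deg = tol_m)
  dis <- detect_distichous(a, tol_deg = tol_distichous) & !ms$flags
  rev <- detect_reversals(a, min_run = min_run, tol_deg = tol_reversal,
                          phi_hat = ms$phi_hat, mask = ms$flags | dis)
  labels <- rep("regular", length(a))
  labels[rev$flags] <- "reversal_segment"
  labels[dis] <- "distichous"
  labels[ms$flags] <- "m_shape"
  pl <- plastochrons(seq)
  props <- c(
    concomitant = conc$proportion,
    m_shape = mean(ms$flags),
    distichous = mean(dis),
    reversal = mean(rev$flags),
    sd_angle_norm = tryCatch(angle_dispersion(a, ms$flags),
                             error = function(e) NA_real_),
    sd_plastochron_norm = if (mean(pl) > 0) sd(pl) / mean(pl) else NA_real_)
  structure(list(labels = labels, concomitant = conc, m_shapes = ms,
                 reversals = rev, distichous = dis, phi_hat = ms$phi_hat,
                 proportions = props,
                 n_events = nrow(seq$events), n_angles = length(a)),
            class = "defect_annotation")
}

#' @export
print.defect_annotation <- function(x, ...) {
  cat(sprintf("<defect_annotation> %d events, %d angles, phi_hat = %.2f deg\n",
              x$n_events, x$n_angles, x$phi_hat))
  p <- x$proportions
  cat(sprintf("  concomitant %.3f | m_shape %.3f | distichous %.3f | reversal %.3f\n",
              p["concomitant"], p["m_shape"], p["distichous"], p["reversal"]))
  cat(sprintf("  sd(angle)/mean %.3f | sd(plastochron)/mean %.3f\n",
              p["sd_angle_norm"], p["sd_plastochron_norm"]))
  invisible(x)
}

#' Pool annotated runs into a defect-summary table
#'
#' Pools events across seeds within each condition; proportions are
#' event-weighted (total flagged counts over total counts), and the
#' dispersion statistics are computed on the pooled angle and plastochron
#' sets.
#'
#' @param runs A list of `event_sequence` objects.
#' @param conditions A vector (one per run) labelling the condition, e.g.
#'   the noise strength in percent.
#' @param ... Passed to [annotate_defects()].
#' @return A data frame with one row per condition: `condition`,
#'   `n_runs`, `n_events`, `n_angles`, `prop_concomitant`, `prop_m_shape`,
#'   `prop_distichous`, `prop_reversal`, `m_per_event`, `sd_angle_norm`,
#'   `sd_plastochron_norm`.
#' @export
defect_summary <- function(runs, conditions = rep(1, length(runs)), ...) {
  stopifnot(length(runs) == length(conditions))
  out <- lapply(unique(conditions), function(cond) {
    idx <- which(conditions == cond)
    anns <- lapply(runs[idx], annotate_defects, ...)
    n_ev <- sum(vapply(anns, function(a) a$n_events, 0))
    n_an <- sum(vapply(anns, function(a) a$n_angles, 0))
    conc <- sum(vapply(anns, function(a)
      a$proportions["concomitant"] * a$n_events, 0))
    msh <- sum(vapply(anns, function(a) sum(a$m_shapes$flags), 0))
    n_m <- sum(vapply(anns, function(a) a$m_shapes$n, 0))
    dis <- sum(vapply(anns, function(a) sum(a$distichous), 0))
    rev <- sum(vapply(anns, function(a) sum(a$reversals$flags), 0))
    pooled_a <- unlist(lapply(seq_along(idx), function(j) {
      ang <- divergence_angles(runs[[idx[j]]])$angles_deg
      abs(ang[!anns[[j]]$m_shapes$flags])
    }))
    pooled_p <- unlist(lapply(runs[idx], plastochrons))
    data.frame(condition = cond, n_runs = length(idx), n_events = n_ev,
               n_angles = n_an,
               prop_concomitant = conc / n_ev,
               prop_m_shape = msh / n_an,
               prop_distichous = dis / n_an,
               prop_reversal = rev / n_an,
               m_per_event = n_m / n_ev,
               sd_angle_norm = if (length(pooled_a) >= 2L)
                 sd(pooled_a) / mean(pooled_a) else NA_real_,
               sd_plastochron_norm = if (length(pooled_p) >= 2L &&
                                         mean(pooled_p) > 0)
                 sd(pooled_p) / mean(pooled_p) else NA_real_)
  })
  do.call(rbind, out)
}
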