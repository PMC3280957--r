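## Conical apex geometry and the primary inhibitory field.

#' Conical apex geometry
#'
#' The shoot apex is modelled as a cone; all distances between points on its
#' surface are geodesic distances obtained by unrolling the cone into a plane
#' sector.  The cone is parameterized by its *unroll factor*: the ratio of
#' the unrolled-sector angle to `2*pi`, which equals the sine of the cone
#' half-angle.  An unroll factor of 1 is a flat disc, on which distances
#' reduce to planar Euclidean distances.
#'
#' @param unroll_factor Dimensionless, in `(0, 1]`.  Default 0.95, a shallow
#'   dome approximating a near-flat *Arabidopsis* apex.
#' @return An object of class `cone_geometry`.
#' @examples
#' geom <- cone_geometry(1)  # flat disc
#' cone_distance(surface_point(2, 0), surface_point(2, pi), geom)  # == 4
#' @export
cone_geometry <- function(unroll_factor = 0.95) {
  stopifnot(is.numeric(unroll_factor), length(unroll_factor) == 1L)
  if (!(unroll_factor > 0 && unroll_factor <= 1))
    stop("`unroll_factor` must lie in (0, 1]")
  structure(list(unroll_factor = unroll_factor), class = "cone_geometry")
}

#' @export
print.cone_geometry <- function(x, ...) {
  cat(sprintf("<cone_geometry> unroll_factor = %g (half-angle %.1f deg)\n",
              x$unroll_factor, asin(x$unroll_factor) * 180 / pi))
  invisible(x)
}

#' A point on the cone surface
#'
#' @param slant_radius Distance from the apex along the cone surface
#'   (arbitrary length units, `>= 0`).
#' @param azimuth Angle in radians; stored wrapped to `[0, 2*pi)`.
#' @return An object of class `surface_point`.
#' @export
surface_point <- function(slant_radius, azimuth) {
  stopifnot(length(slant_radius) == length(azimuth))
  if (any(slant_radius < 0)) stop("slant radius must be non-negative")
  structure(list(slant_radius = slant_radius, azimuth = azimuth %% (2 * pi)),
            class = "surface_point")
}

#' Geodesic distance between two points on the cone
#'
#' Unrolls the cone: an azimuth difference `dth` (wrapped to `[0, pi]`) maps
#' to an unrolled angle `alpha = unroll_factor * dth`.  For `alpha < pi` the
#' geodesic is the planar chord `sqrt(ra^2 + rb^2 - 2*ra*rb*cos(alpha))`;
#' for `alpha >= pi` it passes the apex and has length `ra + rb`.
#'
#' @param a,b [surface_point()] objects (vectorized, equal lengths).
#' @param geom A [cone_geometry()].
#' @return Numeric vector of distances.
#' @export
cone_distance <- function(a, b, geom = cone_geometry()) {
  stopifnot(inherits(a, "surface_point"), inherits(b, "surface_point"),
            inherits(geom, "cone_geometry"))
  n <- max(length(a$slant_radius), length(b$slant_radius))
  cpp_cone_distance(rep_len(a$slant_radius, n), rep_len(a$azimuth, n),
                    rep_len(b$slant_radius, n), rep_len(b$azimuth, n),
                    geom$unroll_factor)
}

#' Inhibition-kernel parameters
#'
#' Each primordium is a source of inhibition decaying with geodesic distance
#' `d`.  The kernel is a pluggable strategy; both shipped forms equal
#' exactly 1 at `d = range_d0` and are strictly decreasing:
#'
#' * `"exponential"` (default): `exp(steepness_s * (1 - d / range_d0))`, a
#'   short-ranged field whose influence is confined to a region of order
#'   `range_d0` around the source (decay length `range_d0 / steepness_s`).
#'   This is the form used by the package's reference parameter set: a
#'   source inhibits a bounded neighbourhood, the equilibrium lattice is
#'   dense, and concomitant initiations land in adjacent spiral basins (the
#'   origin of M-shaped angle motifs).
#' * `"power"`: `(range_d0 / d)^steepness_s`, the long-ranged form of the
#'   classical dynamical models; the algebraic tail makes every primordium
#'   contribute everywhere, which at the same parameters yields a much
#'   sparser, more fragile pattern.
#'
#' @param range_d0 Range of the inhibitory field, length units, `> 0`
#'   (typical 3-4 with a competent-circle radius of 2).
#' @param steepness_s Dimensionless steepness of the decay, `> 0` (typical 2).
#' @param kernel_form `"exponential"` or `"power"` (see Details).
#' @return An object of class `field_params`.
#' @export
field_params <- function(range_d0 = 3, steepness_s = 2,
                         kernel_form = c("exponential", "power")) {
  stopifnot(is.numeric(range_d0), is.numeric(steepness_s))
  kernel_form <- match.arg(kernel_form)
  if (range_d0 <= 0) stop("`range_d0` must be positive")
  if (steepness_s <= 0) stop("`steepness_s` must be positive")
  structure(list(range_d0 = range_d0, steepness_s = steepness_s,
                 kernel_form = kernel_form),
            class = "field_params")
}

## integer code of the kernel form for the compiled backend
kernel_code <- function(fp) if (identical(fp$kernel_form, "exponential")) 1L else 0L

#' Inhibition kernel
#'
#' The contribution of a single primordium at geodesic distance `d`:
#' `(d0/d)^s` for the power-law form, `exp(s*(1 - d/d0))` for the
#' exponential form.  Both are strictly decreasing, equal to 1 at `d = d0`,
#' and vanish as `d -> Inf`.
#'
#' @param d Distance(s), `> 0`.  A distance of exactly 0 is a simulation
#'   fault (a new initium coincident with an existing source) and errors.
#' @param fp A [field_params()].
#' @return Numeric vector of inhibition values (`>= 0`).
#' @export
inhibition_kernel <- function(d, fp = field_params()) {
  stopifnot(inherits(fp, "field_params"))
  if (any(d == 0)) stop("singular distance: probe coincides with a source")
  if (any(d < 0)) stop("distances must be positive")
  if (kernel_code(fp) == 1L) exp(fp$steepness_s * (1 - d / fp$range_d0))
  else (fp$range_d0 / d)^fp$steepness_s
}

#' Primordium set
#'
#' The per-organ state carried by the simulator: azimuth, birth time, the
#' competent-circle radius at birth (so a primordium's slant radius at time
#' `t >= birth_time` is `r0_birth + V0 * (t - birth_time)`), and the
#' physiological age shift applied by a class-iii secondary field (0 unless
#' shifted).  Corrected age at time `t` is `(t - birth_time) + age_shift`.
#'
#' @param azimuth Azimuths in radians.
#' @param birth_time Birth times.
#' @param r0_birth Competent-circle radius at each organ's birth.
#' @param age_shift Physiological age corrections (default 0).
#' @return An object of class `primordia`.
#' @export
primordia <- function(azimuth, birth_time, r0_birth,
                      age_shift = numeric(length(azimuth))) {
  n <- length(azimuth)
  stopifnot(length(birth_time) == n, length(r0_birth) == n,
            length(age_shift) == n)
  structure(list(azimuth = azimuth %% (2 * pi), birth_time = birth_time,
                 r0_birth = r0_birth, age_shift = age_shift),
            class = "primordia")
}

#' @export
print.primordia <- function(x, ...) {
  cat(sprintf("<primordia> %d organs, birth times [%g, %g]\n",
              length(x$azimuth),
              if (length(x$birth_time)) min(x$birth_time) else NA,
              if (length(x$birth_time)) max(x$birth_time) else NA))
  invisible(x)
}

#' Slant radii of primordia at a given time
#'
#' @param p A [primordia()] set.
#' @param t Time (must be `>= birth_time` of every organ).
#' @param V0 Radial velocity.
#' @return Numeric vector of slant radii.
#' @export
primordia_radii <- function(p, t, V0 = 1) {
  stopifnot(inherits(p, "primordia"))
  if (length(p$birth_time) && any(p$birth_time > t))
    stop("all primordia must have birth_time <= t")
  p$r0_birth + V0 * (t - p$birth_time)
}

#' Total inhibition at a probe azimuth on the competent circle
#'
#' The inhibitory field is the sum of the kernel contributions of all
#' existing primordia, each evaluated at the geodesic distance between the
#' probe `(R_circle, theta)` and the primordium's current position.  The sum
#' is additive, non-negative, and 0 for an empty primordium set.  Sources
#' whose maximal possible contribution is below `prune_eps` may be skipped
#' (the total error is bounded by the number pruned times `prune_eps`).
#'
#' @param theta Probe azimuth(s), radians.
#' @param t Evaluation time.
#' @param p A [primordia()] set (all `birth_time <= t`).
#' @param fp [field_params()].
#' @param geom [cone_geometry()].
#' @param R_circle Radius of the competent circle.
#' @param V0 Radial velocity of receding primordia.
#' @param prune_eps Per-source pruning floor (default `1e-9`; 0 disables).
#' @return Numeric vector of total inhibition values.
#' @export
total_inhibition <- function(theta, t, p, fp = field_params(),
                             geom = cone_geometry(), R_circle = 2, V0 = 1,
                             prune_eps = 1e-9) {
  stopifnot(inherits(p, "primordia"), inherits(fp, "field_params"),
            inherits(geom, "cone_geometry"))
  if (length(p$azimuth) == 0L) return(numeric(length(theta)))
  if (any(p$birth_time > t)) stop("all primordia must have birth_time <= t")
  cpp_field_on_circle(theta, t, p$azimuth, p$birth_time, p$r0_birth,
                      V0, R_circle, geom$unroll_factor,
                      fp$range_d0, fp$steepness_s, kernel_code(fp),
                      0L, 0, 0, 0, prune_eps)
}
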