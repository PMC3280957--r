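## Secondary fields: class-ii co-inhibition at initiation (redundant sum or
## synergetic product) and class-iii post-initiation age correction by a
## delayed step field.

#' Combine two inhibitions redundantly
#'
#' Redundant co-inhibition: the total inhibition sensed by a new initium is
#' `E1 + beta * E2`; the initiation rule compares this sum to the threshold.
#'
#' @param E1,E2 Primary and secondary inhibition values (`>= 0`).
#' @param beta Weight of the secondary field.
#' @return `E1 + beta * E2`.
#' @export
combine_redundant <- function(E1, E2, beta) E1 + beta * E2

#' Combine two inhibitions synergetically
#'
#' Synergetic co-inhibition: both fields are needed to repress initiation,
#' and the total inhibition sensed by a new initium is the product `E1 * E2`.
#'
#' @param E1,E2 Primary and secondary inhibition values (`>= 0`).
#' @return `E1 * E2`.
#' @export
combine_synergetic <- function(E1, E2) E1 * E2

#' Is the class-iii step field active at a probe point?
#'
#' A primordium becomes a step-like source of the secondary field a delay
#' `delay_tau` after its initiation; the source is active strictly within
#' `range_d1` (value 0 at and beyond `range_d1`).  The aggregate over
#' sources is a logical OR: the field is non-zero at the probe iff at least
#' one source covers it.
#'
#' @param theta Probe azimuth on the competent circle, radians.
#' @param t Evaluation time.
#' @param p A [primordia()] set.
#' @param params A [secondary_field_params()].
#' @param geom A [cone_geometry()].
#' @param R_circle Competent-circle radius.
#' @param V0 Radial velocity.
#' @return `TRUE` iff some primordium of age `>= delay_tau` lies at geodesic
#'   distance `< range_d1` from the probe.
#' @export
step_field_active <- function(theta, t, p, params, geom = cone_geometry(),
                              R_circle = 2, V0 = 1) {
  stopifnot(inherits(p, "primordia"),
            inherits(params, "secondary_field_params"))
  old <- which((t - p$birth_time) >= params$delay_tau)
  if (length(old) == 0L) return(FALSE)
  rho <- p$r0_birth[old] + V0 * (t - p$birth_time[old])
  d <- cpp_cone_distance(rep_len(R_circle, length(old)),
                         rep_len(theta, length(old)),
                         rho, p$azimuth[old], geom$unroll_factor)
  any(d < params$range_d1)
}

#' Apply a class-iii age shift to a new initium
#'
#' If the step field is active at the initium's position, its physiological
#' age is shifted once, at initiation, by `age_shift_delta`; the shift is
#' permanent and never re-evaluated as the organ recedes.  Corrected age =
#' chronological age + age shift.
#'
#' @param age_shift Current age shift of the initium (normally 0).
#' @param active Logical, from [step_field_active()].
#' @param params A [secondary_field_params()].
#' @return The age shift to store on the initium.
#' @export
shift_age <- function(age_shift, active, params) {
  if (isTRUE(active)) params$age_shift_delta else 0
}

#' Rank concomitant initia by corrected age
#'
#' Events in one concomitance group share a solver time, so their
#' chronological ages are equal and their corrected ages differ only by
#' their age shifts.  The recorded order is by decreasing corrected age
#' (older first); exact ties are broken by the seeded RNG, which for a
#' group with no age shifts reduces to the fully random ordering rule.
#'
#' @param age_shifts Numeric vector of age shifts of the group members, in
#'   placement order.
#' @return An integer permutation: the placement indices in recorded order.
#' @export
rank_by_corrected_age <- function(age_shifts) {
  n <- length(age_shifts)
  if (n <= 1L) return(seq_len(n))
  tie_break <- sample.int(n)
  order(-age_shifts, tie_break)
}

#' Fraction of initia overlapped by the class-iii field
#'
#' The "partial overlap" diagnostic: the proportion of recorded initia for
#' which the step field was active at initiation (i.e. whose age shift was
#' applied).  The secondary field corrects defects only when this overlap is
#' partial -- full or zero overlap generates no age differential between
#' concomitant initia.
#'
#' @param seq An `event_sequence` from [run_simulation()] with a class-iii
#'   secondary field.
#' @return Proportion in `[0, 1]`.
#' @export
overlap_fraction <- function(seq) {
  stopifnot(inherits(seq, "event_sequence"))
  if (seq$config$secondary$mode != "age_shift")
    return(NA_real_)
  mean(seq$events$age_shift != 0)
}
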