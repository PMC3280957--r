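---
title: "Stochastic inhibitory-field phyllotaxis: model, solver and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic inhibitory-field phyllotaxis: model, solver and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`phyllonoise` simulates organ initiation at a plant shoot apex with the
classical inhibitory-field dynamical system.  The apex is an axisymmetric
cone; positions on its surface are written `(rho, theta)` with `rho` the
slant distance from the apex and `theta` the azimuth, and all distances are
geodesics obtained by unrolling the cone into a plane sector.  The cone is
parameterized by its *unroll factor* `c` in `(0, 1]`, the ratio of the
unrolled-sector angle to `2*pi` (equivalently the sine of the cone
half-angle; `c = 1` is a flat disc).

Organ primordia form on the *competent circle* of radius `R0` at the apex
periphery and then recede radially at constant velocity `V0`, so an organ
born at time `t_b` on a circle of radius `R_b` sits at slant radius
`R_b + V0 * (t - t_b)`.  Every primordium is a source of inhibition that
decays with geodesic distance `d`; the total inhibition at a point is the
sum over all sources.  A new organ (an *initium*) appears on the competent
circle at the time and azimuth at which the total inhibition first falls to
the threshold `E*`.  Nothing else is prescribed: the periodicity (the
*plastochron* `T`) and the spatial pattern (the *divergence angle* between
successive organs, and the conspicuous contact spirals or *parastichies*)
self-organize.  The main control parameter is `Gamma = d0 / R0`, the ratio
of the inhibition range to the circle radius.

### Parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `R0_mean` | competent-circle radius | length (arbitrary) | 2 |
| `V0` | radial recession velocity | length / time | 1 |
| `threshold_mean` | initiation threshold `E*` | inhibition | 1 |
| `range_d0` | inhibition range `d0` | length | 3 |
| `steepness_s` | kernel steepness `s` | — | 2 |
| `kernel_form` | kernel strategy | — | `"exponential"` |
| `unroll_factor` | cone unroll factor | — | 0.95 |
| `noise_sd_threshold` | threshold-noise SD | inhibition | 0 |
| `noise_sd_radius` | size-noise SD | length | 0 |
| `time_precision` | solver precision on times | time | `1e-4 * T` |
| `angle_precision` | solver precision on azimuths | rad | `1e-4` |

The length unit is set by the competent circle (`R0 = 2` "arbitrary
units"), the time unit by `V0 = 1`.  At the defaults the deterministic
equilibrium is a left-handed spiral with divergence angle 139.74 degrees,
plastochron 1.306, and contact parastichies (3, 5) — the classical
Fibonacci configuration of an *Arabidopsis*-like apex.  The cone default
0.95 is a shallow dome; results change little between 0.9 and 1.

### The inhibition kernel

The kernel is a pluggable strategy normalized so that a single source
contributes exactly 1 at distance `d0`:

* `"exponential"` (default): `E(d) = exp(s * (1 - d/d0))`, decay length
  `d0 / s`.  A source effectively inhibits a bounded region of diameter a
  few times `d0 / s` around itself.
* `"power"`: `E(d) = (d0/d)^s`, the long-ranged form used by classical
  abstract models; the algebraic tail makes every organ contribute
  everywhere.

The choice matters far more than any other design decision in the package,
because it sets the equilibrium packing.  With the exponential kernel at
the default parameters the plastochron is 1.31, so the radial spacing
between successive organs (`V0 * T = 1.31`) is well below the circle
radius: the lattice is dense, several inhibition basins coexist on the
circle, and a vanishing plastochron puts two initia into *adjacent* spiral
basins — which is what produces the characteristic M-shaped divergence
motifs, and which keeps the spiral handedness robust to threshold noise.
With the power-law kernel at the same parameters the plastochron is 2.30
(radial spacing above `R0`): the lattice is sparse, the circle carries
essentially a single basin, concomitant initia land diametrally (~180
degrees apart), and the handedness flips freely under threshold noise.
The exponential form is the package default because only it reproduces the
qualitative defect taxonomy that the analysis layer is built to measure
(M-shapes from concomitance under threshold noise; handedness reversals
specific to size noise).  The power law remains available through
`field_params(kernel_form = "power")` for studying that sparser regime.

## The event solver

Between initiations all sources recede, so the circle minimum of the
inhibition decays monotonically.  The solver:

1. scans the circle on `n_grid` (default 360) equispaced azimuths —
   enough to isolate every basin, whose angular width at spiral
   equilibria is tens of degrees — and refines the best basin by
   golden-section search to `angle_precision`;
2. brackets the threshold crossing in time by geometric expansion
   (initial step `0.25 * T`, factor 1.5) and bisects to `time_precision`;
3. places the initium, then re-scans the circle at the same solver time:
   any remaining local minimum below the threshold (and farther than
   `100 * angle_precision` from initia already placed) becomes an
   additional, *concomitant* initium.  A warning is issued and the group
   capped at 4 if more appear;
4. redraws the noisy quantity once per accepted initiation event (a
   multi-initium group from a single crossing counts as one redraw).

Initia whose times differ by less than `time_precision` form one
concomitance group (chaining is transitive).  Because such initia are
physically equivalent, their recorded order is drawn at random — the
origin of M-shaped motifs — except that a class-iii secondary field can
break the tie deterministically (below).  Random reordering is applied
only to exact time ties, so the event stream remains sorted by time.

Default precisions are `1e-4` of the mean plastochron in time and `1e-4`
rad in angle.  A property test guards them: halving both changes no
divergence angle of a 100-event deterministic run by more than 0.1
degrees.  Sources whose maximal possible contribution on the circle is
below `prune_eps = 1e-9` are skipped; the error is bounded by the number
pruned times `prune_eps` and is tested.

### The equilibrium fixture

Noise studies must not conflate transients with noise effects, so every
run starts from the converged deterministic state: from an asymmetric
two-organ seed (azimuths 0 and 150 degrees) the noise-free model runs
until the divergence angle is constant to within 0.01 degrees over 20
consecutive events (at the defaults: ~70 events).  The seed asymmetry
selects the handedness; mirroring all azimuths flips it, and the sign
convention for divergence angles is positive = the fixture's handedness.
The fixture keeps the most recent `fixture_keep = 250` organs (under the
exponential kernel organs older than ~25 plastochrons contribute less
than `prune_eps` anyway) and is cached in memory, keyed by the relevant
parameters; set `options(phyllonoise.fixture_cache = <dir>)` for a disk
cache.  A property test verifies that equilibrium statistics are
independent of the seed azimuths.

## Noise and the defect taxonomy

Two noise modes redraw a model quantity after each initiation from a
Gaussian:

* **threshold noise** — the initiation threshold, mean `E*`, SD
  `sigma_E`; strength reported as `sigma_E / E*`;
* **size noise** — the competent-circle radius, mean `R0`, SD `sigma_R`;
  strength `sigma_R / R0`.

Draws are truncated below (at `0.05 * E*` and `0.1 * R0` respectively) by
redrawing, which forbids non-physical values while perturbing the
distribution negligibly at the strengths studied (a `> 3 sigma` event
even at 30% strength).

The analysis layer extracts divergence-angle and plastochron sequences in
recorded-rank order and labels four defect classes:

* **concomitant initiations** — events whose plastochron is below the
  time precision; proportion = events in groups of size 2 or more over
  all events;
* **M-shaped motifs** — angle triples `(2*phi, -phi, 2*phi)` (wrapped),
  the signature of a concomitant pair recorded in permuted order.  The
  reference regular angle `phi_hat` is estimated from the sequence itself
  (median of angles within 30 degrees of the golden angle, signed by the
  majority handedness), because the equilibrium angle depends on `Gamma`;
  the golden-angle constant is only a bracketing prior.  Matching
  tolerance 25 degrees (configurable);
* **distichous angles** — `|angle|` in `[160, 180]` (tolerance 20,
  configurable), a transient visit to the alternate-180-degree mode;
* **handedness reversals** — runs of at least 3 consecutive angles within
  30 degrees of `-phi_hat`, on the sequence with M-shape and distichous
  flags masked; shorter opposite-sign excursions are M-shape candidates,
  not reversals.

Precedence: concomitance is read from times; M-shapes from angles;
distichous and reversal labels from the M-masked sequence.  The
normalized angle dispersion excludes M-flagged angles (they reflect a
recording permutation, not angular noise) and symmetrises the rest to
`(0, 180)` before taking `sd/mean`.  None of the detector tolerances have
canonical published values; all are exposed as arguments with the
defaults above.

At the committed defaults the sweep drivers place the defect onsets
(smallest strength with a pooled proportion above the 1% operational
floor) at: concomitant + distichous under threshold noise near 25-30%;
distichous under size noise near 12-14% and reversals near 18-22%
(reversals are bursty — a single flip persists for many plastochrons —
so this onset is a high-variance statistic and the sweeps pool 6 seeds);
concomitant initiations under size noise stay well below the 1% floor
(about 0.1% at 28-34% strength), because the circle must shrink by about
two standard deviations before the post-initiation minimum drops below
the threshold immediately.  These numbers are recomputed from scratch by
`scripts/acceptance.R`; the test suite asserts the same protocols at the
same scales.

## Secondary fields

Class-ii fields act *during* initiation: primordia older than `delay_tau`
are sources of a second inhibition of range `d1` (same kernel form and
steepness), and the initiation rule compares either `E1 + beta * E2`
(redundant) or `E1 * E2` (synergetic) to the threshold.  Two verified
consequences: a redundant field of different range shifts or destabilizes
the equilibrium (the two ranges favour incommensurate spacings), and an
equal-range synergetic field with `delay_tau = 0` is *exactly* a
threshold change (`E2 = E1` pointwise, so the product rule at `E*^2`
replays the single-field run at `E*` — the test asserts bitwise-level
agreement).

The class-iii field acts *after* initiation: primordia older than
`delay_tau` are step-like sources, active strictly within `range_d1` and
zero at or beyond it (the aggregate is a logical OR).  A new initium
sensing the field has its physiological age shifted once, permanently, by
`age_shift_delta`; concomitant initia are then ranked by corrected age
(descending, random tie-break) instead of fully at random.  With a
*negative* shift (the overlapped initium made younger) the otherwise
50/50 recording coin is biased toward the spiral-consistent order and the
M-shape rate drops — by a factor of about 2.2 at the best sweep point —
while a positive shift increases it (factor ~0.7), reproducing the sign
asymmetry of the correction mechanism.  The `overlap_fraction()`
diagnostic confirms the field only works where its coverage of new initia
is partial: full or zero overlap produces no age differential.  In this
package's geometry the efficacy window sits at `d1/d0 ~ 1.4-1.7` (with
`tau` between a fraction of and ~two plastochrons), i.e. at the top edge
of the nominal `[1.0, 1.5]` sweep window, because concomitant initia lie
4.3-5.2 length units from the nearest old-enough sources.

## The time-varying `Gamma` protocol

`gamma_ramp(start, end, steps)` imposes a piecewise-linear `Gamma` as a
function of the initium rank (by rescaling `d0`; `R0` fixed), emulating
the vegetative-to-reproductive transition of a growing apex.  Driving
`Gamma` deep into the high-order regime (e.g. 1.5 to 0.2) produces
concomitant initiations, and a fast ramp (140 events) produces more of
them than a slow one (350 events) — the transient lags the adiabatic
equilibrium.  Near-degenerate crossings in the high-order regime are
resolved as concomitant only within the configured time precision, so
ramp experiments conventionally run at a coarser `time_precision`
(`0.01 * T` in the tests); at the default `1e-4 * T` almost every
crossing is resolved as sequential.

## What the generator does and does not emulate

The simulator reproduces the tissue-level abstraction: self-organized
timing and spacing, noise injected through the threshold or the circle
radius, and secondary corrective fields.  It does **not** model the
cellular template (cell-size discreteness of initium positioning), auxin
transport or any mechanistic readout of the fields, curved (non-conical)
apex shapes, or radially varying growth.  Passing tests therefore show
that the *dynamical system* behaves as described — not that real apices
do; in particular absolute defect onsets depend on the kernel form (see
above), which is the least constrained ingredient of the abstraction.

## Numerical and design notes

* Problem sizes: unit tests run 30-150-event sequences; the study-scale
  sweeps use 3-6 seeds times 500-1000 events per condition, which puts
  5-15% standard errors on defect proportions near the onsets — the grid
  resolution, not the Monte-Carlo error, dominates the onset estimates.
* The circle scan accumulates source contributions with a rotation
  recurrence (one sine/cosine pair per source per scan), so a full scan
  costs `O(n_grid * n_sources)` multiplications; a 1000-event noisy run
  takes a few seconds on one core.
* Degenerate inputs: an empty primordium set errors in the minimizer
  ("seed with at least one organ"); a probe exactly on a source is
  infinite inhibition during scans but an error in the user-facing field
  evaluation; `Gamma <= 1` warns (outside the spiral regimes); a crossing
  search past 100 mean plastochrons raises a stalled-simulation error
  naming the threshold.
* Exact ties in the corrected-age ranking fall back to the seeded RNG, so
  runs remain bit-for-bit replayable; all randomness flows from the
  single config seed and the caller's RNG state is restored afterwards.
* The contact-parastichy estimator reads the two dominant rank offsets
  among contact pairs (pairs closer than 1.5 times the median
  nearest-neighbour distance) of the most recent organs.  On expanding
  lattices the global distance cut makes the idealized distichous answer
  (1, 1) unreachable — successive-organ contacts dominate but the
  second offset also passes the cut — so tests validate the estimator
  against an exhaustive audit of the same lattice rather than against
  the cylinder idealization.
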