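---
title: "Models and methods behind reachvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reachvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachvr)
```

`reachvr` models a three-game VR reaching suite used in graded
rehabilitation for low back pain: a self-paced reaching task, a slow
fish-catching game and a fast dodgeball game that all drive the hand to the
same four anthropometry-scaled locations. This vignette explains the
models, the parameters that matter, what the synthetic-data generator does
and does not emulate, and the numerical and design choices that were
genuinely open.

## Target geometry

The frame has its origin at the midpoint of the feet on the floor, +x
anterior, +z up, all motion in the midsagittal plane; the hip pivot sits at
height `hip_height` on the vertical through the origin. Targets assume the
trunk and arm rotate rigidly about the hip pivot by the intended flexion
angle $\theta$ from a reference posture with the trunk vertical and the arm
horizontal forward, so the hand-to-pivot distance $\sqrt{L_t^2+L_a^2}$ is
invariant and target height decreases strictly with $\theta$ on (0°, 90°).

The reference arm configuration is a genuine modelling choice: the games'
published description constrains the targets only through a diagram, so we
fix the simplest convention consistent with "move only at the trunk" — arm
perpendicular to the trunk, rotating with it. Changing that convention
rescales all four targets coherently but does not affect any downstream
computation, which only ever consumes target coordinates.

`compute_target()` rejects $\theta$ outside $[0°, 90°)$: at 90° the
reference-posture arm would point straight down along the trunk and the
rigid model stops being a sensible reach description.

## Ballistic solvers

Projectiles are drag-free point masses, so flights are parabolas. Two
inversion modes correspond to the two launch games:

* **Fixed speed** (dodgeball): the quadratic in $\tan\alpha$ has two real
  roots when the target is reachable at $v_0$; we return the *smaller*
  angle (the low, flat arc) because the game's dodgeballs are described as
  flat and fast. The discarded high-arc root is recoverable from the same
  quadratic. A negative discriminant raises an unreachable-target error;
  zero horizontal separation is degenerate.
* **Fixed apex** (fish): the apex height $H$ must strictly exceed both the
  release and intercept heights; the intercept is taken on the descending
  limb, matching fish that jump high and would land short of the player.
  $H$ equal to the intercept height would make the descending-limb time
  zero and is rejected.

Launch sites and parameters are not published for the deployed games; the
defaults (dodgeball released at (3.0, 1.6) m at 8 m/s, fish surfacing at
(2.5, 0) m with a 2.0 m apex) were chosen once as plausible for the scene
layouts and are fully configurable. Nothing downstream depends on the
defaults: solvers are exercised over random geometries in the tests.

Flights are sampled in closed form (default 10 ms steps) with the final
sample placed exactly at the intercept time; mechanical energy is conserved
identically, which the tests use as a free invariant.

## Protocol scheduling

The session order is fixed — reaching, then fish, then dodgeball. The
reaching block presents the four heights from highest (15°) to lowest
(60°), five right-hand then five left-hand reaches per height, with ~15 s
rests between reaches and ~2 min between heights. Each launch game runs
2 sets × 15 launches; "equal and randomized distribution across the 4
target heights and ducking" is read as the only integer-balanced option,
3 events per category per set, shuffled by a seeded RNG so a seed
reproduces a plan exactly. Duck events carry only an audio-cue tag; they
are scheduled but never synthesised or analysed, matching the analysis
scope of the study design. Inter-launch timing is not reported anywhere;
it is exposed as configuration (default 10 s) and affects nothing
downstream.

## Synthetic motion generator

The generator emulates cue → react → reach recordings at 100 Hz. The body
is a planar 2-DoF lumped chain: the total trunk reorientation
$\theta_{req}$ needed to point the hand at the intercept is split into a
lumbar contribution (`lumbar_share`) and a lumped hip/lower-limb
remainder. All profiles are minimum-jerk,
$s(\tau) = 10\tau^3 - 15\tau^4 + 6\tau^5$, whose peak rate is
$1.875\,A/T$ — that closed form is what the pipeline-recovery tests check
against. Gaussian measurement noise (default SD 0.3°) is added to angle
samples only, mirroring joint-angle noise; hand position is treated as
clean.

Intercept choice implements the freedom players have to intercept a launch
anywhere along its flight. A candidate sample qualifies if it lies within
the reach envelope (default 1.02 × arm length, capped at 1.05) of the
posture-matched shoulder and after the participant's ready time. The fish
game uses the `earliest_reachable` policy (catch it as soon as you can —
it will land in the water otherwise); the dodgeball game uses
`closest_to_intended` (block the ball as it arrives at your body). Reaches
degenerate to the static target. Contact is the closest approach between
hand and object, evaluated on a 10× refined grid because a ball at 8 m/s
covers several centimetres per 100 Hz sample; approaches within 5 cm count
as contact, otherwise the trial is a miss (a valid outcome, retained
downstream when the participant reacted).

Cohort-level behaviour is driven by a height- and game-dependent
lumbar-share strategy and per-game speed gains (dodgeball 1.8 × faster
than the 1.1 s base movement, fish 1.0, self-paced reaching 0.8),
plus per-participant variation: anthropometrics drawn around a ~1.72 m
adult (hip 0.93 ± 0.05 m, trunk 0.47 ± 0.03 m, arm 0.62 ± 0.04 m),
log-normal speed multipliers (SD 0.12), additive share shifts (SD 0.06)
and reaction times 0.35 ± 0.05 s. The strategy defaults encode the
qualitative behaviour reported for the real games — heavy lumbar
recruitment at all heights in the fast dodgeball game, steeply
height-dependent recruitment in self-paced reaching, the fish game in
between — so that a synthetic cohort shows the expected ordering (highest
lumbar velocities in dodgeball at every height) and a game × height
interaction. These values were fixed once, as a design choice, before the
acceptance checks were run.

**What passing tests do and do not show.** The generator produces data the
pipeline can analyse without special-casing, with known ground truth for
parameter-recovery tests, and the qualitative between-game structure. It
does *not* reproduce: the full 7-segment kinematic chain (ankle/knee/hip
redundancy is lumped into one angle), absolute velocity magnitudes of real
cohorts (the synthetic between-game contrasts are sharper than a human
cohort's), anticipatory or corrective movement, or the published ordering
of *anterior* impact locations across games (reaching > fish > dodgeball);
with a thin reach envelope all three games intercept close to the intended
points. Pattern-level conclusions about the pipeline and statistics
transfer to real data; biomechanical realism claims do not.

## Kinematic pipeline

Smoothing and differentiation use a 41-point, 4th-order Savitzky–Golay
filter at 100 Hz — the window spans 0.41 s, long relative to the noise and
short relative to a reach. The central least-squares coefficients come
from `signal::sgolay`; boundaries are mirror-padded (reflection about the
end samples, no repetition), a choice the source description leaves open.
A 4th-order fit reproduces polynomials up to degree 4 exactly in the
interior, which the tests exploit.

The analysis window runs from the movement cue to 200 ms after contact.
For misses with an attempted reach — retained by design — the window end
is not specified anywhere, so we close it at the peak of forward hand
displacement, the natural turn-around point of an attempted reach.

Excursion is **peak minus onset** of the smoothed lumbar angle within the
window, not end-minus-start ("net") and not max-minus-min: a flex-and-hold
reach makes peak-minus-onset the faithful reading of "flexion excursion".
Both definitions are implemented (`mode = "peak"` / `"net"`); peak is the
default. Excursion and peak velocity are invariant to constant offsets in
the angle series, so baseline conventions do not matter.

The study team excluded trials by visual review when a launch elicited no
lumbar response. As an automated, reproducible surrogate we exclude trials
with excursion below a configurable 2° threshold. Only right-hand trials
enter the aggregate (the fish game is played right-handed); per-cell means
over included trials form the participant × game × height table, and
missing cells are reported because the ANOVA needs a complete design.

## Statistical battery

The two-way repeated-measures ANOVA uses the standard fully-within
decomposition, each effect tested against its subject × effect
interaction. Sphericity is screened per effect with Mauchly's test on
orthonormal contrast scores; the chi-square approximation includes the
usual second-order correction term (base R's implementation computes one
factor of that term from the total variable count rather than the
contrast dimension — the difference is ~1e-4 in p and never changes a
decision at α = .05, as the cross-check test against `car::Anova`
documents). When Mauchly rejects at p < .05 — the published policy states
the correction but not the trigger threshold; .05 is our choice — both
degrees of freedom are multiplied by the Greenhouse–Geisser
$\hat\varepsilon = \mathrm{tr}(S)^2/(d\,\mathrm{tr}(S^2))$, which is exact
at its bounds ($1/d \le \hat\varepsilon \le 1$, and $\hat\varepsilon = 1$
for two-level factors).

Partial $\eta^2$ is computed from sums of squares and equals
$F\,df_1/(F\,df_1+df_2)$ identically — the identity that lets published F
statistics determine effect sizes. Thresholds 0.25 (moderate) and 0.64
(strong) are strict inequalities. LSD post hoc comparisons are uncorrected
paired t-tests by definition of the method. Simple effects fit a one-way
repeated-measures ANOVA of game at each height with its **own** error term
(whether the original analysis repooled error across heights is not
stated; per-height error terms are the conservative, self-contained
choice). The Shapiro–Wilk screen delegates to `stats::shapiro.test`
(Royston's algorithm); degenerate constant cells — which the generator can
produce, since the fish arc's vertical sampling grid is shared across
participants — return `NA` rather than failing the screen.

## Numerical choices and degenerate inputs

* Quadratic root selection: the low-arc root is the smaller $\tan\alpha$;
  discriminants within −1e−12 of zero are clamped to zero (grazing
  reachability).
* Savitzky–Golay on series shorter than the window is a length error, not
  a silent fallback.
* `choose_intercept` ties (several equidistant samples) resolve to the
  earliest sample.
* Movement duration for launch trials is capped so the hand arrives ~80 ms
  before the object, with a 0.25 s floor — a floor that can make a very
  fast launch physically unmissable to catch, which then records as a
  miss.
* All randomness flows through `withr::with_seed` with sub-seeds derived
  by `sample.int(2^31 − 1)`, so no call disturbs the caller's RNG state
  and every artifact is bit-reproducible per seed on one platform.

## Problem sizes

The test suite fits small ANOVA tables (4–12 subjects) against a
loop-coded sums-of-squares oracle and `car::Anova`, runs the null
calibration at 31 subjects × 2000 replicates, round-trips 1000 random
ballistic geometries per solver, and synthesises cohorts of 2–31
participants (a full 31-participant session is 2728 recordings). These
sizes keep every property estimate well inside its Monte-Carlo error while
the whole suite runs in about a minute.

## Known limitations

Planar kinematics only; no drag, spin or lateral motion; no duck
kinematics; no adaptive progression across sessions; the generator's
redundancy model is a two-joint lump, adequate for exercising the pipeline
and statistics but not for biomechanical inference; and the absolute
magnitudes of synthetic outcomes are design parameters, not predictions.
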