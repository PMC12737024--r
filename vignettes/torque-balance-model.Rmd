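---
title: "A frontal-plane torque-balance model of non-contact ACL injury"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A frontal-plane torque-balance model of non-contact ACL injury}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aclthresh)
```

## The model

During single-leg landing with the knee fully extended and the shank
leaning from the vertical by an angle $\alpha$ in the frontal plane, the
knee can rotate into abduction about the lateral femoral condyle. On a
perfectly slippery surface the ground reaction force (GRF) is purely
vertical, $F_y$, and drives abduction with lever $L \sin\alpha$, where
$L$ is the ground-to-lateral-condyle distance. Abduction is resisted by:

* the ACL at its ultimate tensile strength (2300 N) acting at the
  lateral-condyle-to-ACL distance;
* the MCL at its ultimate strength (799 N) acting at the
  lateral-condyle-to-MCL distance;
* the quadriceps (8000 N maximal force) pulling through the patellar
  tendon, taken to act midway between the condyles (half the
  intercondylar distance);
* the semitendinosus-semimembranosus group, modelled as 2 bodyweights of
  force acting at the MCL lever;
* bodyweight $m g$ acting at the centre of gravity, whose lever with a
  vertical trunk is the bi-acetabular half-distance plus the thigh length
  projected onto the horizontal, $d_{1/2} + T\sin\alpha$.

The balance of abduction and adduction torques about the lateral condyle,

$$F_y \, L \sin\alpha \;=\; C + m g\, T \sin\alpha,
\qquad C = F_{ACL} r_{ACL} + F_{MCL} r_{MCL} + \tfrac{1}{2} F_Q d_{IC}
+ 2\,m g\, r_{MCL} + m g\, d_{1/2},$$

defines the *critical GRF* at each shin angle; its inverse at a given
$F_y$ is the *angle of damage*. Landings whose GRF exceeds the critical
value at their shin angle are classified at risk (strictly: exact
equality balances and is classified safe).

Two extensions make the boundary condition a special case rather than the
only case:

* **Traction.** A Coulomb friction coefficient $\mu$ lets the horizontal
  GRF component (slip limit $F_x = \mu F_y$) oppose the lateral slide of
  the foot with lever $L\cos\alpha$, replacing the abduction lever by
  $L(\sin\alpha - \mu\cos\alpha)$, clamped at zero. $\mu = 0$ recovers
  the slippery-surface model exactly; any $\mu > 0$ raises the threshold
  at every angle below 90 degrees and leaves it unchanged at 90 degrees,
  where the GRF has no horizontal lever.
* **Activation fractions.** Each muscle and the ligament pair carries a
  fraction in $[0,1]$ scaling its contribution. The default of 1
  everywhere is the conservative full-activation convention used to
  locate the threshold; lowering a fraction models delayed or disturbed
  activation, and monotonically lowers the threshold.

## Parameters, units and defaults

All file interfaces carry distances in mm and mass in kg, matching how
such anthropometric measurements are reported; all internal computation
is in m, kg, N and N m. Angles are degrees everywhere at the interface.

The default anthropometric profile is the average of the reference cohort
of 15 young adult male handball players (means and SDs per variable), the
bi-acetabular half-distance is a literature constant (123.78 mm, SD 0
unless the user supplies one), and body mass is 80.2 +/- 6.8 kg. The
gravitational constant defaults to 10 m/s^2: the reference balance uses a
bodyweight of 802 N for the 80.2 kg average subject, which pins $g = 10$;
it is configurable, but the default reproduces the reference
coefficients bit-for-bit (e.g. the semitendinosus force
$2 \times 80.2 \times 10 = 1604$ N).

```{r coefficients}
p <- average_profile()
c(L = grf_abduction_moment_arm(p, 90),
  cog0 = cog_adduction_moment_arm(p, 0),
  acl = p$acl_moment_arm, mcl = p$mcl_moment_arm)
```

Two geometric identifications deserve mention because the reference
balance states them only numerically: the patellar tendon lever equals
half the intercondylar distance (only the quadriceps term carries the
factor 1/2; we read it as the tendon acting midway between the condyles,
and note the alternative bilateral-split reading without implementing
it), and the semitendinosus lever equals the MCL lever (the same value
appears for both terms), so it is stored once on the profile and reused.
The gastrocnemius medialis (931 N maximal force) does not appear in the
reference balance; it is excluded by default and available as an optional
term requiring a user-supplied moment arm, so the default model
reproduces the reference exactly. Bodyweight in the adduction term is the
full 802 N; whether the stance shank's share should be excluded is an
open modelling question we resolve in favour of reproducing the
reference.

## The threshold curve

```{r curve}
curve <- generate_curve(step = 0.5)
head(curve, 3)
critical_grf(30)
critical_grf(90)
angle_of_damage(2500)
```

The production grid runs from 0.01 to 90 degrees in 0.01-degree steps
(9000 points). It starts above zero because the zero-traction threshold
diverges as $\alpha \to 0$: with no horizontal lever the GRF cannot load
the abduction side at all. With $\mu > 0$ the singularity moves to
$\alpha = \arctan\mu$; grid cells at or below it carry an `Inf` sentinel
and an `unreachable` flag rather than erroring, so one curve object can
span both regimes. The curve is emitted both in newtons and in
bodyweight multiples ($F_y / m g$), the conventional axis for this
relation.

## The synthetic cohort generator

`synthesize_cohort()` emulates the reference cohort: each variable is
drawn independently from a Gaussian with the published mean and SD,
truncated below at the larger of mean minus 4 SD and 1 mm (1 kg for
mass) by rejection. The SDs are small relative to the means (3-7%), so
the truncation is almost never active and the sample moments recover the
population values; it exists to make nonphysical non-positive lengths
impossible. No covariances are published for the cohort, hence the
independence default; a user-supplied 7x7 correlation matrix switches to
correlated draws via a Cholesky transform. Identical seeds give
bit-identical cohorts.

What the generator does *not* emulate: real anthropometric variables are
mutually correlated (taller subjects have longer thighs and shanks),
tissue strengths vary across individuals (only the MCL has a published
spread, 799 +/- 209 N; tissue sampling is therefore exposed but disabled
by default), and the reference sample is 15 young male athletes, so the
population the generator describes is narrow. Passing tests therefore
show that the pipeline propagates the *stated* distribution correctly,
not that the bands cover a general population.

Body height is reported for the cohort but unused by the model, so the
profile does not store it.

## Monte Carlo propagation and sweeps

`cohort_thresholds()` evaluates the closed-form threshold per subject and
summarises with percentile bands (default 5/25/50/75/95). Percentiles
use linear interpolation between order statistics (`quantile()` type 7);
band values depend on this definition, so it is fixed and documented
rather than configurable. Because the threshold is nearly linear in the
anthropometric inputs over the +/- 4 SD range, the cohort median
converges to the average-profile value as the cohort grows (checked at
n = 10^4 within 1%). Sweeps are one-at-a-time around the reference
defaults; a full factorial design is out of scope.

The analysis scripts use n = 10 000 subjects for the propagated cohort
and n = 100 000 for the moment-recovery check; both run in seconds, and
at these sizes the Monte Carlo sampling error is small against the
anthropometric spread being propagated (the test suite checks the
cohort median against the average-profile value within 1% at n = 10^4).

## Numerical choices

* The closed-form solver is exact; an independent scalar root-find on
  the net torque (bisection via `uniroot`) serves as a cross-check in the
  test suite, agreeing to better than 1e-6 N on a 1-degree grid.
* Trigonometry uses `sinpi`/`cospi` so the endpoints are exact:
  $\cos 90^\circ$ is exactly 0 (the threshold at 90 degrees is exactly
  $\mu$-independent) and $\sin 0^\circ$ exactly 0.
* The zero-traction angle-of-damage inversion is closed-form,
  $\alpha = \arcsin\!\big(C/(F_y L - m g T)\big)$. $\arcsin$ is
  ill-conditioned where its argument approaches 1, so arguments within
  1e-14 of 1 (and forces within rounding of the 90-degree threshold)
  snap to 90 degrees; angles within about 1e-4 degrees of 90 are
  numerically indistinguishable in this inversion. With $\mu > 0$ the
  inversion brackets the torque residual between $\arctan\mu$ and 90
  degrees and bisects to a residual below 1e-9 N m.
* Forces below the 90-degree minimum threshold have no angle of damage
  and return `NA`; risk classification uses a strict inequality, so a
  landing exactly at the threshold is safe.
* Truncated-Gaussian draws use rejection resampling, which preserves the
  conditional-Gaussian law above the floor and keeps the seed contract
  simple.

## Limitations

The model is two-dimensional and frontal-plane only: no tibial rotation,
anterior translation, knee-flexion dependence, hamstring-to-quadriceps
ratio, or time-dependent activation dynamics. The trunk is assumed
vertical. Tissue forces are literature maxima for young adult men, so
thresholds are conservative (the true at-risk boundary for an individual
with weaker tissues or partial activation lies below the default curve),
and the model is not gender-specific. Torques are reported as unsigned
magnitudes about the lateral condyle with abduction positive; the
clockwise/counter-clockwise language of frontal-plane figures is
frame-dependent and not preserved. Outputs are deterministic model
thresholds given parameters, not epidemiological injury probabilities.
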