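---
title: "Adaptive load sensing in a dynamically scaled insect leg: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive load sensing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cssim)
```

`cssim` simulates the load feedback a stick insect's campaniform sensilla
(CS) would deliver during single-leg stepping, using a 15:1 dynamically
scaled robotic middle leg as the physical template. This vignette is the
package's methodological account: the discharge model and its numerical
treatment, the kinematic chain, the synthetic strain generator that stands
in for the physical robot, what the built-in experiments emulate, and the
design choices made where the problem was genuinely open.

## 1. The CS discharge model

Each of the four modeled CS groups (3 and 4 on the proximal dorsal
trochanterofemur, 6B and 6A on the proximal dorsal tibia) transforms a
scalar bending-load input $u(t)$ into a continuous firing-rate output
$y(t)$ through a single adaptive state $x(t)$:

$$
y = \max\bigl(0,\; a\,(u-x) + c\,u + d\bigr), \qquad
\tau \dot x = \operatorname{sign}(u-x)\,\lvert u-x\rvert^{\,b} .
$$

The threshold $x$ chases the input; $a(u-x)$ is the phasic term, $cu+d$
the tonic term, and the outer rectification keeps $y \ge 0$. With the
shared parameter set ($a = 338.9952$, $b = 2.2707$, $c = 7.1531$,
$d = -27.9311$, $\tau = 0.025$ s; group 6A: $d = -17.9311$) the model
shows every qualitative property expected of large CS: a burst at load
onset whose height grows with loading *rate* (approximately as
$\text{rate}^{1/b}$, the power-law rate code), adaptation under tonic
load, hysteresis under cyclic load, and silence during unloading. Because
group 6A's tonic threshold $-d/c \approx 2.51$ is lower than the
$\approx 3.90$ of the other groups, 6A fires tonically at loads where 6B
is already silent.

**Inputs are signed; only the output is rectified.** Each group reads its
own rosette element with its own sign (axial and transverse elements of
one rosette are antagonists: the transverse element reads
$-\nu\,\varepsilon_\text{axial}$). During stance the transverse groups (4,
6A) therefore hold a *negative* input, their threshold adapts to it, and
when the load releases and the input rises back toward zero they produce
the characteristic rebound burst. Half-wave rectifying the inputs instead
would pin the antagonist input at zero throughout stance and make the
rebound burst — the very signature of stance offset and foot slip —
unreproducible, which is why the signed convention is used.

### Numerical treatment

The threshold ODE is integrated per 1/60 s sample (the robot's serial
rate) with a zero-order hold on $u$, using classical fixed-step
Runge-Kutta with 10 internal sub-steps. Two properties of the flow shape
the implementation:

* The continuous solution approaches $u$ one-sidedly and never crosses
  it, but a finite step can. Every Runge-Kutta *stage state* and the step
  result are clamped at $u$; this both enforces the no-overshoot property
  and keeps the power-law derivative bounded when the gap is large.
* For constant $u$ the gap $e = u - x$ has the closed form
  $e(t) = \bigl(e_0^{\,1-b} + (b-1)\,t/\tau\bigr)^{-1/(b-1)}$. The test
  suite locks the integrator to this solution to within $10^{-3}$
  relative error; halving the sub-step changes the canonical
  ramp-hold-release peak by under $10^{-6}$ relative.

The power-law tail of that closed form is worth noting: for $b \approx
2.27$ the late-time gap decays only algebraically,
$e(t) \sim ((b-1)t/\tau)^{-1/(b-1)}$, *independently of the step size*.
Twenty time constants after a step the phasic remnant $a\,e$ is still
about 26 AP/s, for any step amplitude. "Convergence to steady state" is
therefore assessed the way settling is defined in control practice —
within a band of 1% of the response amplitude (peak minus steady state) —
on a full-scale step ($u: 0 \to 10$); a band defined as a percentage of
the steady-state value alone would not close in any realistic time for
this parameter set.

**Input normalization.** The discharge parameters assume an input of
order 0–10 (the tonic thresholds sit near 4). Physical strain is mapped
to this scale by one configurable factor per rosette,
`cs_input_scales()`; the defaults (820 for the trochanterofemur, 4190 for
the tibia) were calibrated once so that the baseline stepping scenario
peaks near $u \approx 5$ at each site, and are not otherwise tuned. The
initial threshold defaults to $x_0 = u(0)$ (fully adapted start), so a
recording that begins under load does not open with a spurious burst.

## 2. Kinematics

The leg is a three-joint chain (ThC, CTr, FTi) described by a product of
exponentials over revolute twists, with the published axis directions,
axis points and zero-configuration foot position (mm, body frame: x
anterior-posterior, y lateral, z dorso-ventral; the ThC axis is tilted
37° in the y–z plane). At zero angles the foot sits at
$(0, 362.42, -180.99)$ mm — a fully extended (singular) posture, which is
why inverse kinematics uses a *damped* Newton iteration on the $3\times3$
position Jacobian (residual tolerance $10^{-9}$ mm, 200 iterations,
Levenberg damping raised on step rejection). Path tracking warm-starts
each solve from the previous sample, keeping the angle series on one
solution branch; a per-sample jump guard turns branch changes into
errors. Unreachable targets raise a typed error carrying the residual.

The footpath generator produces one C¹ periodic cycle: stance is a
straight rearward sweep at treadmill speed on the ground plane
($z = -170$ mm, lateral offset $y = 260$ mm, touchdown at $x = 0$ by
default); swing is a single quintic in $x$ whose boundary conditions
(positions, end velocities equal to belt velocity, zero end
accelerations) force an anterior overshoot and return the foot to the
touchdown point already moving at belt speed — the velocity-matched
touchdown that avoids impact transients — plus a smooth quartic lift bump
(40 mm apex) with zero vertical velocity at both contacts. Defaults:
step period 4 s, belt speed 50 mm/s, duty factor 0.75, sampled at 60/s.
The foot line was placed where the tibia lands near-vertical, for reasons
described in §4.

## 3. Dynamic scaling

The simulator's time base follows the dynamic-scaling argument that the
ratio of step period to joint natural period should match between animal
and robot. Treating the insect leg as an 11 mg, 1.2 cm slender rod
pivoting at the femur-tibia joint gives $J = mL^2/3 = 5.28\times10^{-10}$
kg m²; with passive joint stiffness $10^{-6}$ N m/rad the natural period
$T_n = 2\pi\sqrt{J/k}$ is 0.14 s, about one sixth of the insect's ≈1 s
step. The robot's joint (rotor-dominated inertia $10^{-2}$ kg m², servo
feedback stiffness 1 N m/rad) has $T_n = 0.63$ s, and six times that —
rounded — is the 4 s robot step period used throughout. (The period
formula printed in the source description, $T_n = k/J$, is dimensionally
inconsistent; $2\pi\sqrt{J/k}$ reproduces both printed periods and is
what the package implements.) `body_mass_fraction()` records the
mass-distribution bookkeeping: 800 g total with under 100 g moving
relative to the carriage puts ≥87% of the mass in the "body", comparable
to a locust's ≈83%.

## 4. The synthetic leg

The physical robot measures strain; the simulator must synthesize it.
The generator is deliberately quasi-static: each leg segment is a rigid
link whose gauge site reads the elastic surface strain that the
instantaneous distal load would produce in a hollow-square beam
(1 cm × 1 cm, 1 mm wall, E = 2.4 GPa) — bending moment
$M = r \times F$ about the gauge section, projected on the segment's
dorso-ventral bending axis, through $\varepsilon = M\,(h/2)/(EI)$ with
the closed-form hollow-square $I$, plus the (small) axial-force term.
Sign convention: positive = compression of the dorsal face, so a
dorsally directed foot force reads positive. Inertial strain is neglected
— this is exactly the regime the dynamic scaling creates, and it yields
the free-leg property that motion without contact produces zero strain
and zero discharge.

The transverse rosette element is modeled as Poisson coupling only,
$\varepsilon_t = -\nu\,\varepsilon_a$ with $\nu = 0.35$: a rosette
centred on the dorsal face sits on the neutral axis for
anterior-posterior bending, so resolving AP bending onto it would be
inconsistent with the geometry and would also break the observed ≈180°
separation between axial and transverse directional-tuning maxima.

**Load schedule.** During stance the foot carries the carriage weight
(0.8 kg plus any added mass) as a vertical contact force; during swing it
is free. Force transfer at touchdown and lift-off is rate-limited at a
fixed 100 N/s — a property of the velocity-matched touchdown kinematics,
deliberately independent of the carried mass. This single assumption
reproduces the central load-sensitivity dissociation: the
trochanterofemoral strain *rate* at touchdown (and hence group 3's
rate-coded burst) is nearly load-invariant, while the tibial strain grows
through stance at a rate proportional to the carried mass (the foot lands
under the knee and the tibial moment arm opens as the leg sweeps back),
so the tibial discharge encodes body load. The foot line defaults were
chosen once to produce exactly these shapes — near-zero tibial strain at
touchdown, monotone growth to end-stance, trochanterofemoral strain
several-fold larger throughout — and are not otherwise adjusted. With no
relative foot-belt motion the tangential force is zero in normal stance;
a friction coefficient (μ = 0.4) is carried in the configuration for
sliding-contact variants.

**Signal chain.** Strain → quarter-bridge voltage (0.4 V/strain) →
amplifier (gain 250) → slow sinusoidal offset drift (default 5 ADC counts
over 60 s, emulating trimpot/temperature drift) and Gaussian noise
(default 2 counts) → clipping to the 0–3.3 V ADC range (flagged, not an
error) → 12-bit quantization → centred 13-sample moving median
(`stats::runmed`). The median window suppresses single-sample artifacts
exactly while passing monotone ramps unchanged, so edges are not delayed.
All noise is seedable; a fixed seed reproduces a record bit for bit.

## 5. The experiment protocols

All five protocols run through `run_experiment()` with parameters
validated per protocol; magnitudes the hardware description leaves open
are defaults chosen once to emulate the published traces:

* **Ramp-hold-release** (fixed / free): commanded CTr angle trapezoid
  (amplitude 1.5 rad, 0.5 s ramps, 2 s hold); with the distal end fixed
  the servo's feedback stiffness (1 N m/rad) converts angle displacement
  to bending moment, giving a trapezoidal strain near $u \approx 5$;
  free, strain is identically zero.
* **Asterisk**: leg at zero configuration, an 8 N force at the distal
  trochanterofemur cycling through 12 directions at 30° spacing in the
  segment's dorso-ventral / anterior-posterior plane, 1 s dwell with
  return to centre; the polar summary averages the central 60% of each
  hold.
* **Stepping load**: treadmill stepping with 0, 500 or 1000 g added.
* **Transient load**: a 4.9 N half-sine (0.5 s wide, starting 1.25 s into
  stance) added to the vertical force — the cable-pull perturbation
  modeled directly as a force profile.
* **Slip**: foot contact lost for 0.4 s starting 1.5 s into stance
  (sudden drop, rate-limited recovery). Contact loss is used rather than
  a capped tangential force because the emulated event is the tarsus
  breaking contact, after which the tibia is simply unloaded.

The stance-event detector marks stance onset at upward threshold
crossings of group 3 and stance offset at bursts of group 4 (default
threshold: 10% of the run's peak discharge, 1 s refractory), and reports
timing errors against the ground-truth phase labels. Across the three
load conditions it detects 100% of transitions with errors well under
0.2 s, the offset error being dominated by the anticipatory unloading
ramp (≤0.18 s at 1000 g).

Load sensitivity is summarized per group as the ratio of peak discharge
at 1000 g to baseline; a site's sensitivity is that of its most
load-sensitive group. (The tibial site's *absolute* peak is its 6A
lift-off rebound, which is rate-limited and hence load-insensitive by
construction; the load information lives in 6B's stance discharge, ratio
≈1.5–1.6 versus ≈1.15 for group 3.)

## 6. What the generator does and does not emulate

Passing tests on this synthetic leg demonstrate that the *discharge
model* behaves correctly given beam-theory strain under the stated load
schedule. Real robot (and animal) data differ in ways the generator
deliberately omits: touchdown impact transients and carriage bounce
(excluded by the quasi-static assumption and the idealized
velocity-matched touchdown), servo torque ripple, temperature-dependent
gauge drift beyond the sinusoidal stand-in, compliant-tarsus mechanics,
and inertial strain at speeds that violate dynamic scaling. Two known
divergences from the published robot traces: during slip the
trochanterofemoral strain here *decreases* (both sites unload under
contact loss) whereas the robot showed an increase, and the
trochanterofemoral strain does not decline mid-stance as strongly as the
robot's. Neither affects the slip signature carried by the tibial groups
(6B silenced, 6A burst). The model also emulates only the large,
strongly adapting CS population; the small, tonically discharging
receptors would need a second parameter set.

Problem sizes used throughout the documentation and tests (20-step runs,
60 samples/s, 10 integration sub-steps) are the package's defaults and
complete in seconds on a single core.
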