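---
title: "Conductance catheter volumetry: models, inversion and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conductance catheter volumetry: models, inversion and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvcond)
```

## The measurement problem

A tetrapolar catheter inside the left ventricle injects a current through
its outer electrode pair (spacing $d$) and measures the resulting voltage
across its inner pair (spacing $L$). The ratio is a conductance $G$ that
grows with the amount of conductive blood around the catheter, and hence
with the cavity radius $R$. Conductance volumetry turns a measured $G$
into a radius estimate and then into a ventricular volume. Two physical
effects make the naive picture inaccurate: part of the current leaks into
the myocardium and the tissue behind it (*parallel conductance*), and the
field geometry itself is altered both by the conductivity step at the
blood--muscle boundary and by the presence of the measurement electrodes.

`lvcond` implements three analytical calculation methods (ACMs) for the
forward map $G(R)$, inverts them through lookup tables, and ships the
bench-style fixtures and agreement statistics used to compare them.

## Geometry, units and compartments

An `electrode_config(r0_mm, d_mm, L_mm)` describes the catheter: injection
electrodes modelled as spheres of radius $r_0$ at $z=\pm d/2$ on the axis,
measurement electrodes at $z=\pm L/2$, with $r_0 < L/2 < d/2$. A
`tissue_model()` holds three concentric compartments: blood out to the
cavity radius $R$ (conductivity $\sigma_{bl}$), a muscle shell of
thickness $b$ ($\sigma_m$), and background from $R+b$ out to an outer
radius that may be infinite ($\sigma_{ba}$); the compartment conductance
integrals converge, so the unbounded case is well defined.

All lengths cross the API in millimetres and are converted to metres
internally; with conductivities in S/m every conductance is in siemens.
The drive strength enters only through $k = V_0 r_0$ and cancels from
every conductance, so $V_0$ defaults to 1 V.

## The three forward models

**Wei (two point charges).** The injection pair is idealised as two
opposite point charges. Integrating the current density over the mid-plane
annulus $[r_0, R]$ and the field along the axis between the measurement
electrodes gives

$$G_{\mathrm{wei}}(R) = \frac{\pi\sigma\, d\,(d^2-L^2)}{2L}
  \left(\frac{1}{\sqrt{d^2+4r_0^2}} - \frac{1}{\sqrt{d^2+4R^2}}\right).$$

The same expression with the annulus moved to $[R_{in}, R_{out}]$
(`annulus_conductance()`) yields the muscle and background terms; the
bracketed kernel telescopes, so compartments add exactly. A frequently
quoted variant of this closed form omits the factor $d$ and halves the
denominator; that variant is dimensionally inconsistent (it yields S/m,
not S), and the form above is the one certified against direct quadrature
of the defining field integrals (see *Numerical oracle* below).

**Plate (sphere + charged disc).** Because blood conducts better than
muscle, the field refracts at the boundary and is compressed into the
cavity. The plate ACM emulates this by replacing one charge with a
uniformly charged disc of the cavity's cross-sectional radius at $z=0$,
superposed with a single charged sphere at $z=d/2$. The disc's field is
purely axial, $E_z = k\,(2/R^2)\,(\mathrm{sign}(z) - z/\sqrt{z^2+R^2})$.
Carrying out the same two integrals (the voltage as twice the integral
over $[0, L/2]$, using the mirror symmetry of the arrangement about the
disc plane) gives the blood term in closed form; muscle and background
reuse the Wei-style annulus extension. The uniform charge assumption
degrades once $R$ approaches $L$, so radii with $R \ge L$ are flagged as
outside the model's validity range (they remain computable — the bench
comparisons apply the plate method to large containers precisely to show
its underestimation there).

**Lead (reciprocity-consistent).** Swapping the roles of injection and
measurement electrodes must not change a tetrapolar measurement. The
two-sphere idealisation satisfies this for the voltage
($V_d = V_L = V_{all}$) but not for the currents. The lead ACM restores
reciprocity by weighting the two fields equally, which forces the
geometric-mean current $I_{lead} = \sqrt{I_L I_d}$, so each compartment
contributes $G = \sqrt{|I_d I_L|}/|V_{all}|$ with both currents taken over
that compartment's annulus with its conductivity. We write $V_{all}$ in
the manifestly symmetric form $4k(1/|d-L| - 1/(d+L))$, making the
implementation invariant under the $d \leftrightarrow L$ interchange to
machine precision rather than only analytically.

Signs: the printed integrals of these models carry orientation-dependent
minus signs; `lvcond` reports all conductances as positive magnitudes,
the ratio of consistently oriented current and voltage.

## Numerical oracle

Every closed form above is re-derived in the package from the field
definitions, and then certified against an independent path:
`numeric_current()` and `numeric_voltage()` integrate the field functions
themselves (adaptive quadrature, relative tolerance $10^{-10}$ with an
absolute floor of $10^{-15}$ for near-zero integrals). The test suite
requires agreement to a relative $10^{-6}$ on a grid of 25 geometry-radius
combinations per method; the observed worst case is at rounding level
($\sim 10^{-14}$).

One technical point: checking $V_d = V_L$ requires integrating the
$L$-spacing dipole's field along $[-d/2, d/2]$, a path that crosses both
charges. The integral exists as a Cauchy principal value (it is the
potential difference of the endpoints), and `numeric_voltage()` evaluates
it by integrating a symmetric window around each crossed charge as the
pair $E(z_0+u) + E(z_0-u)$ with that charge's own term dropped — the
dropped term's symmetric principal value is identically zero, and the
remaining pair integrand is regular. The exclusion is done analytically
(per-charge term decomposition), not by subtracting large numbers, so the
check holds to $10^{-9}$ and better.

## Inversion

None of the forward maps inverts in closed form, so `build_lookup_table()`
samples $G(R)$ on a uniform grid — by default 2000 points on
$[r_0 + 0.5\,\mathrm{mm}, 80\,\mathrm{mm}]$, wide enough for severely
dilated ventricles — verifies strict monotonicity at build time, and
`radius_from_conductance()` interpolates the inverse with a monotone
Fritsch--Carlson piecewise cubic (knot conductances map back to their
radii exactly; the estimate is non-decreasing in $G$). The round-trip
error at this resolution is below $10^{-6}$ mm, far inside the 0.01 mm
contract the tests enforce. Conductances outside the table span are
clamped to the nearest endpoint and flagged `in_range = FALSE` rather
than rejected, since noisy measurements can fall marginally outside.

Two degenerate situations are handled deliberately. For plate tables
extending beyond $L$, a `plate_policy` of `"warn"` (default),
`"truncate"` or `"error"` decides between flagging, cutting the grid at
$L$, or refusing. And with an (almost) insulating wall in front of a
conductive background, the *total* $G(R)$ is slightly non-monotone within
roughly 1 mm of the catheter surface, where the shrinking background
annulus outweighs the tiny blood increment; `run_validation()` therefore
spans its lookup grid from half the smallest reference radius instead of
from the catheter surface. Radii that close to the electrode are outside
any measurement scenario of interest, and the monotonicity gate still
protects every table that is actually built.

## Volumes

`wyatt_volume()` implements $LVV = \tfrac{5}{6}\pi R^2 LV_h$ with the
ventricle height $LV_h$ as the single remaining calibration length;
`cylinder_volume()` is the plain $\pi R^2 L$ of the classical method (a
sometimes-quoted form of that model drops the $\pi$, which we read as
typesetting loss — a cylinder volume without $\pi$ is not a volume).
`equivalent_radius_from_area()` converts a CT cross-sectional area to the
radius of the equal-area circle, $\sqrt{A/\pi}$, the reference radius used
for non-circular phantom sections.

## Fixtures, synthetic measurements and what they do (not) show

The package reproduces the two bench setups as fixture generators:
five cylindrical glass containers (radii 13.3, 17.5, 32.8, 38.6,
50.4 mm; insulating wall and surround) at two saline conductivities
(1.68 and 0.62 S/m — one source figure quotes 1.69; we use the body-text
1.68), and a ventricle-shaped silicone phantom at six filling steps whose
reference radii come from the CT areas via $\sqrt{A/\pi}$, in saline of
0.7 S/m inside a 0.2 S/m tank, with a wall that is either effectively
insulating ($10^{-6}$ S/m) or carbon-doped conductive (0.3 S/m). The
phantom wall thickness is not on record; we default to 10 mm
(configurable). The default catheter geometry ($r_0 = 1$, $d = 40$,
$L = 20$ mm) is likewise a package default chosen to be plausible for an
LVAD-carried catheter, not a documented bench value.

Raw bench conductance recordings were never published, so
`simulate_measurements()` stands in for them: the forward model value at
the fixture's true radius with multiplicative Gaussian noise
($G_i = G\,(1+\varepsilon_i)$, default SD 2%, seeded and reproducible),
reflecting that impedance-analyzer noise scales with signal. This
generator emulates measurement repetition noise only. It does not emulate
catheter decentring or tilt, longitudinal placement error (to which real
measurements are quite sensitive), electrode polarisation, non-circular
cross-sections, or conductivity drift. Consequently the closed-loop
tests (simulate, invert with the same model, compare) demonstrate the
numerical correctness of the model/inversion pipeline — they cannot and
do not validate the physics against a real bench. The published bench
agreement figures are therefore kept verbatim in
`reference_agreement()` as orientation constants, explicitly not as
reproduction targets; what the package *does* reproduce is their
structure: cross-model runs (lead-generated conductances inverted with
the classical insulating model) show the classical method's large
positive radius bias, e.g. about +120% for the conductive-wall phantom
series, matching the reported sign and order of magnitude.

## Statistics

`bias_loa()` computes Bland–Altman agreement normalised by the mean
reference radius: bias is the mean of (estimated − reference) as a
percentage of the mean reference, and the limits of agreement are 1.96
sample standard deviations (denominator $n-1$) of those differences on
the same scale. Both come with `tidy()`/`glance()` methods, and
`run_validation()` wires simulate → invert → agreement into one call.

## Problem sizes and determinism

The shipped test-suite and acceptance computations use 2000-point lookup
tables, 25-point oracle grids, 50 random geometries for the reciprocity
property, 100 random radii per method for round-trips, and 5–100
simulated measurements per fixture — sizes at which every reported
quantity is stable to well below its tolerance while the whole suite runs
in seconds. All stochastic steps take explicit integer seeds;
`simulate_measurements()` restores the caller's RNG state.

## Known limitations

* The three ACMs share the axisymmetric, centred-catheter idealisation;
  none models catheter displacement or non-circular chambers.
* The plate model's uniform charge assumption makes it a small-radius
  ($R < L$) method; beyond that it systematically underestimates.
* Compartment corrections treat muscle and background as concentric
  shells sensed through the same field as the blood; no refraction is
  computed at the shell boundaries (an analytic solution of that boundary
  problem does not exist — the plate construction is a deliberate
  workaround, not a solution).
* Frequency dependence (complex impedance), electrode polarisation and
  multipolar (>4 electrode) configurations are out of scope.
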