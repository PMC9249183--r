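---
title: "Casson flow through stenosed and post-stenotically dilated vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Casson flow through stenosed and post-stenotically dilated vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

## The model

`stenoflow` implements the steady, incompressible flow of a Casson
(yield-stress) fluid — the standard low-shear rheology for blood — through an
inclined, axisymmetric vessel whose wall carries cosine-shaped abnormal
segments: stenoses (narrowings) and post-stenotic dilatations (widenings).
Besides the pressure gradient $P = \partial p/\partial z$, the fluid is driven
by two constant dimensionless body forces: a magnetization constant $M$ and a
gravity term $f = F\sin\phi$ set by the inclination angle $\phi$. All
quantities are dimensionless: radii are scaled by the healthy vessel radius
$R_0$, axial lengths by the vessel length, and the viscosity is absorbed into
the scaling, so $\mu = 1$.

### Wall geometry

Segment $i$ with signed height $\delta_i$ (positive for a stenosis, negative
for a dilatation), length $L_i$ and upstream gap $d_i$ occupies
$[\alpha_i, \beta_i]$ with $\beta_i = \sum_{j\le i}(L_j + d_j)$ and
$\alpha_i = \beta_i - L_i$. Inside it the wall radius is

$$H(z) = R_0 - \frac{\delta_i}{2}\left[1 +
  \cos\frac{2\pi}{L_i}\Bigl(z - \alpha_i - \frac{L_i}{2}\Bigr)\right],$$

and $H \equiv R_0$ elsewhere. The bump vanishes continuously at both ends and
attains its full height at the segment midpoint (the *throat* of a stenosis).
Users state heights as positive magnitudes plus an explicit `kind`
(`stenosis`/`dilatation`); the sign is applied internally so it cannot be
mistyped.

The closed form rests on the mild-stenosis approximation
($|\delta_i| \ll L_i$ and $|\delta_i| \ll R_0$), under which the flow is
locally Poiseuille-like at each station. `validate_mild_stenosis()`
operationalizes "much smaller than" as a ratio threshold (default 0.3) and
*reports* rather than enforces, because the anchor values used throughout the
published parameter studies ($\delta = 0.05\ldots0.15$, $L = 0.2$) themselves
exceed a literal reading. A `strict = TRUE` mode promotes flags to errors.
The outlet radius entering the second constraint is never specified
numerically in the source material; since every lesion closes up at its ends,
we take it equal to $R_0$.

### Per-station Casson solution

With the local momentum balance $\tau(r) = D\,r/2$, drive $D = M + f + P$,
and the Casson law $\sqrt{\tau} = \sqrt{\tau_0} + \sqrt{-\mathrm{d}u/\mathrm{d}r}$
above the yield stress $\tau_0 = D\,r_0/2$, the velocity has a rigid plug core
of radius $r_0$ and, for $r_0 \le r \le H$,

$$u(r) = \frac{D}{2}\left[\frac{H^2 - r^2}{2}
  - \frac{4}{3}\sqrt{r_0}\,(H^{3/2} - r^{3/2}) + r_0 (H - r)\right],$$

which satisfies no-slip $u(H) = 0$ and a shear-free plug rim. Integrating over
the cross-section gives the Buckingham–Reiner-type flux relation
$Q = g(H, r_0)\,D$ with conductance

$$g(H, r_0) = \frac{H^3 r_0}{6} + \frac{H^4}{8} - \frac{r_0^4}{168}
  - \frac{2}{7}\sqrt{r_0}\,H^{7/2},$$

collapsing to the Newtonian $H^4/8$ at $r_0 = 0$. The plug radius is treated
as a free input, as the published sweeps do; `plug_radius_from_yield()`
provides the optional converter $r_0 = 2\tau_0/|P|$ from the core force
balance.

### Axial assembly, impedance and wall shear stress

The pressure drop is $\Delta p = \int_0^{L_\mathrm{dom}} P(z)\,\mathrm{d}z$,
the impedance $\lambda = \Delta p / Q$, and both are normalized by the
healthy-tube values over the *same* domain length
($\bar\lambda = \lambda/\lambda_n$, $\bar\tau_w = \tau_w/\tau_{wn}$ —
a ratio over mismatched lengths would be meaningless). The wall shear stress
at a station is $\tau_w = Q(\sqrt{H}-\sqrt{r_0})^2/(2g)$ in its
velocity-gradient form. Because the published figures report a single
$\bar\tau_w$ per parameter set without naming the station, we evaluate at the
throat of the varied lesion by default — the clinically and mathematically
distinguished station — and accept any axial coordinate.

### The two sign conventions (`mode`)

The flux relation $Q = g\,(M + f + P)$ inverts to
$P = Q/g - (M+f)$, yet the published pressure-gradient and wall-shear
formulas carry the opposite sign on the flux term and an additive $(M+f)$ in
$\tau_w$: $P = -Q/g + (M+f)$ and
$\tau_w = Q(\sqrt{H}-\sqrt{r_0})^2/(2g) + (M+f)$. Both are exposed:

* `mode = "paper"` (default) — the published forms; these are what produce
  the reported qualitative responses of $\bar\lambda$ and $\bar\tau_w$ to
  $M$ and $\phi$, and are therefore the reproduction target.
* `mode = "derived"` — the self-consistent inversion; the physically
  meaningful choice for the velocity-gradient wall shear stress, and the one
  verified against the finite-difference oracle.

With $M = f = 0$ the two differ only by an overall sign, and the normalized
ratios coincide — a property test asserts this.

A consequence of the published form worth knowing: the healthy-tube pressure
gradient $-Q/g(1, r_0) + (M+f)$ changes sign where $g(1, r_0) = Q/(M+f)$
(near $r_0 \approx 0.127$ at the anchor values $M = 2$, $F = 0.3$,
$\phi = \pi/6$, $Q = 0.1$). $\lambda_n$ crosses zero there, so the
$\bar\lambda$-versus-$r_0$ curves have a pole inside the default sweep range
and the family ordering by stenosis height reverses below it. Tests
therefore pin the height-ordering assertions to the anchor plug radius
$r_0 = 0.2$, beyond the sign change.

## Parameters and defaults

| Parameter | Meaning | Default | Units |
|---|---|---|---|
| `height` ($\delta_i$) | lesion height magnitude | 0.1 | fraction of $R_0$ |
| `length` ($L_i$) | lesion axial extent | 0.2 | fraction of vessel length |
| `gap` ($d_i$) | distance from previous segment | 0.2 / 0.6 | same |
| `plug_radius` ($r_0$) | unyielded core radius | 0.2 | fraction of $R_0$ |
| `M` | magnetization constant | 2.0 | dimensionless |
| `F` | gravity constant | 0.3 | dimensionless |
| `phi` ($\phi$) | inclination angle | $\pi/6$ | radians |
| `flux` ($Q$) | volumetric flux | 0.1 | dimensionless |
| `mode` | sign convention | `"paper"` | — |
| `quadrature_points` | axial node budget | 2001 | nodes |

These defaults are the anchor values printed with the published parameter
studies. The default domain length is $\max(1, \beta_\mathrm{last})$ — with
the default gaps and lengths the second lesion ends at $\beta_2 = 1.2$, and
truncating a lesion mid-bump is never acceptable; a literal unit-length
domain remains configurable.

## Numerical choices

* **Quadrature.** Composite Simpson with panels aligned to the segment
  boundaries, where $H(z)$ has derivative kinks; within each panel the
  integrand is smooth. The default budget of 2001 nodes is far into the
  converged regime — node doubling changes $\Delta p$ by less than $10^{-8}$
  relative (a test asserts this), and at the anchor parameters the change is
  at rounding level.
* **Oracle tolerances.** The closed forms are guarded by brute force:
  adaptive quadrature of the flux integral ($10^{-8}$ relative), a
  Richardson-extrapolated finite difference for the wall shear stress
  ($10^{-6}$ relative), and the Casson constitutive residual measured with
  numerically differentiated velocities ($10^{-8}$ absolute). The
  tolerances are chosen to separate transcription errors in the closed
  forms (order-one effects) from floating-point noise.
* **Degenerate inputs.** $r_0 = H$ is a valid degenerate station (zero
  velocity, zero flux) for the velocity and flux routines; the
  pressure-gradient inversion rejects it as a zero-conductance station. A
  plug core wider than the narrowest lumen raises a classed error naming
  the worst axial station. Ties at shared segment boundaries resolve to the
  segment starting there; the wall radius is identical either way by
  continuity.
* **Determinism.** The entire pipeline is closed-form plus fixed
  quadrature; repeated runs are bit-identical, which the figure-suite test
  checks byte for byte.

## The sweep engine and trend expectations

`run_sweep()` varies one of $\delta_1$, $\delta_2$, $M$, $\phi$, $r_0$ over
a grid (defaults: 21 uniform points over $[0, 0.2]$ for heights,
$[0.01, 0.4]$ for $r_0$, $[0, 4]$ for $M$, $[0, \pi/2]$ for $\phi$ —
bracketing every anchor value while keeping the plug inside the lumen), with
an optional second "family" parameter giving one curve per value. Wall shear
stress and velocity are reported at the throat of the lesion being varied,
so the response actually reflects the sweep; the velocity is reported both
on the axis (`u_center`) and at a fixed probe radius (`u_at_r`, default
0.2), the two defensible readings of the published velocity studies, whose
radial evaluation point is not stated. Sweeps of a single lesion set the
other height to zero, isolating one lesion per study.

`monotonicity_report()` sign-tests successive finite differences of a
response against the shipped `default_trend_expectations()`: normalized
impedance and throat wall shear stress increase with stenosis height and
decrease with dilatation height; velocity decreases with stenosis height
and plug radius, and increases with dilatation height, magnetization and
inclination. The concluding summary of the study that introduced this model
states the *opposite* direction for the stenosis-height response of
$\bar\lambda$ and $\bar\tau_w$; its abstract and figure-by-figure
descriptions state the directions encoded here, and the discrepancy is noted
in the expectation `source` strings rather than reconciled silently.

`figure_suite()` regenerates the 24 multi-curve parameter studies
(`fig02`–`fig25`) as CSV + plot pairs. Two of the wall-shear-stress studies
print anchor values with magnetization and plug radius apparently
transposed ($r = 2.0$ would put the plug outside the lumen everywhere, which
is non-physical and cannot be run); they are generated with the standard
anchors and flagged in the returned manifest.

## What the tests do and do not show

The test suite runs entirely on the model's own closed forms at desk scale:
48-point verification grids, 21-point sweep grids, 2001-node quadrature —
seconds of runtime. Passing shows that the implementation solves *this*
model exactly as stated and reproduces its qualitative parameter responses.
It does not validate the model against measured hemodynamics: the mild-
stenosis approximation, steady flow, rigid walls, axisymmetry and a constant
(z-independent) plug radius are all idealizations, and the `paper`-mode sign
convention is a reproduction choice, not a physical claim.

## Worked example

```{r example}
sol <- solve_config(default_config())
sol
```

The normalized impedance and throat wall shear stress sit a few percent
above one: the stenosis raises both relative to a healthy tube, partially
offset by the dilatation. The negative $\Delta p$ is the literal integral of
the published pressure-gradient form; `sol$abs_delta_p` is provided for
plotting parity.

```{r trends}
cfg <- default_config()
cfg$geometry$segments[[2]]$height <- 0  # stenosis in isolation
tab <- run_sweep(sweep_spec("delta1", grid = seq(0, 0.15, 0.05)), cfg)
tab[, c("swept_value", "lambda_bar", "tau_bar_w", "u_center")]
```

## Known limitations

* Non-axisymmetric or overlapping lesions, tapered baselines and
  elastic/moving walls are out of scope.
* The plug radius is uniform along the vessel; the coupled problem with
  $r_0(z)$ set locally by the yield stress is not solved.
* `paper`-mode velocities can turn negative at strongly constricted
  stations where the flux term dominates the body forces; this is a
  property of the published sign convention, preserved deliberately.
* Pulsatile flow, wall compliance and turbulence are not modelled.
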