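---
title: "The linear-response loss model behind ferroheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The linear-response loss model behind ferroheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferroheat)
```

## Scope and assumptions

`ferroheat` predicts the heating power of a dilute suspension of
single-domain superparamagnetic nanoparticles in a sinusoidal magnetic
field. The model is *linear response* (Debye) theory: the magnetization is
assumed to follow the field as a first-order system with a single effective
relaxation time per particle size class. That assumption holds when the
magnetic energy per particle is small against the thermal energy — in
practice for core diameters below about 20 nm and field inductions below
about 10 mT. The package warns (but does not refuse) outside this envelope;
hysteresis-type (Stoner–Wohlfarth) losses, field-dependent relaxation
corrections, interparticle interactions and eddy currents are out of scope,
so predictions for large particles or strong fields are underestimates of a
physically different regime, not noisy versions of a correct answer.

A polydisperse fluid is treated as a sum of independent monodisperse
sub-fluids ("size groups"): each group gets its own relaxation time and
chord susceptibility, and powers add. This superposition is exact within
linear response and is tested as such (twelve-group total equals the sum of
twelve single-group runs, to machine precision).

## Relaxation

Two channels act in parallel:

* **Néel**, `τ_N = τ₀ exp(K_a V_p / k_B T)` — internal moment flipping over
  the anisotropy barrier; exponential in core volume, so it spans many
  decades across a 3–15 nm grid.
* **Brownian**, `τ_B = 3 V_h η / k_B T` — rigid rotation of the whole
  particle; linear in the carrier viscosity and in the hydrodynamic volume,
  which includes the surfactant shell (2·δ added to the diameter).

The effective time is the harmonic combination `τ = (τ_N⁻¹ + τ_B⁻¹)⁻¹`: the
faster channel wins. When the Néel exponent would overflow double precision
(exponent > 700) the Néel time saturates to `+Inf` rather than erroring —
a thermally blocked moment simply leaves the Brownian channel in charge,
and the harmonic combination degrades gracefully.

The crossover diameter (where `τ_N = τ_B`) is found by bracketed root search
on `log τ_N − log τ_B`, which is analytic in `d` and immune to the overflow;
the default bracket is 1–100 nm and the root is polished to a relative
tolerance of 1e-10. Note the direction of its viscosity dependence: thinning
the carrier lowers `τ_B` everywhere, so the steeply rising `τ_N(d)` meets it
*earlier* — the crossover moves to smaller diameters as viscosity falls
(equivalently, as temperature rises). This falls out of the monotonicity of
the two laws and is verified numerically in the tests.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `tau0` | 1e-9 | s | Néel attempt time; standard literature value |
| `delta` | 1e-9 | m | surfactant thickness (fatty-acid capping ≈ 1 nm) |
| `K_a` | 4.7e4 | J/m³ | effective anisotropy; the dominant calibration knob |
| `M_d` | — | A/m | bulk saturation magnetization (400 kA/m for maghemite) |
| `rho_m` | 4860 | kg/m³ | maghemite mass density |

`K_a` deserves emphasis. Bulk maghemite crystalline anisotropy is only a few
kJ/m³, but effective single-particle anisotropies inferred from relaxation
measurements are far larger because surface and shape contributions dominate
at these sizes; 47 kJ/m³ is the standard effective value for maghemite
nanoparticles in the hyperthermia-modelling literature. We adopt it as the
default because it places the Néel/Brownian crossover near 12 nm for a
mineral-oil carrier (η ≈ 75 mPa·s at 20 °C), consistent with where maghemite
ferrofluids are observed to hand over between mechanisms. A bulk-like
10 kJ/m³ would push the crossover above 20 nm and make every group in a
3.5–14.5 nm fluid Néel-dominated with much longer times — materially
different SAR predictions. Treat `K_a` as *the* quantity to calibrate
against a relaxation or susceptibility-spectroscopy measurement of your own
sample; everything downstream inherits its uncertainty.

## Field response and power

For each axis the chord susceptibility is
`χ = (φ_d M_d / H) · L(α)` with the Langevin function
`L(α) = coth(α) − 1/α` and `α = µ₀ V_p M_d H / k_B T`. "Chord" means the
secant slope of the equilibrium magnetization curve at amplitude `H` rather
than its tangent at zero — the standard linearization for a finite-amplitude
drive. Numerics: `L` is evaluated by its series `α/3 − α³/45` below
`α = 1e-4`, where the coth form loses digits to cancellation; the branches
agree to better than 1e-12 at the switch. At exactly `H = 0` the chord
expression is 0/0 and the analytic initial susceptibility
`φ_d µ₀ V_p M_d² / 3 k_B T` is returned instead.

The magnetization phasor is `M = χ h / (1 + iωτ)` per axis, with `h_x = H_x`
and `h_y = iH_y` (quadrature) for a rotating field, and the time-averaged
volumetric power is

`P = (µ₀/2) Re Σᵢ [iω M_xi h_x* + iω M_yi h_y*]`.

The implementation deliberately evaluates this complex expression — not the
equivalent real closed form `(µ₀/2) χ H² ω²τ/(1+(ωτ)²)` — so the phasor
algebra itself is exercised; the closed form lives only in the test suite as
an independent oracle (1000 random draws, relative agreement < 1e-12, and a
numerically integrated Debye ODE as a second, slower oracle). Two structural
consequences are tested exactly: a rotating field with matched per-axis
amplitudes dissipates exactly twice the alternating power, and dissipation
peaks at `ωτ = 1`.

### SAR conventions

Model power is per m³ of fluid; calorimetric SAR is per kg of magnetic
material. The default conversion divides `P` by `φ·ρ_m` (kg of magnetic
material per m³ of fluid), which is the only convention commensurable with
the initial-slope estimator's `m_Fe` normalization. A literal `P/ρ_m`
variant is exposed (`convention = "literal-eq7"`) because part of the
modelling literature normalizes that way; the two differ by the factor `φ`
(≈9.5× here), so mixing them is the easiest way to be wrong by an order of
magnitude when comparing to published curves. Both are computed from the
same `P`; nothing else changes.

## Size distribution

The total volume fraction comes from magnetometry: `φ = M_s,fluid / M_d`
(10.575% for 42.3/400 kA/m). Diameter observations are converted
number→volume by weighting each particle with `d³`, fitted with a log-normal
law by maximum likelihood on log-diameters — closed form, deterministic, no
optimizer — and the arithmetic mean/sd recovered through the standard moment
relations. For an exact log-normal, volume weighting multiplies the median
by `exp(3σ²)` with unchanged shape; the fit recovers this analytically known
shift on synthetic data within sampling error.

The per-group fractions that enter the power sum are, by default, the
*empirical* per-group volumes rescaled to partition `φ` exactly
(`φ_d,i = V_i φ / ΣV`), not the fitted curve: measured group volumes can
deviate from a log-normal fit by tens of percent, and the physics consumes
the actual material distribution. The fitted law is kept for synthesis only.
Raw diameters are binned to the group grid by nearest grid point, exact
midpoints resolving to the lower bin (a fixed, documented tie-break rather
than an implementation accident).

Because no tabulated group-volume vector exists for the reference fluid —
only the 7.5 nm group's 1.611% and the 10.57% total are quoted — the
fixtures module constructs a **surrogate** vector: a discretized log-normal
on the twelve-point grid whose median is solved (bracketed root search on
the mass-ratio equation) so the anchor group takes exactly 1.611% and the
groups sum exactly to the total, the residual being absorbed by the
non-anchor groups. It is smooth, unimodal and consistent with both quoted
values, but it is a stand-in, not the measured distribution; files and
functions that carry it say "surrogate".

## Carrier properties

Viscosity through three measured points is fitted with the
Vogel–Fulcher–Tammann law `η = A exp(B/(T−T₀))` — the natural
three-parameter description of a mineral oil's super-Arrhenius thinning —
by closed-form elimination of `T₀` (exact interpolation, reproduction of the
inputs to < 1e-9 relative). Degenerate solutions (non-positive `B`, `T₀`
inside the 0–100 °C evaluation range) and point counts other than three fall
back to an Arrhenius least-squares fit; two equal values give a constant.
Density is a linear fit. Evaluation outside 0–100 °C errors by contract:
these are interpolating models through sparse points, and silent
extrapolation of a VFT law is how one gets negative-viscosity nonsense. The
shipped example triple (75/40/24 mPa·s at 20/40/60 °C) is a plausible
mineral-oil surrogate used in examples and tests, not a measurement.

## Calorimetric estimator

`SAR = c ρ (dT/dt)_max / m_Fe`. The maximal derivative is operationalized as
the steepest sliding least-squares window (default 5 s window, 30 s search
horizon) because pointwise finite differences amplify probe noise
(both are exposed). Two estimator properties worth knowing:

* It is exactly offset-invariant and exact on linear curves, for any window.
* Taking the *maximum* over many noisy windows is selection-biased upward by
  roughly the largest order statistic of the window-slope noise
  (~2 standard errors). With 0.02 K Gaussian probe noise and a 5 s window at
  10 Hz the slope standard error is ≈0.002 K/s, so heating rates below
  ~0.05 K/s (sub-W/g SAR for a 10% fluid) cannot be estimated to 5% this
  way — a real limitation of initial-slope calorimetry at low heating rates,
  not of the implementation. The closure tests therefore run at the
  reference fluid's realistic conditions (`m_Fe = φρ_m ≈ 514 kg/m³`,
  `cρ ≈ 2.2 MJ/(m³K)`, SAR ≈ 2 W/g, i.e. slopes ≈ 0.47 K/s), where 100/100
  seeded curves close within 5%. For slower heating, widen the window.

The synthetic heating curves behind these tests are single-exponential
saturation (`T₀ + slope₀·τ_c(1 − e^{−t/τ_c})`, `τ_c = 300 s`) plus i.i.d.
Gaussian noise. That emulates the linear-plus-saturation shape of real
calorimetry but not probe lag, drift, or convective losses; closure here
demonstrates estimator correctness, not immunity to those effects.

## Reference conditions and problem sizes

The worked reference system throughout the package: maghemite
(`M_d = 400 kA/m`, `ρ_m = 4860 kg/m³`) in mineral oil, `φ = 10.575%` from
magnetometry, twelve groups at 3.5–14.5 nm (1 nm step) with the surrogate
vector anchored at (7.5 nm, 1.611%), 20 °C, VFT viscosity from the surrogate
triple. At 4.3 kA/m and 395 kHz its twelve chord susceptibilities span
0.0006–0.097 and the model SAR is ≈4.6 W/g; at 1–3 kA/m and 402 kHz the
rotating:alternating ratio is exactly 2. Test problem sizes — 1000 random
draws for the power oracle, 5000 diameters for fit recovery, 100 seeds for
calorimetric closure, 601–1201-point τ grids — were chosen as the smallest
sizes at which the corresponding statistical statements are stable.

## Known limitations

* All losses are relaxational; above ~20 nm or ~10 mT the model is the wrong
  physics, and the guard is a warning, not a wall.
* `K_a` and the carrier viscosity are the two inputs the output is most
  sensitive to, and both are usually the least well known; the per-group
  `summary()` exists largely so users can see which groups sit near `ωτ = 1`
  and how a `K_a` shift would move them.
* Monodisperse groups ignore intra-bin dispersion; a 1 nm bin is fine at
  these sizes, but coarser grids bias the power sum because `τ_N` is
  exponential in `d³`.
* The surrogate group vector and carrier triple are stand-ins constrained by
  two quoted values; conclusions that depend on the detailed shape of the
  size distribution should be re-run with measured data
  (`empirical_group_volumes()` + `group_volume_fractions()`).
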