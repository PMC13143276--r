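---
title: "The economics of eye design: model, parameters, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The economics of eye design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyecost)
```

## The question

An eye has two major components that compete for the same budget: the
dioptric apparatus that forms the image, and the photoreceptor array that
captures it. Enlarging the lenses sharpens the image; lengthening the
photoreceptive waveguides (rhabdomeres and rhabdoms) lowers photon shot
noise. Both consume space, materials and energy. `eyecost` models this
competition for three eye types — the neural-superposition (NS) apposition
eye of flies, the fused-rhabdom apposition eye of bees, mantids and
dragonflies, and a hemispherical simple (camera-type) eye — under a single
simplifying restriction: a diurnal eye operating in full daylight, where
photons are plentiful and the binding physiological constraint is the
saturation of transduction units.

## Costs: specific volume and the energy tariff

Costs are measured as *specific volume*, µm³ per steradian of visual
field. For a locally spherical apposition eye region the radius is fixed
by geometry, `R = D/Δφ`; the optics occupy the shell of thickness f′
(focal distance) and the array the shell of depth L beneath it
(`apposition_shell_volumes()`). A simple eye is a hemisphere:
`V_o = (π/3)(DF)³` and `V_tot = (π/3)(DF + L)³`
(`simple_eye_volumes()`). Using volume as the cost proxy assumes that
materials, maintenance energy and carriage cost all scale with volume at
equal rates across tissues — a stated starting assumption, not a result.

The one place that assumption demonstrably fails is the photoreceptor
array, whose specific metabolic rate is exceptionally high. The excess is
charged as an energy surcharge `S_E = K_E·N_vil` proportional to the
microvillus count, because the light-gated conductance — the dominant
energy sink — scales with the number of transduction units. The tariff
K_E converts energy per microvillus into equivalent eye volume by
dividing the 24-hour average oxygen consumption per microvillus by the
animal's 24-hour average specific metabolic rate
(`estimate_energy_tariff()`). With the packaged blowfly constants the
tariff spans 0.13 (12 h flight, 12 h daylight) to 0.52 (2 h flight, 16 h
daylight) µm³ per microvillus; morphospace analyses therefore default to
sweeping K_E over 0–0.64 rather than committing to a point value.

## Benefits: information capacity

The benefit of a configuration is the Shannon capacity of the array,
assembled in the frequency domain from five ingredients:

1. **Scene statistics** (`scene_model()`): a 1/f² spatial power spectrum
   with constant `c_c` normalised so the contrast over the band from one
   cycle per 50° to one cycle per 1.5° equals 0.4 (the local contrast of
   natural scenes viewed through a blowfly-scale eye). `c_c` is fixed
   analytically, `c_c = contrast²/(2π ln(band ratio))`, because the
   closed form exists. The band is kept fixed rather than tracking each
   eye's own sampling limit: the printed normalisation constant is tied
   to this band, and letting the band move with Δφ would silently rescale
   scene power between configurations being compared.
2. **Self-motion**: image angular speeds follow
   `a_v(v) = c_v/(|v|+σ_v)²` with `c_v = σ_v/2` so the density integrates
   to one exactly. σ_v defaults to 1 rad s⁻¹ (saccade-free flight);
   0.29 rad s⁻¹, an earlier published choice, is available as a preset.
   Folding this through the scene spectrum gives the spatio-temporal
   density `S_xyt = (π/2f_r³)·c_c·a_v((π/2)(f_t/f_r))`
   (`spatiotemporal_spectrum()`).
3. **Optical blur** (`optical_model()`): Gaussian angular sensitivity of
   half-width Δρ. Two approximations are provided: `COG` adds the
   diffraction half-width λ/D and the rhabdomere subtense d_rh/f in
   quadrature (a conservative lower bound on optical quality), and `WOM`
   uses 1.26·λ/D, the wave-optics result for a fly eye with its
   longitudinal pupil partly closed in daylight. The 1.26 coefficient is
   a parameter (it falls to 1.14 with a fully closed pupil); only the
   coefficient is used here, not the wave-optics machinery behind it.
   λ defaults to 0.5 µm and is stored in micrometres so spatial
   frequencies are cycles per radian without unit juggling.
4. **Transduction** (`photoreceptor_model()`): at half-saturation each
   photoreceptor transduces `ψ = νL/(2τ_r)` bumps s⁻¹ from its `νL`
   microvilli (ν = 230 µm⁻¹). An NS pixel pools six photoreceptors:
   signal power `(3ψ)²·S_xyt·|m|²|m_t|²|m_d|²`, shot noise `3ψ|m_t|²`
   (uncorrelated across cells, binomial statistics at half-saturation).
   A fused rhabdom or simple-eye rhabdom is equivalent to three fly
   rhabdomeres, halving the transduction units per pixel: the factors
   become `(3ψ/2)²` and `3ψ/2`. The bump filter
   `|m_t|² = (1+(2πτf)²)^{-α}` (τ = 1 ms, α = 3.12; half-power at 79 Hz)
   and latency-dispersion filter `|m_d|² = (1+(2πτ_d f)²)^{-2}`
   (τ_d = 1.4 ms) together put the signal corner near the 55 Hz measured
   in light-adapted blowfly. The cycling time τ_r is not directly
   measured; it defaults to 0.1 s. Because ψ enters signal as ψ² and
   shot noise as ψ, τ_r shifts absolute capacity but moves optima only
   weakly; it is carried in all outputs.
5. **Sampling and aliasing**: a hexagonal lattice samples frequencies up
   to `µ_s = 1/(√3 Δφ)` independent of orientation; shot noise is spread
   uniformly over that disc (area πµ_s²). Spatial frequencies between
   µ_s and a cutoff `f_cut = 3/Δρ` (beyond which the squared MTF is below
   10⁻¹⁵) that survive the blur are aliased into the sampled band and
   treated as noise shared equally across it. Aliased components are
   physically signal components, so they carry the same pixel
   multiplicity and temporal filtering as the signal; treating them as a
   bare ψ² term without the multiplicity would change capacity only
   marginally, but the chosen form keeps the signal and aliasing paths
   dimensionally identical.

Capacity is `H = 2√3 ∫∫ f_r log₂(1+S/N) df_r df_t` in bits sr⁻¹ s⁻¹. The
prefactor 2√3 is pinned by a counting argument: with frequency-independent
S/N, H must equal (pixels per steradian) × log₂√(1+S/N), where a
hexagonal lattice packs `2√3/(3Δφ²)` pixels per steradian. A test holds
the implementation to that closed form.

One modelling choice deserves flagging: the per-pixel transduction-unit
count used in the energy surcharge matches the one used in the signal
path (6 rhabdomere-equivalents per NS ommatidium, 3 per fused or simple
pixel), and is exposed as a parameter. Calibration of K_E from
whole-eye oxygen consumption effectively counted 7 equivalents per NS
ommatidium (including the central R7/8 rhabdom); we keep cost and signal
self-consistent by default rather than surcharging units the signal
model ignores.

## Numerics

* **Capacity integral** (`capacity_control()`): Gauss–Legendre in
  log f_r from µ_s·10⁻⁴ to µ_s (64 nodes). The integrand
  f_r·log₂(1+S/N) vanishes toward the origin despite the 1/f_r³
  spectrum, so no analytic subtraction is needed; tests verify this.
  Temporal integration uses Gauss–Legendre panels splitting [0, 2000 Hz]
  logarithmically (48 nodes each) to resolve the narrow low-frequency
  structure that rigid motion induces at low spatial frequencies, then
  doubles the range outward until a doubling adds < 10⁻⁴ of the total;
  non-convergence warns rather than truncating silently. Everything is
  deterministic — the package contains no randomness. Doubling all node
  counts changes the reference-geometry capacity by ~10⁻⁹ relative, and
  an independent dense Riemann evaluation agrees to < 0.5%.
* **Cost-constraint inversion** (`solve_radius_for_cost()`): total cost
  is strictly increasing in R at fixed (D, L), so bisection between
  `R = f′+L` and a geometrically grown upper bracket converges without
  derivatives; tolerance 10⁻⁹ relative on cost. Simple eyes invert for L
  the same way. A budget below the cost at the minimal radius is an
  infeasible pair — outside the morphospace — and errors as such.
* **Morphospace search** (`performance_surface()`, `optimise_eye()`):
  log-spaced 60×60 default grid over D ∈ [5, 500] µm (to 5 mm for simple
  eyes) and L ∈ [5, 5000] µm, clipped to feasibility, followed by
  Nelder–Mead refinement over (log D, log L) from the grid argmax
  (golden-section over log D for simple eyes). The performance surface
  is a flat-topped ridge, so exact argmax positions on the plateau are
  near-degenerate: ties break deterministically toward smaller L, then
  smaller D (cheaper photoreceptors at equal performance), and
  `high_efficiency_zone()` reports the whole >95% set so sweeps can show
  band envelopes rather than fragile argmax tracks. Occasional jumps of
  the argmax along a cost sweep are genuine plateau-hopping, not
  numerical noise. These grid sizes keep a full nine-combination
  optimisation sweep under two minutes on one CPU while leaving optima
  stable to ~1% under grid refinement.
* **Degenerate inputs**: L = 0 gives H = 0 (no transduction units);
  zero-thickness shells give zero volumes; `f_cut ≤ µ_s` gives zero
  aliasing; all validated by tests.

## The packaged measurements

Two delimited tables under `inst/extdata/` transcribe published
morphological measurements verbatim: 12 NS eye regions from 7 fly
species, and the fused-rhabdom apposition regions of a mantid, dragonflies
and honeybees. The fused table contains 17 rows as printed in its source
(whose accompanying prose counts 16 regions); the transcription keeps
every printed row and the loader documents the discrepancy. Three
dragonfly rows print no F-number; `load_measurements()` fills them from
the nearest row of the same species block and flags them. Checksum tests
pin the shipped files. `empirical_costs()` uses tabulated focal distances
where printed and derives `f′ = F·n_i·D` (F = 2, n_i = 1.34) otherwise;
note that several printed f′ values are not consistent with their own
printed F-numbers (e.g. the robber-fly fovea), so the tabulated f′ always
wins. A separate switch, `simple_eye_uses_f_prime`, exists because the
hemispherical simple-eye volume formula is stated in terms of the focal
length in air f = DF, while the printed simple-eye focal-distance range
implies f′ = F·n_i·D; the default follows the stated formula.

Fitting K_E to these data is deliberately out of scope: K_E is species
specific, the NS table never has more than two regions per species, and
the fused-rhabdom regions within a species are specialised for different
tasks, so a fit would be statistically meaningless.

## What the model does and does not show

```{r example}
g <- eye_geometry("NS", D = 16.5, L = 83, delta_phi = deg_to_rad(5),
                  f_prime = 27)
cost_breakdown(g)
```

Within the model, optimised eyes of every type put a large share of the
budget into the photoreceptor array; apposition optima sit on a flat
ridge whose >95% zone spans a more than threefold range of L at high
tariff; optimum capacity grows sublinearly with budget (exponent ≈ 0.8
for simple eyes, ≈ 0.5 for apposition eyes), so a bit of information
costs more in a larger eye; and the simple eye is the better investment
at every budget. These are statements about a *generic* bright-light
model: one ν, one F-number and one rhabdom(ere) diameter per eye type,
no dark noise or channel noise, no adaptation dynamics, no regional
gradients within an eye, no tracheal air spaces lightening large arrays,
no chromatic or polarisation channels, and photoreceptor temporal
bandwidth fixed at the fully light-adapted blowfly value. Real eye
regions adapted to other light levels or specialised tasks will deviate —
and the flat ridge means they can deviate substantially while staying
within a few percent of maximum capacity.
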