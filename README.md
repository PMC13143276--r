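# eyecost

Optics and photoreceptors compete for the resources invested in an eye.
`eyecost` is an R package for cost–benefit analysis of eye design: it
expresses investments in the dioptric apparatus and the photoreceptor
array in a common currency — **specific volume**, µm³ per steradian of
visual field — links both to the three determinants of image quality
(interommatidial angle Δφ, acceptance angle Δρ, photoreceptor
signal-to-noise ratio), and measures the benefit as **spatio-temporal
information capacity** H in bits sr⁻¹ s⁻¹. Holding total cost fixed, it
searches the morphospace of lens diameter D and rhabdom(ere) length L for
the configuration that maximises H, for neural-superposition (NS) and
fused-rhabdom apposition compound eyes and for a hemispherical simple
eye. It is aimed at visual ecologists and computational neuroscientists
who want to ask "was this eye region worth what it cost?".

## The model in brief

For a locally spherical apposition eye region of radius `R = D/Δφ`, the
optics form a shell of thickness f′ (the focal distance) and the
photoreceptor array the shell of depth L beneath it:

    V_o  = [R³ − (R − f′)³] / 3                µm³ sr⁻¹
    V_ph = [(R − f′)³ − (R − f′ − L)³] / 3     µm³ sr⁻¹

Phototransduction's metabolic cost is converted to an equivalent volume
surcharge `S_E = K_E · N_vil`, where the **energy tariff** K_E (µm³ per
microvillus) is estimated from oxygen-consumption and metabolic-rate
measurements, and `N_vil` counts microvilli per steradian. Total cost is
`C_tot = V_o + V_ph + S_E`.

The benefit side drives a 1/f² natural-scene spectrum, converted to
spatio-temporal power by a long-tailed distribution of image angular
velocities, through Gaussian optical blur of half-width Δρ, hexagonal
sampling with orientation-independent cutoff `µ_s = 1/(√3·Δφ)`, microvillus
shot noise at half-saturation (binomial statistics, `SNR = √N_vil / 2`),
quantum-bump and latency-dispersion temporal filters, and aliasing of
undersampled frequencies treated as noise. Capacity is

    H = 2√3 ∫∫ f_r · log₂(1 + S/N(f_r, f_t)) df_r df_t .

## Worked example

```r
library(eyecost)

# Energy tariff for a fly flying 12 h a day with 12 h of daylight
estimate_energy_tariff(tariff_inputs(T_F = 12, DL = 12))
#> [1] 0.1325153        # ~0.13 um^3 of eye volume per microvillus

# Cost decomposition of the fruit-fly eye (D = 16.5 um, dphi = 5 deg,
# L = 83 um, measured f' = 27 um)
g <- eye_geometry("NS", D = 16.5, L = 83, delta_phi = deg_to_rad(5),
                  f_prime = 27)
cost_breakdown(g)
#> <cost_breakdown> V_o = 8.34e+05, V_ph = 1.254e+06, S_E = 0 um^3/sr
#>   C_tot = 2.088e+06 um^3/sr (60.1% photoreceptor array)

# Information capacity of a mid-sized NS eye region
information_capacity(eye_geometry("NS", D = 25, L = 200,
                                  delta_phi = deg_to_rad(1.5)))
#> <capacity_result> H = 487946 bits/sr/s (mu_s = 22.1 cyc/rad)

# The best NS eye money can buy for 1e9 um^3/sr at tariff 0.16
optimise_eye(1e9, K_E = 0.16, eye_type = "NS")[, c("D", "L", "H", "pct_Cph")]
#>          D        L       H  pct_Cph
#> 1 28.83304 1095.589 1087863 90.05527
```

The optimum allocates ~90% of the budget to the photoreceptor array — the
central result of the analysis: arrays, not lenses, absorb most of an
efficient apposition eye's investment. `performance_surface()` maps the
whole fixed-cost morphospace (a flat-topped ridge whose >95% efficiency
zone spans severalfold changes in L), `sweep_total_cost()` tracks optima
across budgets and tariffs, and `empirical_costs(load_measurements("ns"))`
decomposes the packaged published measurements of 12 fly NS eye regions
(plus 17 fused-rhabdom regions via `"fused"`).

## Command line

```sh
Rscript inst/cli/eyecost.R tariff --tf 12 --dl 12           # 0.13
Rscript inst/cli/eyecost.R cost --eye-type NS --D 16.5 \
        --dphi-deg 5 --L 83 --f-prime 27                     # JSON breakdown
Rscript inst/cli/eyecost.R surface --ctot 4e9 --ke 0.16 --out surface.csv
```

Every file output is accompanied by a `.config.json` sidecar echoing the
fully resolved configuration.

## Further reading

The methods vignette (`vignettes/eye-design-economics.Rmd`) documents the
model assumptions, parameter defaults and units, numerical choices, and
known limitations.
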