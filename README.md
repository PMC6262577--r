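# aqpflux

Stopped-flow permeability kinetics and pH-gating analysis for
aquaglyceroporins.

Aquaglyceroporins (AQP3/7/9/10) conduct water and glycerol across cell
membranes, and their activity is measured by challenging cell
suspensions with hyperosmotic shocks in a stopped-flow fluorimeter: a
self-quenching cytoplasmic dye reports cell volume, and the speed of
shrinkage (impermeant shock) or of shrink-then-reswell (permeant
glycerol shock) encodes the water permeability P<sub>f</sub> and
glycerol permeability P<sub>Gly</sub> (both cm/s). `aqpflux` turns raw
traces into those permeabilities and into the gating statistics layered
on top of them, and post-processes MD coordinate streams for channel
permeation metrics. It was built around a study of pH gating of human
AQP7 expressed in an aquaporin-null yeast, but every parameter of the
setup is configurable.

The core is a two-parameter kinetic model of the cell volume `V` and
internal permeant solute `N_g`:

    dV/dt   = -Pf   * A * vw * (C_out - C_in),   C_in = (N_s + N_g)/(V - beta*V0)
    dN_g/dt =  PGly * A * (C_out,g - N_g/(V - beta*V0))

with the impermeant osmole count `N_s` fixed by isotonic equilibrium
and the Boyle-van't Hoff equilibrium `v_inf = (1-beta)/Lambda + beta`
anchoring the fluorescence-to-volume calibration `v_rel = a*F/F0 + b`.
On top of that sit the derived fits: Hill pH-dependence
(`p = p_min + (p_max-p_min) * 10^(n(pH-pKa)) / (1+10^(n(pH-pKa)))`) for
pK<sub>a</sub>, Arrhenius regression (`Ea = -slope(ln p vs 1/T) * R`),
a four-parameter logistic for IC<sub>50</sub>, percent inhibition, and
relative membrane expression from microscopy line profiles. The MD
module counts complete directional channel passages with a
three-region state machine (bilayer paths excluded by per-monomer
cylinders) and computes the single-file water diffusion constant
`D_w = k_o * z^2 / 2`.

## Worked example

Generate five paired sorbitol/glycerol runs at the hAQP7 pH 7.4 preset
(P<sub>f</sub> = 4.38e-4, P<sub>Gly</sub> = 1.31e-5 cm/s), with 1%
noise and photobleaching, and run the full pipeline — baseline
subtraction, per-run calibration, per-trace two-stage fitting:

```r
library(aqpflux)

report <- run_permeability_pipeline(
  list(scenario = "haqp7_ph74", n_runs = 5, seed = 2019,
       noise_sd_frac = 0.01))
str(report$pf)
#> List of 3
#>  $ mean: num 0.000438
#>  $ sem : num 1.28e-06
#>  $ n   : int 5
report$pgly$mean
#> [1] 1.309152e-05
```

The recovered means sit on the generating truth: the water permeability
comes back as 4.38e-4 cm/s +/- 1.3e-6 (SEM over the 5 per-trace fits)
and the glycerol permeability as 1.31e-5 cm/s. Gating fits work the
same way from tables of permeability versus pH, temperature, or dose:

```r
series <- generate_ph_series(
  list(pka = 5.88, n_hill = 1, p_max = 4.38e-4, p_min = 2.2e-5),
  ph_grid = seq(5, 7.5, by = 0.5),
  spec = generator_spec(seed = 45, noise_sd_frac = 0.05, n_replicates = 4))
fit_hill_ph(series$ph, series$p)$pka
#> [1] 5.871923
```

i.e. the pH at which permeability is half-maximal (the channel's
gating pK<sub>a</sub>) is recovered to within 0.01 pH units here. The complete
analyses — permeability and inhibition across the study conditions,
all gating curves, and the MD permeation summaries — are the numbered
drivers in `analysis/`, which print their findings and write tables
under `results/`.

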