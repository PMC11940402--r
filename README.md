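# gliomapd

Invasiveness profiling of supramaximally resected glioblastoma from
volumetric MRI, built on the proliferation–diffusion growth model.

Glioblastoma (GBM, IDH-wildtype WHO grade 4) infiltrates far beyond its
contrast-enhancing rim. The proliferation–diffusion (Fisher-KPP) model

∂n/∂t = D ∇²n + ρ n(1 − n)

describes the tumor-cell density n (fraction of carrying capacity) through
a diffusion coefficient D (mm²/yr) and proliferation rate ρ (1/yr). Under
this model the T1-gadolinium (CE) and FLAIR abnormalities correspond to the
80% and 16% density levels of a rigid travelling-wave profile, so the two
preoperative volumes determine the invasiveness index

ρ/D = (4π/3)^(2/3) · (6.106 / (V_T2^(1/3) − V_T1^(1/3)))²  [mm⁻²]

— low ρ/D means a long invisible infiltrative margin (diffuse tumor), high
ρ/D a nodular one. The package scores and classifies tumors
(0.55/1.80 mm⁻² default cutoffs, 0.38/1.30 alternative), classifies extent
of resection under the 2022 RANO-resect scheme (SUPR / CR / NTR) and MGMT
promoter methylation (5% dichotomization), validates the ρ/D estimator
against a radial Fisher-KPP finite-volume simulator with known (D, ρ), and
runs the accompanying survival analysis — Kaplan–Meier curves, Cox
proportional-hazards regression with p < 0.2 univariable screening, and the
invasiveness-stratified MGMT effect. A synthetic-cohort generator emulates
a 52-patient supramaximal-resection series (descriptive margins, survival
medians, planted stratum hazard ratios) so the whole pipeline is testable
without clinical data.

## Worked example

Score the cohort-mean volumes (31.4 cc CE, 79.9 cc FLAIR):

```r
library(gliomapd)
ratio <- rho_over_d(vt1 = 31.4 * 1000, vt2 = 79.9 * 1000)  # cc -> mm^3
ratio
#> [1] 0.7297165
classify_invasiveness(ratio)
#> [1] MODERATELY_DIFFUSE
```

0.73 mm⁻² sits between the 0.55 and 1.80 cutoffs: a moderately diffuse
tumor under both published schemes.

Generate the default synthetic cohort and summarize it:

```r
summarize_cohort(generate_cohort(cohort_config(n = 52, seed = 1)))
#> Cohort summary (n = 52, scheme 'baldock')
#> Sex:
#>   M                       33 (63.46%)
#>   F                       19 (36.54%)
#> MGMT:
#>   UNMETHYLATED            16 (30.77%)
#>   METHYLATED              36 (69.23%)
#> Invasiveness:
#>   HIGHLY_DIFFUSE          20 (38.46%)
#>   MODERATELY_DIFFUSE      18 (34.62%)
#>   NODULAR                 14 (26.92%)
#> ...
```

The counts are planted exactly; every record is supramaximal by
construction. At large n the planted survival structure is recoverable by
the package's own inference:

```r
co <- generate_cohort(cohort_config(n = 20000, seed = 1))
stratified_mgmt_analysis(co, "baldock", "os")
#> MGMT (methylated) effect by invasiveness class - endpoint OS, scheme 'baldock'
#>   HIGHLY_DIFFUSE       HR 0.82 (95% CI 0.77-0.86), p = 0.000 (n = 7692)
#>   MODERATELY_DIFFUSE   HR 0.22 (95% CI 0.21-0.24), p = 0.000 (n = 6923)
#>   NODULAR              HR 0.54 (95% CI 0.50-0.57), p = 0.000 (n = 5385)
```

recovering the planted hazard ratios 0.80 / 0.23 / 0.51: MGMT methylation
is protective, most strongly in moderately diffuse tumors.

Validate the estimator against a virtual tumor with known parameters:

```r
sim <- simulate_radial_fkpp(pd_params(D = 10, rho = 10))  # true rho/D = 1
t_last <- max(sim$times)
implied_constant(sim, t_last)   # measured margin constant, vs 6.106
#> [1] 6.016685
recover_ratio(virtual_imaging(sim, t_last))
#> [1] 1.02991
```

## Command line

```sh
Rscript exec/gliomapd generate-cohort --n 52 --seed 1 --out cohort.csv
Rscript exec/gliomapd score --cohort cohort.csv --scheme baldock --out scored.csv
Rscript exec/gliomapd analyze --cohort cohort.csv --out results/
Rscript exec/gliomapd simulate-tumor --D 10 --rho 10 --out tumor
Rscript exec/gliomapd run --n 52 --seed 1 --out results/
```

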