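# sarcomech

Multiscale analysis of how two sarcomere-length parameters shape myocardial
contraction and global left-heart function.

## The problem

In time-varying-elastance (TVE) active myocardium models, fiber stress is the
product of a length-dependent calcium-sensitivity factor and a cosine
activation waveform:

```
sigma_af(t, E_ff) = (T_max / 2) * Ca0^2 / (Ca0^2 + ECa50(E_ff)^2) * (1 - cos omega(t, E_ff))
ECa50(E_ff)       = Ca0_max / sqrt(exp(B * (L - L0)) - 1),   L = Lr * sqrt(2 E_ff + 1)
t_r(L)            = m * L + b
```

Two lengths control the law: the unloaded sarcomere length `Lr` (default
1.85 um) and the zero-active-tension length `L0` (default 1.58 um). Their
difference, the sarcomere length difference `SLD = Lr - L0`, fixes the peak
isometric stress exactly, while `Lr` alone sets the duration of contraction
`DOC = t0 + t_r(Lr)`. This package implements the constitutive laws (active
TVE and Holzapfel-Ogden passive, with closed-form biaxial Cauchy stresses and
a finite-difference energy oracle), the 13-scenario `Lr`/`L0` sweep design
(series S0: vary `Lr`; S1: vary `L0`; S2: co-vary both at fixed SLD), a
reduced closed-loop 0D left-heart surrogate for organ-level phenotypes, and
the downstream analytics: cardiac-function metrics (SV, LVEF, CO), percent
changes, ordinary and piecewise normalized sensitivity
(`S* = (p_base / Y_base) * dY/dp`), strain conversions, and deviation scoring
against normal ranges. It is aimed at cardiac-mechanics modelers studying
sarcomere-level disease mechanisms in silico.

## Worked example

Tissue-level twitch properties across the scenario design:

```r
library(sarcomech)
sw <- tissue_sweep()
head(sw[, c("id", "Lr_um", "L0_um", "SLD_um", "peak_stress_MPa", "doc_s")], 5)
#>    id Lr_um L0_um SLD_um peak_stress_MPa  doc_s
#> 1 S00  1.85  1.58   0.27         0.07227 0.6115
#> 2 S01  1.75  1.58   0.17         0.05540 0.5066
#> 3 S02  1.80  1.58   0.22         0.06483 0.5590
#> 4 S03  1.90  1.58   0.32         0.07813 0.6639
#> 5 S04  1.95  1.58   0.37         0.08275 0.7164
```

Peak stress tracks the SLD (0.0554 MPa at 0.17 um up to 0.0828 MPa at
0.37 um) and the duration of contraction grows affinely with `Lr` (0.51 s of
relaxation at 1.85 um). Cardiac-function metrics and percent changes from the
packaged scenario volume table:

```r
rep <- metric_report(load_reference_metrics())
rep[rep$id %in% c("S00", "S01", "S11"), c("id", "SV_mL", "LVEF_pct", "CO_Lmin", "SV_chg", "LVEF_chg")]
#>    id  SV_mL LVEF_pct CO_Lmin SV_chg LVEF_chg
#> 1 S00 77.541   54.305   4.652     NA       NA
#> 2 S01 67.998   46.211   4.080 -12.31   -14.90
#> 6 S11 35.082   40.875   2.105 -54.76   -24.73
```

S01 (short `Lr`, reduced inotropy) loses 12% of its stroke volume; S11
(short `L0`, diastolic-dysfunction phenotype) loses 55%. Normalized
sensitivities over the `Lr` series quantify the inotropic axis:

```r
sg <- global_sensitivity(load_reference_metrics())
subset(sg, series == "Lr")[, c("metric", "slope", "S_star", "R2")]
#>   metric    slope  S_star     R2
#> 1    EDV  -53.300 -0.6906 0.9873
#> 2    ESV -121.200 -3.4364 0.9923
#> 3     SV   67.900  1.6200 0.9428
#> 4   LVEF   67.804  2.3099 0.9863
#> 5     CO    4.074  1.6200 0.9428
```

ESV is the most `Lr`-sensitive volume (`S* = -3.4`): a 0.1-um increase in
`Lr` drops ESV by about 12 mL while EDV falls only 5 mL, so SV, LVEF and CO
all rise.

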