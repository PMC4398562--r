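# tensorGSVD

Comparative modeling of two patient- and platform-matched but
probe-independent genomic datasets — typically tumor and normal DNA
copy-number profiles — by an exact simultaneous tensor decomposition, with
the downstream machinery to turn the uncovered patterns into survival
predictors.

## The problem and the method

Paired tumor/normal copy-number cohorts measured on the same patients by
the same platforms form two third-order tensors `D1` (K1 tumor probes ×
L patients × M platforms) and `D2` (K2 normal probes × L × M) whose
patient and platform dimensions map one-to-one while the probe dimensions
are independent. The **tensor GSVD** decomposes both at once:

    D_i = R_i ×_a U_i ×_b Vx ×_c Vy ,   i = 1, 2

into LM paired rank-1 subtensors: a dataset-specific probe pattern (an
*arraylet*, column of `U_i`, orthonormal), a shared patient pattern (an
*x-probelet*, unit-norm row of `Vxᵀ`) and a shared platform pattern (a
*y-probelet*, row of `Vyᵀ`). Core entries `R_{i,abc}` weight the
subtensors; the **angular distance**

    Θ_abc = arctan(R_{1,abc} / R_{2,abc}) − π/4  =  θ_a = arctan(σ_{1,a}/σ_{2,a}) − π/4

separates what the datasets share from what distinguishes them: +π/4 is
tumor-exclusive, −π/4 normal-exclusive, 0 common to both (e.g. germline
copy-number features). With M = 1 the decomposition reduces to the matrix
GSVD; with an identity row unfolding of `D1` it reduces to the HOSVD of
`D2`.

Downstream, the package selects the most significant tumor-exclusive,
platform-consistent subtensor; classifies patients by its x-probelet
coefficients (median + 0.5 sMAD rule, with a ±0.1 sMAD robustness scan
against the log-rank test) or, for validation cohorts, by Spearman
correlation with its arraylet; scores classifications by Kaplan–Meier,
log-rank and Cox analyses (including a uni- vs bivariate hazard-ratio
independence check and the three-arm A/B/C group combination); and
segments arraylets into amplified/deleted regions with focality
(< 125 probes) and frequency (> 23% of patients) calls. A seeded
synthetic-cohort generator with planted patterns and proportional-hazards
survival makes the whole pipeline verifiable against known truth.

## Worked example

```r
library(tensorGSVD)

cfg  <- syntheticConfig(K1 = 900, K2 = 880, L = 200, M = 2, seed = 11)
pair <- generatePair(cfg)            # planted tumor-exclusive + common patterns
fit  <- tensorGSVD(pair$D1, pair$D2)
fit
#> TensorGSVD: 900- and 880-probe tensors, 200 patients x 2 platforms
#>   160000 paired subtensor triples (a, b, c)
#>   leading row-mode angular distances: 0.7615 0.4901 0.4867 0.4854 0.4750

sel <- selectSignificantSubtensor(fit, dataset = 1)
#  (a=1, b=1, c=1), P1 = 0.445, theta = 0.762, exclusive = TRUE
platformConsistency(yProbelets(fit)[sel$c, ])   # TRUE

cls  <- classifyByProbelet(xProbelets(fit)[sel$b, ])
clin <- generateClinical(pair$truth$carriers, hazardRatio = 2,
                         censoringRate = 0.2, seed = 11)
robustnessScan(cls$scores, clin$time_months, clin$event)$robust   # TRUE
coxFit(clin$time_months, clin$event,
       data.frame(high = as.integer(cls$labels == "high")))
#>   covariate  coef   hr   se lower upper  p.value
#> 1      high 0.798 2.22 0.17  1.59   3.1 2.58e-06

arr  <- arraylets(fit, 1)[, 1]
callSegments(segmentArraylet(arr, seed = 11), arraylet = arr)
#>   start end n_probes mean_level      call
#> 1     1  90       90    1.1e-04   neutral
#> 2    91 360      270   -5.0e-02   deleted
#> 3   361 495      135    8.2e-05   neutral
#> 4   496 630      135    5.0e-02 amplified
#> 5   631 900      270    3.3e-05   neutral
```

The first arraylet's angular distance sits near +π/4 (tumor-exclusive,
θ = 0.762); its cosine with the planted probe pattern is 0.999. The
selected subtensor's x-probelet classifies the cohort at 96.5% carrier
accuracy; the two groups' Kaplan–Meier median survival is 29 vs 56 months
and the Cox hazard ratio 2.22 (planted: 2.0). The segmentation recovers
exactly the planted deletion (probes 91–360) and amplification
(496–630). The second leading block (θ ≈ 0.49) is noise; the planted
common pattern lies in the degenerate ratio-1 region and is assessed with
`patternAngularDistance()` (see the methods vignette).

A thin command-line wrapper with `simulate` / `decompose` / `classify` /
`survive` / `segment` subcommands is installed at
`inst/scripts/tensorgsvd-cli.R`.

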