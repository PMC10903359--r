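# surveycost

Cost-effectiveness analysis of ecological survey methods, built around the
question a manager actually faces: given a budget, should an estuary be
surveyed by seine net, by a species-specific qPCR assay, or by eDNA
metabarcoding? The package is written for monitoring programs targeting a
rare fish (the motivating case is an endangered estuarine goby) and the
surrounding fish community, but every layer is parameterised and reusable.

## The models

**Cost.** Every method's investment is expressed in technician-hours as a
fixed plus a variable cost per location. For a program of `L` locations,
visiting `k` sites per location and taking `n` samples per site:

```
H = (P + G + A)/L + B + W·V + R  +  k·(v + n·(t·W + E + D + q))
```

with `P` permits, `G` gear, `A` assay development, `B` background
knowledge, `W` crew size, `V` per-visit travel/preparation, `R` reporting,
`v` per-site setup, `t` field time per sample, `E` environmental impact
per sample, `D` data entry, and `q` sequencing per sample. A packaged
parameter table covers qPCR, single-species and community metabarcoding,
and single-species and community seining.

**Detection.** Per-sample detectability γ is estimated by logistic
regression on site and method factors; cumulative detection under effort
is `d = 1 − (1 − γ)^(n·k)`, with confidence limits transformed
monotonically from the limits on γ. `min_samples()` gives the smallest
effort reaching a target `d`.

**Species accumulation.** Collector's curves are built from random
re-orderings of sites and samples, and made scenario-flexible by fitting
the two-scale accumulation model `S = (a + k^z·n^c)/(b + n^c)` by
nonlinear least squares (`z` tracks beta diversity among sites, `c` the
within-site curve).

**Consensus taxonomy.** Metabarcoding ASVs are filtered (< 8 total reads
removed), restricted to maximum-identity hits, constrained to a
plausible-species list (implausible hits reassigned to their closest
plausible relative; several candidates collapsed to their lowest common
taxon), and flagged as exogenous when the source taxon is not estuarine.

**Scenarios.** `detection_cost_curves()`, `richness_cost_curves()` and
`summarize_crossovers()` sweep assay-cost assumptions (A = 0 / 8 / 85),
seine cost relaxations, and program sizes (L = 1 / 10 / 100) into tidy
detection-versus-cost and richness-versus-cost tables.

## Worked example

```r
library(surveycost)

seine <- default_cost_params("goby_seine")
d     <- effort_design(L = 1, k = 1, n = 1)
c(fixed_cost(seine, d), variable_cost(seine, d), total_cost(seine, d))
#> [1] 37.0  4.9 41.9
```

A one-sample seine visit costs 37 fixed hours (permits, gear, a crew of
four on site, reporting) plus 4.9 variable hours — 41.9 h, i.e. 42 h to
the nearest hour. Detection for the eDNA methods at a hard,
low-detectability site (γ = 0.62):

```r
est <- rare_case_estimates()
cumulative_detection(est[est$method == "metabarcode", ], n = 1, k = c(1, 3, 5))
#>   effort         d    ci_low   ci_high
#> 1      1 0.6200000 0.4200000 0.7800000
#> 2      3 0.9451280 0.8048880 0.9893520
#> 3      5 0.9920765 0.9343643 0.9994846

min_samples(0.62, 0.99)  # eDNA:  5 samples for confident detection
#> [1] 5
min_samples(0.25, 0.99)  # seine: 17 hauls for the same confidence
#> [1] 17
```

Five eDNA samples already exceed 99% cumulative detection; seining needs
seventeen hauls. Crossing detection with cost over a 10-location program:

```r
cross <- summarize_crossovers(detection_cost_curves(L = c(1, 10)))
subset(cross, threshold == 0.99 & L == 10)
#>   L threshold      method                 scenario k_at_threshold cost_at_threshold rank cheapest
#>  10      0.99 metabarcode                 baseline              5             29.55    3    FALSE
#>  10      0.99        qPCR          assay_validated              5             21.05    1     TRUE
#>  10      0.99        qPCR          assay_published              5             21.85    2    FALSE
#>  10      0.99        qPCR          assay_developed              5             29.55    3    FALSE
#>  10      0.99       seine                 baseline             17            104.10    7    FALSE
#>  10      0.99       seine           no_environment             17             53.10    6    FALSE
#>  10      0.99       seine no_permit_no_environment             17             51.60    5    FALSE
```

With a validated assay in hand and fixed costs shared over ten locations,
qPCR reaches confident detection cheapest (21 h per location);
metabarcoding follows; seining is last even with its permitting and
environmental costs stripped away.

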