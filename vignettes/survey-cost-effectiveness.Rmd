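---
title: "Comparing survey methods by cost effectiveness: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing survey methods by cost effectiveness: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surveycost)
```

Managers choosing between seine netting, a species-specific qPCR assay, and
eDNA metabarcoding rarely lack evidence that eDNA methods detect well; what
they lack is a way to weigh detection against what each method costs to
field. This package puts the three methods on a common footing: every cost
is expressed in technician-hours, detection is modelled per sample, and the
two are combined into detection-versus-cost and richness-versus-cost
tables.

## The cost model

A sampling program visits `L` locations; at each location it visits `k`
sites, and at each site takes `n` samples. Total investment per location is
a fixed plus a variable part:

$$H = \underbrace{\frac{P+G+A}{L} + B + WV + R}_{\text{fixed}}
    + \underbrace{k\,\bigl(v + n\,(tW + E + D + q)\bigr)}_{\text{variable}}$$

All parameters are hours (or hour-equivalents after converting money at a
technician's rate, `hours_to_dollars()` uses $30/h): `P` permit upkeep, `G`
gear, `A` assay development or validation, `B` background knowledge
(building a plausible-species list), `V` per-visit preparation and travel,
`R` reporting, `v` per-site setup, `t` field time per sample, `E`
environmental impact per sample (seining tramples burrows — the hardest
cost to quantify, hence the scenario switches below), `D` data entry per
sample, `q` sequencing per sample, and `W` a crew multiplier entering both
the visit (`WV`) and the per-sample field time (`tW`). Program-level costs
`P`, `G`, `A` are shared across the `L` locations; everything else recurs
per location. A per-technical-replicate qPCR cost `r` is carried as a field
but defaults to zero — at current prices it is negligible and the cost of
the standard three replicates is folded into `q`.

The packaged parameter table (`default_cost_params()`) describes a typical
single-location estuary visit for five method columns. Two choices deserve
note. The qPCR column stores `A = 8` — the cost of validating a published
assay, the middle of the three assay scenarios (`A = 0` validated, `A = 8`
published, `A = 85` developed from scratch) that the scenario engine
sweeps. And seining carries `W = 4`: a crew whose trained lead counts as
three technicians plus a helper, versus a single technician for water
sampling.

Internal arithmetic is never rounded; reports round to 0.1 h, and the
worked single-visit seine example (41.9 h) rounds to 42 h only for display.

## Detection with effort

Per-sample detectability $\gamma$ is the probability that one sample
detects the target species where it is present. It is estimated by a
binomial GLM with logit link on site and method factors
(`fit_detection_glm()`), by maximum likelihood with no regularisation.
Confidence intervals are Wald intervals on the logit scale transformed to
probabilities; profile likelihood is deliberately out of scope. Cells whose
records are all-0 or all-1 cannot be estimated stably (complete
separation); they are flagged and warned about rather than corrected,
since such easy-to-detect sites are anyway uninformative for planning and
are dropped from rare-case analyses.

Cumulative detection under effort is
$d = 1 - (1-\gamma)^{nk}$, with interval endpoints obtained by applying the
same transform to the interval on $\gamma$ — valid because the transform
is monotone in $\gamma$, and the simplest defensible propagation.
`min_samples()` inverts the formula with exact integer verification at the
boundary, since `ceiling()` on a ratio of logarithms can slip by one unit
at floating-point knife edges.

The shipped rare-case parameterisation (`rare_case_estimates()`) is the
conservative planning scenario: $\gamma = 0.62$ (CI 0.42–0.78) for both
eDNA methods — their detection was statistically indistinguishable, so one
shared estimate encodes that — and $\gamma = 0.25$ (CI 0.12–0.43) for
seining, from the low-detection site of a published multi-site comparison.
At these values five eDNA samples give $d > 0.99$ ("confident" detection
is operationalised at the 99% threshold throughout), whereas seining needs
seventeen.

## Species accumulation

Community comparisons resample a site-by-sample-by-species incidence table
into a collector's curve (`collector_curve()`): at each of 1,000 iterations
(the default; examples in the documentation use 100–200 for speed), `n`
samples are drawn per site, sites are accumulated in random order, and
cumulative richness is recorded at every site count. Read-count tables
reduce to incidence at one read or more, assuming the table has already
passed the ASV read filter; abundance-weighted accumulation is out of
scope. A single integer seed drives both the orderings and the per-site
sample draws, so curves are bit-reproducible.

The curve is made scenario-flexible by fitting the two-scale accumulation
model

$$S(n,k) = \frac{a + k^z n^c}{b + n^c},$$

in which `z` grows with beta diversity among sites, `c` shapes the
within-site collector's curve, and `a`, `b` are constants. Fitting is
nonlinear least squares with every starting value at 1, on the log scale:
`log(median S)` against the log of the model prediction, natural
logarithm. (Which side of the regression is logged, and the base, are
genuinely open choices; fitting log-model to log-median is symmetric in
the residual and is switchable via `log_fit = FALSE`. Medians are the
headline response; means are also carried.) The optimiser is
Levenberg–Marquardt with `a, b ≥ 0` bounds — the model's constants are
meaningless negative and the bound keeps the search out of regions where
`b + n^c ≤ 0` makes the prediction undefined. Non-convergence and
unidentifiability (e.g., a flat single-site curve, or a design with only
`n = 1` where `c` and `b` drop out of the model) are reported as flags and
refused by the scenario layer, never silently propagated.

## Consensus taxonomy for metabarcoding

ASVs with fewer than 8 total reads are removed as low-confidence. For each
surviving ASV, only candidate taxa at the maximum percent identity are
kept. Candidates absent from the user-supplied plausible-species list are
reassigned to their closest plausible relative, formalised as maximum
shared rank-path depth (class → order → family → genus) against the
supplied taxonomy — the procedure is specified by a single canonical
example (a Baja congener reassigned to the local, unsequenced member of
its genus), and shared-path depth is the weakest formalisation consistent
with it. Ties break alphabetically and are reported in the output's `note`
column, keeping the procedure deterministic. One surviving candidate gives
a species-rank assignment; several give their lowest common taxon under
the supplied taxonomy. Note this can differ from what a published table
prints: the packaged community table shows a carp/goldfish ASV at the
order Cypriniformes, while the true lowest common taxon under the packaged
taxonomy is the family Cyprinidae — `consensus_assign()` returns the
latter. Taxa flagged non-estuarine on the plausible list are retained as
valid assignments but marked exogenous (DNA plausibly imported by birds or
currents), and the flag is data-driven, not hard-coded to particular bait
fishes.

The packaged community table encodes cell semantics explicitly: `?` means
unknown or possibly subsumed in an ambiguous coarser-rank ASV and never
counts; `Visual` marks a sighting that is not a seine capture; blank means
not detected. `count_species()` applies the five tallying modes used in
method comparisons (all eDNA detections; species-rank non-exogenous eDNA;
seine captures; and the two new-report filters).

## Scenario tables

`detection_cost_curves()` crosses the method set with the assay scenarios
(`A ∈ {0, 8, 85}`), the seine cost relaxations (full; no `E`; no `P` and
no `E`), and program sizes `L ∈ {1, 10, 100}`, over `k = 1…25` sites at
`n = 1` sample per site — sites yield more detection than replicate
samples, so detection planning varies sites. `richness_cost_curves()`
pairs accumulation fits with the community-survey cost columns under
single-sample (`n = 1`) and double-sample (`n = 2`) strategies. Curves are
emitted as tidy tables (per-location and total program hours both
reported); plotting is left to the user so downstream checks never parse
images. `summarize_crossovers()` ranks method/scenario combinations by the
cost of reaching detection thresholds {0.5, 0.9, 0.95, 0.99} — the set is
an implementation choice, the 0.99 headline threshold is always included.

## What the synthetic data emulate

Real inputs of every kind are generated with known truth. The detection
generator draws independent Bernoulli samples from a site-plus-method
logit structure — exactly the estimation model, so it calibrates the GLM
but cannot reveal lack of fit from overdispersion or site-by-method
interaction, which real surveys may show. The community generator gives
each species a region-wide occupancy state that each site, with
probability `turnover`, replaces with an independent draw; occupied sites
then detect per sample independently. That yields the assumed structure —
within-site samples more alike than between-site samples, with `z` rising
with turnover — but not distance decay, abundance-driven detectability,
or correlated samples. Defaults (pool 40, occupancy 0.5, within-site
detection 0.7, turnover 0.5, 8 sites × 2 samples) mirror a small estuary
survey: 8 sites is a realistic single-location effort, and 2 samples per
site is the double-sample strategy evaluated. Read counts, when
requested, are log-normal (`meanlog 4`, `sdlog 2`) — a documented default
chosen because observed ASV tables span single digits to ~10^5 reads, not
a claim about any particular dataset. The ASV generator builds a small
synthetic taxonomy and plants every consensus rule, including an ASV at
exactly 7 reads to pin the filter boundary. Passing tests on these inputs
show the machinery is correct under its own assumptions; they do not show
the assumptions hold in any particular estuary.

## Problem sizes and numerical notes

Test and example runs use collector curves of 60–200 iterations on pools
of 20–35 species, GLM calibration at 200 samples per cell over 500
replicates, and accumulation-recovery studies of 200 replicates on
50-point curves; the full scenario grid (three program sizes, seven
method/scenario combinations, 25 site counts) regenerates in seconds.
Production analyses should keep the 1,000-iteration default for collector
curves. Seeds are explicit everywhere randomness exists; identical seeds
give identical output to the bit.

Known limitations: no occupancy-model hierarchy (detection conditions on
known presence); no optimisation of effort allocation under a budget —
only enumerated scenarios; no travel-distance or inflation modelling; no
sequence-level simulation; and the accumulation model is fitted to curve
summaries, not to iteration-level resamples, so its standard errors
describe curve fit, not resampling uncertainty.
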