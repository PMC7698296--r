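---
title: "Methods: quantifying scavenger visits to livestock farms from GPS tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying scavenger visits to livestock farms from GPS tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(farmvisits)
```

`farmvisits` implements a complete analysis chain for studies that ask how
individual, spatial and temporal factors drive the use of livestock farms by
GPS-tagged avian scavengers: from raw movement fixes and a farm registry to
merged farm areas, detected visits, kernel home ranges, a
carcass-abandonment imputation submodel, and multimodel-averaged binomial
mixed models of farm use. This vignette documents the statistical model,
each tunable parameter, the numerical choices made where the problem left
room for choice, and what the synthetic-data validation does and does not
demonstrate.

## The spatial unit: merged farm areas

Farms are points on a planar metric (projected) coordinate system. Around
each farm a disk of radius `radius_m` (default **180 m**) delimits the zone
where a grounded bird is plausibly interacting with that farm's carcass
dumping; the default is the lower 95% confidence bound of observed distances
between farm buildings and their dumping sites. Two farms whose disks
intersect — centre distance *strictly* below `2 * radius_m` — belong to the
same *farm area*, and farm areas are the connected components of this
intersection graph (`build_farm_areas()`). A strict inequality at the
threshold keeps the rule consistent with the strict visit criteria below.

The farm-area polygon is the union of the member disks. The package traces
that union exactly as circular arcs (arcs of each circle not covered by any
other member disk, chained at circle-circle intersection points) and
discretizes them at 64 segments per full circle, giving sub-metre boundary
error at r = 180 m. The farm-area **centroid** is the area centroid of this
union polygon — not the mean of member points — because every distance
covariate is defined "from the centroid" of the merged unit. Membership
tests for fixes use the exact disk definition (within `radius_m` of any
member farm point; boundary points count as inside), so detection does not
inherit the polygonization error. Holes in a disk union (a closed ring of
farms around an uncovered pocket) are not traced; with 180 m disks and
realistic farm spacing such configurations do not arise.

A merged area sums its members' herd counts, and its carcass value is the
maximum over members: any member abandoning carcasses makes the whole area a
potential food source. Merging farms with different herd sizes and different
farmer behaviour into one unit is an acknowledged ambiguity of the buffer
approach; the radius parameter is exposed so the sensitivity of the grouping
(e.g. to the upper confidence bound, 393 m) can be explored.

## Visit detection

A GPS fix is a **visit** to a farm area iff all three criteria hold
(`classify_fixes()`):

1. the fix lies inside the area polygon;
2. altitude above ground is strictly below **25 m** — GPS altitude minus the
   DEM ground elevation, interpolated bilinearly at the fix coordinate (the
   DEM shares the GPS vertical datum);
3. instantaneous speed is strictly below **2 m/s**.

Both thresholds are strict ("lower than"). Fixes outside the DEM extent are
excluded and counted. Qualifying fixes collapse to one *visit day* per
(bird, farm area, UTC calendar date); days are UTC because the data span a
single longitude band and no timezone convention is otherwise imposed.

Eligibility: a bird-semester enters the analyses only if **every** month of
the semester has at least **15** days with at least one fix; the binomial
denominator for that bird-semester is its total number of days with data.
Semesters are calendar halves (181/182 vs 184 days), and the first half of
each year is the breeding season (`breeding = 1`) — laying dates spread over
several months, so finer phenological windows are deliberately not modelled.

## Home ranges and core areas

Per bird-semester, `kernel_ud()` evaluates a bivariate Gaussian kernel
density with one kernel of standard deviation `h` per fix. The smoothing
factor defaults to **h = 750 m** and is interpreted as the kernel SD in
metres (the convention of the standard kernel-home-range implementations;
stated explicitly because "smoothing factor" alone carries no units). The
grid uses square cells of `cell_size` (default **100 m**) and pads at least
`4 h` beyond the fix bounding box, so that under 10^-4 of kernel mass can
fall off-grid; the density is then renormalized to exact unit volume.

`isopleth()` returns the smallest-area region holding a given UD volume:
cells sorted by density, accumulated to the level, area = cell count x cell
area. The **95%** isopleth is the home range, the **50%** isopleth the core
area. For a single fix the isopleth is a disk of radius
`h * sqrt(-2 * log(1 - level))` — 1835.8 m (10.59 km^2) at 95% and 883.1 m at
50% for h = 750 — and the grid implementation reproduces these within one
cell ring at 100 m cells; halving the cell size changes areas by under 2%.
Distances to an isopleth (`isopleth_distance()`) are measured to boundary
cell centres, so they are resolution-limited to about half a cell; points
inside the region are exactly 0.

A farm area is a **candidate** food source for a bird-semester iff its
centroid lies inside the 95% isopleth, consistent with the centroid
convention used for every other covariate. UDs are not clipped to any
coastline or study boundary; synthetic extents have none, and clipping for
real coastal data would be a pre-processing step.

## The carcass-abandonment submodel

Interviews give a 0/1 abandonment answer for a minority of farms. A
binomial GLM (logit link) regresses that answer on five farm predictors:
distance to the garbage dump, distance to the nearest supplementary feeding
station, distance to the nearest road, herd size, and distance to the
nearest urban area. All subsets of predictors are fitted
(`select_disposal_model()`), except that two predictors with |Spearman
correlation| > 0.5 never co-occur; models are ranked by AICc with `n` = the
number of interviewed farms; separation-flagged fits are excluded; and
nested models that do not buy a net AICc reduction are discarded (see the
pruning rule below). The fit reports the adjusted explained deviance

D^2_adj = 1 - ((n - 1) / (n - k)) * (dev_residual / dev_null),

the deviance analogue of adjusted R^2 (recorded here because the name alone
does not fix a formula). `impute_carcass()` then leaves interviewed farms at
their observed 0/1 and assigns every other farm its predicted probability:
the resulting *Carcass* covariate deliberately mixes hard 0/1 with
probabilities in (0, 1) and is standardized downstream like any other
continuous covariate, with no prior re-scaling.

## The farm-use models

Responses are proportions with binomial denominators, modelled with logit
link:

- **FARM** — one row per active farm area and semester; numerator = number
  of distinct eligible birds with at least one visit day there; denominator
  = number of eligible tracked birds that semester (regardless of whether
  the farm lies inside their home ranges, since the denominator controls
  for tracking effort, not availability). Random intercepts: farm area and
  semester.
- **VULTURE** (territorial and non-territorial fitted separately) — one row
  per eligible bird-semester and candidate farm; numerator = visit days on
  that farm; denominator = the bird's tracked days. Random intercepts: farm
  area, semester and bird. Visits to farms outside the home range are
  excluded from the table but logged. Nest-based covariates (distance to
  own nest, breeding success) exist only for territorial rows; the distance
  to the nearest *other* occupied territory excludes the bird's own nest
  for territorial birds. Birds that switch status contribute semesters to
  the respective analyses. Breeding success refers to the calendar year
  containing the semester.

Continuous covariates are z-scored within each analysis table (mean 0, SD
1); factors (sex — reference female, breeding, success) are untouched, and
scaling constants are retained for back-transformation.

### Estimation and multimodel inference

Mixed models are estimated by Laplace-approximated maximum likelihood via
`lme4::glmer`. The documented optimizer configuration is lme4's default
nonlinear optimizer with derivative re-checking disabled
(`calc.derivs = FALSE`); on reference fixtures this reproduces the default
configuration's log-likelihood and standard errors to ~1e-6 at half the
cost, and the package requires agreement with an independent
implementation (glmmTMB) within 1e-3 on all coefficients. A fit that emits
a convergence warning is flagged and excluded from ranking; a singular fit
(a variance component at zero) is retained with the zero variance and a
flag.

Candidate models are **all subsets** of the term pool (intercept-only
included) minus collinear pairs (|Spearman rho| > 0.5), plus — for each
admissible subset containing both main effects — that subset with one
two-way interaction of biological interest (at most one interaction per
model; defaults: breeding x distance-to-HPFP, age x distance-to-core-area,
breeding x distance-to-territory). Ranking uses

AICc = -2 logLik + 2k + 2k(k + 1)/(n - k - 1),

with `k` = fixed coefficients + variance components and `n` = number of
rows (the criterion's references leave this choice open; counting variance
components penalizes the random structure consistently across candidates).
Ties are broken by fewer parameters, then lexicographic term order.

**Uninformative parameters**: a model is discarded when some retained model
with strictly lower AICc is nested within it (terms a strict subset) and
the AICc difference is at most 2 — the extra terms did not explain enough
deviance to produce a net AICc reduction. The underlying idea names a
concept, not an algorithm; this nesting-based operationalization (one or
more added parameters, delta <= 2) is the package's fixed rule.

**Averaging**: if the best retained model carries Akaike weight >= 0.9 it is
reported alone. Otherwise all retained models with weight > 0.001 enter a
**full** (zero-substitution) average: each coefficient is weight-averaged
with 0 where the term is absent, the unconditional SE is
`sum_m w_m * sqrt(se_m^2 + (b_m - b_bar)^2)`, relative importance is the
summed weight of models containing the term, and 85% confidence limits are
`estimate +/- 1.4395 * SE` (z at 0.925). Conditional averaging is available
as an option but is not the default, because zero-substitution is the
convention the reported coefficient tables follow.

### Diagnostics

- **VIF** per predictor from OLS regressions of each column on the others.
- **Overdispersion**: sum of squared Pearson residuals over residual
  degrees of freedom (`n - k`).
- **Pseudo-R^2** on the latent scale: marginal =
  var(X beta-hat) / (var(X beta-hat) + sum of random-intercept variances +
  pi^2/3); conditional adds the random-intercept variances to the
  numerator.
- **Moran's I** of per-farm mean Pearson residuals over row-standardized
  k-nearest-neighbour weights (default **k = 15** neighbours), with a
  permutation p-value (999 permutations, fixed seed, one-sided for positive
  autocorrelation by default).
- Descriptive group comparisons use two-sided Mann-Whitney tests (exact
  enumeration when both samples together have at most 12 untied values,
  tie-corrected normal approximation otherwise) and Spearman correlations
  of mid-ranks.

## The synthetic-data generator

Because the analyses' field data (GPS fixes, farm registry, interviews)
cannot be redistributed, the package ships a generator
(`simulate_study()`) whose ground truth is fully known, so every stage is
testable end to end:

- **Farms**: a clustered point process (Gaussian scatter around uniform
  cluster centres, minimum separation 30 m) with lognormal per-semester
  herd sizes; a small fraction of farms goes inactive for one semester.
- **Landscape**: roads as jittered polylines, urban rectangles, one garbage
  dump and two feeding stations (together the highly predictable feeding
  places), and a smooth strictly positive DEM.
- **Disposal**: per-farm Bernoulli draws from a logit-linear model in the
  z-scored farm predictors; the defaults make abandonment more likely far
  from urban areas and far from the dump, matching the direction the
  interview submodel is expected to recover. A configurable 30% of farms
  is "interviewed" (order of the roughly-one-third interview coverage in
  studies of this kind).
- **Programmed visits**: for each eligible bird-semester and each farm area
  within the bird's foraging radius, visit-day counts are drawn from a
  binomial GLMM with the configured coefficients (defaults at the
  magnitudes reported for farm-level analyses: herd 0.44, carcass 0.56,
  road 0.60, HPFP -0.86, breeding 0.49, breeding x HPFP 0.31, on z-scored
  covariates) and independent farm / semester / bird random intercepts
  (SDs 0.5 / 0.3 / 0.4 on the logit scale). Counts are materialized as
  concrete dates among the bird's tracked days.
- **Rendering**: each true visit day gets fixes inside the farm polygon at
  2-15 m above ground and under 1.5 m/s; *decoy* fixes over farms violate
  exactly one criterion each (high pass >= 40 m, fast transit >= 3 m/s, or
  a near miss just outside the polygon), so each criterion is exercised by
  construction; background fixes fill the day at the configured interval
  (1-1200 s; default 1200 s across an 8 h activity window) at cruising
  altitude and speed. Flight between fixes is not modelled — only the
  criterion-relevant fields matter — and altitudes/speeds are jittered
  within their class ranges.

Simulated calendars use real year/semester labels so the breeding-season
rule applies unchanged. Identical configurations produce byte-identical
outputs.

**What passing tests show — and what they do not.** On rendered tracks the
detector provably returns exactly the true visit days (precision = recall
= 1); this validates the detection logic, not the 25 m / 2 m/s thresholds
themselves, whose adequacy is an empirical property of real GPS error and
bird behaviour. Likewise, coefficient recovery on simulated tables
validates the enumerate-fit-prune-average machinery under a correctly
specified model; real data bring overdispersion, spatial structure and
covariate error the generator does not emulate (no correlated random
walks, no weather, no heterogeneous pre-2015 duty cycles, no coastline).

## Numerical choices and problem sizes

- Circle polygonization: 64 segments (area error ~0.1%, centroid error
  well under 1 m at r = 180 m).
- Kernel grids: 100 m cells, padding 4h; isopleth distances are
  resolution-limited to about half a cell.
- GLMM optimizer: lme4 default (nloptwrap) with `calc.derivs = FALSE`;
  determinism given data is part of the fitting contract.
- Permutation tests: 999 permutations, seed recorded.
- The validation suite runs the recovery experiment at 50 replicates of
  2000-row tables with denominator 50 and a 20-model candidate set, and
  the geometry oracle at 100 random instances of up to 200 farms; the
  pipeline demonstration uses ~40 farms, 8 birds and 2 semesters. These
  sizes were chosen so that each property is tested at a scale where its
  failure modes (boundary arcs, rank deficiency, singular fits,
  saturation) actually occur.
- The demonstration pipeline's non-territorial/territorial candidate pools
  default to 5 terms; the full 11-13 term menus are available through
  `run_config()` but enumerate thousands of candidates, which is a batch
  job, not a demo.

## Known limitations

- Holes in disk-union polygons are not traced (see above).
- `isopleth_distance()` and candidate membership are grid-resolution
  limited; covariates derived from them inherit ~cell/2 quantization.
- The betabinomial refit for overdispersed VULTURE-type tables is not
  implemented; the overdispersion diagnostic flags when it would matter.
- Geographic (lon/lat) input is out of scope: coordinates must arrive
  projected in metres.
- Spline correlograms are not provided; Moran's I over k nearest
  neighbours is the autocorrelation diagnostic.
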