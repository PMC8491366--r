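---
title: "Models and methods behind wildcanid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wildcanid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildcanid)
```

wildcanid implements the quantitative workflow of a collar-and-scat field
study of a territorial canid: kernel and minimum-convex-polygon home
ranges, utilization-distribution overlap, group-count density, a
used–available resource-selection function (RSF) with individual-blocked
cross-validation, and a scat-based diet pipeline. This vignette documents
the models, the tunable parameters, the numerical choices, and — because
no field data ship with the package — exactly what the synthetic-data
module emulates and what a passing test does and does not demonstrate.

All spatial functions assume projected planar coordinates in meters.
Nothing here reprojects; feeding longitude/latitude degrees in will produce
nonsense areas.

## Kernel home ranges

The utilization distribution (UD) is a discretized fixed-kernel density:
cell mass proportional to $\sum_i \exp\{-[(x-x_i)^2+(y-y_i)^2]/(2h^2)\}$
at cell centers, normalized to sum to one. The grid covers the data
bounding box expanded by $3h$ on every side (beyond $3h$ a Gaussian kernel
contributes less than 1% of its mass), with square cells and a nominal 256
cells along the longer axis (`grid_n`; tests mostly use 96–192 for speed —
the grid-stability test shows halving the cell size moves 95% areas by
less than 5% for smooth point sets of 100+ fixes).

**Bandwidth.** The reference bandwidth is the bivariate-normal plug-in
rule $h_{ref} = \hat\sigma\, n^{-1/6}$ with
$\hat\sigma = \sqrt{(s_x^2+s_y^2)/2}$. Because the reference rule
over-smooths multimodal ranges, the working bandwidth is
$h = \max(0.8\,h_{ref},\, h_{adhoc})$. The ad hoc bandwidth scans
multipliers $1.00, 0.95, \dots, 0.05$ of $h_{ref}$ (step and floor 0.05)
and keeps the smallest multiple whose 95% isopleth is still a single
8-connected cell set without interior holes (holes are detected by
4-connected flood fill of the complement from the grid border). If the
isopleth is fragmented already at $h_{ref}$ — disjoint range cores far
apart — the scan warns and returns $h_{ref}$. One point worth flagging:
for a single tight Gaussian cluster the scan typically bottoms out near
0.5–0.6, not lower, because at small bandwidths the isopleth picks up
disconnected islands around extreme fixes; the returned multiplier is a
property of the sample, not a constant.

**Isopleths.** The $p$% isopleth is the smallest set of highest-mass
cells whose cumulative mass reaches $p$; area is counted cell area (no
contour interpolation — simple, and convergent under grid refinement).
Ties at the crossing are broken deterministically: cells are ordered by
mass descending then cell index ascending and the scan stops at the first
crossing, so an exactly uniform UD over 100 cells yields exactly 95 cells
at the 95% level. Nesting (50% set inside the 95% set) is automatic from
the shared ordering.

**MCP.** The percent minimum convex polygon removes
$\lfloor(1-p)\,n\rfloor$ points farthest (Euclidean) from the arithmetic
mean of *all* points — the centroid is computed once, not recomputed after
removals — then takes the convex hull. Area is the shoelace formula; the
tests cross-check it against an independent monotone-chain hull.

**Overlap.** The UD overlap index in discrete form is
$\mathrm{UDOI} = A_{overlap} \sum_c UD_a(c)\,UD_b(c) / \text{cell area}$
with $A_{overlap}$ the intersection area of the two level-isopleth cell
sets. The classical identity "identical uniform distributions give
UDOI = 1" holds when the isopleths cover the full support (level 1.0);
at level 0.95 the deterministic tie-break leaves out 5% of an exactly
uniform support, giving 0.95 — a discretization fact, not a bug, and the
test suite checks both the identity at level 1.0 and agreement within 2%
with the closed-form double integral for Gaussian UDs at level 0.95.
Percent area overlap of two (convex) MCPs uses Sutherland–Hodgman
clipping; both directed overlaps and their mean are reported, since
published pair-overlap figures rarely state the direction.

**Filters.** Monthly ranges keep a calendar month only with at least 28
locations spanning at least 14 days. Extraterritorial forays are removed
only through an explicit id + time-window exclusion list; the automatic
mode (default threshold 12 km from the animal's median location) only
*flags* fixes for review — silent deletion of movement data is a
non-goal. Range summaries report mean and $SE = s/\sqrt n$ with the
$n-1$ sample SD, and density is the group-count construction
(groups × adults per group / area), appropriate for saturated
territorial mosaics, not for dispersers.

## Resource selection

The design contrasts presences (case 1, weight 1) with available points
(case 0, weight 1000) sampled uniformly within each animal's 100% MCP at a
1:10 ratio. Covariates are distances (m) to the nearest feature of each
layer, transformed $\log(d+1)$ — the +1 m offset keeps fixes *on* a road
finite — then centered and scaled against the pooled sample. Covariate
pairs with $|r| \ge 0.7$ are reported and the lower-priority member
dropped (`drop_priority`; by default the later column, and in a typical
configuration the coarse land-cover layer is the one sacrificed).

The estimator maximizes the weighted Bernoulli likelihood
$\sum_i w_i [y_i\log\pi_i + (1-y_i)\log(1-\pi_i)]$ with
$\pi = \mathrm{logit}^{-1}(\beta_0 + a_{id} + x(\beta + b_{id}))$. The
per-animal random intercept has its variance *fixed* at $10^6$ rather than
estimated — with a large availability weight this makes each animal's
intercept free, absorbing per-individual availability, which is the
standard recipe for weighted RSF likelihoods — while random-slope
variances are estimated by Laplace approximation (glmmTMB, with the fixed
variance imposed through a mapped-out `theta` entry). A fixed-effects mode
(plain weighted IRLS via `glm`) is provided and is the right tool when
slope variances are near zero, as in simulations where all animals share
one true coefficient vector. Estimates are invariant to rescaling all
weights, and fixed-effect slopes move by well under 1% between
availability weights of 1,000 and 10,000. Wald 95% intervals
($\beta \pm 1.96\,SE$) match the symmetric intervals such models are
reported with. Scores are relative: $\exp(x\hat\beta)$, fixed-effect
slopes only, no intercept.

**Cross-validation.** Each fold withholds one animal entirely, trains on
the rest, and scores the withheld animal's available points. Ten
equal-available-area bins are the score deciles of those available points
(so each bin holds 10% of available area by construction); the
area-adjusted frequency per bin is the withheld *presence* share in the
bin divided by 0.1; Spearman's rho against bin rank measures whether
predicted selection orders realized use. How exactly "equal-area bins" are
built is rarely stated in print; deciles of the withheld availability
sample is this package's documented operationalization. Folds with fewer
than 10 withheld presences are skipped with a warning. Per-fold rho, their
mean, and a pooled rho (Spearman on fold-averaged frequencies) are
reported.

## Scat diet pipeline

Scats are long-format records (scat id, date, dry weight g, taxon, visual
volume percent). Items at or below a 2% volume threshold are trace and
dropped without renormalizing the rest (threshold configurable; 0 disables;
whether field protocols excluded trace before or after estimating the other
volumes is unknowable from published tables, so exclusion is applied once,
up front). Scats left empty drop out entirely.

Biomass consumed allocates each scat's dry weight to items by volume share
and multiplies by the taxon's correction factor (CF, grams ingested per
gram dry residue, from feeding trials); unidentified volume contributes
nothing. Results are scale-invariant in the dry weights. Percent volume is
the per-scat mean including zeros — an aggregate dry-weight-share variant
would weight heavy scats more; the per-scat mean is the standard reading
and the default. Frequency of occurrence counts scats containing the
taxon; category-level occurrence counts a scat once if any member taxon is
present (set union). Seasons default to the dry-forest calendar (Nov–Feb
cool-dry, Mar–May hot-dry, Jun–Oct rainy) by collection month only. The
seasonal contrast is a Pearson chi-square on a seasons × categories
occurrence-count table; a zero expected cell is an error, an expected cell
below 5 a warning. Because published contingency tables rarely state their
category set or degrees of freedom, the chi-square is validated against
closed-form arithmetic, not against a printed statistic.

**Metrics.** Levins $B = 1/\sum p_i^2$ is computed over the finest
(item-level) rows; Horn's
$R_0 = [\sum(p+q)\ln(p+q) - \sum p\ln p - \sum q\ln q]/(2\ln 2)$ over the
union of taxon sets, zero-filled, with $0\ln 0 = 0$. Ungulate availability
shares are density × adult-female-mass, normalized. Jacobs'
$D = (r-p)/(r+p-2rp)$.

Two denominator conventions deserve a note. First, the consumed share $r$
fed to Jacobs' index is each species' biomass percent divided by the
*ungulate category total* of the composition (the category roll-up row
when present), not by the sum over availability species only: published
selection values are reproducible only under the category-total
convention, and it is also the ecologically coherent one (the share of
ungulate biomass, with rare unassessed ungulates still in the
denominator). Second, proportion vectors are accepted when they sum to 1
within $10^{-6}$ (then renormalized) and rejected otherwise;
`as_proportions()` converts percentage columns. When recomputing derived
statistics from published tables, entries printed as "< 0.1" enter at
their printed precision (0.0): imputing unprinted digits moves Levins B by
under 0.02 here but is not this package's convention.

## The synthetic-data module

The generators are first-class, tested code: they define the ground truth
every acceptance property is checked against.

**Landscape.** Roads and streams are random-walk polylines (40 steps,
step length diagonal/40, heading jitter 0.25/0.45 rad), forest and
open-forest patches are 24-gon buffers of random points (radii 2–6% and
4–12% of the short extent side). Nothing about the geometry matters beyond
supporting distance queries; vertices are clamped to the extent.

**Movement.** Fixes are independent draws: proposals from a bivariate
normal (center, $\sigma$) accepted with probability
$\propto \exp(x\beta_{true})$, where $x$ is the standardized
$\log(d+1)$ covariate vector (scaler frozen from a 2,000-point calibration
sample of the availability kernel, acceptance bounded by the calibration
maximum). Independence matches a 6-h fix schedule treated as
autocorrelation-free; no autocorrelated process is simulated, so the
package's RSF tests say nothing about the bias autocorrelation would add.
Acceptance rates below $10^{-4}$ abort — the coefficient vector is too
extreme for the landscape. Timestamps are evenly spaced (default 6 h; 737
fixes span 184 days, the GPS design the defaults emulate).

One statistical subtlety is made explicit rather than hidden: coefficient
*recovery* holds when the design's available points come from the same
normal kernel the proposals came from (`gen_availability`). The field
protocol — uniform sampling in the 100% MCP — is also implemented and is
what `run_rsf` does, but against simulated tracks it adds the log of the
normal availability density to the linear predictor, biasing coefficients
whose distances correlate with distance-from-center. The end-to-end
pipeline test therefore uses a feature-dense landscape where distances
vary on scales much shorter than the home range; the quantitative
recovery criterion (mean $|\hat\beta - \beta_{true}| < 0.1$ over 100
replicates of 5 animals × 500 fixes) uses the kernel availability, which
is the correct contrast for that estimand.

**Scats.** The design goal is exact invertibility of the CF pipeline.
Residue weight per unit biomass of taxon $t$ is $1/CF_t$, so the target
dry-residue composition is $w_t \propto p_t/CF_t$. Literally sampling
items one by one with probability $\propto w_t$ and symmetric volumes does
*not* make the reconstructed biomass unbiased (measured bias up to 15
points for an 18-taxon configuration) because without-replacement
inclusion probabilities are not proportional to the weights. Instead, for
a scat with $k$ items: (1) taxa are selected by systematic
probability-proportional-to-size sampling with closed-form inclusion
probabilities $\pi_t$ ($\pi_t = k w_t/\sum w$, capped at 1 with the
remainder re-solved recursively); (2) volume shares are Dirichlet with
mean $\propto w_t/\pi_t$ within the scat (concentration
`volume_concentration`, default 6 — coarse visual volume estimates are
noisy); (3) the lognormal dry weight (default log-mean $\ln 10$ g, log-sd
0.5 — unreported in the field literature, chosen for plausibility; results
are scale-invariant) is multiplied by the scat's total residue weight
$A(S) = \sum_{t\in S} w_t/\pi_t$, which has expectation 1. Then
$E[\text{dry}_t] \propto w_t$ exactly, so the CF pipeline recovers
$p_t$ in expectation — heavier-residue scats being heavier is also the
physically right coupling. Item counts follow the configured distribution
over 1–5 (default the observed field mix 14.4/38.4/27.4/17.1/2.7%),
truncated to the number of taxa. Items co-occur independently; no prey
association structure is simulated.

**What passing tests show.** Recovery at 10,000 synthetic scats within ±2
points per taxon validates the pipeline's arithmetic and the generator's
inverse construction; it does not validate CF values themselves (those
come from feeding trials), visual-volume estimation error, differential
scat decay, or anything about rainy-season diets.

## Problem sizes and tolerances

The validation battery uses: 10,000 scats for diet recovery (±2 points);
100 replicates of 5 animals × 500 fixes for RSF recovery (sign agreement
≥ 95%, mean absolute error < 0.1 on standardized coefficients);
one strong-selection and twenty null cross-validations (mean rho ≥ 0.8
and |mean rho| < 0.35 respectively); 1,000-point Gaussian samples for the
95%-area check against $\pi\,\chi^2_{2,0.95}(1+h^2)$ within 15% (the
$1+h^2$ factor is the kernel's variance inflation); and 400-cell-per-side
grids for the UDOI quadrature check within 2%. These sizes keep the whole
battery to a few minutes on one core while leaving each tolerance
comfortably above Monte-Carlo noise.

## Known limitations

No autocorrelated movement models (aKDE, dBBMM) — estimates from the
6-h-independence assumption inherit its optimism on real, autocorrelated
tracks. No CRS handling beyond assuming planar meters. Isopleth areas are
counted-cell areas, slightly grid-dependent at coarse resolutions. The
mixed RSF fixes the intercept variance rather than estimating it; this is
deliberate (see above) but means the reported intercept is meaningless.
Dietary overlap against other predators requires their composition tables
as input; none are bundled.
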